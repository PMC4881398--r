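#' Declarative-memory chunks and retrieval cue sets
#'
#' A chunk represents one discourse referent (a noun phrase) held in
#' declarative memory, with the feature values a retrieval request can probe
#' (gender, syntactic category, grammatical role, clause membership) and a
#' creation-time history: the ages, in seconds before the retrieval, of its
#' mentions, most recent last. A cue set is the retrieval request itself:
#' required feature values with the total source activation divided evenly
#' over the cues.
#'
#' @param id chunk label (character scalar).
#' @param gender `"masc"` or `"fem"` (stereotypical gender is encoded
#'   identically to definitional gender).
#' @param role grammatical role, `"subject"` or `"object"`.
#' @param clause `"current"` if the referent is in the clause containing the
#'   retrieval trigger, `"other"` otherwise.
#' @param creation_times numeric vector of mention ages in seconds before the
#'   retrieval; all strictly positive, most recent mention last.
#' @param category syntactic category; referent chunks are nouns.
#' @return `chunk()` returns an object of class `cb_chunk`; `cue_set()` an
#'   object of class `cb_cues`.
#' @examples
#' surgeon <- chunk("surgeon", gender = "masc", role = "subject",
#'                  clause = "current", creation_times = 0.15)
#' cues <- reflexive_cues("masc")
#' cue_match_count(surgeon, cues)
#' @export
chunk <- function(id, gender, role, clause, creation_times, category = "noun") {
  gender <- match.arg(gender, c("masc", "fem"))
  role <- match.arg(role, c("subject", "object"))
  clause <- match.arg(clause, c("current", "other"))
  if (!is.numeric(creation_times) || length(creation_times) == 0L)
    stop("creation_times must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(creation_times)) || any(creation_times <= 0))
    stop("invalid timeline: all creation times must be strictly positive ages",
         call. = FALSE)
  structure(list(id = as.character(id),
                 features = c(gender = gender, category = category,
                              role = role, clause = clause),
                 creation_times = as.numeric(creation_times)),
            class = "cb_chunk")
}

#' @param cues named character vector mapping feature names to required values,
#'   e.g. `c(gender = "masc", category = "noun")`.
#' @param total_source_activation total source activation `W` spread evenly
#'   over the cues.
#' @rdname chunk
#' @export
cue_set <- function(cues, total_source_activation = 1) {
  if (length(cues) == 0L || is.null(names(cues)) || any(names(cues) == ""))
    stop("a cue set needs at least one named cue", call. = FALSE)
  structure(list(cues = cues,
                 weights = stats::setNames(
                   rep(total_source_activation / length(cues), length(cues)),
                   names(cues))),
            class = "cb_cues")
}

#' Retrieval cues issued at a reflexive
#'
#' The full cue set probes gender, category (noun), grammatical role (subject)
#' and clause (the reflexive's own clause). With `structural_only = TRUE` the
#' gender cue is dropped, yielding the strictly-structural variant in which
#' agreement features play no role in the antecedent search.
#'
#' @param gender gender value of the reflexive (`"masc"` for *himself*).
#' @param structural_only drop the gender cue?
#' @inheritParams cue_set
#' @return A `cb_cues` object with 4 cues (3 when `structural_only`).
#' @export
reflexive_cues <- function(gender, structural_only = FALSE,
                           total_source_activation = 1) {
  cues <- c(gender = match.arg(gender, c("masc", "fem")), category = "noun",
            role = "subject", clause = "current")
  if (structural_only) cues <- cues[-1L]
  cue_set(cues, total_source_activation)
}

#' @export
print.cb_chunk <- function(x, ...) {
  cat(sprintf("chunk '%s': %s; mention ages (s): %s\n", x$id,
              paste(names(x$features), x$features, sep = "=", collapse = ", "),
              paste(signif(x$creation_times, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.cb_cues <- function(x, ...) {
  cat(sprintf("retrieval cues {%s}, W_j = %s\n",
              paste(names(x$cues), x$cues, sep = "=", collapse = ", "),
              format(x$weights[[1]])))
  invisible(x)
}

#' Base-level activation of a chunk
#'
#' The power-law base-level learning term
#' \eqn{B = \log \sum_r t_r^{-d}}, summed over the ages \eqn{t_r} of the
#' chunk's mentions: more recent and more frequent mentions yield higher
#' activation.
#'
#' @param chunk a [chunk()].
#' @param params a [model_params()].
#' @return Base-level activation (unitless).
#' @examples
#' p <- model_params()
#' ch <- chunk("x", "masc", "subject", "current", creation_times = 4)
#' base_level_activation(ch, p)  # log(4^-0.5) = -log(2)
#' @export
base_level_activation <- function(chunk, params) {
  t <- chunk$creation_times
  if (any(t <= 0)) stop("invalid timeline: all creation times must be > 0",
                        call. = FALSE)
  log(sum(t^(-params$decay)))
}

#' Fan of a retrieval cue over a chunk set
#'
#' The fan of a cue is the number of chunks whose feature value matches the
#' cue value; larger fan dilutes the strength of association between the cue
#' and any one chunk.
#'
#' @param feature feature name, e.g. `"gender"`.
#' @param value required feature value, e.g. `"masc"`.
#' @param chunks list of [chunk()] objects (the contents of memory).
#' @return Integer count >= 0.
#' @export
fan_of_cue <- function(feature, value, chunks) {
  stopifnot(length(chunks) > 0L)
  sum(vapply(chunks, function(ch) identical(unname(ch$features[[feature]]), value),
             logical(1)))
}

#' Strength of association between a cue and an associated chunk
#'
#' \eqn{S_{ji} = S - \log(\mathrm{fan}_j)}: the maximum associative strength
#' reduced by the log fan of the cue. Negative strengths (fan > e^S) are
#' permitted. A cue with fan 0 is associated with no chunk and contributes
#' strength 0.
#'
#' @inheritParams fan_of_cue
#' @inheritParams base_level_activation
#' @return Associative strength (unitless), decreasing in fan.
#' @export
strength_of_association <- function(feature, value, chunks, params) {
  fan <- fan_of_cue(feature, value, chunks)
  if (fan == 0L) return(0)
  params$max_assoc_strength - log(fan)
}

#' Spreading activation received by a chunk from a cue set
#'
#' Sum of \eqn{W_j S_{ji}} over the cues whose required value the chunk
#' matches; cues the chunk does not match spread nothing to it (mismatches are
#' penalized separately through partial matching).
#'
#' @param cue_set a [cue_set()].
#' @inheritParams fan_of_cue
#' @inheritParams base_level_activation
#' @return Spreading activation (unitless); 0 if the chunk matches no cue.
#' @export
spreading_activation <- function(chunk, cue_set, chunks, params) {
  total <- 0
  for (j in names(cue_set$cues)) {
    if (identical(unname(chunk$features[[j]]), unname(cue_set$cues[[j]]))) {
      total <- total + cue_set$weights[[j]] *
        strength_of_association(j, unname(cue_set$cues[[j]]), chunks, params)
    }
  }
  total
}

#' Partial-matching penalty of a chunk against a cue set
#'
#' Each cue whose required value the chunk does not carry contributes
#' \eqn{P \cdot \mathrm{maxdiff}} (with maxdiff <= 0), letting partially
#' matching chunks compete for retrieval at an activation cost.
#'
#' @inheritParams spreading_activation
#' @return Penalty (unitless, <= 0); 0 when all cues match.
#' @export
mismatch_penalty <- function(chunk, cue_set, params) {
  mismatched <- sum(vapply(names(cue_set$cues), function(j)
    !identical(unname(chunk$features[[j]]), unname(cue_set$cues[[j]])),
    logical(1)))
  params$match_scale * params$max_difference * mismatched
}

#' Total activation of a chunk, with its additive breakdown
#'
#' \eqn{A = B + \sum_j W_j S_{ji} + \sum_k P M_{ki} + \epsilon}: base-level
#' activation plus spreading activation, partial-match penalty and an
#' instantaneous noise term supplied by the caller.
#'
#' @param noise a single draw from the logistic noise distribution with scale
#'   `params$noise_scale` (0 when the scale is 0).
#' @inheritParams spreading_activation
#' @return A one-row data frame with columns `id`, `base`, `spreading`,
#'   `penalty`, `noise`, `total`.
#' @export
total_activation <- function(chunk, cue_set, chunks, params, noise = 0) {
  b <- base_level_activation(chunk, params)
  s <- spreading_activation(chunk, cue_set, chunks, params)
  p <- mismatch_penalty(chunk, cue_set, params)
  data.frame(id = chunk$id, base = b, spreading = s, penalty = p,
             noise = noise, total = b + s + p + noise,
             stringsAsFactors = FALSE)
}

#' Number and names of cues matched by a chunk
#'
#' @inheritParams spreading_activation
#' @return `cue_match_set()` returns the character vector of matched cue
#'   names; `cue_match_count()` its length.
#' @export
cue_match_set <- function(chunk, cue_set) {
  if (length(cue_set$cues) == 0L) return(character(0))
  m <- vapply(names(cue_set$cues), function(j)
    identical(unname(chunk$features[[j]]), unname(cue_set$cues[[j]])),
    logical(1))
  names(cue_set$cues)[m]
}

#' @rdname cue_match_set
#' @export
cue_match_count <- function(chunk, cue_set) length(cue_match_set(chunk, cue_set))

#' Perform a single cue-based retrieval
#'
#' Draws one independent logistic noise value per candidate chunk, computes
#' each candidate's total activation, and returns the candidate with the
#' highest activation provided it reaches the retrieval threshold. The
#' retrieval latency is \eqn{F e^{-A}} of the winning (noisy) activation plus
#' the fixed non-retrieval cost; when no candidate reaches the threshold the
#' retrieval fails and takes the threshold-bound time \eqn{F e^{-\tau}}.
#' Ties in activation (possible only at noise 0) resolve to the first
#' candidate in the supplied order.
#'
#' @param chunks non-empty list of candidate [chunk()]s.
#' @inheritParams spreading_activation
#' @return An object of class `cb_retrieval`: list with `winner_id` (chunk id,
#'   or `"FAILURE"`), `failed` (logical), `latency` (seconds, including the
#'   fixed cost) and `breakdowns` (data frame, one row per candidate).
#' @examples
#' p <- model_params(noise_scale = 0, latency_factor = 0.14, fixed_cost = 0)
#' mem <- encode_condition("sturt_exp1", "b", p)
#' retrieve_once(mem$chunks, mem$cues, p)
#' @export
retrieve_once <- function(chunks, cue_set, params) {
  if (length(chunks) == 0L)
    stop("configuration error: empty candidate set", call. = FALSE)
  noise <- if (params$noise_scale > 0)
    stats::rlogis(length(chunks), location = 0, scale = params$noise_scale)
  else rep(0, length(chunks))
  rows <- lapply(seq_along(chunks), function(i)
    total_activation(chunks[[i]], cue_set, chunks, params, noise[i]))
  breakdowns <- do.call(rbind, rows)
  win <- which.max(breakdowns$total)
  failed <- breakdowns$total[win] < params$retrieval_threshold
  latency <- if (failed)
    params$latency_factor * exp(-params$retrieval_threshold) + params$fixed_cost
  else
    params$latency_factor * exp(-breakdowns$total[win]) + params$fixed_cost
  structure(list(winner_id = if (failed) "FAILURE" else breakdowns$id[win],
                 failed = failed, latency = latency, breakdowns = breakdowns),
            class = "cb_retrieval")
}

#' @export
print.cb_retrieval <- function(x, ...) {
  cat(sprintf("retrieval -> %s in %.1f ms\n", x$winner_id, 1000 * x$latency))
  print(x$breakdowns, digits = 4)
  invisible(x)
}
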