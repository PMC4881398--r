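#' Model parameters for the cue-based retrieval architecture
#'
#' Container for every architecture constant used by the activation calculus
#' and the simulator. The defaults reproduce the canonical parameterization of
#' the ACT-R family of sentence-processing retrieval models: power-law decay 0.5,
#' maximum associative strength 1.5, mismatch-penalty ceiling -1 with unit
#' match scale, retrieval threshold -1.5 and one unit of source activation
#' divided evenly over the retrieval cues. The latency factor and the fixed
#' (non-retrieval) cost are calibrated jointly so that the noiseless
#' accessible-antecedent retrieval in the canonical design lands on the
#' published match/mismatch retrieval times (about 194 and 295 ms); the
#' logistic noise scale 0.3 reproduces the published interference pattern.
#' See the package vignette for the calibration.
#'
#' @param decay base-level decay exponent \eqn{d} (unitless, > 0).
#' @param max_assoc_strength maximum associative strength \eqn{S} (unitless):
#'   the strength of association of a cue with fan 1.
#' @param max_difference similarity of a mismatching feature value (unitless,
#'   must be <= 0). A matching value has similarity 0.
#' @param match_scale weight \eqn{P} applied to each mismatch penalty
#'   (unitless, >= 0).
#' @param noise_scale scale of the logistic instantaneous activation noise
#'   added independently to every chunk at retrieval (unitless, >= 0; 0
#'   disables noise).
#' @param latency_factor latency factor \eqn{F} in seconds: retrieval latency
#'   is \eqn{F e^{-A}} for winning activation \eqn{A}.
#' @param retrieval_threshold minimum activation \eqn{\tau} a chunk must reach
#'   to be retrievable; if no candidate reaches it the retrieval fails.
#' @param total_source_activation total source activation \eqn{W} divided
#'   evenly over the retrieval cues (unitless, > 0).
#' @param per_word_time seconds of encoding time per word; converts word-index
#'   distances into chunk ages.
#' @param fixed_cost constant non-retrieval cost in seconds added to every
#'   reported retrieval time (encoding and rule-firing overhead).
#' @param multi_mention logical; if `TRUE`, referents first mentioned in a
#'   preceding context sentence carry that earlier mention in their
#'   creation-time history in addition to the most recent one.
#' @param sentence1_offset_words word distance assumed between the context
#'   sentence mention and the start of the critical sentence (used only when
#'   `multi_mention = TRUE`).
#'
#' @return An object of class `cb_params`: a validated named list.
#' @examples
#' p <- model_params(noise_scale = 0)
#' p$decay
#' @export
model_params <- function(decay = 0.5,
                         max_assoc_strength = 1.5,
                         max_difference = -1,
                         match_scale = 1,
                         noise_scale = 0.3,
                         latency_factor = 0.244,
                         retrieval_threshold = -1.5,
                         total_source_activation = 1,
                         per_word_time = 0.05,
                         fixed_cost = 0.160,
                         multi_mention = FALSE,
                         sentence1_offset_words = 8) {
  p <- list(
    decay = decay,
    max_assoc_strength = max_assoc_strength,
    max_difference = max_difference,
    match_scale = match_scale,
    noise_scale = noise_scale,
    latency_factor = latency_factor,
    retrieval_threshold = retrieval_threshold,
    total_source_activation = total_source_activation,
    per_word_time = per_word_time,
    fixed_cost = fixed_cost,
    multi_mention = isTRUE(multi_mention),
    sentence1_offset_words = sentence1_offset_words
  )
  class(p) <- "cb_params"
  validate_params(p)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "cb_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("decay", "max_assoc_strength", "max_difference", "match_scale",
              "noise_scale", "latency_factor", "retrieval_threshold",
              "total_source_activation", "per_word_time", "fixed_cost",
              "sentence1_offset_words")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite number", call. = FALSE)
  }
  if (p$decay <= 0) stop("decay must be > 0", call. = FALSE)
  if (p$max_difference > 0) stop("max_difference must be <= 0", call. = FALSE)
  if (p$match_scale < 0) stop("match_scale must be >= 0", call. = FALSE)
  if (p$noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (p$latency_factor <= 0) stop("latency_factor must be > 0", call. = FALSE)
  if (p$total_source_activation <= 0) stop("total_source_activation must be > 0", call. = FALSE)
  if (p$per_word_time <= 0) stop("per_word_time must be > 0", call. = FALSE)
  if (p$fixed_cost < 0) stop("fixed_cost must be >= 0", call. = FALSE)
  p
}

#' @export
print.cb_params <- function(x, ...) {
  cat("Cue-based retrieval model parameters:\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read or write a model-parameter configuration file
#'
#' Parameters round-trip through a plain-text JSON file of key = value pairs,
#' so a full configuration can be versioned alongside an analysis. Unknown
#' keys are rejected; missing keys take their defaults.
#'
#' @param path file path of the JSON configuration.
#' @param params a [model_params()] object.
#' @return `read_params()` returns a `cb_params` object; `write_params()`
#'   invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_params(model_params(noise_scale = 0.2), f)
#' read_params(f)$noise_scale
#' @export
read_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(model_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
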