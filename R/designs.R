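#' Experimental design specifications
#'
#' The three reflexive-binding designs ship as a human-editable JSON file
#' (`system.file("extdata", "designs.json", package = "cuebind")`); users can
#' point `file` at their own schema-compatible file to add designs. Each
#' design records, for the accessible and the inaccessible referent, the
#' grammatical role, clause membership and mention word positions (0-based
#' within the critical sentence), plus the word position of the reflexive.
#'
#' @param file path to a designs JSON file; `NULL` uses the shipped designs
#'   (`sturt_exp1`, `sturt_exp2`, `modified`).
#' @return A named list of design specifications.
#' @examples
#' names(design_specs())
#' @export
design_specs <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "designs.json", package = "cuebind")
  specs <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    for (ref in c("accessible", "inaccessible")) {
      r <- s$referents[[ref]]
      if (is.null(r)) stop("design '", nm, "' is missing referent '", ref, "'",
                           call. = FALSE)
      if (length(r$mention_word_indices) == 0L ||
          any(r$mention_word_indices >= s$reflexive_word_index))
        stop("design '", nm, "': mentions must precede the reflexive", call. = FALSE)
    }
    if (!identical(s$referents$accessible$clause, "current"))
      stop("design '", nm, "': the accessible referent must be clause-mate ",
           "with the reflexive", call. = FALSE)
    if (identical(s$referents$inaccessible$clause, "current"))
      stop("design '", nm, "': exactly one referent may be in the current clause",
           call. = FALSE)
  }
  specs
}

#' Mention timelines of a design
#'
#' Word positions of every referent mention and of the reflexive, read off the
#' design's critical sentence.
#'
#' @param design design name (see [design_specs()]).
#' @inheritParams design_specs
#' @return List with `accessible` and `inaccessible` mention word indices and
#'   `reflexive` word index.
#' @examples
#' default_timelines("modified")
#' @export
default_timelines <- function(design, file = NULL) {
  specs <- design_specs(file)
  if (!design %in% names(specs))
    stop("unknown design: ", design, call. = FALSE)
  s <- specs[[design]]
  list(accessible = as.integer(s$referents$accessible$mention_word_indices),
       inaccessible = as.integer(s$referents$inaccessible$mention_word_indices),
       reflexive = as.integer(s$reflexive_word_index))
}

# Gender assignment implied by a condition label. The accessible noun carries
# a fixed (stereotypical) gender; the reflexive agrees with it in the match
# conditions (a, b) and disagrees in the mismatch conditions (c, d); the
# inaccessible referent carries the reflexive's gender in the interference
# conditions (a, c) and the opposite gender otherwise.
condition_genders <- function(condition, base_gender = "masc") {
  condition <- match.arg(condition, c("a", "b", "c", "d"))
  other <- function(g) if (g == "masc") "fem" else "masc"
  accessible <- base_gender
  reflexive <- if (condition %in% c("a", "b")) accessible else other(accessible)
  inaccessible <- if (condition %in% c("a", "c")) reflexive else other(reflexive)
  list(condition = condition, reflexive = reflexive,
       accessible = accessible, inaccessible = inaccessible)
}

#' Encode a design/condition cell as memory contents and a retrieval request
#'
#' Builds the two candidate antecedent chunks and the reflexive's cue set for
#' one condition of one design. Chunk ages are word distances to the reflexive
#' times `params$per_word_time`; with `params$multi_mention = TRUE`, referents
#' flagged as mentioned in the preceding context sentence additionally carry
#' that older mention, placed `params$sentence1_offset_words` words before the
#' critical sentence.
#'
#' Conditions follow the standard 2 (accessible gender match) x 2
#' (inaccessible gender match) labeling: `"a"` match-interference, `"b"`
#' match, `"c"` mismatch-interference, `"d"` mismatch.
#'
#' @param condition condition label, one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param structural_only drop the gender cue from the retrieval request?
#' @param base_gender stereotypical gender of the accessible noun; swapping it
#'   flips every gender in the cell and leaves all cue-match patterns intact.
#' @inheritParams default_timelines
#' @inheritParams base_level_activation
#' @return List with `chunks` (accessible first, then inaccessible), `cues`
#'   (a [cue_set()]), and `genders`.
#' @examples
#' mem <- encode_condition("sturt_exp1", "a")
#' cue_match_set(mem$chunks[[1]], mem$cues)
#' cue_match_set(mem$chunks[[2]], mem$cues)
#' @export
encode_condition <- function(design, condition, params = model_params(),
                             structural_only = FALSE, base_gender = "masc",
                             file = NULL) {
  specs <- design_specs(file)
  if (!design %in% names(specs)) stop("unknown design: ", design, call. = FALSE)
  condition <- match.arg(condition, c("a", "b", "c", "d"))
  s <- specs[[design]]
  g <- condition_genders(condition, base_gender)

  ages <- function(ref) {
    mentions <- sort(as.integer(ref$mention_word_indices))
    if (params$multi_mention && isTRUE(ref$context_sentence_mention))
      mentions <- c(-params$sentence1_offset_words, mentions)
    # most recent mention last; ages are distances to the reflexive in words
    (s$reflexive_word_index - mentions) * params$per_word_time
  }
  mk <- function(which) {
    ref <- s$referents[[which]]
    chunk(id = which, gender = g[[which]], role = ref$role, clause = ref$clause,
          creation_times = ages(ref))
  }
  list(chunks = list(mk("accessible"), mk("inaccessible")),
       cues = reflexive_cues(g$reflexive, structural_only = structural_only,
                             total_source_activation = params$total_source_activation),
       genders = g)
}

#' Cue-match table of one design across the four conditions
#'
#' Tabulates, for every condition, which retrieval cues each antecedent
#' matches — the match-pattern table that determines the interference
#' predictions of a design.
#'
#' @inheritParams encode_condition
#' @return Data frame with columns `condition`, `referent`, `matched`
#'   (comma-separated cue names) and `n_matched`.
#' @examples
#' cue_match_table("sturt_exp1")
#' @export
cue_match_table <- function(design, params = model_params(),
                            structural_only = FALSE, file = NULL) {
  rows <- lapply(c("a", "b", "c", "d"), function(cond) {
    mem <- encode_condition(design, cond, params, structural_only, file = file)
    do.call(rbind, lapply(mem$chunks, function(ch) {
      m <- cue_match_set(ch, mem$cues)
      data.frame(condition = cond, referent = ch$id,
                 matched = paste(m, collapse = ","),
                 n_matched = length(m), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
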