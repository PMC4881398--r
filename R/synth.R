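#' Configuration for the synthetic fixation generator
#'
#' Describes a synthetic reading experiment: a single-line stimulus layout, a
#' participants-by-items Latin-square assignment of the four conditions, a
#' simple left-to-right gaze process with log-normal fixation durations,
#' occasional short-word skipping and optional regressions from the critical
#' region, and per-condition effect injections used for parameter-recovery
#' testing of the measures:
#' `ffd_shift` adds to the first fixation duration on the critical word,
#' `regress_prob` sets the probability of a first-pass regression from the
#' critical word (followed by a return to it, so it also produces re-reading),
#' and `dwell_shift` adds an extra first-pass refixation of that duration on
#' the critical word, delaying all forward progression.
#'
#' Defaults mirror the scale of the reflexive reading study this toolkit
#' accompanies: 40 participants, 24 items, four conditions rotated by Latin
#' square, a 16-word stimulus with the reflexive as word 12.
#'
#' @param n_participants,n_items design size.
#' @param words stimulus words, left to right.
#' @param critical_word 1-based index of the critical region (the reflexive).
#' @param char_px,space_px layout geometry passed to [region_layout()].
#' @param dur_meanlog,dur_sdlog log-normal fixation duration parameters
#'   (duration in ms).
#' @param skip_prob probability of skipping a word of three or fewer
#'   characters.
#' @param landing_sd,y_sd SD in pixels of the horizontal landing-position and
#'   vertical gaze noise.
#' @param ffd_shift,regress_prob,dwell_shift named numeric vectors over
#'   conditions `a`–`d` (see above); probabilities must lie in `[0, 1]`.
#' @return A validated list of class `cb_synth_config`.
#' @export
synth_config <- function(n_participants = 40, n_items = 24,
                         words = c("The", "tough", "soldier", "that", "Katie",
                                   "treated", "in", "the", "military",
                                   "hospital", "introduced", "himself", "to",
                                   "all", "the", "nurses"),
                         critical_word = 12,
                         char_px = 11, space_px = 11,
                         dur_meanlog = log(200), dur_sdlog = 0.25,
                         skip_prob = 0.25, landing_sd = 4, y_sd = 5,
                         ffd_shift = c(a = 0, b = 0, c = 0, d = 0),
                         regress_prob = c(a = 0.1, b = 0.1, c = 0.1, d = 0.1),
                         dwell_shift = c(a = 0, b = 0, c = 0, d = 0)) {
  conds <- c("a", "b", "c", "d")
  full <- function(v) {
    out <- c(a = 0, b = 0, c = 0, d = 0)
    out[names(v)] <- v
    out
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_items = as.integer(n_items), words = words,
              critical_word = as.integer(critical_word), char_px = char_px,
              space_px = space_px, dur_meanlog = dur_meanlog,
              dur_sdlog = dur_sdlog, skip_prob = skip_prob,
              landing_sd = landing_sd, y_sd = y_sd,
              ffd_shift = full(ffd_shift), regress_prob = full(regress_prob),
              dwell_shift = full(dwell_shift))
  if (cfg$n_participants < 1 || cfg$n_items < 1)
    stop("need at least one participant and one item", call. = FALSE)
  if (cfg$critical_word < 2 || cfg$critical_word > length(words))
    stop("critical_word must index a non-initial stimulus word", call. = FALSE)
  if (any(cfg$regress_prob < 0 | cfg$regress_prob > 1) || cfg$skip_prob < 0 ||
      cfg$skip_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$dur_sdlog < 0 || cfg$landing_sd < 0 || cfg$y_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  class(cfg) <- "cb_synth_config"
  cfg
}

#' Generate a synthetic fixation data set
#'
#' Simulates every participant reading every item once, in a condition
#' determined by the Latin-square rotation `condition = (item + participant)
#' mod 4`. Each trial traverses the layout left to right (short words may be
#' skipped; the first and the critical word never are), with fixation
#' positions jittered around word centers and onsets chained so fixations are
#' ordered and non-overlapping (saccades take no time at measure resolution).
#' At the critical word the configured condition effects are injected.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same seed reproduces the data set exactly.
#' @return List of class `cb_synth_data`: `fixations` (data frame `trial`,
#'   `participant`, `item`, `condition`, `x`, `y`, `onset`, `duration`),
#'   `layout` (a [region_layout()]), and `config`.
#' @examples
#' d <- generate_fixations(synth_config(n_participants = 2, n_items = 4), seed = 1)
#' head(d$fixations)
#' @export
generate_fixations <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "cb_synth_config"))
  if (!is.null(seed)) set.seed(seed)
  layout <- region_layout(config$words, config$char_px, config$space_px)
  centers <- (layout$left + layout$right) / 2
  y_mid <- (layout$top[1] + layout$bottom[1]) / 2
  conds <- c("a", "b", "c", "d")
  crit <- config$critical_word
  trials <- list()
  trial_id <- 0L
  for (p in seq_len(config$n_participants)) {
    for (i in seq_len(config$n_items)) {
      trial_id <- trial_id + 1L
      cond <- conds[((i + p) %% 4L) + 1L]
      word_seq <- numeric(0); dur_seq <- numeric(0)
      for (k in seq_along(config$words)) {
        skip <- k != 1L && k != crit && nchar(config$words[k]) <= 3 &&
          stats::runif(1) < config$skip_prob
        if (skip) next
        d <- stats::rlnorm(1, config$dur_meanlog, config$dur_sdlog)
        if (k == crit) d <- d + config$ffd_shift[[cond]]
        word_seq <- c(word_seq, k); dur_seq <- c(dur_seq, d)
        if (k == crit) {
          if (config$dwell_shift[[cond]] > 0) {
            word_seq <- c(word_seq, crit)
            dur_seq <- c(dur_seq, config$dwell_shift[[cond]])
          }
          if (stats::runif(1) < config$regress_prob[[cond]]) {
            back <- max(1L, crit - 2L)
            word_seq <- c(word_seq, back, crit)
            dur_seq <- c(dur_seq,
                         stats::rlnorm(2, config$dur_meanlog, config$dur_sdlog))
          }
        }
      }
      n <- length(word_seq)
      x <- centers[word_seq] + stats::rnorm(n, 0, config$landing_sd)
      y <- y_mid + stats::rnorm(n, 0, config$y_sd)
      onset <- c(0, cumsum(dur_seq))[seq_len(n)]
      trials[[trial_id]] <- data.frame(
        trial = trial_id, participant = p, item = i, condition = cond,
        x = x, y = y, onset = onset, duration = dur_seq,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fixations = do.call(rbind, trials), layout = layout,
                 config = config), class = "cb_synth_data")
}

#' @export
print.cb_synth_data <- function(x, ...) {
  cat(sprintf("synthetic reading data: %d fixations, %d trials (%d x %d), %d words\n",
              nrow(x$fixations), length(unique(x$fixations$trial)),
              x$config$n_participants, x$config$n_items,
              length(x$config$words)))
  invisible(x)
}
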