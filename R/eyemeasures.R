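#' Build a single-line word-box layout
#'
#' Constructs the per-word bounding boxes of a one-line text display from word
#' strings, assuming a fixed-width font. Boxes are half-open `[left, right)`
#' pixel intervals separated by one space width.
#'
#' @param words character vector of the displayed words, left to right.
#' @param char_px pixel width of one character.
#' @param space_px pixel width of the inter-word space.
#' @param x0 left edge of the first word.
#' @param top,bottom pixel extent of the text line (y grows downward).
#' @return Data frame of class `cb_layout`: `word`, `word_index` (1-based),
#'   `left`, `right`, `top`, `bottom`.
#' @examples
#' region_layout(c("The", "surgeon", "slept"))
#' @export
region_layout <- function(words, char_px = 11, space_px = 11, x0 = 20,
                          top = 580, bottom = 600) {
  stopifnot(length(words) > 0, char_px > 0, space_px > 0, bottom > top)
  w <- nchar(words) * char_px
  left <- x0 + c(0, cumsum(w + space_px))[seq_along(words)]
  structure(data.frame(word = words, word_index = seq_along(words),
                       left = left, right = left + w, top = top,
                       bottom = bottom, stringsAsFactors = FALSE),
            class = c("cb_layout", "data.frame"))
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout),
            all(c("word_index", "left", "right", "top", "bottom") %in% names(layout)))
  layout <- layout[order(layout$left), ]
  if (any(layout$right <= layout$left)) stop("word boxes must have right > left", call. = FALSE)
  if (nrow(layout) > 1 &&
      any(layout$left[-1] <= layout$right[-nrow(layout)]))
    stop("word boxes must be non-overlapping, left to right, with spaces between",
         call. = FALSE)
  layout
}

#' Assign fixations to words
#'
#' Maps each fixation to a word of a single-line layout, or discards it:
#' fixations inside a word box (extended `vertical_margin` pixels above and
#' below the line) belong to that word; fixations in the blank space between
#' two words are split at the midpoint — the first half goes to the preceding
#' word, the second half to the following word; everything else (beyond the
#' line ends or outside the vertical band) is discarded, never an error.
#'
#' @param fixations data frame with at least `x` and `y` (pixels).
#' @param layout a [region_layout()] data frame.
#' @param vertical_margin pixels above/below the line still counted as on the
#'   line.
#' @return `fixations` with an integer `word_index` column (`NA` = discarded).
#' @export
assign_fixations <- function(fixations, layout, vertical_margin = 30) {
  layout <- validate_layout(layout)
  n <- nrow(layout)
  # breaks: first word's left edge, the inter-word midpoints, last right edge;
  # a word's horizontal catchment spans its box plus the near halves of the
  # adjacent spaces
  breaks <- c(layout$left[1],
              if (n > 1) (layout$right[-n] + layout$left[-1]) / 2,
              layout$right[n])
  idx <- findInterval(fixations$x, breaks, rightmost.closed = FALSE)
  idx[idx < 1L | idx > n] <- NA_integer_
  ok <- !is.na(idx)
  if (any(ok)) {
    top <- layout$top[idx[ok]] - vertical_margin
    bot <- layout$bottom[idx[ok]] + vertical_margin
    bad <- fixations$y[ok] < top | fixations$y[ok] > bot
    idx[ok][bad] <- NA_integer_
  }
  fixations$word_index <- layout$word_index[idx]
  fixations
}

# measures for one trial's assigned fixations (single data frame, ordered by
# onset) at one region (word index)
trial_region_measures <- function(fix, region) {
  fix <- fix[order(fix$onset), ]
  fix <- fix[!is.na(fix$word_index), ]
  na_row <- data.frame(FFD = NA_real_, FPRT = NA_real_, RRT = NA_real_,
                       TRT = NA_real_, FPRP = NA_real_, RRP = 0)
  if (nrow(fix) == 0L) return(na_row)
  in_reg <- which(fix$word_index == region)
  if (length(in_reg) == 0L) return(na_row)
  first <- in_reg[1]
  total <- sum(fix$duration[in_reg])
  # first pass exists only if the region was not skipped: no fixation on a
  # later word before the region's first fixation
  if (first > 1L && any(fix$word_index[seq_len(first - 1L)] > region)) {
    return(data.frame(FFD = NA_real_, FPRT = NA_real_, RRT = total,
                      TRT = total, FPRP = NA_real_, RRP = as.numeric(total > 0)))
  }
  # maximal run of consecutive region fixations from first entry to first exit
  run_end <- first
  while (run_end < nrow(fix) && fix$word_index[run_end + 1L] == region)
    run_end <- run_end + 1L
  fp <- first:run_end
  ffd <- fix$duration[first]
  fprt <- sum(fix$duration[fp])
  rrt <- sum(fix$duration[setdiff(in_reg, fp)])
  fprp <- if (run_end < nrow(fix)) as.numeric(fix$word_index[run_end + 1L] < region) else 0
  data.frame(FFD = ffd, FPRT = fprt, RRT = rrt, TRT = fprt + rrt,
             FPRP = fprp, RRP = as.numeric(rrt > 0))
}

#' Reading-time and regression measures for one region
#'
#' Computes the standard region-based measures from assigned fixations, per
#' trial: first fixation duration (FFD, the first fixation of the first pass),
#' first-pass reading time (FPRT, all fixations of the first pass), re-reading
#' time (RRT, all region fixations after the first pass), total reading time
#' (TRT = FPRT + RRT), first-pass regression probability (FPRP, 1 iff the
#' saccade leaving the first pass lands on an earlier word) and re-reading
#' probability (RRP, 1 iff RRT > 0). The first pass is the maximal run of
#' consecutive fixations in the region starting at its first fixation,
#' provided no later word was fixated beforehand; if the region was skipped
#' during first pass, FFD/FPRT/FPRP are missing and all region fixations
#' count as re-reading. A region never fixated yields missing duration
#' measures (not zeros) and RRP = 0.
#'
#' @param fixations data frame with columns `trial`, `x`, `y`, `onset`,
#'   `duration` (ms); any of `participant`, `item`, `condition` are carried
#'   through. If no `word_index` column is present, fixations are first
#'   assigned via [assign_fixations()].
#' @param layout a [region_layout()]; only needed when fixations are not yet
#'   assigned.
#' @param region word index of the region of interest (e.g. the reflexive).
#' @return Data frame, one row per trial: id columns plus `FFD`, `FPRT`,
#'   `RRT`, `TRT` (ms), `FPRP`, `RRP`.
#' @export
compute_measures <- function(fixations, region, layout = NULL) {
  if (!"word_index" %in% names(fixations)) {
    if (is.null(layout)) stop("need a layout to assign fixations first", call. = FALSE)
    fixations <- assign_fixations(fixations, layout)
  }
  if (!"trial" %in% names(fixations)) fixations$trial <- 1L
  ids <- intersect(c("trial", "participant", "item", "condition"), names(fixations))
  pieces <- lapply(split(fixations, fixations$trial), function(tr) {
    if (nrow(tr) == 0L) return(NULL)
    cbind(tr[1, ids, drop = FALSE], trial_region_measures(tr, region))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Cumulative forward progression from a region
#'
#' Tracks how far the eyes have progressed, in pixels, to the right of the
#' first fixation in the region of interest, sampled on a fixed time grid
#' starting at that fixation's onset. Only forward movements change the value;
#' regressions and fixations leave it unchanged, so the curve is monotonically
#' non-decreasing and starts at 0. Between a saccade's start and the landing
#' fixation's onset the pre-saccade value is carried forward.
#'
#' @param fixations one trial's fixations with `x`, `onset`, `duration` and
#'   `word_index` columns (see [assign_fixations()]), ordered by onset.
#' @param region word index of the region of interest.
#' @param window length of the sampled interval in ms.
#' @param dt grid spacing in ms; the default 2-ms grid over 1000 ms gives 501
#'   samples.
#' @return Object of class `cb_progression`: list with `time` (ms after first
#'   fixation in the region), `distance` (pixels), `origin_x`, `origin_onset`.
#'   `NULL` if the region was never fixated.
#' @export
cumulative_progression <- function(fixations, region, window = 1000, dt = 2) {
  fixations <- fixations[order(fixations$onset), ]
  hit <- which(!is.na(fixations$word_index) & fixations$word_index == region)
  if (length(hit) == 0L) return(NULL)
  first <- hit[1]
  sub <- fixations[first:nrow(fixations), ]
  x0 <- sub$x[1]; t0 <- sub$onset[1]
  disp <- cummax(pmax(0, sub$x - x0))
  grid <- seq(0, window, by = dt)
  idx <- findInterval(t0 + grid, sub$onset)
  structure(list(time = grid, distance = disp[idx], origin_x = x0,
                 origin_onset = t0), class = "cb_progression")
}

#' Progression curves for a whole data set
#'
#' Applies [cumulative_progression()] per trial and returns the curves in long
#' format, carrying trial identifiers; trials that never fixate the region
#' contribute no curve.
#'
#' @inheritParams compute_measures
#' @inheritParams cumulative_progression
#' @return Data frame: id columns plus `time` (ms) and `distance` (px).
#' @export
progression_table <- function(fixations, region, layout = NULL,
                              window = 1000, dt = 2) {
  if (!"word_index" %in% names(fixations)) {
    if (is.null(layout)) stop("need a layout to assign fixations first", call. = FALSE)
    fixations <- assign_fixations(fixations, layout)
  }
  if (!"trial" %in% names(fixations)) fixations$trial <- 1L
  ids <- intersect(c("trial", "participant", "item", "condition"), names(fixations))
  pieces <- lapply(split(fixations, fixations$trial), function(tr) {
    pc <- cumulative_progression(tr, region, window, dt)
    if (is.null(pc)) return(NULL)
    cbind(tr[rep(1, length(pc$time)), ids, drop = FALSE],
          data.frame(time = pc$time, distance = pc$distance))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Condition-difference curves of cumulative progression
#'
#' Averages the progression curves within each condition at every timestamp
#' and differences the averages to produce the three effect curves of the
#' 2 x 2 design: mismatch (mean of conditions c, d minus mean of a, b),
#' match-interference (a minus b) and mismatch-interference (c minus d). A
#' negative value means the condition of interest has progressed less (is
#' being read more slowly) than its baseline. The 95% band pools the
#' per-timestamp standard errors over trials; because trials are pooled over
#' participants and items, the band underestimates between-participant and
#' between-item variance and is exploratory only.
#'
#' @param progressions long-format curves from [progression_table()], with a
#'   `condition` column using labels `"a"`–`"d"`.
#' @return Data frame: `effect` (`mismatch`, `match_interference`,
#'   `mismatch_interference`), `time`, `difference` (px), `lower`, `upper`.
#' @export
progression_difference <- function(progressions) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% progressions$condition))
    stop("progressions must contain curves for all four conditions", call. = FALSE)
  agg <- stats::aggregate(distance ~ condition + time, data = progressions,
                          FUN = function(v) c(m = mean(v),
                                              se = stats::sd(v) / sqrt(length(v))))
  agg <- cbind(agg[c("condition", "time")], as.data.frame(agg$distance))
  agg$se[is.na(agg$se)] <- 0
  wide_m <- stats::reshape(agg[c("condition", "time", "m")], idvar = "time",
                           timevar = "condition", direction = "wide")
  wide_s <- stats::reshape(agg[c("condition", "time", "se")], idvar = "time",
                           timevar = "condition", direction = "wide")
  m <- function(cond) wide_m[[paste0("m.", cond)]]
  s <- function(cond) wide_s[[paste0("se.", cond)]]
  build <- function(effect, diff, se) {
    data.frame(effect = effect, time = wide_m$time, difference = diff,
               lower = diff - 1.96 * se, upper = diff + 1.96 * se,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    build("mismatch",
          (m("c") + m("d")) / 2 - (m("a") + m("b")) / 2,
          sqrt(s("a")^2 + s("b")^2 + s("c")^2 + s("d")^2) / 2),
    build("match_interference", m("a") - m("b"), sqrt(s("a")^2 + s("b")^2)),
    build("mismatch_interference", m("c") - m("d"), sqrt(s("c")^2 + s("d")^2)))
  out <- out[order(out$effect, out$time), ]
  rownames(out) <- NULL
  out
}

#' Nested contrast matrix for the 2 x 2 reflexive design
#'
#' Three centered contrasts over the conditions (a, b, c, d), with the two
#' interference contrasts nested within the match/mismatch pairs and signs
#' chosen so that a positive coefficient on a reading-time measure means the
#' effect goes in the model-predicted direction: mismatch
#' (−1/2, −1/2, +1/2, +1/2), match-interference (+1/2, −1/2, 0, 0) and
#' mismatch-interference (0, 0, −1/2, +1/2) — the last is reversed because
#' the mismatch-interference condition is predicted to be read faster.
#'
#' @return 4 x 3 numeric matrix, rows named `a`–`d`, columns `mismatch`,
#'   `match_interference`, `mismatch_interference`; every column sums to 0.
#' @examples
#' drop(crossprod(nested_contrast_matrix(), c(198, 194, 274, 295)))
#' @export
nested_contrast_matrix <- function() {
  m <- cbind(mismatch = c(-0.5, -0.5, 0.5, 0.5),
             match_interference = c(0.5, -0.5, 0, 0),
             mismatch_interference = c(0, 0, -0.5, 0.5))
  rownames(m) <- c("a", "b", "c", "d")
  m
}

#' Model-ready table of measures with nested contrasts
#'
#' Joins the per-trial measures with the nested contrast codes, a centered
#' trial predictor, and log-transformed duration measures, ready for a linear
#' mixed model fit (fitting itself is left to the user's modeling package).
#'
#' @param measures output of [compute_measures()] with a `condition` column.
#' @return The input with columns `c_mismatch`, `c_match_interference`,
#'   `c_mismatch_interference`, `trial_c`, and `log_FFD`, `log_FPRT`,
#'   `log_RRT`, `log_TRT` (log of positive durations, `NA` otherwise).
#' @export
measures_model_table <- function(measures) {
  if (!"condition" %in% names(measures))
    stop("measures need a 'condition' column", call. = FALSE)
  cm <- nested_contrast_matrix()
  idx <- match(measures$condition, rownames(cm))
  if (anyNA(idx)) stop("conditions must be labeled a-d", call. = FALSE)
  for (j in colnames(cm)) measures[[paste0("c_", j)]] <- cm[idx, j]
  measures$trial_c <- if ("trial" %in% names(measures))
    measures$trial - mean(measures$trial) else 0
  for (v in c("FFD", "FPRT", "RRT", "TRT")) {
    if (v %in% names(measures))
      measures[[paste0("log_", v)]] <-
        ifelse(!is.na(measures[[v]]) & measures[[v]] > 0, log(measures[[v]]), NA_real_)
  }
  measures
}
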