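#' Monte-Carlo simulation of one design/condition cell
#'
#' Runs `n_runs` independent retrievals at the reflexive for one condition of
#' one design and summarizes the outcomes: the percentage of runs in which the
#' grammatically inaccessible antecedent was retrieved (the retrieval-error
#' rate), the mean and SD of the retrieval time over successful retrievals,
#' and the number of retrieval failures (no candidate reached the threshold;
#' failures count toward `n_runs` but are excluded from the latency summary).
#'
#' The deterministic activation components are computed once per cell and the
#' per-run logistic noise is drawn in the same order as sequential
#' [retrieve_once()] calls would draw it, so under a common seed the two
#' routes produce identical run sequences.
#'
#' @param n_runs number of simulated retrievals.
#' @param seed integer seed fixing the RNG stream (`NULL` leaves the RNG
#'   state untouched).
#' @inheritParams encode_condition
#' @return A one-row data frame: `design`, `condition`, `n_runs`, `error_pct`,
#'   `mean_latency_ms`, `sd_latency_ms`, `failure_count`.
#' @examples
#' simulate_condition("sturt_exp1", "b", n_runs = 100, seed = 1)
#' @export
simulate_condition <- function(design, condition, params = model_params(),
                               n_runs = 1000, seed = NULL,
                               structural_only = FALSE, base_gender = "masc",
                               file = NULL) {
  stopifnot(n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  mem <- encode_condition(design, condition, params, structural_only,
                          base_gender, file)
  k <- length(mem$chunks)
  det <- vapply(mem$chunks, function(ch)
    base_level_activation(ch, params) +
      spreading_activation(ch, mem$cues, mem$chunks, params) +
      mismatch_penalty(ch, mem$cues, params), numeric(1))
  noise <- if (params$noise_scale > 0)
    matrix(stats::rlogis(k * n_runs, 0, params$noise_scale), nrow = k)
  else matrix(0, nrow = k, ncol = n_runs)
  totals <- det + noise
  winner <- max.col(t(totals), ties.method = "first")
  a_win <- totals[cbind(winner, seq_len(n_runs))]
  failed <- a_win < params$retrieval_threshold
  latency <- params$latency_factor * exp(-a_win) + params$fixed_cost
  ok <- !failed
  errors <- ok & winner == 2L   # chunk 2 is the inaccessible antecedent
  data.frame(design = design, condition = condition, n_runs = n_runs,
             error_pct = 100 * sum(errors) / n_runs,
             mean_latency_ms = if (any(ok)) 1000 * mean(latency[ok]) else NA_real_,
             sd_latency_ms = if (sum(ok) > 1) 1000 * stats::sd(latency[ok]) else 0,
             failure_count = sum(failed), stringsAsFactors = FALSE)
}

# deterministic substream seed for a (cell, condition) pair; kept < 2^31
substream_seed <- function(seed, cell, cond_idx) {
  as.integer((as.numeric(seed) + 7919 * cell + 104729 * cond_idx) %% 2147483647)
}

# substream key from a sweep cell's parameter values (not its grid position),
# so sweep results do not depend on grid ordering or composition
cell_key <- function(noise, max_assoc_strength, max_difference) {
  (abs(round(noise * 1e5)) * 131 + abs(round(max_assoc_strength * 1e5)) * 137 +
     abs(round(max_difference * 1e5)) * 139) %% 2147483647
}

#' Simulate all four conditions of a design
#'
#' @inheritParams simulate_condition
#' @return Four-row data frame of per-condition summaries (conditions
#'   `"a"`–`"d"`), as from [simulate_condition()]. Each condition runs on a
#'   deterministic substream derived from `seed`.
#' @examples
#' simulate_design("sturt_exp1", n_runs = 200, seed = 1)
#' @export
simulate_design <- function(design, params = model_params(), n_runs = 1000,
                            seed = NULL, structural_only = FALSE,
                            base_gender = "masc", file = NULL) {
  conds <- c("a", "b", "c", "d")
  do.call(rbind, lapply(seq_along(conds), function(i)
    simulate_condition(design, conds[i], params, n_runs,
                       seed = if (is.null(seed)) NULL else substream_seed(seed, 0L, i),
                       structural_only = structural_only,
                       base_gender = base_gender, file = file)))
}

#' Derived mismatch and interference effects of a design
#'
#' Collapses the four condition summaries of one design into the five standard
#' effects, oriented so the model's predicted pattern is E1–E4 positive and E5
#' negative:
#' \itemize{
#'   \item E1 mismatch effect on retrieval errors:
#'     mean errors (c, d) − mean errors (a, b), percentage points;
#'   \item E2 interference effect on retrieval errors:
#'     mean errors (a, c) − mean errors (b, d), percentage points;
#'   \item E3 mismatch effect on retrieval times:
#'     mean RT (c, d) − mean RT (a, b), ms;
#'   \item E4 match-interference effect: RT(a) − RT(b), ms;
#'   \item E5 mismatch-interference effect: RT(c) − RT(d), ms.
#' }
#'
#' @param summaries data frame with one row per condition `"a"`–`"d"` of a
#'   single design, as returned by [simulate_design()].
#' @return Data frame with columns `effect` (`E1`–`E5`), `label`, `unit`, and
#'   `value`.
#' @examples
#' compute_effects(simulate_design("sturt_exp1", n_runs = 200, seed = 1))
#' @export
compute_effects <- function(summaries) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% summaries$condition) ||
      length(unique(summaries$design)) != 1L)
    stop("summaries must cover conditions a-d of exactly one design",
         call. = FALSE)
  re <- stats::setNames(summaries$error_pct, summaries$condition)[need]
  rt <- stats::setNames(summaries$mean_latency_ms, summaries$condition)[need]
  data.frame(
    effect = c("E1", "E2", "E3", "E4", "E5"),
    label = c("mismatch (retrieval errors)", "interference (retrieval errors)",
              "mismatch (retrieval time)", "match-interference (retrieval time)",
              "mismatch-interference (retrieval time)"),
    unit = c("pct", "pct", "ms", "ms", "ms"),
    value = c(mean(re[c("c", "d")]) - mean(re[c("a", "b")]),
              mean(re[c("a", "c")]) - mean(re[c("b", "d")]),
              mean(rt[c("c", "d")]) - mean(rt[c("a", "b")]),
              rt[["a"]] - rt[["b"]],
              rt[["c"]] - rt[["d"]]),
    stringsAsFactors = FALSE)
}

#' Parameter grid for the sensitivity sweep
#'
#' The canonical three-parameter grid: noise 0.05–0.4 in steps of 0.05,
#' maximum associative strength 1–4 in steps of 0.25, and maximum difference
#' −1 to 0 in steps of 0.1 (8 x 13 x 11 = 1144 cells).
#' `include_zero_noise = TRUE` prepends noise 0 (9 x 13 x 11 = 1287 cells),
#' in which the error-rate effects are exactly zero.
#'
#' @param include_zero_noise also sweep the noiseless model?
#' @return Data frame with columns `noise`, `max_assoc_strength`,
#'   `max_difference`, one row per grid cell.
#' @export
sweep_grid <- function(include_zero_noise = FALSE) {
  noise <- round(seq(0.05, 0.4, by = 0.05), 10)
  if (include_zero_noise) noise <- c(0, noise)
  expand.grid(noise = noise,
              max_assoc_strength = round(seq(1, 4, by = 0.25), 10),
              max_difference = round(seq(-1, 0, by = 0.1), 10),
              KEEP.OUT.ATTRS = FALSE)
}

#' Sweep the model effects over a parameter grid
#'
#' Re-runs the four-condition Monte-Carlo simulation of a design at every
#' (noise, maximum associative strength, maximum difference) cell of a grid
#' and records the five effects per cell. Every (cell, condition) pair uses a
#' deterministic substream derived from `seed`, so results are independent of
#' evaluation order.
#'
#' @param grid data frame as produced by [sweep_grid()].
#' @inheritParams simulate_condition
#' @return Data frame: `design`, the three grid columns, and `E1`–`E5`.
#' @examples
#' g <- sweep_grid()[c(1, 500, 1100), ]
#' run_sweep("sturt_exp1", grid = g, n_runs = 100, seed = 1)
#' @export
run_sweep <- function(design, grid = sweep_grid(), params = model_params(),
                      n_runs = 1000, seed = 1, structural_only = FALSE,
                      base_gender = "masc", file = NULL) {
  stopifnot(all(c("noise", "max_assoc_strength", "max_difference") %in% names(grid)),
            all(is.finite(as.matrix(grid))))
  conds <- c("a", "b", "c", "d")
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$noise_scale <- grid$noise[i]
    p$max_assoc_strength <- grid$max_assoc_strength[i]
    p$max_difference <- grid$max_difference[i]
    key <- cell_key(p$noise_scale, p$max_assoc_strength, p$max_difference)
    summ <- do.call(rbind, lapply(seq_along(conds), function(j)
      simulate_condition(design, conds[j], p, n_runs,
                         seed = substream_seed(seed, key, j),
                         structural_only = structural_only,
                         base_gender = base_gender, file = file)))
    eff <- compute_effects(summ)
    out[[i]] <- cbind(data.frame(design = design), grid[i, , drop = FALSE],
                      as.data.frame(as.list(stats::setNames(eff$value, eff$effect))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sweep several designs on a common grid
#'
#' Runs [run_sweep()] for each design with the same grid and seed policy and
#' stacks the results, enabling effect-by-effect cross-design comparison
#' (see [design_deltas()]). With a single design the output is identical to
#' [run_sweep()].
#'
#' @param designs character vector of design names.
#' @inheritParams run_sweep
#' @return Data frame as from [run_sweep()], rows stacked across designs.
#' @export
compare_designs <- function(designs, grid = sweep_grid(),
                            params = model_params(), n_runs = 1000, seed = 1,
                            structural_only = FALSE, base_gender = "masc",
                            file = NULL) {
  do.call(rbind, lapply(designs, function(d)
    run_sweep(d, grid, params, n_runs, seed, structural_only, base_gender, file)))
}

#' Per-cell effect differences between designs
#'
#' @param sweep stacked sweep result from [compare_designs()].
#' @param reference design against which the others are differenced.
#' @return Data frame of `E1`–`E5` differences (design minus reference) per
#'   grid cell and non-reference design.
#' @export
design_deltas <- function(sweep, reference) {
  if (!reference %in% sweep$design) stop("reference design not in sweep", call. = FALSE)
  keys <- c("noise", "max_assoc_strength", "max_difference")
  eff <- paste0("E", 1:5)
  ref <- sweep[sweep$design == reference, c(keys, eff)]
  names(ref)[match(eff, names(ref))] <- paste0(eff, "_ref")
  others <- sweep[sweep$design != reference, ]
  m <- merge(others, ref, by = keys, sort = FALSE)
  for (e in eff) m[[e]] <- m[[e]] - m[[paste0(e, "_ref")]]
  m[, c("design", keys, eff)]
}

#' Marginal mean effects along one swept parameter
#'
#' Averages each effect over the other two grid parameters, one mean per value
#' of `by` — the curve showing how an effect's size varies with the parameter
#' that drives it.
#'
#' @param sweep result of [run_sweep()] (single design).
#' @param by one of `"noise"`, `"max_assoc_strength"`, `"max_difference"`.
#' @return Data frame with the `by` column and mean `E1`–`E5`.
#' @export
marginal_effects <- function(sweep, by = c("noise", "max_assoc_strength",
                                           "max_difference")) {
  by <- match.arg(by)
  eff <- paste0("E", 1:5)
  agg <- stats::aggregate(sweep[eff], by = sweep[by], FUN = mean)
  agg[order(agg[[by]]), , drop = FALSE]
}
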