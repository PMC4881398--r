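# three words wide enough to give distinct catchment areas
toy_layout <- region_layout(c("The", "surgeon", "slept"), char_px = 10,
                            space_px = 20, x0 = 100, top = 400, bottom = 420)
# boxes: [100,130) [150,220) [240,290); midpoints of the spaces: 140, 230

fx <- function(x, y = 410, onset = 0, duration = 200, trial = 1)
  data.frame(trial = trial, x = x, y = y, onset = onset, duration = duration)

test_that("fixations map to word boxes, split spaces, and drop outliers", {
  f <- rbind(fx(185),          # center of word 2
             fx(185, y = 375), # 25 px above the line: kept
             fx(185, y = 365), # 35 px above: dropped
             fx(135),          # first half of space 1 -> word 1
             fx(145),          # second half -> word 2
             fx(140),          # exactly at the midpoint -> following word
             fx(95),           # left of the line start
             fx(290),          # at/after the last right edge
             fx(229.9), fx(230))
  a <- assign_fixations(f, toy_layout)
  expect_equal(a$word_index,
               c(2L, 2L, NA, 1L, 2L, 2L, NA, NA, 2L, 3L))
})

test_that("measure extraction ignores uniform horizontal translation", {
  f <- rbind(fx(110, onset = 0), fx(185, onset = 200),
             fx(260, onset = 400, duration = 150),
             fx(185, onset = 550, duration = 120))
  shift <- 137
  lay2 <- toy_layout; lay2$left <- lay2$left + shift; lay2$right <- lay2$right + shift
  f2 <- f; f2$x <- f2$x + shift
  m1 <- compute_measures(f, region = 2, layout = toy_layout)
  m2 <- compute_measures(f2, region = 2, layout = lay2)
  expect_equal(m1, m2)
  p1 <- progression_table(f, 2, layout = toy_layout)
  p2 <- progression_table(f2, 2, layout = lay2)
  expect_equal(p1$distance, p2$distance)
})

test_that("first-pass measures follow their definitions", {
  # single 250 ms fixation in the region, then a forward exit
  f <- rbind(fx(185, onset = 0, duration = 250), fx(260, onset = 250))
  m <- compute_measures(f, 2, layout = toy_layout)
  expect_equal(m[, c("FFD", "FPRT", "RRT", "TRT", "FPRP", "RRP")],
               data.frame(FFD = 250, FPRT = 250, RRT = 0, TRT = 250,
                          FPRP = 0, RRP = 0))

  # two first-pass fixations, forward exit, later return
  f <- rbind(fx(180, onset = 0, duration = 200),
             fx(190, onset = 200, duration = 150),
             fx(260, onset = 350, duration = 180),
             fx(185, onset = 530, duration = 100))
  m <- compute_measures(f, 2, layout = toy_layout)
  expect_equal(m$FFD, 200); expect_equal(m$FPRT, 350)
  expect_equal(m$RRT, 100); expect_equal(m$TRT, 450)
  expect_equal(m$FPRP, 0);  expect_equal(m$RRP, 1)

  # first-pass exit to an earlier word counts as a regression
  f <- rbind(fx(185, onset = 0), fx(110, onset = 200))
  expect_equal(compute_measures(f, 2, layout = toy_layout)$FPRP, 1)

  # region never fixated: missing durations, RRP 0
  f <- rbind(fx(110, onset = 0), fx(260, onset = 200))
  m <- compute_measures(f, 2, layout = toy_layout)
  expect_true(all(is.na(m[, c("FFD", "FPRT", "RRT", "TRT", "FPRP")])))
  expect_equal(m$RRP, 0)

  # region skipped during first pass, read only later: no first-pass measures
  f <- rbind(fx(110, onset = 0), fx(260, onset = 200),
             fx(185, onset = 400, duration = 130))
  m <- compute_measures(f, 2, layout = toy_layout)
  expect_true(is.na(m$FFD) && is.na(m$FPRT) && is.na(m$FPRP))
  expect_equal(m$RRT, 130); expect_equal(m$TRT, 130); expect_equal(m$RRP, 1)
})

test_that("cumulative progression is a forward-only running maximum", {
  still <- assign_fixations(fx(185, onset = 0, duration = 1200), toy_layout)
  pc <- cumulative_progression(still, 2)
  expect_length(pc$distance, 501)
  expect_equal(pc$time, seq(0, 1000, by = 2))
  expect_true(all(pc$distance == 0))

  # +80 px saccade at 300 ms, regression of -120 px at 600 ms
  f <- assign_fixations(
    rbind(fx(180, onset = 0, duration = 300),
          fx(260, onset = 300, duration = 300),
          fx(140, onset = 600, duration = 600)), toy_layout)
  pc <- cumulative_progression(f, 2)
  expect_equal(pc$origin_x, 180)
  expect_true(all(pc$distance[pc$time < 300] == 0))
  expect_true(all(pc$distance[pc$time >= 300] == 80))

  # never fixated -> no curve
  expect_null(cumulative_progression(
    assign_fixations(fx(110), toy_layout), 2))

  # monotone, zero-origin curves on generated data
  d <- generate_fixations(synth_config(n_participants = 3, n_items = 4,
                                       regress_prob = c(a = 0.5, b = 0.5,
                                                        c = 0.5, d = 0.5)),
                          seed = 21)
  prog <- progression_table(d$fixations, d$config$critical_word,
                            layout = d$layout)
  for (tr in split(prog, prog$trial)) {
    expect_equal(nrow(tr), 501L)
    expect_equal(tr$distance[1], 0)
    expect_true(all(diff(tr$distance) >= 0))
  }
})

test_that("progression differences average within conditions before differencing", {
  grid <- seq(0, 1000, by = 2)
  mk <- function(cond, trial, dist)
    data.frame(trial = trial, condition = cond, time = grid, distance = dist)
  flat <- function(level) rep(level, length(grid))

  # identical curve sets in all conditions -> zero everywhere
  prog <- rbind(mk("a", 1, flat(30)), mk("b", 2, flat(30)),
                mk("c", 3, flat(30)), mk("d", 4, flat(30)))
  pd <- progression_difference(prog)
  expect_equal(unique(pd$difference), 0)
  expect_equal(nrow(pd), 3 * 501)

  # one condition uniformly 10 px ahead
  prog$distance[prog$condition == "a"] <- 40
  pd <- progression_difference(prog)
  expect_equal(unique(pd$difference[pd$effect == "match_interference"]), 10)
  expect_equal(unique(pd$difference[pd$effect == "mismatch"]), -5)

  # a +50 px shift injected into condition c from 400 ms onward
  shifted <- ifelse(grid >= 400, 80, 30)
  prog <- rbind(mk("a", 1, flat(30)), mk("b", 2, flat(30)),
                mk("c", 3, shifted), mk("d", 4, flat(30)))
  pd <- progression_difference(prog)
  mi <- pd[pd$effect == "mismatch_interference", ]
  expect_equal(unique(mi$difference[mi$time < 400]), 0)
  expect_equal(unique(mi$difference[mi$time >= 400]), 50)

  expect_error(progression_difference(prog[prog$condition != "b", ]),
               "four conditions")
})

test_that("the nested contrasts are centered, orthogonal where disjoint, and signed as predicted", {
  cm <- nested_contrast_matrix()
  expect_equal(colSums(cm), c(mismatch = 0, match_interference = 0,
                              mismatch_interference = 0))
  expect_equal(sum(cm[, "match_interference"] * cm[, "mismatch_interference"]), 0)
  expect_equal(drop(crossprod(cm, c(198, 194, 274, 295))),
               c(mismatch = 88.5, match_interference = 2,
                 mismatch_interference = 10.5))
})

test_that("the model-ready table carries contrasts, centered trial and log times", {
  meas <- data.frame(trial = 1:4, condition = c("a", "b", "c", "d"),
                     FFD = c(200, NA, 250, 300), FPRT = c(220, NA, 260, 310),
                     RRT = c(0, NA, 100, 0), TRT = c(220, NA, 360, 310),
                     FPRP = c(0, NA, 1, 0), RRP = c(0, 0, 1, 0))
  mt <- measures_model_table(meas)
  expect_equal(mt$c_mismatch, c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(mean(mt$trial_c), 0)
  expect_equal(mt$log_FFD, c(log(200), NA, log(250), log(300)))
  expect_true(is.na(mt$log_RRT[1]))  # zero re-reading has no log time
  expect_error(measures_model_table(data.frame(FFD = 1)), "condition")
})
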