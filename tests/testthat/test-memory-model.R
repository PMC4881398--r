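p_quiet <- model_params(noise_scale = 0)

test_that("base-level activation follows the power-law recency and frequency law", {
  one <- function(t) chunk("x", "masc", "subject", "current", creation_times = t)
  expect_equal(base_level_activation(one(1), p_quiet), 0)
  expect_equal(base_level_activation(one(4), p_quiet), -log(2))
  expect_equal(base_level_activation(one(c(1, 1)), p_quiet), log(2))

  # strictly decreasing as the single mention ages
  ages <- c(0.1, 0.5, 1, 2, 5, 20)
  b <- vapply(ages, function(t) base_level_activation(one(t), p_quiet), numeric(1))
  expect_true(all(diff(b) < 0))

  # an extra mention always raises activation
  expect_gt(base_level_activation(one(c(3, 0.5)), p_quiet),
            base_level_activation(one(0.5), p_quiet))

  expect_error(chunk("x", "masc", "subject", "current", creation_times = c(1, -2)),
               "invalid timeline")
  bad <- one(1); bad$creation_times <- 0
  expect_error(base_level_activation(bad, p_quiet), "invalid timeline")
})

test_that("associative strength is diluted by cue fan", {
  surgeon <- mini_chunk("surgeon", gender = "masc")
  jonathan <- mini_chunk("jonathan", gender = "masc", clause = "other")
  mem <- list(surgeon, jonathan)

  expect_identical(fan_of_cue("category", "noun", mem), 2L)
  expect_identical(fan_of_cue("gender", "fem", mem), 0L)
  expect_identical(fan_of_cue("gender", "masc", mem), 2L)

  expect_equal(strength_of_association("clause", "current", mem, p_quiet), 1.5)
  expect_equal(strength_of_association("gender", "masc", mem, p_quiet), 1.5 - log(2))
  p3 <- model_params(max_assoc_strength = 1, noise_scale = 0)
  mem3 <- c(mem, list(mini_chunk("nurse", gender = "masc")))
  expect_equal(strength_of_association("gender", "masc", mem3, p3), 1 - log(3))
  expect_lt(strength_of_association("gender", "masc", mem3, p3), 0)

  # strictly decreasing in fan at fixed S
  s_by_fan <- vapply(1:6, function(k) {
    mem_k <- lapply(seq_len(k), function(i) mini_chunk(paste0("c", i)))
    strength_of_association("gender", "masc", mem_k, p_quiet)
  }, numeric(1))
  expect_true(all(diff(s_by_fan) < 0))

  # a cue matching nothing contributes no association
  expect_equal(strength_of_association("gender", "fem", mem, p_quiet), 0)
})

test_that("spreading activation and mismatch penalties decompose additively", {
  target <- mini_chunk("target", age = 1)                    # B = 0
  # a verb chunk shares no cue with the retrieval request
  distractor <- chunk("distractor", gender = "fem", role = "object",
                      clause = "other", creation_times = 1, category = "verb")
  mem <- list(target, distractor)
  cues <- reflexive_cues("masc")

  # all four cues matched at fan 1 -> 4 x 0.25 x 1.5
  expect_equal(spreading_activation(target, cues, list(target), p_quiet), 1.5)
  # raising only the gender fan to 2 replaces one component with S - log 2
  mem2 <- list(target, chunk("rival", gender = "masc", role = "object",
                             clause = "other", creation_times = 1,
                             category = "verb"))
  expect_equal(spreading_activation(target, cues, mem2, p_quiet),
               0.25 * (1.5 - log(2)) + 0.75 * 1.5)
  # a chunk matching no cue receives nothing and pays the full penalty
  expect_equal(spreading_activation(distractor, cues, mem, p_quiet), 0)
  expect_equal(mismatch_penalty(distractor, cues, p_quiet), -4)
  expect_equal(mismatch_penalty(target, cues, p_quiet), 0)
  one_off <- mini_chunk("near", gender = "fem", age = 1)
  expect_equal(mismatch_penalty(one_off, cues, p_quiet), -1)

  # breakdown example assembled from the parts above
  ch <- mini_chunk("b", age = 4)
  bd <- total_activation(ch, cues, mem2, p_quiet, noise = 0)
  expect_equal(bd$total, -log(2) + 0.25 * (1.5 - log(2)) + 0.75 * 1.5,
               tolerance = 1e-12)
  expect_equal(bd$noise, 0)

  # additivity invariant across random feature/noise combinations
  set.seed(11)
  for (i in 1:25) {
    ch <- mini_chunk(paste0("r", i),
                     gender = sample(c("masc", "fem"), 1),
                     role = sample(c("subject", "object"), 1),
                     clause = sample(c("current", "other"), 1),
                     age = runif(1, 0.05, 5))
    eps <- rnorm(1)
    bd <- total_activation(ch, cues, list(ch, target), p_quiet, noise = eps)
    expect_equal(bd$total, bd$base + bd$spreading + bd$penalty + bd$noise,
                 tolerance = 1e-12)
    expect_lte(bd$penalty, 0)
  }
})

test_that("a single retrieval selects the highest activation above threshold", {
  # construct totals 0.5 and -0.2: B = 0 chunks, one matching cue with S = 0.5,
  # non-matcher penalized 0.2
  p <- model_params(noise_scale = 0, max_assoc_strength = 0.5,
                    max_difference = -0.2, latency_factor = 0.14,
                    fixed_cost = 0)
  winner <- mini_chunk("w", gender = "masc", age = 1)
  loser <- mini_chunk("l", gender = "fem", age = 1)
  cues <- cue_set(c(gender = "masc"))
  out <- retrieve_once(list(winner, loser), cues, p)
  expect_equal(sort(out$breakdowns$total), c(-0.2, 0.5))
  expect_identical(out$winner_id, "w")
  expect_equal(out$latency, 0.14 * exp(-0.5))

  # neither candidate reaches the threshold -> failure at the threshold bound
  p_hi <- p; p_hi$retrieval_threshold <- 2
  out_f <- retrieve_once(list(winner, loser), cues, p_hi)
  expect_identical(out_f$winner_id, "FAILURE")
  expect_true(out_f$failed)
  expect_equal(out_f$latency, 0.14 * exp(-2))

  # noise-free retrieval is a pure function of its inputs
  expect_identical(retrieve_once(list(winner, loser), cues, p),
                   retrieve_once(list(winner, loser), cues, p))

  # latency strictly decreases as winner activation increases
  lat <- vapply(c(0.25, 0.5, 1, 2), function(S) {
    pS <- p; pS$max_assoc_strength <- S
    retrieve_once(list(winner, loser), cues, pS)$latency
  }, numeric(1))
  expect_true(all(diff(lat) < 0))

  expect_error(retrieve_once(list(), cues, p), "empty candidate set")
})

test_that("noise-free retrievals match the hand-computed activation table", {
  frozen <- list(a = c(1.928700, 0.130051), b = c(2.101986, -1.071663),
                 c = c(0.726986, 0.303337), d = c(0.726986, -1.071663))
  for (cond in c("a", "b", "c", "d")) {
    mem <- encode_condition("sturt_exp1", cond, p_quiet)
    got <- vapply(mem$chunks, function(ch)
      total_activation(ch, mem$cues, mem$chunks, p_quiet)$total, numeric(1))
    expect_equal(unname(got), unname(oracle_exp1_activations(cond)),
                 tolerance = 1e-10)
    expect_equal(unname(got), frozen[[cond]], tolerance = 1e-6)
    # without noise the accessible antecedent wins every retrieval
    out <- retrieve_once(mem$chunks, mem$cues, p_quiet)
    expect_identical(out$winner_id, "accessible")
    expect_equal(out$latency,
                 p_quiet$latency_factor * exp(-max(got)) + p_quiet$fixed_cost)
  }
})
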