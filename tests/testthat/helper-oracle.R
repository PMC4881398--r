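# Independent oracle: activations for the canonical two-referent design,
# computed by direct transliteration of the activation equations onto an
# explicit feature table (no package internals).
oracle_exp1_activations <- function(cond, d = 0.5, S = 1.5, md = -1, P = 1,
                                    W = 1, pwt = 0.05) {
  flip <- function(g) if (g == "masc") "fem" else "masc"
  refl <- if (cond %in% c("a", "b")) "masc" else "fem"
  inacc_g <- if (cond %in% c("a", "c")) refl else flip(refl)
  chunks <- list(
    accessible = list(
      f = c(gender = "masc", category = "noun", role = "subject", clause = "current"),
      age = (7 - 4) * pwt),
    inaccessible = list(
      f = c(gender = inacc_g, category = "noun", role = "subject", clause = "other"),
      age = 7 * pwt))
  cues <- c(gender = refl, category = "noun", role = "subject", clause = "current")
  fan <- sapply(names(cues), function(j)
    sum(sapply(chunks, function(ch) ch$f[[j]] == cues[[j]])))
  sapply(chunks, function(ch) {
    B <- log(ch$age^(-d))
    spread <- 0
    miss <- 0
    for (j in names(cues)) {
      if (ch$f[[j]] == cues[[j]]) spread <- spread + (W / 4) * (S - log(fan[[j]]))
      else miss <- miss + 1
    }
    B + spread + P * md * miss
  })
}

# quick builder for a bare two-chunk memory with fully controllable features
mini_chunk <- function(id, gender = "masc", role = "subject", clause = "current",
                       age = 1) {
  chunk(id, gender = gender, role = role, clause = clause, creation_times = age)
}
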