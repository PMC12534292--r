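# Shared fixtures and independent oracles, built in code at test time.

# small hand-written cohort: two patients with contrasting courses
toy_cohort <- function() {
  psp_cohort(
    data.frame(patient_id = c("a", "b"),
               sex = c("male", "female"),
               age_at_onset = c(65, 70),
               disease_duration = c(8, 6)),
    data.frame(patient_id = c("a", "a", "a", "a", "b", "b"),
               symptom = c("postural_instability", "frontal_presentation",
                           "ocular_motor", "bradykinesia",
                           "speech_language", "speech_language"),
               t = c(0.5, 1.5, 5, 4, 1, 4),
               present = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)))
}

# tri-state feature row builder for classifier tests
composite_row <- function(frontal = "A", pi = "A", sl = "A", om = "A",
                          parkinsonism = "A") {
  data.frame(frontal = frontal, pi = pi, sl = sl, om = om,
             parkinsonism = parkinsonism, stringsAsFactors = FALSE)
}

# brute-force Harrell's C by explicit double loop over all ordered pairs
concordance_oracle <- function(durations, events, scores) {
  n <- length(durations)
  num <- den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (durations[i] < durations[j] && events[i]) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# single-step max-T permutation reference for all-pairs rank comparisons,
# recomputing the same tie-corrected pair statistic as the implementation
steel_dwass_perm_oracle <- function(groups, n_perm = 4000, seed = 1) {
  pairs <- utils::combn(length(groups), 2)
  stat <- function(gr) {
    apply(pairs, 2, function(pq) {
      a <- gr[[pq[1]]]; b <- gr[[pq[2]]]
      na <- length(a); nb <- length(b); N <- na + nb
      r <- rank(c(a, b))
      W <- sum(r[seq_len(na)])
      V <- na * nb / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
      if (V <= 0) 0 else (W - na * (N + 1) / 2) / sqrt(V)
    })
  }
  obs <- abs(stat(groups))
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  set.seed(seed)
  maxT <- replicate(n_perm, {
    perm <- sample(pooled)
    gr <- split(perm, rep(seq_along(sizes), sizes))
    max(abs(stat(gr)))
  })
  vapply(obs, function(t0) mean(maxT >= t0 - 1e-12), 0)
}
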