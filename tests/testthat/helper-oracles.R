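# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (exhaustive enumeration, quadratic
# scans) and share no code with the package internals they check.

# exhaustive Viterbi: enumerate all 5^T state paths and return the best
brute_force_viterbi <- function(x, params) {
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(0:4), Tn)))
  logp <- log(params$initial_probs[paths[, 1] + 1]) +
    dnorm(x[1], params$emission_mean[paths[, 1] + 1],
          params$emission_sd[paths[, 1] + 1], log = TRUE)
  if (Tn > 1) for (t in 2:Tn) {
    logp <- logp +
      log(params$transition[cbind(paths[, t - 1] + 1, paths[, t] + 1)]) +
      dnorm(x[t], params$emission_mean[paths[, t] + 1],
            params$emission_sd[paths[, t] + 1], log = TRUE)
  }
  best <- which.max(logp)
  list(path = unname(paths[best, ]), logp = max(logp))
}

# two-sided Fisher exact p by direct hypergeometric enumeration
brute_force_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(c1, r1)
  pr <- dhyper(k, r1, r2, c1)
  sum(pr[pr <= pr[k == a] * (1 + 1e-7)])
}

# raw CNV segments of one state vector by a literal run scan
brute_force_runs <- function(states, min_len = 3) {
  segs <- list()
  i <- 1
  n <- length(states)
  while (i <= n) {
    j <- i
    while (j < n && states[j + 1] == states[i]) j <- j + 1
    if (states[i] != 2 && j - i + 1 >= min_len)
      segs[[length(segs) + 1]] <- c(start = i, end = j, state = states[i])
    i <- j + 1
  }
  segs
}

# quadratic all-pairs closed-interval overlap test
brute_force_overlap <- function(q_start, q_end, s_start, s_end) {
  vapply(seq_along(q_start), function(i)
    any(q_start[i] <= s_end & s_start <= q_end[i]), logical(1))
}

# Eq.-style permutation FDR by direct counting
brute_force_fdr <- function(observed, ensemble, threshold) {
  num <- sum(sapply(seq_len(ncol(ensemble)),
                    function(m) sum(ensemble[, m] >= threshold)))
  den <- ncol(ensemble) * sum(observed >= threshold)
  min(1, max(0, num / den))
}

# small two-chromosome cohort with one embedded deletion, shared by several
# test files (cheap to build, deterministic)
tiny_fixture <- function(seed = 301) {
  map <- make_snp_map(120, chrom_weights = c(1, 1), mean_spacing = 5000,
                      seed = seed)
  idx <- pick_region_indices(map, 5)
  rr <- risk_region(map$chrom[idx[1]], idx[1], idx[2], "deletion",
                    carrier_freq_cases = 0.5, carrier_freq_controls = 0.05)
  sm <- simulate_cohort(map, 40, 40, list(rr), background_rate = 1,
                        seed = seed + 1)
  list(map = map, region = idx, rr = rr, sm = sm)
}

# two-cohort fixture with a shared embedded deletion region
two_cohorts <- function(seed = 501, freq_test = c(0.5, 0.05),
                        background = 1) {
  map <- make_snp_map(120, chrom_weights = c(1, 1), mean_spacing = 5000,
                      seed = seed)
  idx <- pick_region_indices(map, 5)
  rr_ref <- risk_region(map$chrom[idx[1]], idx[1], idx[2], "deletion",
                        0.5, 0.05)
  rr_test <- risk_region(map$chrom[idx[1]], idx[1], idx[2], "deletion",
                         freq_test[1], freq_test[2])
  ref <- simulate_cohort(map, 50, 50, list(rr_ref), background,
                         seed = seed + 1, cohort_id = "ref")
  tst <- simulate_cohort(map, 40, 45, list(rr_test), background,
                         seed = seed + 2, cohort_id = "test")
  list(map = map, region = idx, ref = ref, test = tst)
}

# sample state paths and emissions from an hmm_params model
make_hmm_data <- function(params, n_ind, n_snps, seed) {
  set.seed(seed)
  states <- matrix(0L, n_ind, n_snps)
  x <- matrix(0, n_ind, n_snps)
  for (i in seq_len(n_ind)) {
    s <- sample(0:4, 1, prob = params$initial_probs)
    for (t in seq_len(n_snps)) {
      if (t > 1) s <- sample(0:4, 1, prob = params$transition[s + 1, ])
      states[i, t] <- s
      x[i, t] <- rnorm(1, params$emission_mean[s + 1],
                       params$emission_sd[s + 1])
    }
  }
  list(states = states, x = x)
}
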