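#' Hidden Markov model parameters for copy-number state inference
#'
#' A homogeneous 5-state HMM over copy numbers 0--4 with normal emissions.
#' The transition matrix is distance-independent with a high self-transition
#' probability, reflecting that copy-number state changes rarely between
#' neighboring array probes.
#'
#' @param initial_probs length-5 simplex of initial state probabilities.
#' @param transition 5 x 5 row-stochastic transition matrix.
#' @param emission_mean,emission_sd length-5 per-state normal emission
#'   means / standard deviations (sds > 0).
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(initial_probs, transition, emission_mean,
                       emission_sd) {
  initial_probs <- as.numeric(initial_probs)
  transition <- as.matrix(transition)
  if (length(initial_probs) != 5L || !all(dim(transition) == c(5L, 5L)) ||
      length(emission_mean) != 5L || length(emission_sd) != 5L)
    stop("a 5-state parameterization is required", call. = FALSE)
  if (abs(sum(initial_probs) - 1) > 1e-9 ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    stop("initial_probs and transition rows must sum to 1", call. = FALSE)
  if (any(initial_probs < 0) || any(transition < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  if (any(rowSums(transition > 0) == 0))
    stop("degenerate transition row (all zero)", call. = FALSE)
  if (any(emission_sd <= 0))
    stop("emission sds must be > 0", call. = FALSE)
  structure(list(initial_probs = initial_probs, transition = transition,
                 emission_mean = as.numeric(emission_mean),
                 emission_sd = as.numeric(emission_sd)),
            class = "hmm_params")
}

#' Default copy-number HMM parameterization
#'
#' States 0--4 with emission means at `-2, -1, 0, 1, 2` (one intensity unit
#' per copy), a common sd, initial distribution concentrated on the diploid
#' state, and self-transition probability `self` (default 0.999, i.e. about
#' one state change per thousand probes).
#'
#' @param emission_mean per-state emission means.
#' @param emission_sd single value or length-5 vector of emission sds.
#' @param self self-transition probability on the diagonal.
#' @param initial_probs initial state distribution.
#' @return an `hmm_params` object.
#' @export
default_hmm_params <- function(emission_mean = c(-2, -1, 0, 1, 2),
                               emission_sd = 0.25, self = 0.999,
                               initial_probs = c(0.001, 0.004, 0.99,
                                                 0.004, 0.001)) {
  trans <- matrix((1 - self) / 4, 5, 5)
  diag(trans) <- self
  hmm_params(initial_probs, trans, emission_mean,
             rep_len(emission_sd, 5L))
}

# per-state log emission densities for one observation vector; always a
# length(x) x 5 matrix, also for single-observation sequences
log_emission <- function(x, params) {
  out <- vapply(1:5, function(s)
    stats::dnorm(x, params$emission_mean[s], params$emission_sd[s],
                 log = TRUE),
    numeric(length(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' Fit the HMM by Baum-Welch expectation-maximization
#'
#' Each row of the training matrix is treated as one observation sequence
#' (one individual); sufficient statistics are pooled across sequences.
#' Forward-backward recursions use per-position scaling so the total
#' log-likelihood is exact. Iteration stops after `max_iter` rounds or when
#' the log-likelihood improves by less than `tol`. The log-likelihood is
#' non-decreasing across iterations (EM monotonicity); the trace is
#' returned as attribute `"loglik"`.
#'
#' @param training numeric matrix of intensities, individuals x SNPs.
#' @param init starting `hmm_params`.
#' @param max_iter maximum EM iterations; `0` returns `init` unchanged.
#' @param tol minimal log-likelihood improvement to continue.
#' @param min_sd lower bound kept on emission sds for numerical stability.
#' @return fitted `hmm_params` with attribute `loglik` (one value per
#'   iteration evaluated at the entering parameters).
#' @export
fit_hmm <- function(training, init, max_iter = 50, tol = 1e-4,
                    min_sd = 1e-3) {
  training <- as.matrix(training)
  if (nrow(training) < 1L)
    stop("training data must contain at least one individual", call. = FALSE)
  stopifnot(inherits(init, "hmm_params"))
  params <- init
  ll_trace <- numeric(0)
  if (max_iter == 0) {
    attr(params, "loglik") <- ll_trace
    return(params)
  }
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(5)        # sum of posteriors (all positions)
    g_first <- numeric(5)      # posteriors at position 1
    g_x <- numeric(5)          # posterior-weighted observations
    g_x2 <- numeric(5)
    xi_sum <- matrix(0, 5, 5)  # expected transition counts
    log_a <- log(params$transition)
    for (i in seq_len(nrow(training))) {
      x <- training[i, ]
      Tn <- length(x)
      b <- exp(log_emission(x, params))   # Tn x 5 scaled below
      alpha <- matrix(0, Tn, 5)
      cscale <- numeric(Tn)
      a0 <- params$initial_probs * b[1, ]
      cscale[1] <- sum(a0)
      alpha[1, ] <- a0 / cscale[1]
      for (t in 2:Tn) {
        at <- (alpha[t - 1, ] %*% params$transition) * b[t, ]
        cscale[t] <- sum(at)
        alpha[t, ] <- at / cscale[t]
      }
      beta <- matrix(0, Tn, 5)
      beta[Tn, ] <- 1
      for (t in (Tn - 1):1)
        beta[t, ] <- (params$transition %*% (b[t + 1, ] * beta[t + 1, ])) /
          cscale[t + 1]
      gamma <- alpha * beta
      gamma <- gamma / rowSums(gamma)
      ll <- ll + sum(log(cscale))
      g_sum <- g_sum + colSums(gamma)
      g_first <- g_first + gamma[1, ]
      g_x <- g_x + colSums(gamma * x)
      g_x2 <- g_x2 + colSums(gamma * x^2)
      # sum_t alpha[t,] (x) (b beta / c)[t+1,], elementwise x transition
      bb <- (b * beta) / cscale
      xi_sum <- xi_sum + params$transition *
        crossprod(alpha[-Tn, , drop = FALSE], bb[-1, , drop = FALSE])
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && (ll - ll_trace[iter - 1]) < tol) break
    # M step
    new_init <- g_first / sum(g_first)
    new_trans <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.xmin)
    bad <- rowSums(xi_sum) == 0
    if (any(bad)) new_trans[bad, ] <- params$transition[bad, ]
    mu <- g_x / pmax(g_sum, .Machine$double.xmin)
    sd2 <- g_x2 / pmax(g_sum, .Machine$double.xmin) - mu^2
    empty <- g_sum < 1e-8
    mu[empty] <- params$emission_mean[empty]
    sdv <- sqrt(pmax(sd2, min_sd^2))
    sdv[empty] <- params$emission_sd[empty]
    params <- hmm_params(new_init, new_trans, mu, sdv)
  }
  attr(params, "loglik") <- ll_trace
  params
}

# log-space Viterbi decoding of one observation sequence -> states 0..4
viterbi_path <- function(x, params) {
  Tn <- length(x)
  logb <- log_emission(x, params)
  if (Tn == 1L)
    return(which.max(log(params$initial_probs) + logb[1, ]) - 1L)
  log_a <- log(params$transition)
  delta <- matrix(-Inf, Tn, 5)
  psi <- matrix(0L, Tn, 5)
  delta[1, ] <- log(params$initial_probs) + logb[1, ]
  for (t in 2:Tn) {
    cand <- delta[t - 1, ] + log_a        # 5 x 5: from x to
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta[t, ] <- cand[cbind(psi[t, ], 1:5)] + logb[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1)
    path[t] <- psi[t + 1, path[t + 1]]
  path - 1L
}

#' Decode copy-number states from intensities (Viterbi)
#'
#' Computes, per individual and per chromosome, the maximum a posteriori
#' Viterbi state path through the 5-state HMM. Chromosomes are decoded
#' independently (each restarts from the initial distribution). All
#' arithmetic is in log space.
#'
#' @param signal intensity matrix (individuals x SNPs).
#' @param params `hmm_params`.
#' @param snp_map optional SNP map; when supplied, decoding is restarted at
#'   each chromosome boundary. Without it the whole row is one sequence.
#' @param labels optional case/control labels for the returned
#'   [state_matrix()]; defaults to all `"control"` (decoding itself is
#'   label-free).
#' @param cohort_id cohort name for the result.
#' @return a [state_matrix()] of decoded states.
#' @export
decode_states <- function(signal, params, snp_map = NULL, labels = NULL,
                          cohort_id = "decoded") {
  signal <- as.matrix(signal)
  stopifnot(inherits(params, "hmm_params"))
  if (!is.null(snp_map)) {
    validate_snp_map(snp_map)
    if (nrow(snp_map) != ncol(signal))
      stop("SNP dimension of `signal` does not match `snp_map`",
           call. = FALSE)
    blocks <- split(seq_len(ncol(signal)), snp_map$chrom)
  } else {
    blocks <- list(seq_len(ncol(signal)))
  }
  states <- matrix(0L, nrow(signal), ncol(signal))
  for (i in seq_len(nrow(signal)))
    for (idx in blocks)
      states[i, idx] <- viterbi_path(signal[i, idx], params)
  rownames(states) <- rownames(signal)
  if (is.null(labels)) labels <- rep("control", nrow(signal))
  state_matrix(states, labels, cohort_id)
}

#' Serialize HMM parameters as plain-text YAML
#'
#' @param params `hmm_params`.
#' @param path file path.
#' @return `write_hmm_params()` returns `path` invisibly;
#'   `read_hmm_params()` returns an `hmm_params`.
#' @export
write_hmm_params <- function(params, path) {
  stopifnot(inherits(params, "hmm_params"))
  yaml::write_yaml(list(
    initial_probs = params$initial_probs,
    transition = apply(params$transition, 1, as.numeric, simplify = FALSE),
    emission_mean = params$emission_mean,
    emission_sd = params$emission_sd), path)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  y <- yaml::read_yaml(path)
  hmm_params(y$initial_probs,
             do.call(rbind, y$transition),
             y$emission_mean, y$emission_sd)
}
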