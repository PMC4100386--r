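#' Generate case/control label permutations
#'
#' Permutes case/control labels `t_pm` times, preserving the original arm
#' sizes in every replicate. One shared permutation set serves the
#' SNP-based, window-based and Rf FDR calculations.
#'
#' @param labels factor/character of `"case"` / `"control"`.
#' @param t_pm number of permutations (>= 1), default 100.
#' @param seed integer seed.
#' @return a logical matrix, individuals x `t_pm`; `TRUE` marks the
#'   individuals assigned the case label in that replicate.
#' @export
permute_labels <- function(labels, t_pm = 100, seed = 1L) {
  if (t_pm < 1) stop("`t_pm` must be >= 1", call. = FALSE)
  labels <- as.character(labels)
  n_case <- sum(labels == "case")
  n <- length(labels)
  withr_seed(seed, {
    out <- matrix(FALSE, n, t_pm)
    for (m in seq_len(t_pm))
      out[sample.int(n, n_case), m] <- TRUE
    out
  })
}

#' Permutation ensemble of per-site hypothesis p-values
#'
#' Recomputes the loss / gain / abnormal Fisher p-values (and the best-p
#' SNP-based statistic) for every site under each label permutation, using
#' the vectorized engine. Because a label permutation leaves the per-site
#' carrier totals unchanged, each site's Fisher p-value is a lookup in a
#' hypergeometric table fixed by its margins.
#'
#' @param states a [state_matrix()].
#' @param perms logical permutation matrix from [permute_labels()].
#' @return a list of class `assoc_ensemble`: `p_loss`, `p_gain`, `p_abnm`
#'   (site x permutation matrices), `stat` (site x permutation matrix of
#'   `-log10` best hypothesis p), `t_pm`.
#' @export
assoc_permutations <- function(states, perms) {
  stopifnot(inherits(states, "state_matrix"))
  t_pm <- ncol(perms)
  S <- ncol(states$states)
  n1 <- sum(perms[, 1])
  n2 <- nrow(perms) - n1
  cm <- carrier_matrices(states$states)
  m_tot <- lapply(cm, function(C)
    as.integer(round(.colSums(C, nrow(C), ncol(C)))))
  # case-carrier counts for all sites and permutations in one product
  a_all <- lapply(cm, function(C) round(crossprod(C, perms)))  # S x t_pm
  out <- list()
  for (h in names(cm)) {
    p <- matrix(1, S, t_pm)
    for (m in seq_len(t_pm))
      p[, m] <- fisher_p_many(as.integer(a_all[[h]][, m]), m_tot[[h]],
                              n1, n2)
    out[[paste0("p_", h)]] <- p
  }
  best <- pmin(out$p_loss, out$p_gain, out$p_abnm)
  out$stat <- -log10(best)
  out$t_pm <- t_pm
  structure(out, class = "assoc_ensemble")
}

#' Permutation false discovery rate at a threshold
#'
#' Estimates `FDR(t) = [sum_m #\{sites: S^(m) >= t\}] /
#' (T_pm x #\{sites: S >= t\})`, clamped to `[0, 1]`: the permutation
#' ensemble plays the null, and the FDR is the expected null exceedance
#' count divided by the observed one. Ties are counted with `>=`.
#'
#' @param observed numeric vector of observed per-site statistics.
#' @param ensemble matrix (sites x permutations) of the same statistic
#'   under permuted labels.
#' @param threshold statistic threshold; at least one observed value must
#'   reach it.
#' @return single FDR estimate in `[0, 1]`.
#' @export
permutation_fdr <- function(observed, ensemble, threshold) {
  ensemble <- as.matrix(ensemble)
  if (ncol(ensemble) < 1) stop("`t_pm` must be >= 1", call. = FALSE)
  n_obs <- sum(observed >= threshold)
  if (n_obs == 0)
    stop("no observed statistic reaches the threshold; FDR undefined",
         call. = FALSE)
  n_null <- sum(ensemble >= threshold)
  min(1, max(0, n_null / (ncol(ensemble) * n_obs)))
}

#' Permutation FDR curve over all attained thresholds
#'
#' Evaluates [permutation_fdr()] at every distinct observed statistic value
#' and enforces monotonicity (FDR non-increasing in the threshold) by the
#' standard q-value adjustment: the FDR reported at threshold `t` is the
#' minimum raw FDR over all rejection regions containing `t` (i.e. over
#' thresholds `<= t`), since cutting lower would reject a superset at a
#' smaller estimated FDR.
#'
#' @inheritParams permutation_fdr
#' @return `data.frame` with columns `threshold` (increasing), `fdr_raw`
#'   and `fdr` (monotone non-increasing).
#' @export
fdr_curve <- function(observed, ensemble) {
  ensemble <- as.matrix(ensemble)
  th <- sort(unique(observed))
  raw <- vapply(th, function(t) permutation_fdr(observed, ensemble, t),
                numeric(1))
  mono <- cummin(raw)
  data.frame(threshold = th, fdr_raw = raw, fdr = mono)
}

# FDR (monotone) attached to each observed value
fdr_at_observed <- function(observed, ensemble) {
  curve <- fdr_curve(observed, ensemble)
  curve$fdr[match(observed, curve$threshold)]
}

#' Select candidate SNP sites from the SNP-based scan
#'
#' The SNP-based statistic is `-log10` of the smallest of the three
#' hypothesis p-values. Sites are selected at the smallest attained
#' statistic threshold whose (monotone) permutation FDR is at or below
#' `fdr_max`.
#'
#' @param scan result of [assoc_scan()].
#' @param ensemble an `assoc_ensemble` from [assoc_permutations()].
#' @param fdr_max FDR ceiling, default 0.15.
#' @return `scan` rows of the selected candidates, with columns `stat` and
#'   `fdr` appended; zero rows when no threshold attains the ceiling.
#' @export
select_candidates <- function(scan, ensemble, fdr_max = 0.15) {
  stat <- -log10(pmin(scan$p_loss, scan$p_gain, scan$p_abnm))
  curve <- fdr_curve(stat, ensemble$stat)
  ok <- curve$threshold[curve$fdr <= fdr_max]
  scan$stat <- stat
  scan$fdr <- curve$fdr[match(stat, curve$threshold)]
  if (!length(ok)) return(scan[0, , drop = FALSE])
  scan[stat >= min(ok), , drop = FALSE]
}
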