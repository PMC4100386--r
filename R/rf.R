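#' Cross-cohort model p-values at one SNP site
#'
#' Tests the accordance of copy-number-state distributions between a
#' Reference and a Testing cohort through four models, each a Pearson
#' chi-square test of equality between two groups' state distributions at
#' the site (restricted to observed states; degenerate tables give p = 1):
#' \describe{
#'   \item{M00}{Testing cases vs Reference cases}
#'   \item{M10}{Testing controls vs Reference cases}
#'   \item{M01}{Testing cases vs Reference controls}
#'   \item{M11}{Testing controls vs Reference controls}
#' }
#' Concordant association (similar case distributions AND similar control
#' distributions, but cases differing from controls across cohorts) shows
#' as large p00/p11 and small p01/p10.
#'
#' @param reference,testing [state_matrix()] cohorts sharing one SNP map.
#' @param snp_index column index of the SNP.
#' @return list of class `rf_models` with elements `p00`, `p01`, `p10`,
#'   `p11`.
#' @export
model_pvalues <- function(reference, testing, snp_index) {
  stopifnot(inherits(reference, "state_matrix"),
            inherits(testing, "state_matrix"))
  if (ncol(reference$states) != ncol(testing$states))
    stop("cohorts must share the SNP map", call. = FALSE)
  if (snp_index < 1 || snp_index > ncol(reference$states))
    stop("`snp_index` out of range", call. = FALSE)
  grp <- function(sm, lab)
    tabulate(sm$states[sm$labels == lab, snp_index] + 1L, 5L)
  rc <- grp(reference, "case"); rn <- grp(reference, "control")
  tc <- grp(testing, "case");  tn <- grp(testing, "control")
  two_group_p <- function(g1, g2) {
    tab <- rbind(g1, g2)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) return(1)
    floor_p(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value))
  }
  structure(list(p00 = two_group_p(tc, rc),
                 p01 = two_group_p(tc, rn),
                 p10 = two_group_p(tn, rc),
                 p11 = two_group_p(tn, rn)),
            class = "rf_models")
}

#' Relative factor from the four model p-values
#'
#' `Rf = (p00 * p11) / (p01 * p10)`: the ratio of the concordant model
#' p-values (case/case and control/control agreement across cohorts) to the
#' discordant ones. The higher the value, the more similar the association
#' patterns of the two cohorts at the site. P-values are floored at
#' `p_min` before the ratio to prevent division blow-ups.
#'
#' @param models an `rf_models` list (or any list with `p00`, `p01`,
#'   `p10`, `p11`).
#' @param p_min floor applied to each p-value, default `1e-12`.
#' @return the relative factor (positive scalar).
#' @examples
#' relative_factor(list(p00 = 0.8, p01 = 0.1, p10 = 0.2, p11 = 0.9)) # 36
#' @export
relative_factor <- function(models, p_min = 1e-12) {
  p <- unlist(models[c("p00", "p01", "p10", "p11")])
  if (any(!is.finite(p)) || any(p <= 0))
    stop("model p-values must be positive", call. = FALSE)
  p <- pmax(p, p_min)
  (p[["p00"]] * p[["p11"]]) / (p[["p01"]] * p[["p10"]])
}

# vectorized four-model scan given the four groups' 5 x S count matrices
rf_from_counts <- function(rc, rn, tc, tn, p_min = 1e-12) {
  p00 <- pmax(pearson_p_2xK(tc, rc), p_min)
  p01 <- pmax(pearson_p_2xK(tc, rn), p_min)
  p10 <- pmax(pearson_p_2xK(tn, rc), p_min)
  p11 <- pmax(pearson_p_2xK(tn, rn), p_min)
  list(p00 = p00, p01 = p01, p10 = p10, p11 = p11,
       rf = (p00 * p11) / (p01 * p10))
}

#' Genome-wide relative-factor scan
#'
#' Computes the four model p-values and the relative factor at every SNP.
#'
#' @inheritParams model_pvalues
#' @param snp_map shared SNP map.
#' @param p_min p-value floor, as in [relative_factor()].
#' @return `data.frame`: `snp_id`, `p00`, `p01`, `p10`, `p11`, `rf`,
#'   `log10_rf`.
#' @export
rf_scan <- function(reference, testing, snp_map, p_min = 1e-12) {
  stopifnot(inherits(reference, "state_matrix"),
            inherits(testing, "state_matrix"))
  validate_snp_map(snp_map)
  if (ncol(reference$states) != nrow(snp_map) ||
      ncol(testing$states) != nrow(snp_map))
    stop("cohorts must share the SNP map", call. = FALSE)
  rc <- state_counts(reference$states, reference$labels == "case")
  rn <- state_counts(reference$states, reference$labels == "control")
  tc <- state_counts(testing$states, testing$labels == "case")
  tn <- state_counts(testing$states, testing$labels == "control")
  m <- rf_from_counts(rc, rn, tc, tn, p_min)
  data.frame(snp_id = snp_map$snp_id,
             p00 = m$p00, p01 = m$p01, p10 = m$p10, p11 = m$p11,
             rf = m$rf, log10_rf = log10(m$rf),
             stringsAsFactors = FALSE)
}

#' Relative factors under joint label permutations
#'
#' Labels are permuted independently within each cohort (arm sizes
#' preserved) and the full four-model Rf is recomputed per site and
#' replicate.
#'
#' @inheritParams rf_scan
#' @param perms_ref,perms_test permutation matrices from
#'   [permute_labels()], one per cohort, with equal column counts.
#' @return matrix, sites x permutations, of Rf values (rownames = snp ids).
#' @export
rf_permutations <- function(reference, testing, snp_map, perms_ref,
                            perms_test, p_min = 1e-12) {
  if (ncol(perms_ref) != ncol(perms_test))
    stop("both cohorts need the same number of permutations", call. = FALSE)
  t_pm <- ncol(perms_ref)
  S <- nrow(snp_map)
  # per-state indicator matrices, computed once per cohort
  ind_ref <- lapply(0:4, function(s)
    matrix(as.numeric(reference$states == s), nrow(reference$states)))
  ind_test <- lapply(0:4, function(s)
    matrix(as.numeric(testing$states == s), nrow(testing$states)))
  counts_for <- function(ind, grp)
    do.call(rbind, lapply(ind, function(M)
      as.vector(crossprod(as.numeric(grp), M))))
  out <- matrix(0, S, t_pm)
  for (m in seq_len(t_pm)) {
    rcase <- perms_ref[, m]
    tcase <- perms_test[, m]
    rc <- counts_for(ind_ref, rcase)
    rn <- counts_for(ind_ref, !rcase)
    tc <- counts_for(ind_test, tcase)
    tn <- counts_for(ind_test, !tcase)
    out[, m] <- rf_from_counts(rc, rn, tc, tn, p_min)$rf
  }
  rownames(out) <- snp_map$snp_id
  out
}

#' Permutation FDR for the relative factor
#'
#' `FDR(rf_site) = [sum_m #\{sites: Rf^(m) in tail\}] /
#' (T_pm x #\{sites: Rf in tail\})`, clamped to `[0, 1]`. The accordance
#' tail is `Rf >= rf_site` by default (high Rf = concordant association);
#' the opposite low tail is available with `tail = "le"`.
#'
#' @param observed_rf per-site observed Rf vector.
#' @param ensemble sites x permutations Rf matrix from
#'   [rf_permutations()].
#' @param rf_site Rf threshold; some observed site must lie in its tail.
#' @param tail `"ge"` (default, accordance tail) or `"le"`.
#' @return FDR estimate in `[0, 1]`.
#' @export
rf_fdr <- function(observed_rf, ensemble, rf_site, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (tail == "ge")
    permutation_fdr(observed_rf, ensemble, rf_site)
  else
    permutation_fdr(-observed_rf, -as.matrix(ensemble), -rf_site)
}

#' Joint (window, Rf) risk-locus selection under a false-positive budget
#'
#' Starting from the window-passing sites, finds the smallest Rf threshold
#' `t` (searched over the observed Rf values of those sites) such that the
#' permutation-estimated expected number of null sites jointly passing the
#' window criterion and `Rf >= t` stays below `fp_budget`, then selects
#' the window-passing sites with `Rf >= t`. With the default budget of 1
#' the expected count of false positives among the reported risk loci is
#' below one.
#'
#' @param window_results window-passing sites from [select_windows()] (or
#'   [window_test()] output restricted to the passing set).
#' @param rf_results result of [rf_scan()].
#' @param rf_perm sites x permutations Rf matrix from
#'   [rf_permutations()]; rows are matched to `rf_results$snp_id` by
#'   rowname.
#' @param fp_budget expected false positives tolerated (> 0), default 1.
#' @param tail Rf tail direction, as in [rf_fdr()].
#' @return `data.frame` of selected risk loci: `snp_id`, `chrom`, `pos`,
#'   `hypothesis` (the locus type), `s_w`, `rf`, `log10_rf`, plus
#'   attribute `"rf_threshold"`. Empty (with a warning) when no threshold
#'   satisfies the budget.
#' @export
select_risk_loci <- function(window_results, rf_results, rf_perm,
                             fp_budget = 1, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (fp_budget <= 0) stop("`fp_budget` must be > 0", call. = FALSE)
  if (nrow(window_results) == 0) return(empty_risk_loci())
  j <- match(window_results$snp_id, rf_results$snp_id)
  if (any(is.na(j)))
    stop("window results and rf results must index the same sites",
         call. = FALSE)
  rf <- rf_results$rf[j]
  perm <- as.matrix(rf_perm)[match(window_results$snp_id,
                                   rownames(rf_perm)), , drop = FALSE]
  if (any(is.na(perm)))
    stop("`rf_perm` must cover all window-passing sites", call. = FALSE)
  sgn <- if (tail == "ge") 1 else -1
  obs <- sgn * rf
  nullmat <- sgn * perm
  t_pm <- ncol(nullmat)
  # expected null joint count is non-increasing in t: smallest passing
  # threshold among observed values is well-defined
  cand_t <- sort(unique(obs))
  expected <- vapply(cand_t, function(t) sum(nullmat >= t) / t_pm,
                     numeric(1))
  ok <- which(expected < fp_budget)
  if (!length(ok)) {
    warning("no Rf threshold satisfies the false-positive budget; ",
            "returning no risk loci")
    return(empty_risk_loci())
  }
  t_star <- cand_t[min(ok)]
  keep <- obs >= t_star
  out <- data.frame(snp_id = window_results$snp_id[keep],
                    chrom = window_results$chrom[keep],
                    pos = window_results$pos[keep],
                    hypothesis = window_results$hypothesis[keep],
                    s_w = window_results$s_w[keep],
                    rf = rf[keep],
                    log10_rf = log10(rf[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rf_threshold") <- sgn * t_star
  out
}

empty_risk_loci <- function() {
  data.frame(snp_id = character(), chrom = integer(), pos = numeric(),
             hypothesis = character(), s_w = numeric(), rf = numeric(),
             log10_rf = numeric(), stringsAsFactors = FALSE)
}
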