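#' Cross-tabulate one SNP site
#'
#' Builds the 2 x 5 case/control-by-state count table at one SNP, plus the
#' collapsed 2 x 2 carrier tables for the three CNV hypotheses:
#' loss (states \{0, 1\}), gain (states \{3, 4\}) and abnormal
#' (states \{0, 1, 3, 4\}).
#'
#' @param states a [state_matrix()].
#' @param snp_index column index of the SNP.
#' @return a list of class `site_table` with elements `counts` (2 x 5,
#'   rows case/control, columns states 0--4) and `collapsed` (named list of
#'   2 x 2 matrices with columns carrier / non-carrier).
#' @export
tabulate_site <- function(states, snp_index) {
  stopifnot(inherits(states, "state_matrix"))
  if (snp_index < 1 || snp_index > ncol(states$states))
    stop("`snp_index` out of range", call. = FALSE)
  s <- states$states[, snp_index]
  counts <- rbind(
    case = tabulate(s[states$labels == "case"] + 1L, 5L),
    control = tabulate(s[states$labels == "control"] + 1L, 5L))
  colnames(counts) <- as.character(0:4)
  collapsed <- lapply(hypothesis_states(), function(set) {
    carrier <- rowSums(counts[, as.character(set), drop = FALSE])
    cbind(carrier = carrier, noncarrier = rowSums(counts) - carrier)
  })
  structure(list(counts = counts, collapsed = collapsed),
            class = "site_table")
}

hypothesis_states <- function() {
  list(loss = c(0L, 1L), gain = c(3L, 4L), abnm = c(0L, 1L, 3L, 4L))
}

#' Test one SNP site for case-control association
#'
#' Computes, from a [tabulate_site()] table: the Pearson chi-square p-value
#' on the 2 x K table restricted to observed states; two-sided Fisher exact
#' p-values on the collapsed loss / gain / abnormal carrier tables; and the
#' Cochran-Armitage trend p-value with copy numbers (0--4) as scores.
#' Degenerate tables (a zero-variance margin) yield p = 1. The reported
#' `best_hypothesis` is the one with the smallest of the three collapsed
#' p-values (ties broken in the order loss, gain, abnm).
#'
#' @param table a `site_table`.
#' @param snp_id optional SNP identifier carried into the result.
#' @return a one-row `data.frame`: `snp_id`, `p_pearson`, `p_loss`,
#'   `p_gain`, `p_abnm`, `p_trend`, `best_hypothesis`.
#' @export
test_site <- function(table, snp_id = NA_character_) {
  stopifnot(inherits(table, "site_table"))
  counts <- table$counts
  if (any(rowSums(counts) == 0))
    stop("both cohorts must be non-empty", call. = FALSE)
  obs <- counts[, colSums(counts) > 0, drop = FALSE]
  p_pearson <- if (ncol(obs) < 2) 1 else
    suppressWarnings(stats::chisq.test(obs, correct = FALSE)$p.value)
  p_hyp <- vapply(table$collapsed, function(tab) {
    if (any(colSums(tab) == 0)) 1 else stats::fisher.test(tab)$p.value
  }, numeric(1))
  p_trend <- trend_p_single(counts)
  # tie-break on rounded p so sub-ulp numerical noise cannot flip the call
  best <- names(p_hyp)[which.min(signif(floor_p(p_hyp), 12))]
  data.frame(snp_id = snp_id,
             p_pearson = floor_p(p_pearson),
             p_loss = floor_p(p_hyp[["loss"]]),
             p_gain = floor_p(p_hyp[["gain"]]),
             p_abnm = floor_p(p_hyp[["abnm"]]),
             p_trend = floor_p(p_trend),
             best_hypothesis = best,
             stringsAsFactors = FALSE)
}

trend_p_single <- function(counts) {
  keep <- colSums(counts) > 0
  if (sum(keep) < 2) return(1)
  x <- counts["case", keep]
  n <- colSums(counts)[keep]
  if (sum(x) == 0 || sum(x) == sum(n)) return(1)
  scores <- as.numeric(colnames(counts))[keep]
  suppressWarnings(stats::prop.trend.test(x, n, score = scores)$p.value)
}

# clamp p-values to (0, 1]: strictly positive and capped at 1 (fisher.test
# can return 1 + eps, which would break tie-breaking on degenerate tables)
floor_p <- function(p) pmin(pmax(p, 1e-300), 1)

## ---- vectorized engine -----------------------------------------------
## The scan/permutation machinery below computes the same quantities as the
## stats:: calls in test_site() in closed form across all sites at once;
## equality is asserted site-by-site in the test suite.

# 5 x S state count matrix for a set of individuals (matrix rows)
state_counts <- function(states, rows) {
  sub <- states[rows, , drop = FALSE]
  out <- matrix(0, 5, ncol(states))
  for (s in 0:4)
    out[s + 1L, ] <- .colSums(sub == s, nrow(sub), ncol(sub))
  out
}

# Pearson chi-square p for 2 x K tables across sites.
# A, B: 5 x S count matrices (the two groups); columns with zero total are
# excluded from both the statistic and the degrees of freedom.
pearson_p_2xK <- function(A, B) {
  tot <- A + B
  rA <- .colSums(A, 5, ncol(A))
  rB <- .colSums(B, 5, ncol(B))
  N <- rA + rB
  EA <- sweep(tot, 2, rA / N, `*`)
  EB <- sweep(tot, 2, rB / N, `*`)
  contrib <- ifelse(tot > 0, (A - EA)^2 / EA + (B - EB)^2 / EB, 0)
  chi2 <- .colSums(contrib, 5, ncol(A))
  df <- .colSums(tot > 0, 5, ncol(A)) - 1
  p <- rep(1, ncol(A))
  ok <- df >= 1 & rA > 0 & rB > 0
  p[ok] <- stats::pchisq(chi2[ok], df[ok], lower.tail = FALSE)
  floor_p(p)
}

# Cochran-Armitage trend p across sites (scores = copy numbers 0..4)
trend_p_2x5 <- function(A, B, scores = 0:4) {
  n <- A + B
  N <- .colSums(n, 5, ncol(n))
  xs <- .colSums(A, 5, ncol(A))          # total cases per site
  pbar <- xs / N
  w <- scores
  num <- .colSums(A * w, 5, ncol(A)) - pbar * .colSums(n * w, 5, ncol(n))
  denom <- pbar * (1 - pbar) *
    (.colSums(n * w^2, 5, ncol(n)) - .colSums(n * w, 5, ncol(n))^2 / N)
  p <- rep(1, ncol(A))
  ok <- denom > 0
  p[ok] <- stats::pchisq(num[ok]^2 / denom[ok], 1, lower.tail = FALSE)
  floor_p(p)
}

# Two-sided Fisher exact p for many 2x2 tables sharing the case/control
# margin: a = case carriers, m = total carriers, n1 cases, n2 controls.
# Lookup tables are built per distinct m (the hypergeometric support is
# fixed by the margins), matching fisher.test's two-sided rule: the sum of
# all outcome probabilities <= (1 + 1e-7) x the observed one.
fisher_lookup <- function(m, n1, n2) {
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  k <- lo:hi
  dh <- stats::dhyper(k, n1, n2, m)
  p <- vapply(seq_along(k),
              function(i) sum(dh[dh <= dh[i] * (1 + 1e-7)]),
              numeric(1))
  full <- rep(NA_real_, m + 1L)
  full[k + 1L] <- pmin(p, 1)
  full
}

fisher_p_many <- function(a, m, n1, n2) {
  p <- numeric(length(a))
  for (mm in unique(m)) {
    idx <- which(m == mm)
    if (mm == 0L) { p[idx] <- 1; next }
    tab <- fisher_lookup(mm, n1, n2)
    p[idx] <- tab[a[idx] + 1L]
  }
  floor_p(p)
}

# carrier indicator matrices (individuals x SNPs) per hypothesis
carrier_matrices <- function(states) {
  lapply(hypothesis_states(), function(set)
    matrix(as.numeric(states %in% set), nrow = nrow(states)))
}

#' Per-SNP association scan
#'
#' Applies [test_site()]'s battery of tests to every SNP at once (via an
#' internal vectorized engine that reproduces the single-site results
#' exactly).
#'
#' @param states a [state_matrix()].
#' @param snp_map the matching SNP map.
#' @return a `data.frame` with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `p_pearson`, `p_loss`, `p_gain`, `p_abnm`, `p_trend`,
#'   `best_hypothesis`.
#' @export
assoc_scan <- function(states, snp_map) {
  stopifnot(inherits(states, "state_matrix"))
  validate_snp_map(snp_map)
  if (nrow(snp_map) != ncol(states$states))
    stop("SNP map does not match the state matrix", call. = FALSE)
  case <- states$labels == "case"
  A <- state_counts(states$states, case)
  B <- state_counts(states$states, !case)
  n1 <- sum(case); n2 <- sum(!case)
  cm <- carrier_matrices(states$states)
  hyp <- lapply(cm, function(C) {
    m <- as.integer(round(.colSums(C, nrow(C), ncol(C))))
    a <- as.integer(round(as.vector(crossprod(as.numeric(case), C))))
    fisher_p_many(a, m, n1, n2)
  })
  ph <- cbind(loss = hyp$loss, gain = hyp$gain, abnm = hyp$abnm)
  best <- colnames(ph)[max.col(-signif(ph, 12), ties.method = "first")]
  data.frame(snp_id = snp_map$snp_id, chrom = snp_map$chrom,
             pos = snp_map$pos,
             p_pearson = pearson_p_2xK(A, B),
             p_loss = ph[, "loss"], p_gain = ph[, "gain"],
             p_abnm = ph[, "abnm"],
             p_trend = trend_p_2x5(A, B),
             best_hypothesis = best,
             stringsAsFactors = FALSE)
}
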