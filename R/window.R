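#' Window-based CNV pattern testing
#'
#' For each candidate SNP, evidence is aggregated over a window of
#' `half_width` consecutive SNPs on either side of the candidate (never
#' crossing a chromosome boundary, and truncated where the gap between two
#' neighboring SNPs exceeds `max_gap`). The window statistic is
#' `S_w = sum over members of -log10 p_h`, where `h` is the candidate's
#' best hypothesis and member p-values are floored at `p_floor` to keep the
#' sum finite.
#'
#' @param results per-site results from [assoc_scan()] (all sites).
#' @param snp_map the matching SNP map.
#' @param candidates character vector of candidate `snp_id`s (must be a
#'   subset of `results$snp_id`).
#' @param half_width window half-width in SNPs (>= 0); default 2, i.e. a
#'   5-SNP window.
#' @param max_gap maximal inter-SNP distance (bp) treated as consecutive;
#'   default 30 kb.
#' @param p_floor lower bound applied to member p-values before `-log10`.
#' @return `data.frame` with one row per candidate: `snp_id`, `chrom`,
#'   `pos`, `hypothesis`, `s_w`, `members` (comma-separated member ids),
#'   plus attribute `"member_idx"` (list of member row indices into
#'   `results`).
#' @export
window_test <- function(results, snp_map, candidates, half_width = 2,
                        max_gap = 30000, p_floor = 1 / (2e6)) {
  if (half_width < 0) stop("`half_width` must be >= 0", call. = FALSE)
  idx <- match(candidates, results$snp_id)
  if (any(is.na(idx)))
    stop("candidates must be a subset of the tested sites", call. = FALSE)
  member_idx <- lapply(idx, function(i)
    window_members(i, snp_map, half_width, max_gap))
  hyp <- results$best_hypothesis[idx]
  s_w <- vapply(seq_along(idx), function(k) {
    p <- results[[paste0("p_", hyp[k])]][member_idx[[k]]]
    sum(-log10(pmax(p, p_floor)))
  }, numeric(1))
  out <- data.frame(
    snp_id = results$snp_id[idx],
    chrom = results$chrom[idx],
    pos = results$pos[idx],
    hypothesis = hyp,
    s_w = s_w,
    members = vapply(member_idx, function(m)
      paste(results$snp_id[m], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(out, "member_idx") <- member_idx
  out
}

# member row indices of the window around site i (row of snp_map)
window_members <- function(i, snp_map, half_width, max_gap) {
  chrom <- snp_map$chrom
  pos <- snp_map$pos
  lo <- i
  while (lo > 1 && i - lo < half_width &&
         chrom[lo - 1] == chrom[i] &&
         pos[lo] - pos[lo - 1] <= max_gap)
    lo <- lo - 1
  hi <- i
  n <- nrow(snp_map)
  while (hi < n && hi - i < half_width &&
         chrom[hi + 1] == chrom[i] &&
         pos[hi + 1] - pos[hi] <= max_gap)
    hi <- hi + 1
  lo:hi
}

#' Window statistics under label permutations
#'
#' Recomputes every candidate's window statistic for each permutation,
#' re-using the fixed windows and hypotheses of the observed analysis (the
#' permutation null is conditional on the selected windows).
#'
#' @param windows result of [window_test()].
#' @param ensemble an `assoc_ensemble` from [assoc_permutations()].
#' @param p_floor as in [window_test()].
#' @return matrix, candidates x permutations, of `S_w` values.
#' @export
window_permutations <- function(windows, ensemble, p_floor = 1 / (2e6)) {
  member_idx <- attr(windows, "member_idx")
  if (is.null(member_idx))
    stop("`windows` must come from window_test()", call. = FALSE)
  t_pm <- ensemble$t_pm
  out <- matrix(0, nrow(windows), t_pm)
  for (k in seq_len(nrow(windows))) {
    pm <- ensemble[[paste0("p_", windows$hypothesis[k])]][
      member_idx[[k]], , drop = FALSE]
    out[k, ] <- .colSums(-log10(pmax(pm, p_floor)),
                         length(member_idx[[k]]), t_pm)
  }
  rownames(out) <- windows$snp_id
  out
}

#' Select window-passing sites at an FDR ceiling
#'
#' @param windows result of [window_test()].
#' @param window_perm matrix from [window_permutations()].
#' @param fdr_max FDR ceiling on the window statistic, default 0.15.
#' @return the passing rows of `windows` with `fdr` appended (monotone
#'   permutation FDR at each site's statistic), and the attribute
#'   `"member_idx"` subset accordingly.
#' @export
select_windows <- function(windows, window_perm, fdr_max = 0.15) {
  fdr <- fdr_at_observed(windows$s_w, window_perm)
  windows$fdr <- fdr
  keep <- which(fdr <= fdr_max)
  out <- windows[keep, , drop = FALSE]
  attr(out, "member_idx") <- attr(windows, "member_idx")[keep]
  out
}
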