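#' Recombination-rate level around a SNP
#'
#' `level = log10(max rate over the map intervals intersecting the window
#' centered on the SNP)`. The window spans `window` bp in total (default
#' 10 kb, i.e. +/- 5 kb); rates are floored at `rate_floor` before the log
#' so the level stays finite. Returns `NA` when no interval intersects the
#' window (the SNP falls outside map coverage).
#'
#' @param pos SNP position(s), bp.
#' @param chrom chromosome(s), recycled against `pos`.
#' @param recomb_map a `recomb_map` (see [make_recomb_map()],
#'   [read_recomb_map()]).
#' @param window total window span in bp, default 10000.
#' @param rate_floor rate floor in cM/Mb, default `1e-4`.
#' @return numeric vector of levels (`NA` where uncovered).
#' @export
recomb_level <- function(pos, chrom, recomb_map, window = 10000,
                         rate_floor = 1e-4) {
  stopifnot(inherits(recomb_map, "recomb_map"))
  n <- max(length(pos), length(chrom))
  pos <- rep_len(pos, n); chrom <- rep_len(chrom, n)
  iv <- recomb_map$intervals
  half <- window / 2
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    which_q <- which(chrom == ch)
    if (!nrow(ivc)) next
    q <- IRanges::IRanges(start = pmax(1, pos[which_q] - half),
                          end = pos[which_q] + half)
    s <- IRanges::IRanges(start = ivc$start, end = ivc$end)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    mx <- tapply(ivc$rate[S4Vectors::subjectHits(ov)], qh, max)
    out[which_q[as.integer(names(mx))]] <- as.numeric(mx)
  }
  log10(pmax(out, rate_floor))
}

#' Assign SNPs to analysis-stage groups
#'
#' Hierarchical, exclusive grouping by the furthest stage each SNP passed:
#' `window_Rf` (selected risk locus) > `window` (window-passing) >
#' `snp_based` (SNP-based candidate) > `not_sig`.
#'
#' @param snp_ids all tested SNP ids.
#' @param candidates ids passing SNP-based testing.
#' @param window_pass ids passing window-based testing.
#' @param risk_loci ids selected by the combined (window + Rf) analysis.
#' @return factor of groups with levels
#'   `not_sig, snp_based, window, window_Rf`.
#' @export
assign_snp_groups <- function(snp_ids, candidates, window_pass,
                              risk_loci) {
  grp <- rep("not_sig", length(snp_ids))
  grp[snp_ids %in% candidates] <- "snp_based"
  grp[snp_ids %in% window_pass] <- "window"
  grp[snp_ids %in% risk_loci] <- "window_Rf"
  factor(grp, levels = c("not_sig", "snp_based", "window", "window_Rf"))
}

#' Compare recombination levels across analysis-stage groups
#'
#' Reports the per-group sum and mean of recombination levels, and a
#' permutation p-value for the risk-locus group (`window_Rf`) having a
#' higher mean level than the non-significant group: group labels are
#' shuffled between those two groups `n_perm` times and the p-value is
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`. SNPs with missing levels
#' are excluded; empty groups are dropped with a warning.
#'
#' @param levels `data.frame` with columns `level` (numeric) and `group`
#'   (factor from [assign_snp_groups()]).
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed.
#' @return list with `summary` (`data.frame`: group, n, sum, mean) and
#'   `p_value` (NA when either compared group is empty).
#' @export
compare_recomb_groups <- function(levels, n_perm = 1000, seed = 1L) {
  stopifnot(all(c("level", "group") %in% names(levels)))
  lv <- levels[!is.na(levels$level), , drop = FALSE]
  counts <- table(lv$group)
  if (any(counts == 0))
    warning("dropping empty group(s): ",
            paste(names(counts)[counts == 0], collapse = ", "))
  if (sum(counts > 0) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  summ <- do.call(rbind, lapply(names(counts)[counts > 0], function(g) {
    x <- lv$level[lv$group == g]
    data.frame(group = g, n = length(x), sum = sum(x), mean = mean(x),
               stringsAsFactors = FALSE)
  }))
  x_rf <- lv$level[lv$group == "window_Rf"]
  x_ns <- lv$level[lv$group == "not_sig"]
  p <- NA_real_
  if (length(x_rf) && length(x_ns)) {
    obs <- mean(x_rf) - mean(x_ns)
    pool <- c(x_rf, x_ns)
    n_rf <- length(x_rf)
    p <- withr_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        pick <- sample.int(length(pool), n_rf)
        if (mean(pool[pick]) - mean(pool[-pick]) >= obs) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  list(summary = summ, p_value = p)
}

#' Overlap of CNV records with recombination hotspots
#'
#' A CNV overlaps when any hotspot interval intersects its closed 1-based
#' span `[start_pos, end_pos]` (sharing a single bp counts). Counts are
#' reported per CNV type.
#'
#' @param cnvs CNV record `data.frame` (needs `chrom`, `start_pos`,
#'   `end_pos`, `cnv_type`).
#' @param hotspots `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive, e.g. from [read_hotspots_bed()] or
#'   `recomb_map$hotspots`).
#' @return `data.frame` with one row per CNV type: `cnv_type`,
#'   `overlapping`, `total`.
#' @export
hotspot_overlap <- function(cnvs, hotspots) {
  if (!nrow(cnvs))
    return(data.frame(cnv_type = character(), overlapping = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  hit <- rep(FALSE, nrow(cnvs))
  for (ch in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == ch)
    h <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    if (!nrow(h)) next
    q <- IRanges::IRanges(start = cnvs$start_pos[ci],
                          end = cnvs$end_pos[ci])
    s <- IRanges::IRanges(start = h$start, end = h$end)
    ov <- IRanges::findOverlaps(q, s)
    hit[ci[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  types <- sort(unique(cnvs$cnv_type))
  data.frame(cnv_type = types,
             overlapping = vapply(types, function(tp)
               sum(hit[cnvs$cnv_type == tp]), integer(1)),
             total = vapply(types, function(tp)
               sum(cnvs$cnv_type == tp), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
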