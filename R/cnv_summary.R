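#' Call raw per-individual CNV segments
#'
#' A raw CNV is a maximal run of three or more consecutive SNPs sharing the
#' same abnormal copy-number state (any state other than 2) within one
#' individual; runs never cross a chromosome boundary, and runs of mixed
#' abnormal states are not merged. These raw calls are descriptive only --
#' the reliable CNVs come from the association layers.
#'
#' @param states a [state_matrix()].
#' @param snp_map the matching SNP map.
#' @param min_snps minimal run length, default 3.
#' @return `data.frame` with one row per segment: `individual_id`,
#'   `label`, `chrom`, `first_snp`, `last_snp` (map row indices),
#'   `start_pos`, `end_pos`, `state`, `n_snps`.
#' @export
call_raw_cnvs <- function(states, snp_map, min_snps = 3L) {
  stopifnot(inherits(states, "state_matrix"))
  validate_snp_map(snp_map)
  if (nrow(snp_map) != ncol(states$states))
    stop("SNP map does not match the state matrix", call. = FALSE)
  chrom_blocks <- split(seq_len(nrow(snp_map)), snp_map$chrom)
  ids <- rownames(states$states)
  labs <- as.character(states$labels)
  segs <- vector("list", 0L)
  for (i in seq_len(nrow(states$states))) {
    row <- states$states[i, ]
    for (idx in chrom_blocks) {
      r <- rle(row[idx])
      if (!length(r$lengths)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values != 2L & r$lengths >= min_snps)
      for (k in hit) {
        fs <- idx[starts[k]]; ls <- idx[ends[k]]
        segs[[length(segs) + 1L]] <- data.frame(
          individual_id = ids[i], label = labs[i],
          chrom = snp_map$chrom[fs],
          first_snp = fs, last_snp = ls,
          start_pos = snp_map$pos[fs], end_pos = snp_map$pos[ls],
          state = unname(r$values[k]), n_snps = unname(r$lengths[k]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(segs))
    return(data.frame(individual_id = character(), label = character(),
                      chrom = integer(), first_snp = integer(),
                      last_snp = integer(), start_pos = numeric(),
                      end_pos = numeric(), state = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of raw CNVs per cohort arm
#'
#' Summarizes [call_raw_cnvs()] output separately for cases and controls:
#' average CNVs per individual (over all individuals of the arm, including
#' those without any segment), SNPs per CNV (min / max / average) and CNV
#' size in bp (`end_pos - start_pos`; min / max / average).
#'
#' @param segments segment `data.frame` from [call_raw_cnvs()].
#' @param labels per-individual labels of the cohort the segments came
#'   from (used for arm sizes).
#' @return `data.frame` with rows `case` and `control` and columns
#'   `n_individuals`, `avg_cnvs_per_individual`, `snps_min`, `snps_max`,
#'   `snps_avg`, `size_min_bp`, `size_max_bp`, `size_avg_bp`. All-zero rows
#'   (with a warning) when an arm has no segments.
#' @export
summarize_raw_cnvs <- function(segments, labels) {
  labels <- as.character(labels)
  arms <- c("case", "control")
  rows <- lapply(arms, function(arm) {
    n_ind <- sum(labels == arm)
    seg <- segments[segments$label == arm, , drop = FALSE]
    if (!nrow(seg)) {
      warning("no raw CNV segments for arm '", arm, "'; reporting zeros")
      return(data.frame(arm = arm, n_individuals = n_ind,
                        avg_cnvs_per_individual = 0,
                        snps_min = 0, snps_max = 0, snps_avg = 0,
                        size_min_bp = 0, size_max_bp = 0, size_avg_bp = 0,
                        stringsAsFactors = FALSE))
    }
    size <- seg$end_pos - seg$start_pos
    data.frame(arm = arm, n_individuals = n_ind,
               avg_cnvs_per_individual = nrow(seg) / n_ind,
               snps_min = min(seg$n_snps), snps_max = max(seg$n_snps),
               snps_avg = mean(seg$n_snps),
               size_min_bp = min(size), size_max_bp = max(size),
               size_avg_bp = mean(size), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CNV size in kb from its coordinates
#'
#' `(end_pos - start_pos) / 1000`, rounded half-up to one decimal -- the
#' convention that reproduces published CNV tables from their printed
#' coordinates.
#'
#' @param start_pos,end_pos 1-based bp coordinates, `start_pos < end_pos`.
#' @return size in kb with one decimal.
#' @examples
#' cnv_size_kb(113681735, 113741162)  # 59.4
#' @export
cnv_size_kb <- function(start_pos, end_pos) {
  if (any(end_pos <= start_pos))
    stop("`end_pos` must exceed `start_pos`", call. = FALSE)
  # integer-safe half-up rounding to 0.1 kb
  floor((end_pos - start_pos) / 100 + 0.5) / 10
}

#' Summarize consecutive risk loci into CNV records
#'
#' Chains risk loci whose successive inter-locus distances are at most
#' `max_gap` (never crossing chromosomes); maximal chains of at least
#' `min_loci` loci become CNV records, the rest are reported as singular
#' risk loci. The record type follows the member hypotheses. `abnm` is a
#' composite (deletion-or-amplification) hypothesis, so it is compatible
#' with either direction: a chain whose directional members are all `gain`
#' is an Amplification, all `loss` a Deletion (in both cases `abnm`
#' members may be interspersed); chains with mixed directions, or with no
#' directional member at all, are Abnormal.
#'
#' @param risk_loci `data.frame` with columns `snp_id`, `chrom`, `pos` and
#'   `hypothesis` (`"loss"` / `"gain"` / `"abnm"`), sorted by
#'   (chrom, pos) -- e.g. the output of [select_risk_loci()].
#' @param max_gap consecutiveness distance in bp, default 30 kb.
#' @param min_loci minimal chain length, default 3.
#' @param dataset label stored in the records.
#' @return list with elements `cnvs` (a `data.frame`: `dataset`, `chrom`,
#'   `start_pos`, `end_pos`, `size_kb`, `cnv_type`, `n_loci`, `loci`) and
#'   `singular` (the loci left outside any record).
#' @export
blocks_to_cnvs <- function(risk_loci, max_gap = 30000, min_loci = 3L,
                           dataset = "cohort") {
  need <- c("snp_id", "chrom", "pos", "hypothesis")
  stopifnot(all(need %in% names(risk_loci)))
  n <- nrow(risk_loci)
  if (n == 0)
    return(list(cnvs = empty_cnv_records(), singular = risk_loci))
  o <- order(risk_loci$chrom, risk_loci$pos)
  if (!identical(o, seq_len(n)))
    stop("`risk_loci` must be sorted by (chrom, pos)", call. = FALSE)
  new_chain <- c(TRUE, diff(risk_loci$chrom) != 0 |
                   diff(risk_loci$pos) > max_gap)
  chain <- cumsum(new_chain)
  recs <- list(); singular <- integer()
  for (cid in unique(chain)) {
    idx <- which(chain == cid)
    if (length(idx) < min_loci) {
      singular <- c(singular, idx)
      next
    }
    hyp <- risk_loci$hypothesis[idx]
    type <- if (any(hyp == "gain") && !any(hyp == "loss")) "Amplification"
            else if (any(hyp == "loss") && !any(hyp == "gain")) "Deletion"
            else "Abnormal"
    start <- risk_loci$pos[idx[1]]
    end <- risk_loci$pos[idx[length(idx)]]
    recs[[length(recs) + 1L]] <- data.frame(
      dataset = dataset, chrom = risk_loci$chrom[idx[1]],
      start_pos = start, end_pos = end,
      size_kb = cnv_size_kb(start, end),
      cnv_type = type, n_loci = length(idx),
      loci = paste(risk_loci$snp_id[idx], collapse = ","),
      stringsAsFactors = FALSE)
  }
  cnvs <- if (length(recs)) do.call(rbind, recs) else empty_cnv_records()
  rownames(cnvs) <- NULL
  list(cnvs = cnvs,
       singular = risk_loci[singular, , drop = FALSE])
}

empty_cnv_records <- function() {
  data.frame(dataset = character(), chrom = integer(),
             start_pos = numeric(), end_pos = numeric(),
             size_kb = numeric(), cnv_type = character(),
             n_loci = integer(), loci = character(),
             stringsAsFactors = FALSE)
}

#' Genes within a flank of any risk locus
#'
#' Returns the unique, sorted names of annotation intervals intersecting
#' the closed interval `[pos - flank, pos + flank]` around any risk locus
#' (a gene sitting exactly at the boundary is included).
#'
#' @param risk_loci `data.frame` with `chrom` and `pos`.
#' @param genes annotation `data.frame` with `chrom`, `start`, `end`,
#'   `name` (1-based inclusive coordinates).
#' @param flank flank size in bp, default 100 kb.
#' @return sorted character vector of gene names.
#' @export
neighboring_genes <- function(risk_loci, genes, flank = 100000) {
  if (!nrow(risk_loci) || !nrow(genes)) return(character())
  hits <- character()
  for (ch in unique(risk_loci$chrom)) {
    loci <- risk_loci[risk_loci$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    q <- IRanges::IRanges(start = loci$pos - flank, end = loci$pos + flank)
    s <- IRanges::IRanges(start = g$start, end = g$end)
    ov <- IRanges::findOverlaps(q, s)
    hits <- c(hits, g$name[unique(S4Vectors::subjectHits(ov))])
  }
  sort(unique(hits))
}

#' Read a gene annotation from BED or simple TSV
#'
#' BED input (no header, 0-based half-open) is converted to the internal
#' 1-based inclusive convention; TSV input must carry a header with
#' columns `chrom`, `start`, `end`, `name` already 1-based.
#'
#' @param path file path; format chosen by extension (`.bed` = BED).
#' @return `data.frame` with `chrom`, `start`, `end`, `name`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(chrom = as.integer(sub("^chr", "", bed[[1]])),
                      start = bed[[2]] + 1, end = bed[[3]],
                      name = if (ncol(bed) >= 4) bed[[4]] else
                        sprintf("feature%d", seq_len(nrow(bed))),
                      stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
    out$chrom <- as.integer(sub("^chr", "", as.character(out$chrom)))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write CNV records as BED and as a summary TSV
#'
#' The BED output converts internal 1-based inclusive coordinates to
#' 0-based half-open (`start - 1`, `end`).
#'
#' @param cnvs CNV record `data.frame` from [blocks_to_cnvs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(cnvs, path) {
  df <- data.frame(chrom = cnvs$chrom, start = cnvs$start_pos,
                   end = cnvs$end_pos)
  write_intervals_bed(df, path, names = cnvs$cnv_type)
}

#' @rdname write_cnv_bed
#' @export
write_cnv_table <- function(cnvs, path) {
  write.table(cnvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV summary table
#'
#' Accepts the package's own [write_cnv_table()] output or any TSV with at
#' least `chrom`, `start_pos`, `end_pos` and `cnv_type` columns (e.g. a
#' transcription of a published CNV table); `size_kb` is recomputed from
#' the coordinates when absent.
#'
#' @param path TSV path.
#' @return CNV record `data.frame`.
#' @export
read_cnv_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$chrom <- as.integer(sub("^chr", "", as.character(df$chrom)))
  if (is.null(df$size_kb))
    df$size_kb <- cnv_size_kb(df$start_pos, df$end_pos)
  df
}
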