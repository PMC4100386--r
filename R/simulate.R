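#' Copy-number state matrix
#'
#' The central analysis substrate: an individuals x SNPs integer matrix of
#' copy-number states (0--4; 2 = diploid), a per-individual case/control
#' label vector, and a cohort identifier.
#'
#' @param states integer matrix, individuals in rows, SNPs in columns,
#'   values in `0:4`.
#' @param labels character/factor of `"case"` / `"control"`, one per row.
#' @param cohort_id single string naming the cohort.
#' @return an object of class `state_matrix`.
#' @export
state_matrix <- function(states, labels, cohort_id = "cohort") {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (any(is.na(states)) || any(states < 0L | states > 4L))
    stop("states must be integers in 0..4", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (any(is.na(labels)))
    stop("labels must be 'case' or 'control'", call. = FALSE)
  if (length(labels) != nrow(states))
    stop("one label per individual (matrix row) required", call. = FALSE)
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("%s_ind%04d", cohort_id, seq_len(nrow(states)))
  structure(list(states = states, labels = labels,
                 cohort_id = as.character(cohort_id)[1]),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix '%s': %d individuals (%d cases / %d controls) x %d SNPs>\n",
              x$cohort_id, nrow(x$states), sum(x$labels == "case"),
              sum(x$labels == "control"), ncol(x$states)))
  invisible(x)
}

#' @export
dim.state_matrix <- function(x) dim(x$states)

#' Specify a ground-truth risk region for simulation
#'
#' A risk region is a contiguous block of SNPs (rows of the SNP map,
#' spanning at least 3 SNPs on one chromosome) carried as a whole-region
#' single-state CNV: state 3 for an amplification, state 1 for a deletion.
#' Cases and controls carry the region with separate frequencies, which is
#' what the association layers are meant to detect.
#'
#' @param chrom chromosome the region lies on (checked against the map when
#'   the region is embedded).
#' @param start_index,end_index first / last SNP map row of the region
#'   (inclusive); `end_index >= start_index + 2`.
#' @param cnv_type `"amplification"` or `"deletion"`.
#' @param carrier_freq_cases,carrier_freq_controls carrier probabilities in
#'   `[0, 1]` for case and control individuals.
#' @return a `risk_region` list.
#' @export
risk_region <- function(chrom, start_index, end_index,
                        cnv_type = c("deletion", "amplification"),
                        carrier_freq_cases, carrier_freq_controls) {
  cnv_type <- match.arg(cnv_type)
  if (end_index < start_index + 2)
    stop("a risk region must span >= 3 SNPs", call. = FALSE)
  for (f in c(carrier_freq_cases, carrier_freq_controls))
    if (f < 0 || f > 1)
      stop("carrier frequencies must be probabilities in [0, 1]",
           call. = FALSE)
  structure(list(chrom = as.integer(chrom),
                 start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 cnv_type = cnv_type,
                 carrier_freq_cases = carrier_freq_cases,
                 carrier_freq_controls = carrier_freq_controls),
            class = "risk_region")
}

#' Locate a SNP-map run suitable for a risk region
#'
#' Returns the (start, end) row indices of the first run of `span`
#' consecutive SNPs that lies on a single chromosome with every internal
#' gap at most `max_gap` -- a convenient anchor for embedding a risk
#' region that the 30 kb consecutiveness rule will keep intact.
#'
#' @param snp_map SNP map.
#' @param span run length in SNPs (>= 3).
#' @param max_gap maximal internal inter-SNP gap in bp.
#' @param offset skip this many suitable runs first (to place several
#'   regions apart from each other).
#' @return integer vector `c(start_index, end_index)`.
#' @export
pick_region_indices <- function(snp_map, span = 5, max_gap = 30000,
                                offset = 0) {
  validate_snp_map(snp_map)
  n <- nrow(snp_map)
  seen <- 0
  i <- 1
  while (i + span - 1 <= n) {
    idx <- i:(i + span - 1)
    ok <- length(unique(snp_map$chrom[idx])) == 1 &&
      all(diff(snp_map$pos[idx]) <= max_gap)
    if (ok) {
      if (seen >= offset) return(c(i, i + span - 1L))
      seen <- seen + 1
      i <- i + span   # skip past this run before counting the next
    } else {
      i <- i + 1
    }
  }
  stop("no suitable run of ", span, " SNPs found", call. = FALSE)
}

carrier_state <- function(cnv_type) {
  if (cnv_type == "amplification") 3L else 1L
}

#' Simulate a case-control cohort of copy-number states
#'
#' Every individual starts diploid (state 2 at every SNP). Each risk region
#' is then carried, as a whole block of its carrier state, with probability
#' `carrier_freq_cases` by each case and `carrier_freq_controls` by each
#' control. Finally sporadic background CNVs -- the label-independent noise
#' process -- are added: each individual receives a Poisson(`background_rate`)
#' number of segments, each starting at a uniform map position, with length
#' `3 + Geometric` (mean 5 SNPs), a state drawn uniformly from `{0, 1, 3, 4}`,
#' and truncation at the chromosome end. Background segments overwrite
#' whatever state they cover, exactly like a real sporadic event would.
#'
#' @param snp_map SNP map from [make_snp_map()].
#' @param n_cases,n_controls cohort arm sizes (>= 1).
#' @param risk_regions list of [risk_region()] specifications.
#' @param background_rate expected background CNV segments per individual.
#' @param mean_seg_snps mean background segment length in SNPs (>= 3).
#' @param seed integer seed.
#' @param cohort_id cohort name carried through all outputs.
#' @return a [state_matrix()] with cases first, then controls.
#' @examples
#' map <- make_snp_map(200, chrom_weights = 1, seed = 1)
#' rr <- risk_region(1, 50, 54, "deletion", 0.2, 0.02)
#' sm <- simulate_cohort(map, 20, 20, list(rr), background_rate = 1, seed = 2)
#' table(sm$states[, 52], sm$labels)
#' @export
simulate_cohort <- function(snp_map, n_cases, n_controls,
                            risk_regions = list(), background_rate = 2,
                            mean_seg_snps = 5, seed = 1L,
                            cohort_id = "cohort") {
  validate_snp_map(snp_map)
  if (n_cases < 1 || n_controls < 1)
    stop("need at least one case and one control", call. = FALSE)
  if (background_rate < 0)
    stop("`background_rate` must be >= 0", call. = FALSE)
  if (mean_seg_snps < 3)
    stop("`mean_seg_snps` must be >= 3", call. = FALSE)
  n_snps <- nrow(snp_map)
  n_ind <- n_cases + n_controls
  labels <- rep(c("case", "control"), c(n_cases, n_controls))
  for (rr in risk_regions) {
    if (rr$start_index < 1 || rr$end_index > n_snps)
      stop("risk region indices out of SNP map bounds", call. = FALSE)
    reg_chr <- unique(snp_map$chrom[rr$start_index:rr$end_index])
    if (length(reg_chr) != 1L || reg_chr != rr$chrom)
      stop("risk region must lie on its declared chromosome", call. = FALSE)
  }

  withr_seed(seed, {
    states <- matrix(2L, nrow = n_ind, ncol = n_snps)
    # embedded risk regions: whole-region single-state carriage
    for (rr in risk_regions) {
      freq <- ifelse(labels == "case",
                     rr$carrier_freq_cases, rr$carrier_freq_controls)
      carriers <- stats::rbinom(n_ind, 1L, freq) == 1L
      if (any(carriers))
        states[carriers, rr$start_index:rr$end_index] <- carrier_state(rr$cnv_type)
    }
    # sporadic background segments, identical process in both arms
    if (background_rate > 0) {
      # geometric length component: mean_seg_snps = 3 + (1 - p) / p
      p_geom <- 1 / (mean_seg_snps - 2)
      chrom_last <- cumsum(table(snp_map$chrom))  # last row index per chrom
      chrom_of <- snp_map$chrom
      n_seg <- stats::rpois(n_ind, background_rate)
      for (i in which(n_seg > 0)) {
        for (k in seq_len(n_seg[i])) {
          start <- sample.int(n_snps, 1L)
          len <- 3L + stats::rgeom(1L, p_geom)
          end <- min(start + len - 1L,
                     chrom_last[as.character(chrom_of[start])])
          st <- sample(c(0L, 1L, 3L, 4L), 1L)
          states[i, start:end] <- st
        }
      }
    }
    state_matrix(states, labels, cohort_id)
  })
}

#' Emit probe intensities from true copy-number states
#'
#' The generative inverse of HMM decoding: each probe intensity is drawn
#' from a normal distribution whose mean depends on the individual's true
#' copy-number state at that SNP. With `emission_sd = 0` the intensities are
#' exactly the state means.
#'
#' @param states a [state_matrix()].
#' @param emission_means length-5 strictly increasing vector of state means
#'   (states 0..4).
#' @param emission_sd common emission standard deviation (>= 0).
#' @param seed integer seed.
#' @return a numeric matrix with the dimensions of `states$states`.
#' @export
emit_intensities <- function(states,
                             emission_means = c(-2, -1, 0, 1, 2),
                             emission_sd = 0.25, seed = 1L) {
  stopifnot(inherits(states, "state_matrix"))
  if (length(emission_means) != 5L || any(diff(emission_means) <= 0))
    stop("`emission_means` must be 5 strictly increasing values",
         call. = FALSE)
  if (emission_sd < 0)
    stop("`emission_sd` must be >= 0", call. = FALSE)
  withr_seed(seed, {
    mu <- matrix(emission_means[states$states + 1L],
                 nrow = nrow(states$states))
    if (emission_sd == 0) {
      dimnames(mu) <- dimnames(states$states)
      mu
    } else {
      out <- mu + stats::rnorm(length(mu), 0, emission_sd)
      dimnames(out) <- dimnames(states$states)
      out
    }
  })
}

#' Write / read a state matrix as tab-separated text
#'
#' One row per individual: `individual_id`, `label`, then one digit column
#' per SNP (header line carries the SNP ids).
#'
#' @param sm a [state_matrix()].
#' @param path file path.
#' @param snp_map optional SNP map supplying column names.
#' @param cohort_id cohort name to attach on read.
#' @return `write_state_matrix()` returns `path` invisibly;
#'   `read_state_matrix()` returns a [state_matrix()].
#' @export
write_state_matrix <- function(sm, path, snp_map = NULL) {
  stopifnot(inherits(sm, "state_matrix"))
  df <- data.frame(individual_id = rownames(sm$states),
                   label = as.character(sm$labels),
                   sm$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(snp_map))
    names(df)[-(1:2)] <- snp_map$snp_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path, cohort_id = "cohort") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  states <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(states) <- df$individual_id
  state_matrix(states, df$label, cohort_id)
}
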