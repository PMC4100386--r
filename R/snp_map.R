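#' Build an ordered autosomal SNP map
#'
#' Generates an artificial array manifest: `n_snps` SNP probes spread over
#' autosomes 1--22 with roughly exponential inter-probe spacing. A
#' configurable fraction of gaps is forced above `big_gap_min` so that
#' downstream consecutiveness rules (runs broken by gaps larger than 30 kb)
#' are exercised.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param chrom_weights non-negative weights, one per autosome used;
#'   SNP counts per chromosome are proportional to these. Default: uniform
#'   over chromosomes `1:22`.
#' @param mean_spacing mean inter-SNP gap in bp (> 0).
#' @param big_gap_frac fraction of gaps drawn above `big_gap_min`.
#' @param big_gap_min threshold (bp) defining a "large" gap; default 30 kb,
#'   the distance beyond which two neighboring SNPs are no longer treated as
#'   consecutive when chaining risk loci.
#' @param seed integer seed; the map is reproducible for a fixed seed.
#' @return a `data.frame` with columns `snp_id`, `chrom` (integer 1--22) and
#'   `pos` (bp, 1-based), sorted by (chrom, pos) with strictly increasing
#'   positions within each chromosome.
#' @examples
#' map <- make_snp_map(100, mean_spacing = 10000, seed = 1)
#' head(map)
#' @export
make_snp_map <- function(n_snps, chrom_weights = NULL, mean_spacing = 3000,
                         big_gap_frac = 0.05, big_gap_min = 30000,
                         seed = 1L) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1)
    stop("`n_snps` must be a single count >= 1", call. = FALSE)
  if (!is.numeric(mean_spacing) || mean_spacing <= 0)
    stop("`mean_spacing` must be > 0", call. = FALSE)
  if (big_gap_frac < 0 || big_gap_frac > 1)
    stop("`big_gap_frac` must lie in [0, 1]", call. = FALSE)
  n_snps <- as.integer(n_snps)
  if (is.null(chrom_weights)) chrom_weights <- rep(1, 22)
  if (length(chrom_weights) > 22 || any(chrom_weights < 0) ||
      sum(chrom_weights) <= 0)
    stop("`chrom_weights` must be <= 22 non-negative weights", call. = FALSE)

  withr_seed(seed, {
    # multinomial split of SNPs over chromosomes, dropping empty ones
    probs <- chrom_weights / sum(chrom_weights)
    counts <- as.vector(stats::rmultinom(1, n_snps, probs))
    chrom <- rep.int(seq_along(counts), counts)
    gaps <- stats::rexp(n_snps, rate = 1 / mean_spacing)
    big <- stats::runif(n_snps) < big_gap_frac
    gaps[big] <- big_gap_min + stats::rexp(sum(big), rate = 1 / mean_spacing)
    gaps <- pmax(1, round(gaps))
    pos <- unlist(lapply(split(gaps, chrom), cumsum), use.names = FALSE)
    data.frame(
      snp_id = sprintf("snp%06d", seq_len(n_snps)),
      chrom = chrom,
      pos = as.numeric(pos),
      stringsAsFactors = FALSE
    )
  })
}

validate_snp_map <- function(snp_map) {
  stopifnot(is.data.frame(snp_map),
            all(c("snp_id", "chrom", "pos") %in% names(snp_map)))
  if (any(snp_map$chrom < 1 | snp_map$chrom > 22))
    stop("SNP map chromosomes must be autosomes 1..22", call. = FALSE)
  o <- order(snp_map$chrom, snp_map$pos)
  if (!identical(o, seq_len(nrow(snp_map))))
    stop("SNP map must be sorted by (chrom, pos)", call. = FALSE)
  d <- unlist(lapply(split(snp_map$pos, snp_map$chrom), diff),
              use.names = FALSE)
  if (length(d) && any(d <= 0))
    stop("positions must be strictly increasing within a chromosome",
         call. = FALSE)
  invisible(snp_map)
}

#' Write / read a SNP map as tab-separated text
#'
#' @param snp_map a SNP map `data.frame` (see [make_snp_map()]).
#' @param path output / input file path.
#' @return `write_snp_map()` returns `path` invisibly; `read_snp_map()`
#'   returns the validated map.
#' @export
write_snp_map <- function(snp_map, path) {
  validate_snp_map(snp_map)
  write.table(snp_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.numeric(map$pos)
  validate_snp_map(map)
  map
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a child seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103515245 + stage * 12345) %% 2147483647)
}
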