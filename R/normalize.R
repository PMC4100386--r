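#' Quantile normalize probe intensities to a common baseline
#'
#' All individuals -- possibly spread over several matrices (e.g. a training
#' set and two study cohorts) -- are pooled and quantile normalized to the
#' same baseline: after normalization every individual's sorted intensity
#' vector equals the cross-individual mean quantile vector, while the rank
#' order within each individual is preserved (ties are averaged).
#'
#' @param matrices a single intensity matrix (individuals x SNPs) or a list
#'   of such matrices sharing the SNP dimension.
#' @return a normalized matrix, or a list of them matching the input
#'   structure.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(10, 20, 30))
#' quantile_normalize(m)   # both rows become (5.5, 11, 16.5)
#' @export
quantile_normalize <- function(matrices) {
  single <- is.matrix(matrices)
  if (single) matrices <- list(matrices)
  if (!length(matrices))
    stop("at least one intensity matrix required", call. = FALSE)
  p <- unique(vapply(matrices, ncol, 1L))
  if (length(p) != 1L)
    stop("all matrices must share the SNP dimension", call. = FALSE)
  pooled <- do.call(rbind, matrices)
  if (any(!is.finite(pooled)))
    stop("intensities must be finite", call. = FALSE)
  # limma normalizes columns-as-samples; individuals are rows here
  norm <- t(limma::normalizeQuantiles(t(pooled), ties = TRUE))
  dimnames(norm) <- dimnames(pooled)
  sizes <- vapply(matrices, nrow, 1L)
  out <- vector("list", length(matrices))
  off <- 0L
  for (i in seq_along(matrices)) {
    out[[i]] <- norm[off + seq_len(sizes[i]), , drop = FALSE]
    off <- off + sizes[i]
  }
  if (single) out[[1]] else out
}
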