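#' Build a synthetic recombination map with hotspots
#'
#' Covers each chromosome span of the SNP map (plus `padding` on both sides)
#' with non-overlapping rate intervals: a uniform background at `base_rate`
#' and `n_hotspots` short intervals at `hot_rate`, which are also recorded
#' in a separate hotspot list. This emulates a population genetic map with
#' localized recombination hotspots.
#'
#' @param snp_map SNP map defining chromosome spans.
#' @param n_hotspots total number of hotspot intervals to place.
#' @param hot_rate hotspot recombination rate in cM/Mb; must exceed
#'   `base_rate`.
#' @param base_rate background rate in cM/Mb (>= 0).
#' @param hotspot_width hotspot interval width in bp.
#' @param padding bp added before the first and after the last SNP of each
#'   chromosome.
#' @param seed integer seed.
#' @return a list of class `recomb_map` with elements `intervals`
#'   (`data.frame`: chrom, start, end, rate; 1-based inclusive, sorted,
#'   non-overlapping) and `hotspots` (`data.frame`: chrom, start, end).
#' @export
make_recomb_map <- function(snp_map, n_hotspots = 10, hot_rate = 50,
                            base_rate = 0.5, hotspot_width = 2000,
                            padding = 10000, seed = 1L) {
  validate_snp_map(snp_map)
  if (hot_rate <= base_rate || base_rate < 0)
    stop("`hot_rate` must exceed `base_rate` >= 0", call. = FALSE)
  spans <- do.call(rbind, lapply(split(snp_map$pos, snp_map$chrom), range))
  spans <- data.frame(chrom = as.integer(rownames(spans)),
                      start = pmax(1, spans[, 1] - padding),
                      end = spans[, 2] + padding)

  withr_seed(seed, {
    # spread hotspots over chromosomes proportionally to span length
    hot <- NULL
    if (n_hotspots > 0) {
      w <- (spans$end - spans$start)
      idx <- sample.int(nrow(spans), n_hotspots, replace = TRUE,
                        prob = w / sum(w))
      rows <- lapply(seq_len(n_hotspots), function(k) {
        sp <- spans[idx[k], ]
        lo <- sp$start
        hi <- max(lo, sp$end - hotspot_width)
        s <- floor(stats::runif(1, lo, hi))
        data.frame(chrom = sp$chrom, start = s,
                   end = min(s + hotspot_width - 1, sp$end))
      })
      hot <- do.call(rbind, rows)
      hot <- hot[order(hot$chrom, hot$start), , drop = FALSE]
      # drop overlaps within a chromosome (re-placed hotspots are rare at
      # the default density; simply keep the first of an overlapping pair)
      keep <- rep(TRUE, nrow(hot))
      for (i in seq_len(nrow(hot))[-1]) {
        prev <- max(which(keep[seq_len(i - 1)]))
        if (hot$chrom[i] == hot$chrom[prev] && hot$start[i] <= hot$end[prev])
          keep[i] <- FALSE
      }
      hot <- hot[keep, , drop = FALSE]
      rownames(hot) <- NULL
    }
    # background intervals split around the hotspots
    iv <- list()
    for (r in seq_len(nrow(spans))) {
      sp <- spans[r, ]
      h <- if (is.null(hot)) hot else hot[hot$chrom == sp$chrom, , drop = FALSE]
      cur <- sp$start
      if (!is.null(h) && nrow(h)) {
        for (j in seq_len(nrow(h))) {
          if (h$start[j] > cur)
            iv[[length(iv) + 1L]] <- data.frame(
              chrom = sp$chrom, start = cur, end = h$start[j] - 1,
              rate = base_rate)
          iv[[length(iv) + 1L]] <- data.frame(
            chrom = sp$chrom, start = h$start[j], end = h$end[j],
            rate = hot_rate)
          cur <- h$end[j] + 1
        }
      }
      if (cur <= sp$end)
        iv[[length(iv) + 1L]] <- data.frame(
          chrom = sp$chrom, start = cur, end = sp$end, rate = base_rate)
    }
    intervals <- do.call(rbind, iv)
    rownames(intervals) <- NULL
    if (is.null(hot))
      hot <- data.frame(chrom = integer(), start = numeric(),
                        end = numeric())
    structure(list(intervals = intervals, hotspots = hot),
              class = "recomb_map")
  })
}

#' Write / read a recombination map in the genetic-map text layout
#'
#' One file per chromosome, named `genetic_map_chr<k>.txt`, with the
#' conventional three columns `position`, `COMBINED_rate(cM/Mb)` and
#' `Genetic_Map(cM)`: each row gives the rate of the interval starting at
#' `position` and the cumulative map length up to it. Hotspots go to a
#' separate BED file (0-based, half-open).
#'
#' @param recomb_map a `recomb_map` (see [make_recomb_map()]).
#' @param dir output directory (created if missing).
#' @return `write_recomb_map()` returns the written file paths invisibly;
#'   `read_recomb_map()` returns a `recomb_map` (hotspots empty unless a
#'   BED is supplied to `read_hotspots_bed()`).
#' @export
write_recomb_map <- function(recomb_map, dir) {
  stopifnot(inherits(recomb_map, "recomb_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (ch in unique(recomb_map$intervals$chrom)) {
    iv <- recomb_map$intervals[recomb_map$intervals$chrom == ch, ,
                               drop = FALSE]
    len_mb <- (iv$end - iv$start + 1) / 1e6
    cum_cm <- c(0, cumsum(iv$rate * len_mb))
    df <- data.frame(position = c(iv$start, iv$end[nrow(iv)] + 1),
                     rate = c(iv$rate, 0),
                     map_cm = cum_cm)
    names(df) <- c("position", "COMBINED_rate(cM/Mb)", "Genetic_Map(cM)")
    p <- file.path(dir, sprintf("genetic_map_chr%d.txt", ch))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  hs <- file.path(dir, "hotspots.bed")
  write_intervals_bed(recomb_map$hotspots, hs)
  invisible(c(paths, hs))
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(dir) {
  files <- list.files(dir, pattern = "^genetic_map_chr[0-9]+\\.txt$",
                      full.names = TRUE)
  if (!length(files))
    stop("no genetic_map_chr*.txt files in ", dir, call. = FALSE)
  iv <- lapply(files, function(p) {
    ch <- as.integer(sub(".*chr([0-9]+)\\.txt$", "\\1", p))
    df <- read.delim(p, check.names = FALSE)
    n <- nrow(df)
    data.frame(chrom = ch,
               start = df[[1]][-n],
               end = df[[1]][-1] - 1,
               rate = df[[2]][-n])
  })
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  hs_path <- file.path(dir, "hotspots.bed")
  hot <- if (file.exists(hs_path)) read_hotspots_bed(hs_path) else
    data.frame(chrom = integer(), start = numeric(), end = numeric())
  structure(list(intervals = iv, hotspots = hot), class = "recomb_map")
}

# write 1-based inclusive intervals as BED (0-based half-open)
write_intervals_bed <- function(df, path, names = NULL) {
  if (!nrow(df)) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = paste0("chr", df$chrom),
                    start = format(df$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(names)) bed$name <- names
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read hotspot intervals from a BED file
#'
#' BED coordinates (0-based half-open) are converted to the package's
#' internal 1-based inclusive convention.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_hotspots_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = integer(), start = numeric(), end = numeric()))
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.integer(sub("^chr", "", bed[[1]])),
             start = bed[[2]] + 1,
             end = bed[[3]])
}
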