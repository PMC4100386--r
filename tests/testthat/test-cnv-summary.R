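test_that("raw CNV calling follows the 3-consecutive-abnormal rule", {
  map <- data.frame(snp_id = paste0("s", 1:5), chrom = 1L,
                    pos = c(100, 200, 300, 400, 500))
  mk <- function(v) state_matrix(matrix(as.integer(v), 1),
                                 "case", "c")
  expect_equal(nrow(call_raw_cnvs(mk(rep(2, 5)), map)), 0L)
  seg <- call_raw_cnvs(mk(c(2, 1, 1, 1, 2)), map)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$state, 1L)
  expect_equal(seg$n_snps, 3L)
  expect_equal(c(seg$start_pos, seg$end_pos), c(200, 400))
  # mixed abnormal states never merge
  expect_equal(nrow(call_raw_cnvs(mk(c(2, 1, 3, 1, 2)), map)), 0L)
})

test_that("raw CNV calls never cross chromosome boundaries", {
  map <- data.frame(snp_id = paste0("s", 1:6),
                    chrom = c(1L, 1L, 1L, 2L, 2L, 2L),
                    pos = c(100, 200, 300, 100, 200, 300))
  sm <- state_matrix(matrix(c(1L, 1L, 1L, 1L, 1L, 1L), 1), "case", "c")
  seg <- call_raw_cnvs(sm, map)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$chrom, c(1L, 2L))
})

test_that("raw CNV caller equals the brute-force run scanner", {
  map <- data.frame(snp_id = sprintf("s%03d", 1:200), chrom = 1L,
                    pos = seq(1000, by = 1000, length.out = 200))
  set.seed(91)
  for (rep in 1:200) {
    v <- sample(0:4, 200, replace = TRUE, prob = c(.05, .15, .6, .15, .05))
    sm <- state_matrix(matrix(as.integer(v), 1), "case", "c")
    seg <- call_raw_cnvs(sm, map)
    oracle <- brute_force_runs(v)
    expect_equal(nrow(seg), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_equal(seg$first_snp, unname(om[, "start"]))
      expect_equal(seg$last_snp, unname(om[, "end"]))
      expect_equal(seg$state, unname(om[, "state"]))
    }
  }
})

test_that("raw CNV summaries compute per-arm descriptive statistics", {
  seg <- data.frame(individual_id = c("a", "a", "b", "b", "b", "b", "c"),
                    label = c(rep("case", 6), "control"),
                    chrom = 1L, first_snp = 1L, last_snp = 3L,
                    start_pos = 1000, end_pos = 2000,
                    state = 1L, n_snps = c(3L, 4L, 3L, 5L, 3L, 6L, 3L))
  labels <- c(rep("case", 2), "control")
  st <- summarize_raw_cnvs(seg, labels)
  case <- st[st$arm == "case", ]
  expect_equal(case$avg_cnvs_per_individual, 3)   # 6 segments / 2 cases
  expect_equal(case$snps_min, 3)
  expect_equal(case$snps_max, 6)
  expect_equal(case$size_avg_bp, 1000)
  w <- capture_warnings(st0 <- summarize_raw_cnvs(seg[0, ], labels))
  expect_length(w, 2)   # one zero-segment warning per arm
  expect_match(w, "zeros", all = TRUE)
  expect_true(all(st0$avg_cnvs_per_individual == 0))
})

test_that("CNV size recomputes published table rows exactly", {
  expect_equal(cnv_size_kb(113681735, 113741162), 59.4)
  expect_equal(cnv_size_kb(56772821, 56803216), 30.4)
  expect_equal(cnv_size_kb(0, 1000), 1.0)
  path <- system.file("extdata", "eagle_predicted_cnvs.tsv",
                      package = "cnvaccord")
  tab <- read.delim(path)
  expect_equal(cnv_size_kb(tab$start_pos, tab$end_pos), tab$size_kb)
})

test_that("risk-locus chains become typed CNV records under the gap rule", {
  mk_loci <- function(pos, hyp, chrom = 1L)
    data.frame(snp_id = sprintf("s%d", seq_along(pos)), chrom = chrom,
               pos = pos, hypothesis = hyp, stringsAsFactors = FALSE)
  # two loci only: below min_loci, both singular
  two <- blocks_to_cnvs(mk_loci(c(100, 10100), c("loss", "loss")))
  expect_equal(nrow(two$cnvs), 0L)
  expect_equal(nrow(two$singular), 2L)
  # three gain loci: one Amplification with the printed-size convention
  amp <- blocks_to_cnvs(mk_loci(c(100, 10100, 20100), rep("gain", 3)))
  expect_equal(nrow(amp$cnvs), 1L)
  expect_equal(amp$cnvs$cnv_type, "Amplification")
  expect_equal(amp$cnvs$start_pos, 100)
  expect_equal(amp$cnvs$end_pos, 20100)
  expect_equal(amp$cnvs$size_kb, 20.0)
  # abnm members are direction-compatible; mixed directions are Abnormal
  del <- blocks_to_cnvs(mk_loci(c(100, 10100, 20100),
                                c("loss", "abnm", "loss")))
  expect_equal(del$cnvs$cnv_type, "Deletion")
  mixed <- blocks_to_cnvs(mk_loci(c(100, 10100, 20100),
                                  c("loss", "gain", "loss")))
  expect_equal(mixed$cnvs$cnv_type, "Abnormal")
  # a 35 kb internal gap splits the chain; a 2+2 split yields no record
  split <- blocks_to_cnvs(mk_loci(c(100, 10100, 45100, 55100),
                                  rep("loss", 4)))
  expect_equal(nrow(split$cnvs), 0L)
  expect_equal(nrow(split$singular), 4L)
  # a 1+3 split keeps the 3-chain as a record
  split2 <- blocks_to_cnvs(mk_loci(c(100, 35200, 45200, 55200),
                                   rep("loss", 4)))
  expect_equal(nrow(split2$cnvs), 1L)
  expect_equal(split2$cnvs$n_loci, 3L)
  expect_equal(nrow(split2$singular), 1L)
  expect_error(blocks_to_cnvs(mk_loci(c(200, 100, 300), rep("loss", 3))),
               "sorted")
})

test_that("chain partition matches a brute-force scan on random loci", {
  set.seed(92)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    pos <- sort(sample(1:20, n) * 1e4)
    loci <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1L,
                       pos = pos,
                       hypothesis = sample(c("loss", "gain", "abnm"), n,
                                           replace = TRUE),
                       stringsAsFactors = FALSE)
    out <- blocks_to_cnvs(loci, max_gap = 30000, min_loci = 3)
    # oracle partition by gaps
    breaks <- c(0, which(diff(pos) > 30000), n)
    sizes <- diff(breaks)
    expect_equal(nrow(out$cnvs), sum(sizes >= 3))
    expect_equal(nrow(out$singular), sum(sizes[sizes < 3]))
    # members of records are disjoint and subsets of the input
    all_members <- unlist(strsplit(out$cnvs$loci, ","))
    expect_true(!anyDuplicated(all_members))
    expect_true(all(all_members %in% loci$snp_id))
  }
})

test_that("neighboring genes use closed-interval flanks", {
  loci <- data.frame(chrom = 1L, pos = 500000)
  genes <- data.frame(chrom = 1L,
                      start = c(100, 500000, 600000, 599000, 600001),
                      end = c(200, 510000, 600000, 601000, 700100),
                      name = c("far", "inside", "boundary", "straddle",
                               "past"),
                      stringsAsFactors = FALSE)
  got <- neighboring_genes(loci, genes, flank = 100000)
  # the flank is the closed interval [400000, 600000]: a gene touching the
  # boundary bp counts, one starting at 600001 does not
  expect_setequal(got, c("inside", "boundary", "straddle"))
  expect_equal(neighboring_genes(loci, genes[genes$name == "far", ],
                                 flank = 100000), character())
})

test_that("neighboring genes match a quadratic all-pairs oracle", {
  set.seed(93)
  for (rep in 1:20) {
    loci <- data.frame(chrom = sample(1:2, 5, TRUE),
                       pos = sample(1e6, 5))
    genes <- data.frame(chrom = sample(1:2, 30, TRUE),
                        start = sample(1e6, 30))
    genes$end <- genes$start + sample(1e4, 30)
    genes$name <- sprintf("g%02d", 1:30)
    got <- neighboring_genes(loci, genes, flank = 5e4)
    keep <- vapply(seq_len(30), function(g) any(
      genes$chrom[g] == loci$chrom &
        genes$start[g] <= loci$pos + 5e4 &
        genes$end[g] >= loci$pos - 5e4), logical(1))
    expect_equal(got, sort(genes$name[keep]))
  }
})

test_that("CNV records export to BED with the half-open conversion", {
  cnvs <- data.frame(dataset = "d", chrom = 8L, start_pos = 113681735,
                     end_pos = 113741162, size_kb = 59.4,
                     cnv_type = "Amplification", n_loci = 5L, loci = "x")
  path <- withr::local_tempfile(fileext = ".bed")
  write_cnv_bed(cnvs, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed[[2]], 113681734)   # start - 1
  expect_equal(bed[[3]], 113741162)   # end unchanged
  # table round trip, size recomputed on read when absent
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_cnv_table(cnvs[, setdiff(names(cnvs), "size_kb")], tpath)
  back <- read_cnv_table(tpath)
  expect_equal(back$size_kb, 59.4)
})
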