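uniform_map <- function(rate = 1, chrom = 1L, lo = 1, hi = 1e6) {
  structure(list(
    intervals = data.frame(chrom = chrom, start = lo, end = hi,
                           rate = rate),
    hotspots = data.frame(chrom = integer(), start = numeric(),
                          end = numeric())), class = "recomb_map")
}

test_that("recombination level is the log10 max rate in the window", {
  expect_equal(recomb_level(5e5, 1, uniform_map(1)), 0)
  # hotspot at rate 100 inside the 10 kb window over background 0.1
  rm <- uniform_map(0.1)
  rm$intervals <- rbind(
    data.frame(chrom = 1L, start = 1, end = 503999, rate = 0.1),
    data.frame(chrom = 1L, start = 504000, end = 506000, rate = 100),
    data.frame(chrom = 1L, start = 506001, end = 1e6, rate = 0.1))
  expect_equal(recomb_level(5e5, 1, rm, window = 10000), 2)
  # just out of reach of the +/- 5 kb window
  expect_equal(recomb_level(498999, 1, rm, window = 10000), -1)
  # uncovered chromosome -> missing
  expect_true(is.na(recomb_level(5e5, 2, rm)))
  # rates are floored before the log
  expect_equal(recomb_level(5e5, 1, uniform_map(0)), -4)
})

test_that("levels are invariant to subdividing equal-rate intervals", {
  rm1 <- uniform_map(2.5)
  rm2 <- uniform_map(2.5)
  rm2$intervals <- data.frame(chrom = 1L,
                              start = c(1, 2e5, 7e5),
                              end = c(2e5 - 1, 7e5 - 1, 1e6),
                              rate = 2.5)
  pos <- c(1e5, 3e5, 699999, 9e5)
  expect_equal(recomb_level(pos, 1, rm1), recomb_level(pos, 1, rm2))
})

test_that("levels on a random step map match an interval-scan oracle", {
  set.seed(101)
  for (rep in 1:10) {
    edges <- sort(sample(2:999, 8)) * 1000
    starts <- c(1, edges)
    ends <- c(edges - 1, 1e6)
    rates <- round(rexp(9, 1), 3)
    rm <- uniform_map()
    rm$intervals <- data.frame(chrom = 1L, start = starts, end = ends,
                               rate = rates)
    pos <- sample(1e4:9.9e5, 20)
    got <- recomb_level(pos, 1, rm, window = 10000)
    oracle <- vapply(pos, function(p) {
      hit <- starts <= p + 5000 & ends >= p - 5000
      log10(max(max(rates[hit]), 1e-4))
    }, numeric(1))
    expect_equal(got, oracle)
  }
})

test_that("group comparison is calibrated and deterministic", {
  lv_equal <- data.frame(
    level = rep(1, 40),
    group = factor(rep(c("not_sig", "window_Rf"), 20),
                   levels = c("not_sig", "snp_based", "window",
                              "window_Rf")))
  res <- suppressWarnings(compare_recomb_groups(lv_equal, n_perm = 1000,
                                                seed = 5))
  expect_gte(res$p_value, 0.5)
  lv_sep <- data.frame(
    level = rep(c(0, 2), each = 20),
    group = factor(rep(c("not_sig", "window_Rf"), each = 20),
                   levels = levels(lv_equal$group)))
  res_sep <- suppressWarnings(compare_recomb_groups(lv_sep, n_perm = 1000,
                                                    seed = 6))
  expect_lte(res_sep$p_value, 2 / 1000)
  again <- suppressWarnings(compare_recomb_groups(lv_sep, n_perm = 1000,
                                                  seed = 6))
  expect_identical(res_sep$p_value, again$p_value)
  # group sums are reported per non-empty group
  expect_setequal(res_sep$summary$group, c("not_sig", "window_Rf"))
  expect_equal(res_sep$summary$sum[res_sep$summary$group == "window_Rf"],
               40)
})

test_that("hierarchical group assignment keeps the furthest stage", {
  ids <- paste0("s", 1:6)
  grp <- assign_snp_groups(ids, candidates = c("s2", "s3", "s4", "s5"),
                           window_pass = c("s3", "s4"),
                           risk_loci = "s4")
  expect_equal(as.character(grp),
               c("not_sig", "snp_based", "window", "window_Rf",
                 "snp_based", "not_sig"))
})

test_that("hotspot overlap counts per type with closed-interval boundaries", {
  cnvs <- data.frame(chrom = c(1L, 1L, 2L),
                     start_pos = c(100, 5000, 100),
                     end_pos = c(200, 6000, 300),
                     cnv_type = c("Deletion", "Deletion", "Amplification"))
  none <- hotspot_overlap(cnvs, data.frame(chrom = 3L, start = 1,
                                           end = 10))
  expect_equal(none$overlapping, c(0L, 0L))
  expect_equal(none$total, c(1L, 2L))
  # hotspot ending exactly at a CNV start shares one bp -> overlap
  hs <- data.frame(chrom = 1L, start = 50, end = 100)
  got <- hotspot_overlap(cnvs, hs)
  expect_equal(got$overlapping[got$cnv_type == "Deletion"], 1L)
  # adding a hotspot never decreases counts
  more <- hotspot_overlap(cnvs, rbind(hs, data.frame(chrom = 2L,
                                                     start = 250,
                                                     end = 400)))
  expect_true(all(more$overlapping >= got$overlapping))
})

test_that("hotspot overlap matches a quadratic all-pairs oracle", {
  set.seed(102)
  for (rep in 1:20) {
    cnvs <- data.frame(chrom = sample(1:2, 8, TRUE),
                       start_pos = sample(1e5, 8))
    cnvs$end_pos <- cnvs$start_pos + sample(5e3, 8)
    cnvs$cnv_type <- sample(c("Deletion", "Amplification"), 8, TRUE)
    hs <- data.frame(chrom = sample(1:2, 10, TRUE),
                     start = sample(1e5, 10))
    hs$end <- hs$start + sample(2e3, 10)
    got <- hotspot_overlap(cnvs, hs)
    hit <- vapply(seq_len(8), function(i) {
      h <- hs[hs$chrom == cnvs$chrom[i], , drop = FALSE]
      nrow(h) > 0 && any(brute_force_overlap(cnvs$start_pos[i],
                                             cnvs$end_pos[i],
                                             h$start, h$end))
    }, logical(1))
    for (tp in unique(cnvs$cnv_type)) {
      expect_equal(got$overlapping[got$cnv_type == tp],
                   sum(hit[cnvs$cnv_type == tp]))
    }
  }
})
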