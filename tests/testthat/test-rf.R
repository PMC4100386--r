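test_that("relative factor follows the closed formula", {
  expect_equal(relative_factor(list(p00 = 0.5, p01 = 0.5, p10 = 0.5,
                                    p11 = 0.5)), 1)
  expect_equal(relative_factor(list(p00 = 0.8, p01 = 0.1, p10 = 0.2,
                                    p11 = 0.9)), 36)
  expect_error(relative_factor(list(p00 = 0, p01 = 1, p10 = 1, p11 = 1)),
               "positive")
})

test_that("degenerate and identical distributions give model p = 1", {
  map <- make_snp_map(5, chrom_weights = 1, seed = 1)
  ref <- simulate_cohort(map, 4, 4, list(), background_rate = 0, seed = 2)
  tst <- simulate_cohort(map, 3, 3, list(), background_rate = 0, seed = 3)
  m <- model_pvalues(ref, tst, 2)
  expect_equal(unlist(m[c("p00", "p01", "p10", "p11")]),
               c(p00 = 1, p01 = 1, p10 = 1, p11 = 1))
})

test_that("model p-values match an independent chi-square computation", {
  # hand-built site: testing controls vs reference cases over 3 states
  ref_states <- c(rep(1L, 6), rep(2L, 10), rep(3L, 4))   # 20 cases
  tst_states <- c(rep(1L, 2), rep(2L, 12), rep(3L, 6))   # 20 controls
  ref <- state_matrix(matrix(c(ref_states, rep(2L, 20)), ncol = 1),
                      rep(c("case", "control"), each = 20))
  tst <- state_matrix(matrix(c(rep(2L, 20), tst_states), ncol = 1),
                      rep(c("case", "control"), each = 20))
  m <- model_pvalues(ref, tst, 1)
  tab <- rbind(table(factor(tst_states, 0:4)),
               table(factor(ref_states, 0:4)))
  tab <- tab[, colSums(tab) > 0]
  direct <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  expect_equal(m$p10, direct, tolerance = 1e-12)
})

test_that("flipping the testing cohort labels inverts the relative factor", {
  tc <- two_cohorts()
  flipped <- state_matrix(tc$test$states,
                          ifelse(tc$test$labels == "case", "control",
                                 "case"), "flipped")
  for (j in c(tc$region[1], tc$region[1] + 2, 60)) {
    m <- model_pvalues(tc$ref, tc$test, j)
    mf <- model_pvalues(tc$ref, flipped, j)
    expect_equal(relative_factor(mf), 1 / relative_factor(m),
                 tolerance = 1e-9)
  }
})

test_that("exchanging cohort roles with a model transpose leaves rf unchanged", {
  tc <- two_cohorts(seed = 502)
  for (j in c(tc$region[1] + 1, 30)) {
    m <- model_pvalues(tc$ref, tc$test, j)
    sw <- model_pvalues(tc$test, tc$ref, j)   # roles exchanged
    rf_orig <- relative_factor(m)
    rf_swap <- relative_factor(list(p00 = sw$p00, p01 = sw$p10,
                                    p10 = sw$p01, p11 = sw$p11))
    expect_equal(rf_swap, rf_orig, tolerance = 1e-9)
  }
})

test_that("the rf scan matches the single-site model computation", {
  tc <- two_cohorts(seed = 503)
  rf <- rf_scan(tc$ref, tc$test, tc$map)
  for (j in c(1, tc$region[1], tc$region[2], 100)) {
    m <- model_pvalues(tc$ref, tc$test, j)
    expect_equal(rf$p00[j], max(m$p00, 1e-12), tolerance = 1e-9)
    expect_equal(rf$p01[j], max(m$p01, 1e-12), tolerance = 1e-9)
    expect_equal(rf$rf[j], relative_factor(m), tolerance = 1e-6)
  }
})

test_that("a shared risk region raises rf; a label-flipped one lowers it", {
  tc <- two_cohorts(seed = 504)
  rf <- rf_scan(tc$ref, tc$test, tc$map)
  reg <- tc$region[1]:tc$region[2]
  expect_gt(median(rf$log10_rf[reg]), median(rf$log10_rf[-reg]))
  flipped <- state_matrix(tc$test$states,
                          ifelse(tc$test$labels == "case", "control",
                                 "case"), "flipped")
  rf_f <- rf_scan(tc$ref, flipped, tc$map)
  expect_lt(median(rf_f$rf[reg]), 1)
})

test_that("rf permutations agree with direct relabeled scans", {
  tc <- two_cohorts(seed = 505)
  pr <- permute_labels(tc$ref$labels, 5, seed = 506)
  pt <- permute_labels(tc$test$labels, 5, seed = 507)
  perm_rf <- rf_permutations(tc$ref, tc$test, tc$map, pr, pt)
  ref3 <- state_matrix(tc$ref$states, ifelse(pr[, 3], "case", "control"))
  tst3 <- state_matrix(tc$test$states, ifelse(pt[, 3], "case", "control"))
  direct <- rf_scan(ref3, tst3, tc$map)
  expect_equal(unname(perm_rf[, 3]), direct$rf, tolerance = 1e-9)
})

test_that("rf FDR obeys the counting formula in both tail directions", {
  obs <- c(10, 0.5, 3, 1)
  ens <- cbind(c(5, 0.1, 0.2, 1), c(12, 2, 0.3, 0.7), c(0.1, 1, 1, 1))
  expect_equal(rf_fdr(obs, ens, rf_site = 3),
               brute_force_fdr(obs, ens, 3))
  expect_equal(rf_fdr(obs, ens, rf_site = 0.5, tail = "le"),
               brute_force_fdr(-obs, -ens, -0.5))
  expect_equal(rf_fdr(obs, matrix(0.1, 4, 3), rf_site = 3), 0)
  expect_equal(rf_fdr(obs, cbind(obs, obs), rf_site = 10), 1)
})

test_that("risk-locus selection matches an exhaustive threshold search", {
  wp <- data.frame(snp_id = paste0("s", 1:6), chrom = 1L,
                   pos = 1:6 * 1e4,
                   hypothesis = rep("loss", 6),
                   s_w = c(9, 8, 7, 6, 5, 4),
                   stringsAsFactors = FALSE)
  rf_res <- data.frame(snp_id = wp$snp_id,
                       rf = c(50, 40, 6, 30, 2, 20),
                       stringsAsFactors = FALSE)
  perm <- rbind(c(10, 3), c(8, 45), c(1, 1), c(5, 2), c(1, 1), c(12, 1))
  rownames(perm) <- wp$snp_id
  sel <- select_risk_loci(wp, rf_res, perm, fp_budget = 1)
  # oracle: smallest observed rf threshold with expected null count < 1
  ts <- sort(unique(rf_res$rf))
  exp_count <- vapply(ts, function(t) sum(perm >= t) / 2, numeric(1))
  t_star <- ts[min(which(exp_count < 1))]
  expect_equal(sort(sel$snp_id),
               sort(wp$snp_id[rf_res$rf >= t_star]))
  expect_equal(attr(sel, "rf_threshold"), t_star)
})

test_that("selection is unconstrained without null passers and monotone in budget", {
  wp <- data.frame(snp_id = paste0("s", 1:3), chrom = 1L, pos = 1:3 * 1e4,
                   hypothesis = "loss", s_w = 5, stringsAsFactors = FALSE)
  rf_res <- data.frame(snp_id = wp$snp_id, rf = c(5, 10, 2))
  zero <- matrix(0.1, 3, 4, dimnames = list(wp$snp_id, NULL))
  all_sel <- select_risk_loci(wp, rf_res, zero, fp_budget = 1)
  expect_setequal(all_sel$snp_id, wp$snp_id)
  expect_equal(nrow(select_risk_loci(wp[0, ], rf_res, zero)), 0L)
  # larger budgets never shrink the selection
  hot <- matrix(c(20, 6, 1, 20, 6, 1, 3, 1, 1, 9, 1, 1), 3,
                dimnames = list(wp$snp_id, NULL))
  prev <- character()
  for (budget in c(0.5, 1, 2, 5)) {
    sel <- tryCatch(
      select_risk_loci(wp, rf_res, hot, fp_budget = budget)$snp_id,
      warning = function(w) character())
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})
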