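#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with its default.
#' Inputs are either simulated (the default; sizes, risk regions and seeds
#' below) or supplied as ready-made objects through `reference`, `testing`,
#' `snp_map` and `recomb_map`. The larger cohort plays the Reference
#' (discovery) role, the smaller one Testing (validation).
#'
#' @param n_snps number of SNPs to simulate.
#' @param mean_spacing mean inter-SNP spacing, bp.
#' @param n_cases_ref,n_controls_ref,n_cases_test,n_controls_test cohort
#'   arm sizes (discovery 400/400 and validation 160/170 by default,
#'   mirroring a larger discovery and smaller validation cohort).
#' @param risk_regions list of [risk_region()] ground-truth regions shared
#'   by both cohorts.
#' @param background_rate expected background CNVs per individual.
#' @param use_hmm when `TRUE`, probe intensities are emitted, quantile
#'   normalized together with a training cohort, an HMM is fitted on the
#'   training set (parameters frozen) and study cohorts are decoded; when
#'   `FALSE` (default) the association layers consume the simulated states
#'   directly.
#' @param n_training training individuals for the HMM (copy-number-normal).
#' @param emission_means,emission_sd intensity emission model.
#' @param t_pm number of label permutations, default 100.
#' @param candidate_fdr SNP-based FDR ceiling, default 0.15.
#' @param window_fdr window-based FDR ceiling, default 0.15.
#' @param half_width window half-width in SNPs, default 2.
#' @param max_gap consecutiveness distance, bp, default 30 kb.
#' @param min_loci minimal loci per CNV record, default 3.
#' @param fp_budget expected false positives allowed in the joint
#'   (window, Rf) selection, default 1.
#' @param rf_tail Rf tail direction (`"ge"` accordance tail by default).
#' @param recomb_window recombination-level window, bp, default 10 kb.
#' @param n_hotspots,hot_rate,base_rate simulated recombination map.
#' @param seed master seed; per-stage seeds are derived from it so stages
#'   can be reproduced in isolation.
#' @param reference,testing optional [state_matrix()] inputs.
#' @param snp_map,recomb_map optional map inputs.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_snps = 2000, mean_spacing = 3000,
                            n_cases_ref = 400, n_controls_ref = 400,
                            n_cases_test = 160, n_controls_test = 170,
                            risk_regions = list(), background_rate = 2,
                            use_hmm = FALSE, n_training = 20,
                            emission_means = c(-2, -1, 0, 1, 2),
                            emission_sd = 0.25,
                            t_pm = 100, candidate_fdr = 0.15,
                            window_fdr = 0.15, half_width = 2,
                            max_gap = 30000, min_loci = 3, fp_budget = 1,
                            rf_tail = "ge", recomb_window = 10000,
                            n_hotspots = 10, hot_rate = 50,
                            base_rate = 0.5, seed = 1L,
                            reference = NULL, testing = NULL,
                            snp_map = NULL, recomb_map = NULL) {
  cfg <- as.list(environment())
  stopifnot(t_pm >= 1, candidate_fdr > 0, window_fdr > 0, fp_budget > 0,
            half_width >= 0, max_gap > 0, min_loci >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full CNV association workflow
#'
#' Executes the stages in order: simulate/ingest, (optional) intensity
#' emission + normalization + HMM decode, SNP-based testing with
#' permutation FDR, window-based testing, cross-cohort Rf and joint
#' risk-locus selection, CNV summarization, and recombination context.
#' Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_bundle`: `snp_map`, `recomb_map`,
#'   `scan_ref`, `scan_test`, `candidates`, `windows`, `window_pass`,
#'   `rf`, `risk_loci`, `cnvs`, `singular_loci`, `raw_stats_ref`,
#'   `raw_stats_test`, `recomb_groups`, `hotspot_overlap`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  snp_map <- config$snp_map
  if (is.null(snp_map))
    snp_map <- make_snp_map(config$n_snps,
                            mean_spacing = config$mean_spacing,
                            seed = derive_seed(seed, 1))
  validate_snp_map(snp_map)
  recomb_map <- config$recomb_map
  if (is.null(recomb_map))
    recomb_map <- make_recomb_map(snp_map, n_hotspots = config$n_hotspots,
                                  hot_rate = config$hot_rate,
                                  base_rate = config$base_rate,
                                  seed = derive_seed(seed, 2))
  reference <- config$reference
  if (is.null(reference))
    reference <- simulate_cohort(snp_map, config$n_cases_ref,
                                 config$n_controls_ref,
                                 config$risk_regions,
                                 config$background_rate,
                                 seed = derive_seed(seed, 3),
                                 cohort_id = "reference")
  testing <- config$testing
  if (is.null(testing))
    testing <- simulate_cohort(snp_map, config$n_cases_test,
                               config$n_controls_test,
                               config$risk_regions,
                               config$background_rate,
                               seed = derive_seed(seed, 4),
                               cohort_id = "testing")

  if (isTRUE(config$use_hmm)) {
    # emit intensities, normalize all cohorts to one baseline, train on
    # the reference-panel individuals, freeze parameters, decode
    train_states <- state_matrix(
      matrix(2L, config$n_training, nrow(snp_map)),
      rep("control", config$n_training), "training")
    sig <- quantile_normalize(list(
      emit_intensities(train_states, config$emission_means,
                       config$emission_sd, derive_seed(seed, 5)),
      emit_intensities(reference, config$emission_means,
                       config$emission_sd, derive_seed(seed, 6)),
      emit_intensities(testing, config$emission_means,
                       config$emission_sd, derive_seed(seed, 7))))
    params <- fit_hmm(sig[[1]], default_hmm_params(
      emission_mean = config$emission_means,
      emission_sd = config$emission_sd), max_iter = 10)
    reference <- decode_states(sig[[2]], params, snp_map,
                               reference$labels, reference$cohort_id)
    testing <- decode_states(sig[[3]], params, snp_map,
                             testing$labels, testing$cohort_id)
  }

  # stage 1: SNP-based testing in the discovery (reference) cohort
  scan_ref <- assoc_scan(reference, snp_map)
  scan_test <- assoc_scan(testing, snp_map)
  perms_ref <- permute_labels(reference$labels, config$t_pm,
                              derive_seed(seed, 8))
  perms_test <- permute_labels(testing$labels, config$t_pm,
                               derive_seed(seed, 9))
  ens_ref <- assoc_permutations(reference, perms_ref)
  candidates <- select_candidates(scan_ref, ens_ref, config$candidate_fdr)

  # stage 2: window-based testing on the candidates
  windows <- window_test(scan_ref, snp_map, candidates$snp_id,
                         config$half_width, config$max_gap)
  if (nrow(windows)) {
    wperm <- window_permutations(windows, ens_ref)
    window_pass <- select_windows(windows, wperm, config$window_fdr)
  } else {
    window_pass <- windows
  }

  # stage 3: combined cross-cohort analysis
  rf <- rf_scan(reference, testing, snp_map)
  rf_perm <- rf_permutations(reference, testing, snp_map,
                             perms_ref, perms_test)
  risk_loci <- if (nrow(window_pass))
    select_risk_loci(window_pass, rf, rf_perm, config$fp_budget,
                     config$rf_tail)
  else empty_risk_loci()

  # stage 4: CNV summarization + raw CNV descriptives
  blocks <- blocks_to_cnvs(risk_loci, config$max_gap, config$min_loci,
                           dataset = reference$cohort_id)
  raw_ref <- call_raw_cnvs(reference, snp_map)
  raw_test <- call_raw_cnvs(testing, snp_map)
  stats_ref <- suppressWarnings(summarize_raw_cnvs(raw_ref,
                                                   reference$labels))
  stats_test <- suppressWarnings(summarize_raw_cnvs(raw_test,
                                                    testing$labels))

  # stage 5: recombination context
  groups <- assign_snp_groups(snp_map$snp_id, candidates$snp_id,
                              window_pass$snp_id, risk_loci$snp_id)
  lev <- recomb_level(snp_map$pos, snp_map$chrom, recomb_map,
                      config$recomb_window)
  levels_df <- data.frame(snp_id = snp_map$snp_id, level = lev,
                          group = groups, stringsAsFactors = FALSE)
  recomb_groups <- tryCatch(
    compare_recomb_groups(levels_df, n_perm = 1000,
                          seed = derive_seed(seed, 10)),
    error = function(e) list(summary = NULL, p_value = NA_real_))
  hs_overlap <- hotspot_overlap(blocks$cnvs, recomb_map$hotspots)

  manifest <- c(
    seed = seed, t_pm = config$t_pm, n_snps = nrow(snp_map),
    n_reference = nrow(reference$states), n_testing = nrow(testing$states),
    candidate_fdr = config$candidate_fdr, window_fdr = config$window_fdr,
    fp_budget = config$fp_budget, half_width = config$half_width,
    max_gap = config$max_gap, min_loci = config$min_loci,
    n_candidates = nrow(candidates), n_window_pass = nrow(window_pass),
    n_risk_loci = nrow(risk_loci), n_cnvs = nrow(blocks$cnvs),
    n_singular = nrow(blocks$singular))

  structure(list(
    snp_map = snp_map, recomb_map = recomb_map,
    reference = reference, testing = testing,
    scan_ref = scan_ref, scan_test = scan_test,
    candidates = candidates, windows = windows,
    window_pass = window_pass, rf = rf, risk_loci = risk_loci,
    cnvs = blocks$cnvs, singular_loci = blocks$singular,
    raw_stats_ref = stats_ref, raw_stats_test = stats_test,
    recomb_levels = levels_df, recomb_groups = recomb_groups,
    hotspot_overlap = hs_overlap, manifest = manifest),
    class = "pipeline_bundle")
}

#' Write all pipeline outputs as tab-separated text
#'
#' Emits `risk_loci.tsv`, `cnvs.tsv`, `cnvs.bed` (0-based half-open),
#' `rf_sites.tsv`, `site_tests.tsv`, `rf_scatter.tsv` (the `-log10 p` vs
#' `log10 Rf` scatter data), `raw_cnv_stats.tsv`, `recomb_groups.tsv` and
#' a key/value `manifest.txt`. Empty result sets produce headers-only
#' files.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    tsv(bundle$risk_loci, "risk_loci.tsv"),
    tsv(bundle$cnvs, "cnvs.tsv"),
    write_cnv_bed(bundle$cnvs, file.path(out_dir, "cnvs.bed")),
    tsv(bundle$rf, "rf_sites.tsv"),
    tsv(bundle$scan_ref, "site_tests.tsv"),
    tsv(data.frame(
      snp_id = bundle$scan_ref$snp_id,
      neglog10_p_pearson = -log10(bundle$scan_ref$p_pearson),
      neglog10_p_gain = -log10(bundle$scan_ref$p_gain),
      log10_rf = bundle$rf$log10_rf), "rf_scatter.tsv"),
    tsv(rbind(cbind(cohort = "reference", bundle$raw_stats_ref),
              cbind(cohort = "testing", bundle$raw_stats_test)),
        "raw_cnv_stats.tsv"),
    tsv(bundle$hotspot_overlap, "hotspot_overlap.tsv"))
  if (!is.null(bundle$recomb_groups$summary))
    paths <- c(paths, tsv(bundle$recomb_groups$summary,
                          "recomb_groups.tsv"))
  mp <- file.path(out_dir, "manifest.txt")
  writeLines(paste(names(bundle$manifest), bundle$manifest, sep = "\t"),
             mp)
  invisible(c(paths, mp))
}
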