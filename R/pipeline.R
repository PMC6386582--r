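#' Pipeline thresholds
#'
#' All decision cut-offs applied by [run_pipeline()], with the analysis
#' defaults: peaks retained above 2-fold enrichment; Pol V absence called
#' above 4-fold ZF-over-Pol V enrichment at FDR 0.05; siRNA bins above
#' 4-fold at FDR 0.05; differential expression above 2-fold at FDR 0.05;
#' DMR windows of 100 bp over 1-kb site flanks with per-context difference
#' thresholds CG 0.4 / CHG 0.2 / CHH 0.1 at q < 0.01 and at least 4 covered
#' cytosines; DMRs merged within 200 bp; heritability at a CG gain of at
#' least 0.10; early flowering at 20 leaves or fewer. Unknown keys are
#' rejected.
#'
#' @param peak_min_fold,polv_min_fold,polv_fdr,sirna_min_fold,sirna_fdr
#'   ChIP/siRNA cut-offs.
#' @param de_min_fold,de_fdr Expression cut-offs.
#' @param dmr_thresholds,dmr_fdr,dmr_min_cytosines,dmr_max_gap DMR calling.
#' @param flank,window Window geometry (bp).
#' @param chh_baseline_max Pre-existing CHH filter level.
#' @param heritable_min_gain CG-gain heritability rule.
#' @param flowering_threshold Early-flowering leaf-count boundary.
#' @param site_dmr_pad Pad (bp) when matching called DMRs back to sites.
#' @param repression_window Upstream window (bp) linking a site to a
#'   repressed gene.
#' @param enrichment_breaks Signed-distance bins for observed/expected.
#' @param n_perm Permutations for observed/expected.
#' @return A validated `rddm_thresholds` list.
#' @export
pipeline_thresholds <- function(peak_min_fold = 2,
                                polv_min_fold = 4, polv_fdr = 0.05,
                                sirna_min_fold = 4, sirna_fdr = 0.05,
                                de_min_fold = 2, de_fdr = 0.05,
                                dmr_thresholds = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                                dmr_fdr = 0.01, dmr_min_cytosines = 4,
                                dmr_max_gap = 200,
                                flank = 1000, window = 100,
                                chh_baseline_max = 0.05,
                                heritable_min_gain = 0.10,
                                flowering_threshold = 20,
                                site_dmr_pad = 500,
                                repression_window = 200,
                                enrichment_breaks = seq(-2000, 2000, 250),
                                n_perm = 200) {
  th <- as.list(environment())
  for (f in c("polv_fdr", "sirna_fdr", "de_fdr", "dmr_fdr")) {
    if (!is.numeric(th[[f]]) || th[[f]] <= 0 || th[[f]] >= 1) {
      abort(sprintf("%s must lie strictly between 0 and 1", f))
    }
  }
  for (f in c("peak_min_fold", "polv_min_fold", "sirna_min_fold", "de_min_fold",
              "flank", "window", "n_perm")) {
    if (!is.numeric(th[[f]]) || th[[f]] <= 0) abort(sprintf("%s must be positive", f))
  }
  structure(th, class = "rddm_thresholds")
}

#' Run the full targeted-methylation pipeline on a simulated dataset
#'
#' Executes the stages in order: simulate, ChIP peak retention and Pol V
#' classification, siRNA-production classification, anchored DMR calling
#' with context combination, heritability deciles, differential expression
#' with TSS-distance enrichment, phenotype classification, and the
#' multilevel funnel. All randomness flows from the configuration seed, so
#' rerunning with the same configuration reproduces the report exactly.
#'
#' @param config A [sim_config()], or an already simulated `rddm_dataset`.
#' @param thresholds A [pipeline_thresholds()].
#' @param outdir Optional directory to write report files into (funnel JSON,
#'   DMR BED, decile/enrichment/classification TSVs, threshold log); each
#'   file carries the configuration hash and seed in a header comment.
#' @return An `rddm_report` list; see Details.
#' @details The report contains: `classifications` (per-site flags and
#'   statistics), `funnel`, `dmrs` (per-context and combined),
#'   `window_tests`, `deciles`, `decile_summary`, `de`, `links`,
#'   `enrichment`, `phenotypes` (with flowering calls), `motif_fraction`,
#'   `truth`, `config`, `thresholds`, `config_hash` and `log` (every
#'   threshold actually applied).
#' @export
run_pipeline <- function(config = sim_config(),
                         thresholds = pipeline_thresholds(),
                         outdir = NULL) {
  stopifnot(inherits(thresholds, "rddm_thresholds"))
  sim <- if (inherits(config, "rddm_dataset")) config else simulate_dataset(config)
  config <- sim$config
  th <- thresholds

  # --- ChIP: peak retention + Pol V recruitment -------------------------
  zf <- sim$chip$counts$zf
  input <- sim$chip$counts$input
  polv <- sim$chip$counts$polv
  zi <- inner_join(zf, input, by = "feature_id")
  sf <- size_factors(zi, fallback_total = TRUE)
  norm <- sweep(count_df_to_matrix(zi), 2, sf, "/")
  norm <- norm[sim$sites$site_id, , drop = FALSE]   # drop background features
  zf_cols <- setdiff(names(zf), "feature_id")
  in_cols <- setdiff(names(input), "feature_id")
  peaks <- sim$sites |>
    mutate(fusion_mean = rowMeans(norm[, zf_cols, drop = FALSE]),
           control_mean = rowMeans(norm[, in_cols, drop = FALSE])) |>
    retain_zf_peaks(min_fold = th$peak_min_fold)
  polv_cls <- classify_polv(zf, polv, min_fold = th$polv_min_fold,
                            fdr = th$polv_fdr)

  # --- siRNA production -------------------------------------------------
  sirna_cls <- classify_sirna(sim$sirna$counts$s24, sim$sirna$samples,
                              sim$sirna$bin_sites,
                              min_fold = th$sirna_min_fold, fdr = th$sirna_fdr,
                              site_ids = sim$sites$site_id)

  # --- anchored DMR calling --------------------------------------------
  wf <- window_flanks(sim$sites, flank = th$flank, window = th$window,
                      chrom_sizes = sim$chrom_sizes)
  wt <- test_windows(wf$windows, sim$bisulfite$fusion, sim$bisulfite$control,
                     min_cytosines = th$dmr_min_cytosines)
  dmrs_ctx <- call_hyperdmrs(wt, thresholds = th$dmr_thresholds,
                             fdr = th$dmr_fdr, max_gap = th$dmr_max_gap)
  dmrs <- combine_contexts(dmrs_ctx, max_gap = th$dmr_max_gap)

  # --- heritability deciles over CG-context DMRs ------------------------
  cg_dmrs <- filter(as_tibble(dmrs_ctx), grepl("(^|,)CG(,|$)", .data$contexts))
  heritability <- NULL
  deciles <- NULL
  decile_tbl <- NULL
  if (nrow(cg_dmrs) > 0) {
    seg <- region_methylation(sim$bisulfite$segregant,
                              mutate(cg_dmrs, name = sprintf("r%05d", row_number())),
                              contexts = "CG")
    heritability <- cg_dmrs |>
      mutate(region = sprintf("r%05d", row_number()),
             level_fusion = .data$m_fus / (.data$m_fus + .data$u_fus),
             level_control = .data$m_ctl / (.data$m_ctl + .data$u_ctl)) |>
      left_join(select(seg, "region", level_segregant = "level"),
                by = "region") |>
      mutate(heritable = classify_heritable(.data$level_segregant,
                                            .data$level_control,
                                            th$heritable_min_gain),
             seg_gain = .data$level_segregant - .data$level_control)
    deciles <- rank_deciles(heritability, metric = "diff")
    decile_tbl <- decile_summary(deciles, c("diff", "seg_gain", "heritable"))
  }

  # --- expression + enrichment ------------------------------------------
  de <- call_de(sim$expression$counts, sim$expression$samples,
                min_fold = th$de_min_fold, fdr = th$de_fdr)
  expressed <- de$feature_id[de$mean_a + de$mean_b > 0]
  links <- link_dmrs_to_genes(dmrs, sim$genes,
                              max_distance = max(abs(th$enrichment_breaks)),
                              breaks = th$enrichment_breaks)
  gene_distances <- links |>
    filter(!is.na(.data$gene_id)) |>
    select("gene_id", "distance")
  down_genes <- intersect(de$feature_id[de$down], expressed)
  enrichment <- NULL
  if (length(down_genes) > 0) {
    enrichment <- observed_expected(
      gene_distances, down_genes, expressed,
      breaks = th$enrichment_breaks, n_perm = th$n_perm,
      seed = substream_seed(config$seed, "enrichment")
    )
  }

  # --- per-site flags + funnel ------------------------------------------
  site_hyper <- overlaps_any(
    mutate(sim$sites, start = pmax(0, .data$start - th$site_dmr_pad),
           end = .data$end + th$site_dmr_pad),
    dmrs
  )
  down_tbl <- sim$genes[sim$genes$gene_id %in% down_genes, , drop = FALSE]
  site_repressed <- vapply(seq_len(nrow(sim$sites)), function(i) {
    g <- down_tbl[down_tbl$chrom == sim$sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(FALSE)
    d <- tss_distance(sim$sites$start[i], sim$sites$end[i], g$tss, g$strand)
    any(d >= -th$repression_window & d <= 0)
  }, logical(1))
  classifications <- sim$sites |>
    select("site_id", "chrom", "start", "end") |>
    mutate(bound = peaks$bound) |>
    left_join(select(polv_cls, "site_id", "polv_recruited",
                     polv_q = "q_value"), by = "site_id") |>
    left_join(select(sirna_cls, "site_id", "sirna_producing", "n_sig_bins"),
              by = "site_id") |>
    mutate(hyperdmr = site_hyper, repressed_gene = site_repressed)
  funnel <- build_funnel(classifications)

  phenotypes <- sim$phenotypes |>
    mutate(flowering = classify_flowering(.data$leaves,
                                          th$flowering_threshold)$flowering)
  motif_fraction <- scan_motif(sim$genome, sim$sites, config$motif)$fraction

  log_tbl <- threshold_log(th)
  report <- structure(list(
    classifications = classifications, funnel = funnel,
    dmrs = dmrs, dmrs_by_context = dmrs_ctx, window_tests = wt,
    deciles = deciles, decile_summary = decile_tbl, heritability = heritability,
    de = de, links = links, enrichment = enrichment,
    phenotypes = phenotypes, motif_fraction = motif_fraction,
    truth = sim$truth, config = config, thresholds = th,
    config_hash = rlang::hash(unclass(config)), seed = config$seed,
    log = log_tbl
  ), class = "rddm_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

threshold_log <- function(th) {
  flat <- unlist(unclass(th))
  tibble(parameter = names(flat), value = unname(flat))
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s seed=%d", report$config_hash, report$seed)
  put_tsv <- function(x, file) {
    path <- file.path(outdir, file)
    writeLines(stamp, path)
    suppressWarnings(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
    path
  }
  put_tsv(select(as_tibble(report$funnel), -"site_ids"), "funnel.tsv")
  funnel_json <- list(
    config_hash = report$config_hash, seed = report$seed,
    levels = purrr::map(seq_len(nrow(report$funnel)), function(i) {
      list(flag = report$funnel$flag[i], n = report$funnel$n[i],
           pct_of_previous = report$funnel$pct_of_previous[i])
    })
  )
  jsonlite::write_json(funnel_json, file.path(outdir, "funnel.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(report$dmrs) > 0) {
    write_bed(mutate(as_tibble(report$dmrs),
                     name = .data$contexts, score = round(.data$diff, 4)),
              file.path(outdir, "hyperdmrs.bed"))
  }
  if (!is.null(report$decile_summary)) put_tsv(report$decile_summary, "deciles.tsv")
  if (!is.null(report$enrichment)) {
    put_tsv(as_tibble(report$enrichment), "enrichment.tsv")
  }
  put_tsv(report$classifications, "classifications.tsv")
  put_tsv(report$phenotypes, "phenotypes.tsv")
  put_tsv(report$log, "thresholds.tsv")
  invisible(outdir)
}

#' @export
print.rddm_report <- function(x, ...) {
  cat("Targeted-methylation pipeline report\n")
  cat(sprintf("  seed %d, config hash %s\n", x$seed, x$config_hash))
  cat(sprintf("  sites: %d | hyperDMRs: %d | motif fraction: %.2f\n",
              nrow(x$classifications), nrow(x$dmrs), x$motif_fraction))
  cat("  funnel:\n")
  f <- as_tibble(x$funnel)
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %d. %-16s n = %4d (%.1f%% of previous)\n",
                f$level[i], f$flag[i], f$n[i], f$pct_of_previous[i]))
  }
  invisible(x)
}
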