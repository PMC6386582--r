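test_that("identical seed and config reproduce the dataset exactly", {
  cfg <- tiny_config(seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$chip$counts, d2$chip$counts)
  expect_identical(d1$sirna$counts, d2$sirna$counts)
  expect_identical(d1$bisulfite, d2$bisulfite)
  expect_identical(d1$expression$counts, d2$expression$counts)
  expect_identical(d1$phenotypes, d2$phenotypes)
  # different seed changes the data
  d3 <- simulate_genome(tiny_config(seed = 100))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("truth labels nest and respect degenerate fractions", {
  for (seed in c(1, 5, 9)) {
    tr <- simulate_genome(tiny_config(seed = seed))$truth
    expect_true(all(!tr$is_polv_recruited | tr$is_bound))
    expect_true(all(!tr$is_sirna_producing | tr$is_polv_recruited))
    expect_true(all(!tr$is_hypermethylated | tr$is_sirna_producing))
    expect_true(all(!tr$is_heritable | tr$is_hypermethylated))
  }
  none <- simulate_genome(tiny_config(frac_polv_recruited = 0))$truth
  expect_equal(sum(none$is_polv_recruited), 0)
  expect_equal(sum(none$is_sirna_producing), 0)
  expect_equal(sum(none$is_hypermethylated), 0)
})

test_that("planted label counts sit inside binomial 99% intervals", {
  cfg <- sim_config(n_sites = 100, frac_polv_recruited = 0.9,
                    frac_sirna_producing = 0.1, frac_hypermethylated = 0.5)
  sites <- tibble::tibble(
    site_id = sprintf("s%03d", 1:100), chrom = "chr1",
    start = seq(0, by = 1000, length.out = 100),
    end = seq(200, by = 1000, length.out = 100),
    strand = "+", motif_start = seq(94, by = 1000, length.out = 100),
    accessibility = runif(100, 0.5, 1.5)
  )
  expected <- c(bound = 100, polv = 90, sirna = 9, hyper = 4.5)
  for (seed in 1:50) {
    tr <- withr::with_seed(seed, rddmtarget:::draw_truth_labels(sites, cfg))
    got <- c(sum(tr$is_bound), sum(tr$is_polv_recruited),
             sum(tr$is_sirna_producing), sum(tr$is_hypermethylated))
    for (j in 1:4) {
      ci <- qbinom(c(0.005, 0.995), 100, expected[j] / 100)
      expect_gte(got[j], ci[1])
      expect_lte(got[j], ci[2])
    }
  }
})

test_that("ChIP counts realise the configured enrichment fold", {
  cfg <- sim_config(seed = 3, n_sites = 200, chip_enrichment_fold = 8)
  tr <- simulate_genome(sim_config(seed = 3, n_sites = 200,
                                   n_chromosomes = 2,
                                   chromosome_length = 250000,
                                   chip_enrichment_fold = 8))$truth
  chip <- simulate_chip_counts(tr, cfg)
  zf <- rddmtarget:::count_df_to_matrix(chip$counts$zf)
  input <- rddmtarget:::count_df_to_matrix(chip$counts$input)
  bound <- tr$site_id[tr$is_bound]
  fold <- mean(zf[bound, ]) / mean(input)
  expect_gt(fold, 8 * 0.75)
  expect_lt(fold, 8 * 1.25)
  # invalid configurations error at construction
  expect_error(sim_config(replicates_per_group = 0), "positive")
  expect_error(sim_config(nb_dispersion = -1), "positive")
  expect_error(sim_config(motif = "ACGU"), "motif")
  expect_error(sim_config(motif = strrep("ACGT", 200),
                          chromosome_length = 500), "longer than chromosome")
  expect_error(sim_config(frac_heritable = 1.7), "proportion")
  expect_error(sim_config(repression_fold = 0.5), "repression_fold")
})

test_that("read-level simulator produces conversion failures the filter catches", {
  cfg <- tiny_config(seed = 8, conversion_failure_rate = 0)
  sim <- simulate_genome(cfg)
  calls <- simulate_bisulfite_reads(sim$genome, "chr1", 1000, 3000, cfg)
  flags <- flag_conversion_failures(calls)
  # at CHH baseline 0.02 a run of 4 methylated CHH is essentially impossible
  expect_lt(mean(flags$removed), 0.01)

  cfg2 <- tiny_config(seed = 8, conversion_failure_rate = 0.3)
  calls2 <- simulate_bisulfite_reads(sim$genome, "chr1", 1000, 3000, cfg2)
  flags2 <- flag_conversion_failures(calls2)
  truthful <- dplyr::distinct(calls2, .data$read_id, .data$failure)
  joined <- dplyr::inner_join(flags2, truthful, by = "read_id")
  # failure reads carry long methylated-CHH runs; clean reads almost never do
  expect_gt(mean(joined$removed[joined$failure]), 0.9)
  expect_lt(mean(joined$removed[!joined$failure]), 0.02)
})

test_that("bisulfite gains are planted where truth says and guard the unit range", {
  cfg <- tiny_config(seed = 4)
  sim <- simulate_genome(cfg)
  bis <- simulate_bisulfite(sim)
  expect_named(bis, c("fusion", "segregant", "control"))
  hyper <- dplyr::filter(sim$truth, is_hypermethylated)
  if (nrow(hyper) > 0) {
    h <- hyper[1, ]
    reg <- tibble::tibble(chrom = h$chrom, start = h$start, end = h$end)
    lev <- function(tb) {
      region_methylation(tb, reg, "CG")$level
    }
    expect_gt(lev(bis$fusion) - lev(bis$control), 0.25)
  }
  cold <- dplyr::filter(sim$truth, !is_hypermethylated)[1, ]
  reg0 <- tibble::tibble(chrom = cold$chrom, start = cold$start, end = cold$end)
  expect_lt(abs(region_methylation(bis$fusion, reg0, "CG")$level -
                  region_methylation(bis$control, reg0, "CG")$level), 0.15)
  # a baseline + maximal gain above 1 is rejected
  bad <- tiny_config(meth_baseline = c(CG = 0.3, CHG = 0.03, CHH = 0.02),
                     meth_gain = c(CG = 0.8, CHG = 0.3, CHH = 0.2))
  expect_error(simulate_bisulfite(sim, config = bad), "exceeds 1")
})

test_that("siRNA channels conserve totals and carry the planted fold", {
  cfg <- tiny_config(seed = 12)
  sim <- simulate_genome(cfg)
  sr <- simulate_sirna_bins(sim)
  per_class <- lapply(sr$counts, function(x) {
    colSums(rddmtarget:::count_df_to_matrix(x))
  })
  expect_equal(sr$totals, Reduce(`+`, per_class))
  expect_error(simulate_sirna_bins(sim, bin_width = 0), "positive")

  prod <- dplyr::filter(sim$truth, is_sirna_producing)
  if (nrow(prod) > 0) {
    hot_bins <- sr$bin_sites$window_id[sr$bin_sites$site_id %in% prod$site_id]
    m <- rddmtarget:::count_df_to_matrix(sr$counts$s24)
    fus <- grepl("^fusion", colnames(m))
    hot <- rownames(m) %in% hot_bins & rowMeans(m[, fus]) > rowMeans(m[, !fus])
    expect_gt(sum(hot), 0)
  }
})

test_that("expression repression follows TSS-proximal hypermethylation", {
  cfg <- tiny_config(seed = 21, n_sites = 30, chromosome_length = 100000,
                     frac_sirna_producing = 0.5)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim)
  genes <- expr$genes
  expect_true(all(ifelse(genes$strand == "+", genes$tss == genes$start,
                         genes$tss == genes$end - 1)))
  m <- rddmtarget:::count_df_to_matrix(expr$counts)
  fus <- grepl("^fusion", colnames(m))
  if (any(genes$repressed)) {
    ratio <- mean(m[genes$repressed, !fus]) / mean(m[genes$repressed, fus])
    expect_gt(ratio, 2.5)
    expect_lt(ratio, 6.5)
  }
  null_ratio <- mean(m[!genes$repressed, !fus]) / mean(m[!genes$repressed, fus])
  expect_lt(abs(log2(null_ratio)), 0.3)
})

test_that("heritability flags interleave evenly across the gain ranking", {
  flags <- rddmtarget:::interleave_flags(45, 0.6)
  expect_equal(sum(flags), 27)
  # any contiguous window of 5 ranks holds exactly 3 heritable sites
  runs <- vapply(1:41, function(i) sum(flags[i:(i + 4)]), numeric(1))
  expect_true(all(runs == 3))
})
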