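test_that("peak retention uses a strict 2-fold rule with pseudocount", {
  peaks <- tibble::tibble(
    fusion_mean = c(1.1, 2.0, 50, 10),
    control_mean = c(0, 0.5, 0, 10)
  )
  out <- retain_zf_peaks(peaks)
  # folds: 2.1 (kept), 3/1.5 = 2.0 (dropped: strict >), 51 (kept), 1 (dropped)
  expect_equal(out$bound, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$fold[2], 2)
  expect_error(retain_zf_peaks(tibble::tibble(fusion_mean = 1)), "control_mean")
})

test_that("fold and FDR cut-offs are strict in the stated directions", {
  tc <- rddmtarget:::threshold_calls
  # fold exactly at the boundary never passes
  expect_false(tc(log2(4), 0.001, 4, 0.05, "up"))
  expect_true(tc(log2(4.05), 0.001, 4, 0.05, "up"))
  # FDR exactly at the boundary never passes
  expect_false(tc(3, 0.05, 4, 0.05, "up"))
  # high fold but weak evidence is not called
  expect_false(tc(log2(6), 0.20, 4, 0.05, "up"))
  # down direction mirrors up
  expect_true(tc(-1.1, 0.01, 2, 0.05, "down"))
  expect_false(tc(-1, 0.01, 2, 0.05, "down"))
})

test_that("Pol V classification inverts the enrichment rule", {
  withr::with_seed(17, {
    n <- 60
    ids <- sprintf("s%03d", 1:n)
    # sites 1-10: fusion signal only (no Pol V) -> should be called NOT recruited
    mu_fus <- rep(800, n)
    mu_pv <- c(rep(100, 10), rep(800, n - 10))
    fus <- tibble::tibble(feature_id = ids,
                          f1 = rpois(n, mu_fus), f2 = rpois(n, mu_fus),
                          f3 = rpois(n, mu_fus))
    pv <- tibble::tibble(feature_id = ids,
                         p1 = rpois(n, mu_pv), p2 = rpois(n, mu_pv),
                         p3 = rpois(n, mu_pv))
    cls <- classify_polv(fus, pv)
    expect_false(any(cls$polv_recruited[1:10]))
    expect_true(all(cls$polv_recruited[11:n]))
  })
  expect_error(classify_polv(tibble::tibble(feature_id = "a", x = 1),
                             tibble::tibble(feature_id = "b", x = 1)),
               "identical")
})

test_that("siRNA production needs one significant bin per site", {
  withr::with_seed(23, {
    n_sites <- 30
    bins <- tidyr::expand_grid(site = sprintf("s%02d", 1:n_sites), bin = 1:5) |>
      dplyr::mutate(window_id = sprintf("%s_b%d", site, bin))
    hot <- bins$site %in% sprintf("s%02d", 1:3) & bins$bin == 3
    mu_f <- ifelse(hot, 300, 20)
    counts <- tibble::tibble(
      feature_id = bins$window_id,
      fusion_rep1 = rpois(nrow(bins), mu_f),
      fusion_rep2 = rpois(nrow(bins), mu_f),
      control_rep1 = rpois(nrow(bins), 20),
      control_rep2 = rpois(nrow(bins), 20)
    )
    samples <- tibble::tibble(
      sample = c("fusion_rep1", "fusion_rep2", "control_rep1", "control_rep2"),
      group = c("fusion", "fusion", "control", "control")
    )
    bin_sites <- dplyr::select(bins, window_id, site_id = site)
    cls <- classify_sirna(counts, samples, bin_sites)
    expect_true(all(cls$sirna_producing[cls$site_id %in% sprintf("s%02d", 1:3)]))
    expect_false(any(cls$sirna_producing[!cls$site_id %in% sprintf("s%02d", 1:3)]))
    # all-zero bins in both groups are never called
    zero <- counts |>
      dplyr::mutate(dplyr::across(-feature_id, ~ 0L))
    cls0 <- classify_sirna(zero, samples, bin_sites)
    expect_false(any(cls0$sirna_producing))
    # sites with no bins are reported non-producing with a warning
    expect_warning(
      cls_orphan <- classify_sirna(counts, samples, bin_sites,
                                   site_ids = c(bins$site, "lonely")),
      "no bins"
    )
    expect_false(cls_orphan$sirna_producing[cls_orphan$site_id == "lonely"])
  })
})

test_that("the funnel nests counts and percentages", {
  cl <- tibble::tibble(
    site_id = sprintf("s%d", 1:10),
    bound = rep(TRUE, 10),
    polv_recruited = c(rep(TRUE, 8), FALSE, FALSE),
    sirna_producing = c(rep(TRUE, 4), rep(FALSE, 6)),
    hyperdmr = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6)),
    repressed_gene = c(TRUE, rep(FALSE, 9))
  )
  f <- build_funnel(cl)
  expect_equal(f$n, c(10, 8, 4, 2, 1))
  expect_true(all(diff(f$n) <= 0))
  expect_true(all(f$pct_of_previous >= 0 & f$pct_of_previous <= 100))
  expect_equal(f$pct_of_previous[2], 80)
  expect_equal(f$site_ids[[4]], c("s1", "s2"))
  # omitting a level (e.g. no Pol V stage for a Pol IV fusion) works
  f4 <- build_funnel(cl, levels = c("bound", "sirna_producing", "hyperdmr"))
  expect_equal(f4$n, c(10, 4, 2))
  # empty input gives an all-zero funnel
  f0 <- build_funnel(cl[0, ])
  expect_equal(f0$n, rep(0L, 5))
  expect_error(build_funnel(cl, levels = c("bound", "nope")), "unknown flag")
})

test_that("venn regions partition the union", {
  v2 <- venn_regions(c(1, 2), c(2, 3))
  expect_equal(v2$n, c(1, 1, 1))
  same <- venn_regions(letters[1:4], letters[1:4])
  expect_equal(same$n[same$region == "ab"], 4)
  expect_equal(sum(same$n), 4)
  disjoint <- venn_regions(1:3, 4:6, 7:9)
  expect_equal(sum(disjoint$n), 9)
  expect_equal(disjoint$n[disjoint$region == "abc"], 0)
  withr::with_seed(2, {
    a <- sample(1:50, 20); b <- sample(1:50, 25); c <- sample(1:50, 10)
  })
  expect_equal(sum(venn_regions(a, b, c)$n), length(union(union(a, b), c)))
})

test_that("metaplots aggregate scaled intervals correctly", {
  flat <- tibble::tibble(chrom = "chr1", start = 0, end = 5000, score = 3)
  iv <- tibble::tibble(chrom = "chr1", start = 2000, end = 2400, strand = "+")
  mp <- metaplot(flat, iv, n_bins = 10, flank = 500, flank_bins = 5)
  expect_true(all(abs(mp$profile$mean - 3) < 1e-12))

  # linear ramp: profile must be monotone and match direct binning
  ramp <- tibble::tibble(chrom = "chr1", start = 0:4999, end = 1:5000,
                         score = 0:4999)
  mpr <- metaplot(ramp, iv, n_bins = 8, flank = 400, flank_bins = 4)
  body <- mpr$profile$mean[mpr$profile$region == "body"]
  expect_true(all(diff(body) > 0))
  direct <- vapply(0:7, function(j) {
    mean((2000:2399)[(j * 50 + 1):((j + 1) * 50)])
  }, numeric(1))
  expect_equal(body, direct, tolerance = 1e-9)

  # strand flip reverses the profile
  ivm <- dplyr::mutate(iv, strand = "-")
  mpm <- metaplot(ramp, ivm, n_bins = 8, flank = 400, flank_bins = 4)
  expect_equal(mpm$profile$mean, rev(mpr$profile$mean), tolerance = 1e-9)

  # conservation: a delta track integrates to the same mass after binning
  delta <- tibble::tibble(chrom = "chr1", start = c(0, 2200),
                          end = c(5000, 2201), score = c(0, 7))
  mpd <- metaplot(delta, iv, n_bins = 10, flank = 500, flank_bins = 5)
  body_mass <- sum(mpd$profile$mean[mpd$profile$region == "body"] * 40)
  flank_mass <- sum(mpd$profile$mean[mpd$profile$region != "body"] * 100)
  expect_equal(body_mass + flank_mass, 7, tolerance = 1e-9)

  # intervals outside the track are skipped with a warning
  expect_warning(
    metaplot(flat, tibble::tibble(chrom = "chr1", start = 4900, end = 4950),
             n_bins = 4, flank = 500, flank_bins = 2),
    "skipped"
  )
})

test_that("motif scanning counts intervals once and honours mismatches", {
  withr::with_seed(31, {
    seqs <- vapply(1:10, function(.) rddmtarget:::random_dna(300), character(1))
  })
  motif <- "GTCACGTTGACA"
  # plant the motif in intervals 1-3 (interval 2 twice, interval 3 on minus)
  substr(seqs[1], 100, 111) <- motif
  substr(seqs[2], 50, 61) <- motif
  substr(seqs[2], 200, 211) <- motif
  substr(seqs[3], 150, 161) <- rddmtarget:::revcomp(motif)
  genome <- c(chr1 = paste(seqs, collapse = ""))
  iv <- tibble::tibble(chrom = "chr1", start = (0:9) * 300, end = (1:10) * 300)
  res <- scan_motif(genome, iv, motif)
  expect_equal(res$fraction, 0.3)
  expect_true(all(res$per_interval$has_motif[1:3]))
  expect_equal(res$per_interval$n_hits[2], 2)

  none <- scan_motif(genome, iv, "TTTTTTTTTTTTTTTT")
  expect_equal(none$fraction, 0)
  expect_error(scan_motif(genome, iv, ""), "non-empty")

  # allowing mismatches can only grow the hit fraction; verify against a
  # brute-force sliding comparison on one interval
  res1 <- scan_motif(genome, iv, motif, max_mismatch = 1)
  expect_gte(res1$fraction, res$fraction)
  seq4 <- substr(genome[["chr1"]], 3 * 300 + 1, 4 * 300)
  brute <- function(s, pat, mm) {
    hits <- 0
    for (strand_seq in c(s, rddmtarget:::revcomp(s))) {
      for (i in 1:(nchar(strand_seq) - nchar(pat) + 1)) {
        w <- substr(strand_seq, i, i + nchar(pat) - 1)
        d <- sum(strsplit(w, "")[[1]] != strsplit(pat, "")[[1]])
        if (d <= mm) hits <- hits + 1
      }
    }
    hits
  }
  got <- scan_motif(c(x = seq4), tibble::tibble(chrom = "x", start = 0,
                                                end = nchar(seq4)),
                    motif, max_mismatch = 2)
  expect_equal(got$per_interval$n_hits, brute(seq4, motif, 2))
})
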