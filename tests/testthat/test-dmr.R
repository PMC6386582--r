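test_that("window tiling covers site plus flanks and truncates at edges", {
  sites <- tibble::tibble(site_id = "s1", chrom = "chr1", start = 5000, end = 5200)
  wf <- window_flanks(sites, flank = 1000, window = 100,
                      chrom_sizes = c(chr1 = 10000))
  expect_equal(nrow(wf$windows), 22)
  expect_equal(min(wf$windows$start), 4000)
  expect_equal(max(wf$windows$end), 6200)
  expect_true(all(wf$windows$end - wf$windows$start == 100))

  near0 <- window_flanks(tibble::tibble(site_id = "s1", chrom = "chr1",
                                        start = 30, end = 230),
                         chrom_sizes = c(chr1 = 10000))
  expect_equal(min(near0$windows$start), 0)

  # two sites sharing a grid: shared windows emitted once, two back-pointers
  pair <- tibble::tibble(site_id = c("a", "b"), chrom = "chr1",
                         start = c(0, 100), end = c(200, 300))
  wfp <- window_flanks(pair, flank = 1000, window = 100,
                       chrom_sizes = c(chr1 = 5000))
  expect_equal(anyDuplicated(wfp$windows$window_id), 0)
  shared <- dplyr::count(wfp$window_sites, window_id)
  expect_true(any(shared$n == 2))
  expect_error(window_flanks(pair, flank = 0), "positive")
})

test_that("window tests pool counts and skip thin windows", {
  win <- tibble::tibble(window_id = "w1", chrom = "chr1", start = 0, end = 100)
  fus <- make_records("chr1", seq(5, 95, by = 10), "CHH",
                      m = rep(4, 10), u = rep(1, 10))
  ctl <- make_records("chr1", seq(5, 45, by = 10), "CHH",
                      m = rep(1, 5), u = rep(9, 5))
  res <- test_windows(win, fus, ctl, contexts = "CHH")
  expect_equal(res$diff, 0.7)
  expect_lt(res$p_value, 1e-10)

  same <- test_windows(win, fus, fus, contexts = "CHH")
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  # a window without covered cytosines in one group is skipped
  skip <- test_windows(win, fus, make_records("chr1", 500, "CHH", 3, 3),
                       contexts = "CHH")
  expect_equal(nrow(skip), 0)
})

test_that("hyperDMR thresholds are per-context, hyper-only and strict on FDR", {
  base <- tibble::tibble(
    window_id = c("w1", "w2", "w3", "w4"), chrom = "chr1",
    start = c(0, 200, 400, 600), end = c(100, 300, 500, 700),
    context = c("CHH", "CG", "CG", "CHH"),
    m_fus = c(60, 390, 500, 10), u_fus = c(440, 610, 500, 490),
    m_ctl = c(0, 0, 900, 260), u_ctl = c(500, 1000, 100, 240),
    n_cyt_fus = 10, n_cyt_ctl = 10,
    diff = c(0.12, 0.39, -0.4, -0.5),
    p_value = c(1e-9, 1e-12, 1e-12, 1e-12),
    q_value = c(1e-3, 1e-6, 1e-6, 1e-6)
  )
  out <- call_hyperdmrs(base)
  # CHH diff 0.12 >= 0.1 retained; CG diff 0.39 < 0.4 dropped; negative dropped
  expect_equal(nrow(out), 1)
  expect_equal(out$contexts, "CHH")
  expect_equal(out$start, 0)
  # FDR boundary is strict
  boundary <- dplyr::mutate(base[1, ], q_value = 0.01)
  expect_equal(nrow(call_hyperdmrs(boundary)), 0)
  expect_error(call_hyperdmrs(dplyr::mutate(base, context = "CNN")),
               "unknown context")
})

test_that("DMR merging applies the strict 200-bp gap rule and pools counts", {
  dmrs <- tibble::tibble(
    chrom = "chr1", start = c(100, 350), end = c(200, 450),
    contexts = "CG", m_fus = c(40, 10), u_fus = c(10, 40),
    m_ctl = c(5, 5), u_ctl = c(45, 45), min_q = c(1e-4, 1e-3)
  )
  merged <- merge_dmrs(dmrs, max_gap = 200)   # gap 150 < 200 -> merged
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 450))
  # coverage-weighted recomputation over the union
  expect_equal(merged$diff, 50 / 100 - 10 / 100)
  expect_equal(merged$min_q, 1e-4)

  apart <- dplyr::mutate(dmrs, start = c(100, 450), end = c(200, 550))
  expect_equal(nrow(merge_dmrs(apart, max_gap = 200)), 2)  # gap 250: kept apart

  # idempotence and order independence
  twice <- merge_dmrs(merged, max_gap = 200)
  expect_equal(twice$start, merged$start)
  expect_equal(twice$end, merged$end)
  shuffled <- merge_dmrs(dmrs[2:1, ], max_gap = 200)
  expect_equal(shuffled$start, merged$start)
  expect_equal(shuffled$diff, merged$diff)
})

test_that("context combination unions overlapping per-context calls", {
  cg <- tibble::tibble(chrom = "chr1", start = 0, end = 100, contexts = "CG",
                       m_fus = 50, u_fus = 50, m_ctl = 5, u_ctl = 95,
                       min_q = 1e-5)
  chh <- tibble::tibble(chrom = "chr1", start = 150, end = 250, contexts = "CHH",
                        m_fus = 30, u_fus = 70, m_ctl = 2, u_ctl = 98,
                        min_q = 1e-4)
  uni <- combine_contexts(cg, chh)
  expect_equal(nrow(uni), 1)
  expect_equal(c(uni$start, uni$end), c(0, 250))
  expect_equal(uni$contexts, "CG,CHH")

  far <- dplyr::mutate(chh, start = 400, end = 500)
  expect_equal(nrow(combine_contexts(cg, far)), 2)
  expect_equal(nrow(combine_contexts(list())), 0)
})

test_that("pre-existing CHH and tRNA filters drop the right regions", {
  dmrs <- tibble::tibble(chrom = "chr1", start = c(0, 200, 400, 600),
                         end = c(100, 300, 500, 700), contexts = "CHH")
  # control CHH baselines: 0.06 (drop), 0.04 (keep), 0.00 (tRNA, drop),
  # exactly 0.05 (keep: the rule is strict >)
  baseline <- dplyr::bind_rows(
    make_records("chr1", 50, "CHH", 6, 94),
    make_records("chr1", 250, "CHH", 4, 96),
    make_records("chr1", 450, "CHH", 0, 100),
    make_records("chr1", 650, "CHH", 5, 95)
  )
  trna <- tibble::tibble(chrom = "chr1", start = 490, end = 520)
  kept <- filter_preexisting_chh(dmrs, baseline, trna)
  expect_equal(kept$start, c(200, 600))
  # an uncovered DMR cannot be cleared and is dropped with a warning
  expect_warning(
    nocov <- filter_preexisting_chh(
      tibble::tibble(chrom = "chr1", start = 900, end = 1000, contexts = "CHH"),
      baseline, trna),
    "no covered"
  )
  expect_equal(nrow(nocov), 0)
})

test_that("decile ranking balances bins and breaks ties by coordinate", {
  regions <- tibble::tibble(chrom = "chr1", start = seq(0, by = 100,
                                                        length.out = 20),
                            end = seq(50, by = 100, length.out = 20),
                            diff = seq(1, 0.05, length.out = 20))
  d <- rank_deciles(regions)
  expect_equal(unname(table(d$decile)), rep(2L, 10), ignore_attr = TRUE)
  expect_equal(d$diff[d$decile == 1], c(1, 0.95), tolerance = 1e-9)

  r23 <- dplyr::bind_rows(regions, regions[1:3, ] |>
                            dplyr::mutate(start = start + 5000,
                                          end = end + 5000))
  d23 <- rank_deciles(r23)
  expect_equal(unname(table(d23$decile)), c(3L, 3L, 3L, rep(2L, 7)),
               ignore_attr = TRUE)

  ties <- dplyr::mutate(regions, diff = 0.5)
  dt <- rank_deciles(ties)
  expect_equal(dt$start, sort(dt$start))  # coordinate order under ties
  expect_equal(unname(table(dt$decile)), rep(2L, 10), ignore_attr = TRUE)

  # decile means are non-increasing from decile 1 to 10
  withr::with_seed(3, {
    rnd <- dplyr::mutate(regions, diff = runif(20, -0.2, 0.8))
  })
  ds <- decile_summary(rank_deciles(rnd), "diff")
  expect_true(all(diff(ds$diff) <= 1e-12))
  expect_error(rank_deciles(regions[0, ]), "no regions")
})

test_that("heritability follows the 10% CG gain rule", {
  expect_true(classify_heritable(0.35, 0.20))
  expect_false(classify_heritable(0.25, 0.20))
  expect_false(classify_heritable(0.10, 0.20))
  expect_true(classify_heritable(0.30, 0.20))    # exactly 0.10 gain counts
  expect_true(classify_heritable(0.35, 0.20, min_gain = 0.10))
  expect_false(classify_heritable(0.29, 0.20))
  expect_true(is.na(classify_heritable(NA, 0.2)))
})
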