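#' Tile site flanks into candidate DMR windows
#'
#' Each site yields contiguous windows (default 100 bp) tiling the site plus
#' 1-kb flanks on both sides, truncated at chromosome edges. Windows shared
#' verbatim between overlapping sites are emitted once, with back-pointers to
#' every contributing site. Anchoring windows to the binding-site universe —
#' rather than scanning the whole genome — is what makes the DMR test a
#' targeted one.
#'
#' @param sites Interval tibble with a `site_id` column (0-based half-open).
#' @param flank Flank width in bp on each side.
#' @param window Window width in bp.
#' @param chrom_sizes Named vector of chromosome lengths; windows are
#'   truncated to `[0, size)`. Optional (no right truncation when absent).
#' @return List: `windows` (tibble `window_id`, `chrom`, `start`, `end`) and
#'   `window_sites` (tibble `window_id`, `site_id`).
#' @export
window_flanks <- function(sites, flank = 1000, window = 100, chrom_sizes = NULL) {
  if (flank <= 0 || window <= 0) abort("flank and window must be positive")
  sites <- check_intervals(sites, "sites")
  if (!"site_id" %in% names(sites)) sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    s0 <- max(0, sites$start[i] - flank)
    e0 <- sites$end[i] + flank
    if (!is.null(chrom_sizes)) e0 <- min(e0, chrom_sizes[[sites$chrom[i]]])
    if (e0 <= s0) return(NULL)
    starts <- seq(s0, e0 - 1, by = window)
    tibble(chrom = sites$chrom[i], start = starts,
           end = pmin(starts + window, e0), site_id = sites$site_id[i])
  }) |> bind_rows()
  rows$window_id <- sprintf("%s:%d-%d", rows$chrom, rows$start, rows$end)
  windows <- rows |>
    dplyr::distinct(.data$window_id, .data$chrom, .data$start, .data$end) |>
    arrange(.data$chrom, .data$start)
  list(windows = windows,
       window_sites = select(rows, "window_id", "site_id"))
}

#' Test windows for differential methylation
#'
#' For each window and context, methylated and unmethylated counts are pooled
#' per group over the cytosines inside the window. The methylation difference
#' is `ratio_fusion - ratio_control` and the p-value comes from the two-sided
#' conditional exact test on the pooled 2x2 table. Windows with fewer covered
#' cytosines than `min_cytosines` in either group are skipped.
#'
#' @param windows Window tibble from [window_flanks()] (or any intervals with
#'   a `window_id` column).
#' @param meth_fusion,meth_control Cytosine-report tibbles for the two
#'   groups.
#' @param contexts Contexts to test.
#' @param min_cytosines Minimum covered cytosines per group per window.
#' @return Tibble: window coordinates, `context`, pooled counts per group
#'   (`m_fus`, `u_fus`, `m_ctl`, `u_ctl`), covered-cytosine counts, `diff`,
#'   `p_value` and BH `q_value` (within context).
#' @export
test_windows <- function(windows, meth_fusion, meth_control,
                         contexts = c("CG", "CHG", "CHH"), min_cytosines = 4) {
  windows <- check_intervals(windows, "windows")
  if (!"window_id" %in% names(windows)) {
    windows$window_id <- sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)
  }
  fus <- region_methylation(meth_fusion, rename_for_regions(windows), contexts)
  ctl <- region_methylation(meth_control, rename_for_regions(windows), contexts)
  joined <- inner_join(
    select(fus, window_id = "region", "chrom", "start", "end", "context",
           m_fus = "total_methylated", u_fus = "total_unmethylated",
           n_cyt_fus = "n_covered"),
    select(ctl, window_id = "region", "context",
           m_ctl = "total_methylated", u_ctl = "total_unmethylated",
           n_cyt_ctl = "n_covered"),
    by = c("window_id", "context")
  ) |>
    filter(.data$n_cyt_fus >= min_cytosines, .data$n_cyt_ctl >= min_cytosines)
  if (nrow(joined) == 0) {
    return(mutate(joined, diff = numeric(0), p_value = numeric(0),
                  q_value = numeric(0)))
  }
  joined |>
    mutate(
      diff = .data$m_fus / (.data$m_fus + .data$u_fus) -
        .data$m_ctl / (.data$m_ctl + .data$u_ctl),
      p_value = exact_rate_test(.data$m_fus, .data$m_ctl,
                                .data$m_fus + .data$u_fus,
                                .data$m_ctl + .data$u_ctl)
    ) |>
    group_by(.data$context) |>
    mutate(q_value = bh_fdr(.data$p_value)) |>
    ungroup()
}

rename_for_regions <- function(windows) {
  w <- windows
  w$name <- w$window_id
  w
}

#' Call hypermethylated regions from window tests
#'
#' Retains windows whose methylation difference meets the per-context
#' threshold (difference >= threshold, hyper only) at `q < fdr`, then merges
#' retained windows per context when their gap is under `max_gap`. The
#' defaults (CG 0.4, CHG 0.2, CHH 0.1 absolute difference, q < 0.01, >= 4
#' covered cytosines per window per group) realise a stringent calling
#' standard for plant methylomes; all are configurable.
#'
#' @param window_tests Output of [test_windows()].
#' @param thresholds Named per-context minimum methylation differences.
#' @param fdr FDR cut-off (strict `<`).
#' @param max_gap Merge gap in bp (strict `<`).
#' @param hypo Also call hypomethylated regions (difference <= -threshold);
#'   off by default.
#' @return An `rddm_dmr` tibble per context: `chrom`, `start`, `end`,
#'   `contexts`, pooled counts, `diff` (recomputed from pooled counts after
#'   merging) and `min_q` (smallest member q-value).
#' @export
call_hyperdmrs <- function(window_tests,
                           thresholds = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                           fdr = 0.01, max_gap = 200, hypo = FALSE) {
  wt <- as_tibble(window_tests)
  bad <- setdiff(unique(wt$context), names(thresholds))
  if (length(bad) > 0) abort(sprintf("unknown context: %s", paste(bad, collapse = ", ")))
  thr <- thresholds[wt$context]
  keep <- wt$q_value < fdr &
    (wt$diff >= thr | (hypo & wt$diff <= -thr))
  if (!hypo) keep <- keep & wt$diff > 0
  hits <- wt[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  contexts = character(), m_fus = numeric(), u_fus = numeric(),
                  m_ctl = numeric(), u_ctl = numeric(), diff = numeric(),
                  min_q = numeric())
    return(new_tbl_class(out, "rddm_dmr"))
  }
  out <- hits |>
    mutate(contexts = .data$context, neg_log_q = -log10(pmax(.data$q_value, 1e-300))) |>
    group_by(.data$context) |>
    dplyr::group_modify(~ merge_dmrs(.x, max_gap = max_gap)) |>
    ungroup() |>
    select(-"context")
  new_tbl_class(arrange(out, .data$chrom, .data$start), "rddm_dmr")
}

#' Merge DMRs closer than a gap threshold
#'
#' Intervals whose gap is strictly below `max_gap` are unioned. Pooled
#' methylation counts are summed across members so the merged difference is
#' the coverage-weighted recomputation over the union; contributing contexts
#' are unioned. Merging is idempotent and order-independent.
#'
#' @param dmrs DMR tibble with pooled count columns `m_fus`, `u_fus`,
#'   `m_ctl`, `u_ctl` and a `contexts` column.
#' @param max_gap Gap threshold in bp (strict `<`).
#' @return Merged DMR tibble with recomputed `diff` and `min_q`.
#' @export
merge_dmrs <- function(dmrs, max_gap = 200) {
  dmrs <- as_tibble(dmrs)
  if (nrow(dmrs) == 0) return(dmrs)
  if (!"contexts" %in% names(dmrs) && "context" %in% names(dmrs)) {
    dmrs$contexts <- dmrs$context
  }
  if (!"neg_log_q" %in% names(dmrs)) {
    dmrs$neg_log_q <- if ("q_value" %in% names(dmrs)) {
      -log10(pmax(dmrs$q_value, 1e-300))
    } else if ("min_q" %in% names(dmrs)) {
      -log10(pmax(dmrs$min_q, 1e-300))
    } else 0
  }
  sum_cols <- intersect(c("m_fus", "u_fus", "m_ctl", "u_ctl"), names(dmrs))
  merged <- merge_intervals(
    select(dmrs, "chrom", "start", "end", all_of(sum_cols), "contexts"),
    max_gap = max_gap,
    sum_cols = sum_cols,
    collapse_cols = "contexts"
  )
  merged$min_q <- purrr::map_dbl(seq_len(nrow(merged)), function(i) {
    member <- dmrs$chrom == merged$chrom[i] &
      dmrs$start >= merged$start[i] & dmrs$end <= merged$end[i]
    if (!any(member)) return(NA_real_)
    10^(-max(dmrs$neg_log_q[member]))
  })
  if (all(c("m_fus", "u_fus", "m_ctl", "u_ctl") %in% names(merged))) {
    merged <- mutate(
      merged,
      diff = .data$m_fus / pmax(.data$m_fus + .data$u_fus, 1) -
        .data$m_ctl / pmax(.data$m_ctl + .data$u_ctl, 1)
    )
  }
  merged$neg_log_q <- -log10(pmax(merged$min_q, 1e-300))
  merged
}

#' Combine per-context hyperDMR lists into one region set
#'
#' Concatenates the already-merged per-context lists, sorts, and merges
#' regions whose gap is under `max_gap`, recording the union of contributing
#' contexts.
#'
#' @param ... Per-context `rddm_dmr` tibbles (or one list of them).
#' @param max_gap Merge gap in bp (strict `<`).
#' @return A unified `rddm_dmr` tibble.
#' @export
combine_contexts <- function(..., max_gap = 200) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  all <- bind_rows(lapply(parts, as_tibble))
  if (nrow(all) == 0) {
    return(new_tbl_class(tibble(chrom = character(), start = numeric(),
                                end = numeric(), contexts = character()),
                         "rddm_dmr"))
  }
  new_tbl_class(merge_dmrs(all, max_gap = max_gap), "rddm_dmr")
}

#' Filter DMRs with pre-existing CHH methylation or tRNA overlap
#'
#' High-confidence de novo CHH regions require the control background to be
#' essentially unmethylated: DMRs whose control CHH weighted level exceeds
#' `max_baseline`, or that overlap a tRNA interval by at least 1 bp, are
#' dropped. DMRs with no covered control CHH cytosine cannot be cleared and
#' are dropped with a warning.
#'
#' @param dmrs DMR tibble.
#' @param baseline_meth Control-genotype cytosine report.
#' @param trna Interval tibble of tRNA genes (may be empty).
#' @param max_baseline Maximum tolerated control CHH level (strict `>` drops).
#' @return Filtered DMR tibble.
#' @export
filter_preexisting_chh <- function(dmrs, baseline_meth, trna = NULL,
                                   max_baseline = 0.05) {
  dmrs <- as_tibble(dmrs)
  if (nrow(dmrs) == 0) return(dmrs)
  base <- region_methylation(baseline_meth,
                             mutate(dmrs, name = sprintf("d%06d", row_number())),
                             contexts = "CHH")
  lev <- base$level[match(sprintf("d%06d", seq_len(nrow(dmrs))), base$region)]
  undefined <- is.na(lev)
  if (any(undefined)) {
    warn(sprintf("%d DMR(s) had no covered control CHH cytosine; dropped", sum(undefined)))
  }
  drop <- undefined | lev > max_baseline
  if (!is.null(trna) && nrow(trna) > 0) drop <- drop | overlaps_any(dmrs, trna)
  dmrs[!drop, , drop = FALSE]
}

#' Rank regions into deciles of methylation difference
#'
#' Regions are ordered by decreasing difference (ties broken by chromosome
#' then start) and split into `n_bins` near-equal bins; the first `n mod
#' n_bins` bins take the extra region. Decile 1 holds the largest
#' differences.
#'
#' @param regions Region tibble.
#' @param metric Column name holding the difference to rank on.
#' @param n_bins Number of bins (default 10; reduced with a warning when
#'   there are fewer regions than bins).
#' @return `regions` with a `decile` column, ordered by rank, carrying class
#'   `rddm_deciles`.
#' @export
rank_deciles <- function(regions, metric = "diff", n_bins = 10) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) abort("no regions to rank")
  if (!metric %in% names(regions)) abort(sprintf("no column `%s`", metric))
  if (nrow(regions) < n_bins) {
    warn(sprintf("only %d regions; using %d bins", nrow(regions), nrow(regions)))
    n_bins <- nrow(regions)
  }
  ord <- order(-regions[[metric]], regions$chrom, regions$start)
  regions <- regions[ord, ]
  n <- nrow(regions)
  base_size <- n %/% n_bins
  sizes <- rep(base_size, n_bins) + c(rep(1, n %% n_bins), rep(0, n_bins - n %% n_bins))
  regions$decile <- rep(seq_len(n_bins), times = sizes)
  attr(regions, "metric") <- metric
  new_tbl_class(regions, "rddm_deciles")
}

#' Summarise deciles across sample groups
#'
#' Mean of the given columns per decile, e.g. methylation differences of the
#' fusion, segregant and control groups.
#'
#' @param deciled Output of [rank_deciles()].
#' @param cols Columns to average per decile.
#' @return Tibble with one row per decile: `decile`, `n`, and the means.
#' @export
decile_summary <- function(deciled, cols) {
  deciled |>
    as_tibble() |>
    group_by(.data$decile) |>
    summarise(n = dplyr::n(), across(all_of(cols), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
}

#' Classify regions as heritable
#'
#' A region's targeted methylation is heritable when the CG methylation of
#' the transgene-segregated plants exceeds the control level by at least
#' `min_gain` (default 0.10, i.e. a 10 percentage-point CG increase).
#' Regions with an undefined level in either group return `NA` and are
#' excluded from denominators.
#'
#' @param segregant_level,control_level CG methylation levels in \[0, 1\].
#' @param min_gain Minimum retained gain (inclusive `>=`).
#' @return Logical vector (NA when a level is undefined).
#' @export
classify_heritable <- function(segregant_level, control_level, min_gain = 0.10) {
  # small tolerance so a gain of exactly min_gain is never lost to floating
  # point (0.30 - 0.20 < 0.10 in binary arithmetic)
  ifelse(is.na(segregant_level) | is.na(control_level), NA,
         segregant_level - control_level >= min_gain - 1e-9)
}
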