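#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n row_number across all_of first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnbinom rbinom rpois runif rnorm rgamma median p.adjust
#'   setNames sd quantile dhyper
#' @importFrom utils head tail
NULL

# Deterministic per-component sub-stream seed. All simulator components draw
# from their own stream so adding one component never perturbs another.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, nchar(name) > 0)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.double(seed)) * 1000003 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

#' Validate a genomic-interval tibble
#'
#' Intervals are 0-based half-open throughout the package; conversion to and
#' from 1-based formats (GFF3, cytosine reports) happens only at file
#' boundaries.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param arg Name used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
check_intervals <- function(x, arg = "intervals") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)", arg,
                  paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(sprintf("%s: negative start coordinate", arg))
    if (any(x$end <= x$start)) {
      abort(sprintf("%s: intervals must satisfy start < end (0-based half-open)", arg))
    }
  }
  invisible(x)
}

intervals_to_granges <- function(x) {
  check_intervals(x)
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(is.na(strand) | strand == "", "*", strand)
  )
}

# Row indices of `x` intervals overlapping any interval in `y` (>= 1 bp).
overlaps_any <- function(x, y) {
  if (nrow(y) == 0 || nrow(x) == 0) return(logical(nrow(x)))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(x), intervals_to_granges(y))
  seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
}

#' Merge intervals closer than a gap threshold
#'
#' Two intervals on the same chromosome are unioned when the gap between them
#' (`next.start - prev.end`) is strictly less than `max_gap`; touching or
#' overlapping intervals (gap <= 0) always merge. Numeric count columns listed
#' in `sum_cols` are summed across merged members so region-level ratios can
#' be recomputed from pooled counts.
#'
#' @param x Interval tibble (0-based half-open).
#' @param max_gap Gap threshold in bp; strict (`gap < max_gap` merges).
#' @param sum_cols Character vector of columns to sum over merged members.
#' @param collapse_cols Character columns to union (comma-separated, sorted).
#' @return Tibble of merged intervals, sorted by (chrom, start).
#' @export
merge_intervals <- function(x, max_gap = 200, sum_cols = character(),
                            collapse_cols = character()) {
  x <- check_intervals(x)
  if (max_gap < 0) abort("max_gap must be >= 0")
  if (nrow(x) == 0) return(x)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  new_block <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                   x$start[-1] - cummax_by_chrom(x) >= max_gap)
  x$.block <- cumsum(new_block)
  out <- x |>
    group_by(.data$.block) |>
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      across(all_of(sum_cols), sum),
      across(all_of(collapse_cols), ~ paste(sort(unique(unlist(strsplit(.x, ",")))),
                                            collapse = ",")),
      .groups = "drop"
    ) |>
    select(-".block")
  arrange(out, .data$chrom, .data$start)
}

# Running max of `end` within chromosome, lagged by one row (for gap tests
# against everything seen so far, robust to nested intervals).
cummax_by_chrom <- function(x) {
  ends <- numeric(nrow(x) - 1)
  cur_chrom <- x$chrom[1]
  cur_max <- x$end[1]
  for (i in seq_len(nrow(x) - 1)) {
    if (x$chrom[i + 1] != cur_chrom) {
      cur_chrom <- x$chrom[i + 1]
      cur_max <- x$end[i + 1]
    }
    ends[i] <- cur_max
    cur_max <- max(cur_max, x$end[i + 1])
  }
  ends
}

# Counts tibble (feature_id + one column per sample) -> integer matrix.
count_df_to_matrix <- function(counts) {
  counts <- as_tibble(counts)
  if (!"feature_id" %in% names(counts)) {
    abort("count table must have a `feature_id` column")
  }
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$feature_id
  m
}

# Validate a sample->group table and return it with samples in `sample_ids`
# order. Exactly two groups are required for differential testing.
check_samples <- function(samples, sample_ids = NULL) {
  samples <- as_tibble(samples)
  if (!all(c("sample", "group") %in% names(samples))) {
    abort("samples must have columns `sample` and `group`")
  }
  if (anyDuplicated(samples$sample)) abort("duplicate sample ids")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, samples$sample)
    if (length(miss) > 0) {
      abort(sprintf("samples missing group assignment: %s", paste(miss, collapse = ", ")))
    }
    samples <- samples[match(sample_ids, samples$sample), ]
  }
  samples
}

# Apply fold + FDR cut-offs the way the thresholds are worded: fold change
# strictly greater than `min_fold`, FDR strictly below `max_fdr`.
threshold_calls <- function(log2_fc, q_value, min_fold, max_fdr,
                            direction = c("up", "down", "either")) {
  direction <- match.arg(direction)
  lf <- log2(min_fold)
  hit <- switch(direction,
    up = log2_fc > lf,
    down = log2_fc < -lf,
    either = abs(log2_fc) > lf
  )
  hit & !is.na(q_value) & q_value < max_fdr
}

new_tbl_class <- function(x, class) {
  class(x) <- c(class, class(x))
  x
}
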