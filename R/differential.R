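#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over features with
#' positive counts in every sample, of the ratio of each count to the
#' feature's geometric mean across samples. This is the standard
#' count-normalisation used for ChIP, small-RNA and RNA libraries before
#' fold-change computation.
#'
#' @param counts Tibble with a `feature_id` column and one numeric column per
#'   sample, or a numeric matrix with features in rows.
#' @param fallback_total If no feature has all-positive counts, fall back to
#'   total-count (library-size) factors instead of erroring.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' counts <- tibble::tibble(feature_id = c("a", "b"), s1 = c(10, 20), s2 = c(20, 40))
#' size_factors(counts)
#' @export
size_factors <- function(counts, fallback_total = FALSE) {
  m <- if (is.matrix(counts)) counts else count_df_to_matrix(counts)
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    if (fallback_total) {
      tot <- colSums(m)
      return(setNames(tot / exp(mean(log(tot))), colnames(m)))
    }
    abort(paste0("no feature has positive counts in every sample; ",
                 "set fallback_total = TRUE to use library-size factors"))
  }
  lg <- log(m[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  setNames(sf, colnames(m))
}

# Vectorised two-sided conditional exact test on 2x2 tables
# [a, total_a - a; b, total_b - b]. Two-sided p-value sums hypergeometric
# probabilities of all tables (fixed margins) no more likely than the
# observed one, with the usual relative-error guard on ties.
exact_rate_test <- function(a, b, total_a, total_b) {
  stopifnot(length(a) == length(b), length(total_a) %in% c(1, length(a)))
  total_a <- rep_len(total_a, length(a))
  total_b <- rep_len(total_b, length(a))
  if (any(a > total_a | b > total_b)) abort("cell count exceeds its margin")
  p <- numeric(length(a))
  for (i in seq_along(a)) {
    m <- a[i] + b[i]                       # feature margin
    n <- total_a[i] + total_b[i] - m       # remainder margin
    k <- total_a[i]                        # group-A margin
    if (m == 0) { p[i] <- 1; next }
    lo <- max(0L, k - n)
    hi <- min(k, m)
    d <- dhyper(lo:hi, m, n, k)
    d_obs <- dhyper(a[i], m, n, k)
    p[i] <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }
  p
}

#' Two-group differential test for a count matrix
#'
#' For every feature, the two-sided p-value comes from a conditional exact
#' test on the 2x2 table of the feature's pooled raw counts per group against
#' the pooled library remainder per group. The log2 fold change is computed
#' from size-factor-normalised group means with a pseudocount. Benjamini-
#' Hochberg q-values are attached across all features.
#'
#' @param counts Tibble: `feature_id` plus one column per sample.
#' @param samples Tibble with `sample`, `group` columns (exactly two groups).
#' @param group_a,group_b Group labels; fold change is `group_a` over
#'   `group_b`. Default: first and second level in `samples`.
#' @param pseudocount Added to both normalised means before the ratio.
#' @param sf Optional precomputed size factors (named vector).
#' @return A `rddm_diff` tibble: `feature_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `p_value`, `q_value`.
#' @export
differential_test <- function(counts, samples, group_a = NULL, group_b = NULL,
                              pseudocount = 1, sf = NULL) {
  m <- count_df_to_matrix(counts)
  samples <- check_samples(samples, colnames(m))
  groups <- unique(samples$group)
  if (length(groups) != 2) abort("differential_test needs exactly two groups")
  group_a <- group_a %||% groups[1]
  group_b <- group_b %||% groups[2]
  if (!all(c(group_a, group_b) %in% groups)) abort("unknown group label")
  ia <- samples$sample[samples$group == group_a]
  ib <- samples$sample[samples$group == group_b]
  if (length(ia) == 0 || length(ib) == 0) abort("each group needs >= 1 sample")

  sf <- sf %||% size_factors(m, fallback_total = TRUE)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2_fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  raw_a <- rowSums(m[, ia, drop = FALSE])
  raw_b <- rowSums(m[, ib, drop = FALSE])
  p <- exact_rate_test(raw_a, raw_b, sum(raw_a), sum(raw_b))
  zero <- raw_a + raw_b == 0
  p[zero] <- 1
  log2_fc[zero] <- 0

  out <- tibble(
    feature_id = rownames(m),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2_fc = unname(log2_fc), p_value = p,
    q_value = bh_fdr(p)
  )
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "size_factors") <- sf
  new_tbl_class(out, "rddm_diff")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_i` is the minimum over ranks
#' at or above `i` of `m * p_(j) / j`, clipped to 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' @method tidy rddm_diff
#' @export
tidy.rddm_diff <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance rddm_diff
#' @export
glance.rddm_diff <- function(x, fdr = 0.05, ...) {
  g <- attr(x, "groups")
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$q_value < fdr, na.rm = TRUE),
    fdr = fdr,
    group_a = unname(g["a"]),
    group_b = unname(g["b"])
  )
}
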