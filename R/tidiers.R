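#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy rddm_funnel
#' @export
tidy.rddm_funnel <- function(x, ...) {
  select(as_tibble(unclass(x)), -"site_ids")
}

#' @method glance rddm_funnel
#' @export
glance.rddm_funnel <- function(x, ...) {
  tibble(n_levels = nrow(x), n_top = x$n[1], n_bottom = x$n[nrow(x)])
}

#' @method tidy rddm_dmr
#' @export
tidy.rddm_dmr <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance rddm_dmr
#' @export
glance.rddm_dmr <- function(x, ...) {
  tb <- as_tibble(unclass(x))
  tibble(
    n_regions = nrow(tb),
    total_bp = if (nrow(tb)) sum(tb$end - tb$start) else 0,
    mean_diff = if (nrow(tb) && "diff" %in% names(tb)) mean(tb$diff) else NA_real_
  )
}

#' @method tidy rddm_enrichment
#' @export
tidy.rddm_enrichment <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance rddm_enrichment
#' @export
glance.rddm_enrichment <- function(x, ...) {
  tb <- as_tibble(unclass(x))
  peak <- which.max(tb$z)
  tibble(
    n_bins = nrow(tb), n_de = attr(x, "n_de"), n_perm = attr(x, "n_perm"),
    peak_bin_left = if (length(peak)) tb$bin_left[peak] else NA_real_,
    peak_bin_right = if (length(peak)) tb$bin_right[peak] else NA_real_,
    peak_ratio = if (length(peak)) tb$ratio[peak] else NA_real_,
    peak_z = if (length(peak)) tb$z[peak] else NA_real_
  )
}

#' @method tidy rddm_deciles
#' @export
tidy.rddm_deciles <- function(x, ...) {
  as_tibble(unclass(x))
}
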