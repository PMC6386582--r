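#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_ribbon geom_point
#'   geom_hline labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the multilevel targeting funnel
#'
#' @param object An `rddm_funnel`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rddm_funnel
#' @export
autoplot.rddm_funnel <- function(object, ...) {
  tb <- tidy(object)
  tb$flag <- factor(tb$flag, levels = rev(tb$flag))
  ggplot(tb, aes(x = .data$n, y = .data$flag)) +
    geom_col(fill = "steelblue") +
    labs(x = "sites", y = NULL, title = "Targeting funnel") +
    theme_minimal()
}

#' Plot an observed/expected TSS-distance enrichment curve
#'
#' @param object An `rddm_enrichment`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rddm_enrichment
#' @export
autoplot.rddm_enrichment <- function(object, ...) {
  tb <- tidy(object)
  tb$mid <- (tb$bin_left + tb$bin_right) / 2
  ggplot(tb, aes(x = .data$mid, y = .data$ratio)) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "distance to TSS (bp, upstream negative)",
         y = "observed / expected",
         title = "hyperDMR enrichment around TSSs") +
    theme_minimal()
}

#' Plot a signal metaplot profile
#'
#' @param object An `rddm_metaplot`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rddm_metaplot
#' @export
autoplot.rddm_metaplot <- function(object, ...) {
  tb <- object$profile
  ggplot(tb, aes(x = .data$bin, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
                fill = "grey80") +
    geom_line() +
    labs(x = "bin (flank | scaled body | flank)", y = "mean signal") +
    theme_minimal()
}

#' Plot decile means per group
#'
#' @param object An `rddm_deciles` tibble (from [rank_deciles()]).
#' @param cols Columns to summarise per decile.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rddm_deciles
#' @export
autoplot.rddm_deciles <- function(object, cols = "diff", ...) {
  tb <- decile_summary(object, cols) |>
    tidyr::pivot_longer(all_of(cols), names_to = "series", values_to = "value")
  ggplot(tb, aes(x = factor(.data$decile), y = .data$value,
                 group = .data$series, colour = .data$series)) +
    geom_line() + geom_point() +
    labs(x = "decile (1 = largest difference)", y = "mean value") +
    theme_minimal()
}
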