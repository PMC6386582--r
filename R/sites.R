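#' Retain ZF peaks by fold enrichment over control
#'
#' Keeps peaks whose fusion-over-control normalised signal exceeds
#' `min_fold` (strictly), with a pseudocount on both means so that peaks
#' with zero control signal are handled.
#'
#' @param peaks Tibble with `fusion_mean` and `control_mean` columns
#'   (normalised signal).
#' @param min_fold Fold cut-off (strict `>`; default 2).
#' @param pseudocount Added to both means.
#' @return `peaks` with `fold` and `bound` columns.
#' @export
retain_zf_peaks <- function(peaks, min_fold = 2, pseudocount = 1) {
  peaks <- as_tibble(peaks)
  if (!all(c("fusion_mean", "control_mean") %in% names(peaks))) {
    abort("peaks need `fusion_mean` and `control_mean` columns")
  }
  peaks |>
    mutate(fold = (.data$fusion_mean + pseudocount) /
             (.data$control_mean + pseudocount),
           bound = .data$fold > min_fold)
}

#' Classify Pol V recruitment at bound sites
#'
#' The classification is deliberately inverted: a site is called *not*
#' recruited when the ZF-fusion ChIP signal is significantly higher than the
#' Pol V ChIP signal — normalised fold strictly above `min_fold` at
#' `q < fdr` (BH across sites). Every other bound site is considered
#' recruited, reflecting that Pol V follows the fusion to most binding
#' sites.
#'
#' @param fusion_counts,polv_counts Count tibbles (`feature_id` + replicate
#'   columns) over identical site features.
#' @param min_fold Fold cut-off for the *absence* call (strict `>`).
#' @param fdr FDR cut-off (strict `<`).
#' @return Tibble: `site_id`, `log2_fc` (fusion over Pol V), `q_value`,
#'   `polv_recruited`.
#' @export
classify_polv <- function(fusion_counts, polv_counts, min_fold = 4, fdr = 0.05) {
  fusion_counts <- as_tibble(fusion_counts)
  polv_counts <- as_tibble(polv_counts)
  if (!identical(fusion_counts$feature_id, polv_counts$feature_id)) {
    abort("fusion and Pol V counts must cover identical site features")
  }
  fus_samp <- setdiff(names(fusion_counts), "feature_id")
  pv_samp <- setdiff(names(polv_counts), "feature_id")
  if (length(fus_samp) == 0 || length(pv_samp) == 0) {
    abort("each group needs >= 1 sample")
  }
  merged <- inner_join(fusion_counts, polv_counts, by = "feature_id",
                       suffix = c(".fus", ".pv"))
  samp_names <- setdiff(names(merged), "feature_id")
  samples <- tibble(sample = samp_names,
                    group = ifelse(seq_along(samp_names) <= length(fus_samp),
                                   "fusion", "polv"))
  res <- differential_test(merged, samples, group_a = "fusion", group_b = "polv")
  not_recruited <- threshold_calls(res$log2_fc, res$q_value, min_fold, fdr, "up")
  tibble(site_id = res$feature_id, log2_fc = res$log2_fc,
         q_value = res$q_value, polv_recruited = !not_recruited)
}

#' Classify de novo siRNA production per site
#'
#' A site produces 24-nt siRNAs when at least one of its 100-bp bins shows a
#' fusion-over-control fold change strictly above `min_fold` at `q < fdr`,
#' with BH computed jointly across all bins of all sites.
#'
#' @param bin_counts 24-nt bin count tibble (`feature_id` = bin id +
#'   samples).
#' @param samples Sample/group map (groups `fusion`, `control`).
#' @param bin_sites Tibble mapping `window_id` (bin) to `site_id`.
#' @param min_fold Fold cut-off (strict `>`; default 4).
#' @param fdr FDR cut-off (strict `<`; default 0.05).
#' @param min_bins Number of significant bins required per site (default 1).
#' @param site_ids Optional full site universe; sites absent from
#'   `bin_sites` are marked non-producing with a warning.
#' @return Tibble: `site_id`, `n_sig_bins`, `best_log2_fc`,
#'   `sirna_producing`.
#' @export
classify_sirna <- function(bin_counts, samples, bin_sites, min_fold = 4,
                           fdr = 0.05, min_bins = 1, site_ids = NULL) {
  res <- differential_test(bin_counts, samples, group_a = "fusion",
                           group_b = "control")
  res$sig <- threshold_calls(res$log2_fc, res$q_value, min_fold, fdr, "up")
  per_site <- bin_sites |>
    left_join(select(res, window_id = "feature_id", "sig", "log2_fc"),
              by = "window_id") |>
    group_by(.data$site_id) |>
    summarise(n_sig_bins = sum(.data$sig, na.rm = TRUE),
              best_log2_fc = suppressWarnings(max(.data$log2_fc, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(sirna_producing = .data$n_sig_bins >= min_bins,
           best_log2_fc = ifelse(is.finite(.data$best_log2_fc),
                                 .data$best_log2_fc, NA_real_))
  if (!is.null(site_ids)) {
    orphan <- setdiff(site_ids, per_site$site_id)
    if (length(orphan) > 0) {
      warn(sprintf("%d site(s) had no bins; marked non-producing", length(orphan)))
      per_site <- bind_rows(per_site,
                            tibble(site_id = orphan, n_sig_bins = 0L,
                                   best_log2_fc = NA_real_,
                                   sirna_producing = FALSE))
    }
  }
  per_site
}

#' Build the multilevel targeting funnel
#'
#' Level `k` counts the sites satisfying flags 1..k jointly (binding, Pol V
#' recruitment, siRNA production, hypermethylation, proximal repressed
#' gene). Percentages are relative to the previous level. Any ordered flag
#' subset works, e.g. omitting the Pol V level for a Pol IV fusion funnel.
#'
#' @param classifications Tibble with `site_id` and one logical column per
#'   flag.
#' @param levels Ordered character vector of flag column names.
#' @return An `rddm_funnel` tibble: `level`, `flag`, `n`, `pct_of_previous`,
#'   `site_ids` (list-column).
#' @export
build_funnel <- function(classifications,
                         levels = c("bound", "polv_recruited",
                                    "sirna_producing", "hyperdmr",
                                    "repressed_gene")) {
  cl <- as_tibble(classifications)
  miss <- setdiff(levels, names(cl))
  if (length(miss) > 0) abort(sprintf("unknown flag name(s): %s", paste(miss, collapse = ", ")))
  keep <- rep(TRUE, nrow(cl))
  prev_n <- nrow(cl)
  rows <- purrr::map(seq_along(levels), function(k) {
    keep <<- keep & !is.na(cl[[levels[k]]]) & cl[[levels[k]]]
    n <- sum(keep)
    row <- tibble(level = k, flag = levels[k], n = n,
                  pct_of_previous = if (prev_n > 0) 100 * n / prev_n else 0,
                  site_ids = list(cl$site_id[keep]))
    prev_n <<- n
    row
  })
  new_tbl_class(bind_rows(rows), "rddm_funnel")
}

#' Venn region cardinalities for two or three site sets
#'
#' @param a,b,c Vectors of site identifiers (`c` optional).
#' @return Tibble of disjoint region names and counts; counts sum to the
#'   size of the union.
#' @export
venn_regions <- function(a, b, c = NULL) {
  a <- unique(a); b <- unique(b)
  if (is.null(c)) {
    tibble(
      region = c("a_only", "ab", "b_only"),
      n = c(length(setdiff(a, b)), length(intersect(a, b)), length(setdiff(b, a)))
    )
  } else {
    c <- unique(c)
    abc <- intersect(intersect(a, b), c)
    tibble(
      region = c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc"),
      n = c(
        length(setdiff(a, union(b, c))),
        length(setdiff(b, union(a, c))),
        length(setdiff(c, union(a, b))),
        length(setdiff(intersect(a, b), c)),
        length(setdiff(intersect(a, c), b)),
        length(setdiff(intersect(b, c), a)),
        length(abc)
      )
    )
  }
}

#' Aggregate a signal track over scaled intervals
#'
#' Each interval body is scaled to `n_bins` bins flanked by fixed-width
#' flanks split into `flank_bins` bins each; minus-strand intervals are
#' reversed so profiles read 5' to 3'. Returns the per-bin mean and standard
#' error over intervals plus the per-interval matrix for heatmaps.
#'
#' @param track bedGraph-style tibble (`chrom`, `start`, `end`, `score`;
#'   0-based half-open).
#' @param intervals Interval tibble (optional `strand`).
#' @param n_bins Bins across the interval body.
#' @param flank Flank width in bp on each side.
#' @param flank_bins Bins per flank.
#' @return An `rddm_metaplot` list: `profile` (tibble `bin`, `region`,
#'   `mean`, `se`) and `matrix` (intervals x bins).
#' @export
metaplot <- function(track, intervals, n_bins = 20, flank = 1000,
                     flank_bins = 10) {
  track <- check_intervals(track, "track")
  if (!"score" %in% names(track)) abort("track needs a `score` column")
  intervals <- check_intervals(intervals)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", nrow(intervals))
  vecs <- track_to_vectors(track)
  total_bins <- n_bins + 2 * flank_bins
  mat <- matrix(NA_real_, nrow(intervals), total_bins)
  skipped <- 0
  for (i in seq_len(nrow(intervals))) {
    v <- vecs[[intervals$chrom[i]]]
    s <- intervals$start[i]; e <- intervals$end[i]
    if (is.null(v) || s - flank < 0 || e + flank > length(v)) {
      skipped <- skipped + 1
      next
    }
    left <- bin_means(v[(s - flank + 1):s], flank_bins)
    body <- bin_means(v[(s + 1):e], n_bins)
    right <- bin_means(v[(e + 1):(e + flank)], flank_bins)
    prof <- c(left, body, right)
    if (!is.na(strand[i]) && strand[i] == "-") prof <- rev(prof)
    mat[i, ] <- prof
  }
  if (skipped > 0) warn(sprintf("%d interval(s) outside the track; skipped", skipped))
  region <- rep(c("upstream", "body", "downstream"), c(flank_bins, n_bins, flank_bins))
  profile <- tibble(
    bin = seq_len(total_bins),
    region = region,
    mean = apply(mat, 2, mean, na.rm = TRUE),
    se = apply(mat, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
    })
  )
  structure(list(profile = profile, matrix = mat,
                 n_bins = n_bins, flank = flank, flank_bins = flank_bins),
            class = "rddm_metaplot")
}

track_to_vectors <- function(track) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    v <- numeric(max(tr$end))
    for (i in seq_len(nrow(tr))) v[(tr$start[i] + 1):tr$end[i]] <- tr$score[i]
    out[[ch]] <- v
  }
  out
}

# mean signal in k equal partitions of a vector (edges by rounding)
bin_means <- function(v, k) {
  edges <- round(seq(0, length(v), length.out = k + 1))
  vapply(seq_len(k), function(j) {
    if (edges[j + 1] <= edges[j]) return(NA_real_)
    mean(v[(edges[j] + 1):edges[j + 1]])
  }, numeric(1))
}

#' Scan intervals for a motif
#'
#' Both strands are scanned; an interval counts once however many hits it
#' contains. Mismatches are allowed via `max_mismatch`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param intervals Interval tibble (0-based half-open).
#' @param motif Motif string over A/C/G/T.
#' @param max_mismatch Maximum mismatches per hit.
#' @return List: `per_interval` (tibble with `n_hits`, `has_motif`) and
#'   `fraction` (fraction of intervals containing the motif).
#' @export
scan_motif <- function(genome, intervals, motif, max_mismatch = 0) {
  if (is.null(motif) || !nzchar(motif)) abort("motif must be non-empty")
  if (!grepl("^[ACGT]+$", motif)) abort("motif must be over {A, C, G, T}")
  intervals <- check_intervals(intervals)
  pat <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(pat)
  n_hits <- vapply(seq_len(nrow(intervals)), function(i) {
    seqc <- substr(genome[[intervals$chrom[i]]], intervals$start[i] + 1,
                   intervals$end[i])
    subj <- Biostrings::DNAString(seqc)
    length(Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)) +
      length(Biostrings::matchPattern(rc, subj, max.mismatch = max_mismatch))
  }, numeric(1))
  per_interval <- mutate(intervals, n_hits = n_hits, has_motif = n_hits > 0)
  list(per_interval = per_interval, fraction = mean(per_interval$has_motif))
}
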