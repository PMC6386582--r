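#' Reads per kilobase of exon per million aligned reads
#'
#' @param count Reads mapped to the gene.
#' @param exon_length_bp Total exon length in bp (> 0).
#' @param library_size Total aligned reads in the library (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(count, exon_length_bp, library_size) {
  if (any(exon_length_bp <= 0)) abort("exon length must be positive")
  if (any(library_size <= 0)) abort("library size must be positive")
  count / (exon_length_bp / 1000) / (library_size / 1e6)
}

#' Call differentially expressed genes
#'
#' Runs the two-group count test over genes and applies the standard
#' cut-offs: down-regulated when the fusion-over-control fold change is
#' strictly below `1/min_fold` at `q < fdr`; up-regulated symmetrically.
#'
#' @param counts Gene count tibble (`feature_id` + samples).
#' @param samples Sample/group map with groups `fusion` and `control`.
#' @param min_fold Fold-change cut-off (strict; default 2).
#' @param fdr FDR cut-off (strict `<`; default 0.05).
#' @return An `rddm_diff` tibble with added logical `down` and `up` columns.
#' @export
call_de <- function(counts, samples, min_fold = 2, fdr = 0.05) {
  res <- differential_test(counts, samples, group_a = "fusion",
                           group_b = "control")
  res$down <- threshold_calls(res$log2_fc, res$q_value, min_fold, fdr, "down")
  res$up <- threshold_calls(res$log2_fc, res$q_value, min_fold, fdr, "up")
  res
}

#' Signed distance from a region to a gene's TSS
#'
#' Zero when the region overlaps the TSS; otherwise the gap in bp from the
#' nearest region edge to the TSS, negative when the region lies upstream of
#' the TSS in the gene's orientation and positive when downstream.
#'
#' @param start,end Region coordinates (0-based half-open; vectorised).
#' @param tss TSS position (0-based; the strand-aware 5' end of the gene).
#' @param strand Gene strand, `"+"` or `"-"`.
#' @return Signed distance(s) in bp.
#' @export
tss_distance <- function(start, end, tss, strand) {
  n <- max(length(start), length(tss))
  start <- rep_len(start, n); end <- rep_len(end, n)
  tss <- rep_len(tss, n); strand <- rep_len(strand, n)
  # plus-strand convention first: left of the TSS is negative
  gap <- ifelse(tss >= start & tss < end, 0,
                ifelse(end <= tss, -(tss - end), start - tss))
  ifelse(strand == "-", -gap, gap)
}

#' Link DMRs to their nearest gene TSS
#'
#' Each DMR is assigned the gene whose TSS is nearest by absolute signed
#' distance (ties broken towards the smaller gene start coordinate); DMRs
#' farther than `max_distance` stay unassigned. A distance histogram is
#' attached.
#'
#' @param dmrs DMR tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param max_distance Maximum absolute distance for assignment (bp).
#' @param breaks Histogram bin edges over signed distance (default 250-bp
#'   bins spanning +/- 2 kb).
#' @return Tibble: one row per DMR with `gene_id`, `distance` (NA when
#'   unassigned); histogram tibble in attribute `"histogram"`.
#' @export
link_dmrs_to_genes <- function(dmrs, genes, max_distance = 2000,
                               breaks = seq(-2000, 2000, by = 250)) {
  dmrs <- check_intervals(as_tibble(dmrs), "dmrs")
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) abort("empty gene set")
  res <- purrr::map(seq_len(nrow(dmrs)), function(i) {
    g <- genes[genes$chrom == dmrs$chrom[i], ]
    if (nrow(g) == 0) return(tibble(gene_id = NA_character_, distance = NA_real_))
    d <- tss_distance(dmrs$start[i], dmrs$end[i], g$tss, g$strand)
    j <- order(abs(d), g$start)[1]
    if (abs(d[j]) > max_distance) {
      return(tibble(gene_id = NA_character_, distance = NA_real_))
    }
    tibble(gene_id = g$gene_id[j], distance = d[j])
  }) |> bind_rows()
  out <- dplyr::bind_cols(dmrs, res)
  d <- res$distance[!is.na(res$distance)]
  d <- d[d >= min(breaks) & d <= max(breaks)]
  hist_tbl <- tibble(
    bin_left = head(breaks, -1), bin_right = tail(breaks, -1),
    n = as.vector(table(cut(d, breaks = breaks, right = TRUE,
                            include.lowest = FALSE)))
  )
  attr(out, "histogram") <- hist_tbl
  out
}

#' Observed-over-expected TSS-distance enrichment
#'
#' For each signed-distance bin, the observed statistic counts the
#' differentially expressed genes having a hyperDMR whose TSS distance falls
#' in that bin. The expected value is the mean of the same statistic over
#' `n_perm` random draws of equally many genes from the expressed universe
#' (uniform, without replacement). The ratio per bin measures whether DMRs
#' concentrate at particular positions around the TSSs of regulated genes.
#'
#' @param gene_distances Tibble of gene-to-DMR distances (`gene_id`,
#'   `distance`), e.g. built from [link_dmrs_to_genes()] output; a gene may
#'   appear with several DMR distances.
#' @param de_genes Character vector of differentially expressed gene ids
#'   (must be a subset of `expressed_genes`).
#' @param expressed_genes Character vector: the expressed-gene universe.
#' @param breaks Signed-distance bin edges (default 250-bp bins, +/- 2 kb).
#' @param n_perm Number of permutation draws (> 0).
#' @param seed Seed for the permutation draws.
#' @param sample_fun Permutation draw hook: `function(universe, k)` returning
#'   `k` gene ids. Default uniform sampling without replacement; tests can
#'   inject the identity.
#' @return An `rddm_enrichment` tibble: `bin_left`, `bin_right`, `observed`,
#'   `expected`, `ratio` (NA where expected is 0), `perm_sd`.
#' @export
observed_expected <- function(gene_distances, de_genes, expressed_genes,
                              breaks = seq(-2000, 2000, by = 250),
                              n_perm = 1000, seed = 1, sample_fun = NULL) {
  if (n_perm <= 0) abort("n_perm must be positive")
  de_genes <- unique(de_genes)
  expressed_genes <- unique(expressed_genes)
  if (!all(de_genes %in% expressed_genes)) {
    abort("de_genes must be a subset of expressed_genes")
  }
  if (length(de_genes) > length(expressed_genes)) {
    abort("more DE genes than expressed genes")
  }
  gd <- as_tibble(gene_distances) |>
    filter(!is.na(.data$distance))
  bin_of <- function(genes) {
    sub <- gd[gd$gene_id %in% genes, ]
    if (nrow(sub) == 0) return(integer(length(breaks) - 1))
    idx <- findInterval(sub$distance, breaks, left.open = TRUE,
                        rightmost.closed = FALSE)
    ok <- idx >= 1 & idx <= length(breaks) - 1 & sub$distance <= max(breaks)
    counts <- integer(length(breaks) - 1)
    # one count per distinct gene per bin
    pairs <- unique(data.frame(g = sub$gene_id[ok], b = idx[ok]))
    for (b in pairs$b) counts[b] <- counts[b] + 1L
    counts
  }
  observed <- bin_of(de_genes)
  sample_fun <- sample_fun %||% function(universe, k) sample(universe, k)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(.) bin_of(sample_fun(expressed_genes, length(de_genes))),
           numeric(length(breaks) - 1))
  })
  perm <- matrix(perm, nrow = length(breaks) - 1)
  expected <- rowMeans(perm)
  perm_sd <- apply(perm, 1, sd)
  out <- tibble(
    bin_left = head(breaks, -1), bin_right = tail(breaks, -1),
    observed = observed, expected = expected,
    ratio = ifelse(expected > 0, observed / expected, NA_real_),
    perm_sd = perm_sd,
    # permutation z-score: a noise-robust peak statistic (a ratio can be
    # huge in a bin whose expectation is nearly zero)
    z = ifelse(perm_sd > 0, (observed - expected) / perm_sd, NA_real_)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_de") <- length(de_genes)
  new_tbl_class(out, "rddm_enrichment")
}

#' Classify flowering time from leaf counts
#'
#' A plant flowering with 20 or fewer rosette-plus-cauline leaves is early
#' flowering; more than 20 is late.
#'
#' @param leaf_counts Positive integer leaf counts, or a tibble with a
#'   `leaves` column.
#' @param threshold Early/late boundary (early when `leaves <= threshold`).
#' @return Tibble: `leaves`, `flowering` (`"early"`/`"late"`); summary
#'   counts in attribute `"summary"`.
#' @export
classify_flowering <- function(leaf_counts, threshold = 20) {
  if (is.data.frame(leaf_counts)) leaf_counts <- leaf_counts$leaves
  if (length(leaf_counts) == 0) abort("no leaf counts supplied")
  if (any(leaf_counts <= 0 | leaf_counts != round(leaf_counts))) {
    abort("leaf counts must be positive integers")
  }
  out <- tibble(leaves = leaf_counts,
                flowering = ifelse(leaf_counts <= threshold, "early", "late"))
  attr(out, "summary") <- dplyr::count(out, .data$flowering)
  out
}
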