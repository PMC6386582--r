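#' Assign the sequence context of a cytosine
#'
#' Plant methylation is quantified separately in the CG, CHG and CHH contexts
#' (H = A, T or C). The context is read 5'->3' on the cytosine's own strand
#' from the two bases immediately downstream. Positions whose downstream
#' bases run off the chromosome end resolve only when unambiguous (a single
#' downstream G gives CG); otherwise the context is `NA`. A position whose
#' base on the queried strand is not C returns `NA`.
#'
#' @param genome Named character vector of chromosome sequences (A/C/G/T).
#' @param chrom,pos,strand Vectors (recycled): chromosome name, 1-based
#'   position, strand `"+"` or `"-"`.
#' @return Character vector with values `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @examples
#' assign_context(c(chr1 = "ACGT"), "chr1", 2, "+") # "CG"
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    seqc <- genome[[ch]]
    if (is.null(seqc) || is.na(seqc)) abort(sprintf("chromosome %s not in genome", ch))
    bases <- strsplit(toupper(seqc), "")[[1]]
    idx <- which(chrom == ch)
    if (any(pos[idx] < 1 | pos[idx] > length(bases))) {
      abort(sprintf("position outside chromosome %s", ch))
    }
    out[idx] <- context_from_bases(bases, pos[idx], strand[idx])
  }
  out
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

context_from_bases <- function(bases, pos, strand) {
  len <- length(bases)
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    if (strand[i] == "+") {
      if (bases[p] != "C") return(NA_character_)
      d1 <- if (p + 1 <= len) bases[p + 1] else NA
      d2 <- if (p + 2 <= len) bases[p + 2] else NA
    } else {
      if (bases[p] != "G") return(NA_character_)   # C on minus strand
      d1 <- if (p - 1 >= 1) comp_base(bases[p - 1]) else NA
      d2 <- if (p - 2 >= 1) comp_base(bases[p - 2]) else NA
    }
    if (is.na(d1)) return(NA_character_)
    if (d1 == "G") return("CG")
    if (is.na(d2)) return(NA_character_)           # CHG vs CHH unresolvable
    if (d2 == "G") "CHG" else "CHH"
  }, character(1))
}

#' Flag bisulfite reads that failed conversion
#'
#' A read in which bisulfite conversion failed reports every cytosine as
#' methylated, producing long runs of methylated CHH calls — a pattern that
#' is vanishingly rare in genuine plant methylomes. A read is flagged when it
#' carries a run of more than `max_consecutive` methylated CHH calls, counted
#' over the read's CHH calls in order; intervening CG/CHG calls neither break
#' nor extend the run.
#'
#' @param calls Tibble of per-read cytosine calls with columns `read_id`,
#'   `pos`, `context`, `methylated` (logical). Calls are taken in `pos` order
#'   within each read.
#' @param max_consecutive Longest tolerated run (default 3; a run of 4 or
#'   more methylated CHH calls removes the read).
#' @return Tibble with one row per read: `read_id`, `max_chh_run`, `removed`.
#' @export
flag_conversion_failures <- function(calls, max_consecutive = 3) {
  calls <- as_tibble(calls)
  stopifnot(all(c("read_id", "pos", "context", "methylated") %in% names(calls)))
  calls |>
    arrange(.data$read_id, .data$pos) |>
    group_by(.data$read_id) |>
    summarise(max_chh_run = max_run(.data$methylated[.data$context == "CHH"]),
              .groups = "drop") |>
    mutate(removed = .data$max_chh_run > max_consecutive)
}

max_run <- function(x) {
  if (length(x) == 0 || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Remove conversion-failure reads from a call stream
#'
#' @inheritParams flag_conversion_failures
#' @return The retained calls; the number of removed reads is attached as
#'   attribute `"n_removed"`.
#' @export
filter_conversion_failures <- function(calls, max_consecutive = 3) {
  flags <- flag_conversion_failures(calls, max_consecutive)
  bad <- flags$read_id[flags$removed]
  out <- filter(as_tibble(calls), !.data$read_id %in% bad)
  attr(out, "n_removed") <- length(bad)
  out
}

#' Per-cytosine methylation levels
#'
#' The methylation level of a cytosine is `#C / (#C + #T)`, the fraction of
#' reads reporting it methylated. Records below a minimum coverage are
#' flagged `discarded` (amplicon/BS-PCR analyses use `min_coverage = 20`;
#' whole-genome analyses apply no per-cytosine floor, `min_coverage = 0`).
#'
#' @param records Tibble with `count_methylated`, `count_unmethylated`.
#' @param min_coverage Minimum total reads; records with fewer are discarded.
#' @return `records` with added `coverage`, `level` (NA at zero coverage) and
#'   `discarded` columns.
#' @export
cytosine_ratio <- function(records, min_coverage = 0) {
  records <- as_tibble(records)
  stopifnot(all(c("count_methylated", "count_unmethylated") %in% names(records)))
  if (any(records$count_methylated < 0 | records$count_unmethylated < 0)) {
    abort("methylation counts must be non-negative")
  }
  records |>
    mutate(
      coverage = .data$count_methylated + .data$count_unmethylated,
      level = ifelse(.data$coverage > 0, .data$count_methylated / .data$coverage, NA_real_),
      discarded = .data$coverage < min_coverage
    )
}

#' Region-level methylation summaries
#'
#' Coverage-weighted methylation per interval and context: pooled methylated
#' counts over pooled total counts across the covered cytosines inside the
#' interval. Pooling (rather than averaging per-cytosine ratios) matches the
#' pooled-count testing used for DMR calling and is robust at low coverage.
#'
#' @param records Cytosine records (`chrom`, `pos` 1-based, `context`,
#'   `count_methylated`, `count_unmethylated`).
#' @param intervals Interval tibble (0-based half-open); a `name` column, if
#'   present, is carried through as `region`.
#' @param contexts Contexts to summarise.
#' @return Tibble: region, interval, context, `total_methylated`,
#'   `total_unmethylated`, `n_covered` (covered cytosines) and `level`
#'   (NA when no covered cytosine).
#' @export
region_methylation <- function(records, intervals,
                               contexts = c("CG", "CHG", "CHH")) {
  records <- as_tibble(records)
  intervals <- check_intervals(intervals)
  if (!"name" %in% names(intervals)) {
    intervals$name <- sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  }
  records <- filter(records, .data$context %in% contexts)
  grid <- tidyr::expand_grid(region = intervals$name, context = contexts)
  if (nrow(records) == 0 || nrow(intervals) == 0) {
    base <- left_join(grid, select(intervals, region = "name", "chrom", "start", "end"),
                      by = "region")
    return(mutate(base, total_methylated = 0, total_unmethylated = 0,
                  n_covered = 0L, level = NA_real_))
  }
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rec_gr, intervals_to_granges(intervals),
                                ignore.strand = TRUE)
  )
  ov <- records[S4Vectors::queryHits(hits), ]
  ov$region <- intervals$name[S4Vectors::subjectHits(hits)]
  agg <- ov |>
    group_by(.data$region, .data$context) |>
    summarise(
      total_methylated = sum(.data$count_methylated),
      total_unmethylated = sum(.data$count_unmethylated),
      n_covered = sum(.data$count_methylated + .data$count_unmethylated > 0),
      .groups = "drop"
    )
  out <- grid |>
    left_join(agg, by = c("region", "context")) |>
    mutate(across(c("total_methylated", "total_unmethylated"), ~ ifelse(is.na(.x), 0, .x)),
           n_covered = ifelse(is.na(.data$n_covered), 0L, .data$n_covered)) |>
    mutate(level = ifelse(.data$total_methylated + .data$total_unmethylated > 0,
                          .data$total_methylated /
                            (.data$total_methylated + .data$total_unmethylated),
                          NA_real_)) |>
    left_join(select(intervals, region = "name", "chrom", "start", "end"), by = "region")
  select(out, "region", "chrom", "start", "end", "context",
         "total_methylated", "total_unmethylated", "n_covered", "level")
}

#' Combine amplicon region summaries into one level
#'
#' For amplicon (BS-PCR) panels covering several regions of one locus, the
#' per-region methylated and total counts are pooled before the ratio, per
#' context.
#'
#' @param region_summaries Output of [region_methylation()] for the amplicons.
#' @return Tibble with one row per context: pooled counts and pooled `level`
#'   (NA when nothing is covered).
#' @export
combine_bspcr_regions <- function(region_summaries) {
  region_summaries <- as_tibble(region_summaries)
  if (nrow(region_summaries) == 0) abort("need at least one region summary")
  region_summaries |>
    group_by(.data$context) |>
    summarise(
      total_methylated = sum(.data$total_methylated),
      total_unmethylated = sum(.data$total_unmethylated),
      n_covered = sum(.data$n_covered),
      .groups = "drop"
    ) |>
    mutate(level = ifelse(.data$total_methylated + .data$total_unmethylated > 0,
                          .data$total_methylated /
                            (.data$total_methylated + .data$total_unmethylated),
                          NA_real_))
}
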