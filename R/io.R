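#' Read and write FASTA genomes
#'
#' Thin wrappers over Biostrings keeping the package's plain named-character
#' genome representation.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

io_error <- function(path, line, field, msg) {
  abort(sprintf("%s:%d: %s (%s)", path, line, msg, field))
}

#' Read and write BED6 intervals
#'
#' BED coordinates are 0-based half-open, matching the package's internal
#' convention, so values pass through unchanged.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) < 3) abort(sprintf("%s: BED needs at least 3 columns", path))
  names(x)[1:min(6, ncol(x))] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(6, ncol(x))]
  x$start <- suppressWarnings(as.numeric(x$start))
  x$end <- suppressWarnings(as.numeric(x$end))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$start[i]) || is.na(x$end[i])) {
      io_error(path, i, "start/end", "non-numeric coordinate")
    }
    if (x$start[i] < 0) io_error(path, i, "start", "negative coordinate")
    if (x$end[i] <= x$start[i]) io_error(path, i, "end", "end must exceed start")
  }
  if (!"name" %in% names(x)) x$name <- sprintf("%s:%s-%s", x$chrom, x$start, x$end)
  if (!"score" %in% names(x)) x$score <- "0"
  if (!"strand" %in% names(x)) x$strand <- "."
  as_tibble(x[c("chrom", "start", "end", "name", "score", "strand")])
}

#' @rdname read_bed
#' @param intervals Interval tibble (0-based half-open); `name`, `score`,
#'   `strand` optional.
#' @export
write_bed <- function(intervals, path) {
  x <- check_intervals(as_tibble(intervals))
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else
      sprintf("%s:%d-%d", x$chrom, x$start, x$end),
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write gene annotations as GFF3
#'
#' GFF3 is 1-based inclusive on disk; coordinates are converted to the
#' package's 0-based half-open convention on read and back on write.
#'
#' @param path File path.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`
#'   (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  out <- tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,     # 1-based inclusive -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  )
  mutate(out, tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
}

#' @rdname read_gff3
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
write_gff3 <- function(genes, path) {
  genes <- check_intervals(as_tibble(genes), "genes")
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1, genes$end),  # back to 1-based inclusive
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "rddmtarget"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write cytosine reports
#'
#' Cytosine-report TSV: chrom, position (1-based), strand, context,
#' methylated count, unmethylated count.
#'
#' @param path File path.
#' @return Tibble with those six columns.
#' @export
read_cytosine_report <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "pos", "strand", "context",
                                           "count_methylated", "count_unmethylated"),
                       show_col_types = FALSE,
                       col_types = "ciccii")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$pos[i]) || x$pos[i] < 1) io_error(path, i, "pos", "position must be >= 1")
    if (is.na(x$count_methylated[i]) || is.na(x$count_unmethylated[i]) ||
        x$count_methylated[i] < 0 || x$count_unmethylated[i] < 0) {
      io_error(path, i, "counts", "counts must be non-negative integers")
    }
    if (!x$context[i] %in% c("CG", "CHG", "CHH")) {
      io_error(path, i, "context", "context must be CG, CHG or CHH")
    }
  }
  x
}

#' @rdname read_cytosine_report
#' @param records Cytosine-record tibble.
#' @export
write_cytosine_report <- function(records, path) {
  readr::write_tsv(
    select(as_tibble(records), "chrom", "pos", "strand", "context",
           "count_methylated", "count_unmethylated"),
    path, col_names = FALSE)
  invisible(path)
}

#' Read and write count matrices
#'
#' TSV with a `feature_id` column and one column per sample (header row =
#' sample ids).
#'
#' @param path File path.
#' @return Count tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"feature_id" %in% names(x)) {
    abort(sprintf("%s: count matrix needs a `feature_id` header column", path))
  }
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    io_error(path, bad[1, 1] + 1, colnames(m)[bad[1, 2]],
             "counts must be non-negative integers")
  }
  x
}

#' @rdname read_counts
#' @param counts Count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' Read and write bedGraph tracks
#'
#' Four-column bedGraph (chrom, start, end, score), 0-based half-open.
#'
#' @param path File path.
#' @return Track tibble.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                       comment = "#", show_col_types = FALSE,
                       col_types = "cddd")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$start[i]) || x$start[i] < 0) io_error(path, i, "start", "negative coordinate")
    if (is.na(x$end[i]) || x$end[i] <= x$start[i]) io_error(path, i, "end", "end must exceed start")
  }
  x
}

#' @rdname read_bedgraph
#' @param track Track tibble.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(select(as_tibble(track), "chrom", "start", "end", "score"),
                   path, col_names = FALSE)
  invisible(path)
}
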