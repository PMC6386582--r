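#' Simulation configuration
#'
#' Builds the parameter set for the synthetic-data generator. The generator
#' emulates the statistical structure of a zinc-finger (ZF) targeted RdDM
#' experiment: a small multi-chromosome genome carrying planted ZF motif
#' sites of varying accessibility; negative-binomial ChIP counts with
#' site-specific enrichment; 24-nt siRNA counts over 100-bp bins with de novo
#' production planted at a subset of recruited sites; binomial per-cytosine
#' bisulfite counts with context-specific methylation gains planted at a
#' subset of siRNA-producing sites (plus conversion-failure reads); and gene
#' expression counts with repression tied to TSS-proximal planted
#' methylation. Truth labels nest: hypermethylated => siRNA-producing =>
#' Pol V-recruited => bound.
#'
#' @param seed Master seed. Every component draws from its own named
#'   sub-stream derived from this seed.
#' @param n_chromosomes,chromosome_length Genome shape (bp).
#' @param n_sites Number of planted ZF motif sites.
#' @param site_width Width of each planted site interval (bp); the motif is
#'   written at its centre.
#' @param motif ZF recognition motif (A/C/G/T), planted on a random strand.
#' @param frac_bound Fraction of motif sites actually bound by the ZF fusion
#'   (unbound motif sites model inaccessible chromatin).
#' @param frac_polv_recruited Fraction of bound sites recruiting Pol V.
#' @param frac_sirna_producing Fraction of recruited sites producing 24-nt
#'   siRNAs.
#' @param frac_hypermethylated Fraction of producing sites gaining DNA
#'   methylation.
#' @param frac_heritable Fraction of hypermethylated sites whose CG gain is
#'   retained after the transgene segregates away; interleaved evenly across
#'   the planted CG-gain ranking so every decile of gain carries this
#'   fraction.
#' @param chip_enrichment_fold ChIP mean fold enrichment at bound (ZF) and
#'   recruited (Pol V) sites over background.
#' @param chip_background_mean,sirna_background_mean NB background means.
#' @param nb_dispersion Shared NB dispersion for count assays.
#' @param sirna_fold Planted 24-nt siRNA fold gain at producing sites.
#' @param meth_baseline,meth_gain Named proportions per context (CG/CHG/CHH):
#'   background methylation and mean planted gain at hypermethylated sites.
#'   Per-site gains scale with accessibility (0.9-1.3 x the mean; the most
#'   accessible tenth of sites is boosted to 1.5 x so the top gain decile is
#'   a well-separated tier).
#' @param meth_gain_span Methylation/siRNA gain extends this many bp beyond
#'   each site edge.
#' @param coverage_mean Mean bisulfite reads per cytosine (Poisson).
#' @param conversion_failure_rate Fraction of reads that escaped bisulfite
#'   conversion (every cytosine on such a read reads methylated).
#' @param read_length Bisulfite read length for the read-level simulator.
#' @param n_genes,gene_length,exon_length Gene annotation shape.
#' @param expr_base_mean Mean expression count scale.
#' @param repression_fold Expression fold repression of genes with a
#'   hypermethylated site immediately upstream of the TSS.
#' @param repression_window Upstream window (bp) within which a
#'   hypermethylated site represses a gene.
#' @param frac_hyper_with_gene Fraction of hypermethylated sites that get a
#'   gene planted with its TSS 20-180 bp downstream.
#' @param replicates_per_group Library replicates per group for count assays.
#' @param n_plants Plants per genotype for the flowering phenotype.
#' @return A validated `rddm_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 5,
                       chromosome_length = 400000,
                       n_sites = 500,
                       site_width = 200,
                       motif = "GCCGTTGACGTG",
                       frac_bound = 1,
                       frac_polv_recruited = 0.9,
                       frac_sirna_producing = 0.2,
                       frac_hypermethylated = 0.5,
                       frac_heritable = 0.6,
                       chip_enrichment_fold = 8,
                       chip_background_mean = 100,
                       sirna_background_mean = 20,
                       nb_dispersion = 0.01,
                       sirna_fold = 10,
                       meth_baseline = c(CG = 0.05, CHG = 0.03, CHH = 0.02),
                       meth_gain = c(CG = 0.5, CHG = 0.3, CHH = 0.2),
                       meth_gain_span = 150,
                       coverage_mean = 30,
                       conversion_failure_rate = 0.005,
                       read_length = 100,
                       n_genes = 200,
                       gene_length = 1200,
                       exon_length = 1000,
                       expr_base_mean = 200,
                       repression_fold = 4,
                       repression_window = 200,
                       frac_hyper_with_gene = 0.8,
                       replicates_per_group = 3,
                       n_plants = 12) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "rddm_sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_bound", "frac_polv_recruited", "frac_sirna_producing",
             "frac_hypermethylated", "frac_heritable", "conversion_failure_rate",
             "frac_hyper_with_gene")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("%s must be a proportion in [0, 1]", p))
    }
  }
  pos <- c("n_chromosomes", "chromosome_length", "n_sites", "site_width",
           "chip_enrichment_fold", "chip_background_mean", "sirna_background_mean",
           "nb_dispersion", "sirna_fold", "meth_gain_span", "coverage_mean",
           "read_length", "n_genes", "gene_length", "exon_length",
           "expr_base_mean", "replicates_per_group", "n_plants")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) abort(sprintf("%s must be positive", p))
  }
  if (cfg$repression_fold < 1) abort("repression_fold must be >= 1")
  if (!nzchar(cfg$motif) || !grepl("^[ACGT]+$", cfg$motif)) {
    abort("motif must be a non-empty string over {A, C, G, T}")
  }
  if (nchar(cfg$motif) > cfg$chromosome_length) {
    abort("motif longer than chromosome")
  }
  if (nchar(cfg$motif) > cfg$site_width) abort("site_width must cover the motif")
  for (ctx in c("CG", "CHG", "CHH")) {
    if (is.na(cfg$meth_baseline[ctx]) || is.na(cfg$meth_gain[ctx])) {
      abort("meth_baseline and meth_gain need named CG, CHG, CHH entries")
    }
    if (cfg$meth_baseline[[ctx]] < 0 || cfg$meth_baseline[[ctx]] > 1 ||
        cfg$meth_gain[[ctx]] < 0 || cfg$meth_gain[[ctx]] > 1) {
      abort("methylation baselines and gains must be proportions")
    }
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Even interleaving of `k TRUE in n` by Bresenham so any contiguous rank
# window carries close to fraction f of TRUEs.
interleave_flags <- function(n, f) {
  if (n == 0) return(logical(0))
  r <- seq_len(n)
  floor(r * f) > floor((r - 1) * f)
}

#' Simulate a genome with planted ZF sites, genes and truth labels
#'
#' Chromosome sequences are uniform random DNA with the ZF motif written at
#' the centre of each planted site (random strand). Sites are laid out on a
#' jittered grid so that flanking windows of neighbouring sites stay
#' disjoint. Truth flags are drawn to satisfy the nesting hypermethylated =>
#' siRNA-producing => Pol V-recruited => bound; planted per-context gains at
#' hypermethylated sites scale with site accessibility; heritability flags
#' are interleaved evenly across the CG-gain ranking at `frac_heritable`.
#' A fraction of hypermethylated sites get a gene planted with its TSS 20 to
#' 180 bp downstream, so that targeted methylation lands in the promoter;
#' remaining genes fill free genomic space.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character), `chrom_sizes`, `sites`,
#'   `genes`, `truth` (one row per site) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "rddm_sim_config"))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- setNames(rep(config$chromosome_length, length(chroms)), chroms)

  genome <- with_substream(config$seed, "genome", {
    setNames(vapply(chroms, function(.) random_dna(config$chromosome_length),
                    character(1)), chroms)
  })

  sites <- with_substream(config$seed, "sites", {
    place_sites(config, chroms)
  })

  # plant the motif at the centre of each site, random strand
  motif <- config$motif
  for (ch in chroms) {
    idx <- which(sites$chrom == ch)
    if (length(idx) == 0) next
    bases <- strsplit(genome[[ch]], "")[[1]]
    for (i in idx) {
      m0 <- sites$motif_start[i]
      ins <- if (sites$strand[i] == "+") motif else revcomp(motif)
      bases[(m0 + 1):(m0 + nchar(motif))] <- strsplit(ins, "")[[1]]
    }
    genome[[ch]] <- paste(bases, collapse = "")
  }

  truth <- with_substream(config$seed, "labels", {
    draw_truth_labels(sites, config)
  })

  genes <- with_substream(config$seed, "genes", {
    place_genes(truth, config, chrom_sizes)
  })

  truth <- annotate_nearest_gene(truth, genes)

  list(genome = genome, chrom_sizes = chrom_sizes, sites = sites,
       genes = genes, truth = truth, config = config)
}

place_sites <- function(config, chroms) {
  per_chrom <- diff(round(seq(0, config$n_sites, length.out = length(chroms) + 1)))
  rows <- purrr::map2(chroms, per_chrom, function(ch, k) {
    if (k == 0) return(NULL)
    slot <- config$chromosome_length / k
    pad <- config$site_width + 2
    if (slot < pad + 2) abort("too many sites for the chromosome length")
    jitter <- runif(k, 0, slot - pad)
    start <- floor((seq_len(k) - 1) * slot + jitter)
    tibble(chrom = ch, start = start, end = start + config$site_width,
           strand = sample(c("+", "-"), k, replace = TRUE))
  })
  sites <- bind_rows(rows)
  sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
  sites$motif_start <- sites$start +
    floor((config$site_width - nchar(config$motif)) / 2)
  sites$accessibility <- runif(nrow(sites), 0.5, 1.5)
  select(sites, "site_id", "chrom", "start", "end", "strand",
         "motif_start", "accessibility")
}

draw_truth_labels <- function(sites, config) {
  n <- nrow(sites)
  draw <- function(candidates, frac) {
    k <- round(length(candidates) * frac)
    sort(sample(candidates, k))
  }
  bound <- draw(seq_len(n), config$frac_bound)
  polv <- draw(bound, config$frac_polv_recruited)
  sirna <- draw(polv, config$frac_sirna_producing)
  hyper <- draw(sirna, config$frac_hypermethylated)

  truth <- sites |>
    mutate(
      is_bound = row_number() %in% bound,
      is_polv_recruited = row_number() %in% polv,
      is_sirna_producing = row_number() %in% sirna,
      is_hypermethylated = row_number() %in% hyper,
      gain_cg = 0, gain_chg = 0, gain_chh = 0,
      is_heritable = FALSE
    )

  if (length(hyper) > 0) {
    # gains scale with accessibility: 0.9-1.3 x the configured mean gain,
    # with the most accessible tenth of sites boosted to 1.5 x — the top
    # gain decile is a distinctly strongest tier, not a noise ranking
    acc <- truth$accessibility[hyper]
    r <- rank(acc, ties.method = "first")
    mult <- if (length(hyper) == 1) 1 else {
      0.9 + 0.4 * (r - 1) / (length(hyper) - 1)
    }
    if (length(hyper) > 1) {
      mult[r > length(hyper) - ceiling(length(hyper) / 10)] <- 1.5
    }
    truth$gain_cg[hyper] <- config$meth_gain[["CG"]] * mult
    truth$gain_chg[hyper] <- config$meth_gain[["CHG"]] * mult
    truth$gain_chh[hyper] <- config$meth_gain[["CHH"]] * mult
    # heritability interleaved across the CG-gain ranking (largest first)
    ord <- hyper[order(-truth$gain_cg[hyper])]
    truth$is_heritable[ord] <- interleave_flags(length(ord), config$frac_heritable)
  }
  truth
}

place_genes <- function(truth, config, chrom_sizes) {
  glen <- config$gene_length
  anchored <- list()
  hyper <- filter(truth, .data$is_hypermethylated)
  if (nrow(hyper) > 0 && config$frac_hyper_with_gene > 0) {
    pick <- runif(nrow(hyper)) < config$frac_hyper_with_gene
    hh <- hyper[pick, ]
    if (nrow(hh) > 0) {
      d <- floor(runif(nrow(hh), 20, 180))
      strand <- sample(c("+", "-"), nrow(hh), replace = TRUE)
      # TSS placed `d` bp downstream of the site edge, in the gene's own
      # orientation, so the site sits within (-200, 0] upstream of the TSS
      start <- ifelse(strand == "+", hh$end + d, hh$start - d - glen)
      anchored <- tibble(chrom = hh$chrom, start = start, end = start + glen,
                         strand = strand)
      anchored <- filter(anchored, .data$start >= 0,
                         .data$end <= chrom_sizes[.data$chrom])
    }
  }
  anchored <- bind_rows(anchored)

  n_bg <- max(0, config$n_genes - nrow(anchored))
  chroms <- names(chrom_sizes)
  per_chrom <- diff(round(seq(0, n_bg, length.out = length(chroms) + 1)))
  bg <- purrr::map2(chroms, per_chrom, function(ch, k) {
    if (k == 0) return(NULL)
    slot <- chrom_sizes[[ch]] / k
    if (slot < glen + 2) abort("too many genes for the chromosome length")
    start <- floor((seq_len(k) - 1) * slot + slot / 2 +
                     runif(k, 0, max(1, slot / 2 - glen - 1)))
    tibble(chrom = ch, start = start, end = start + glen,
           strand = sample(c("+", "-"), k, replace = TRUE))
  }) |> bind_rows()
  # drop background genes colliding with anchored ones
  if (nrow(anchored) > 0 && nrow(bg) > 0) {
    bg <- bg[!overlaps_any(bg, anchored), ]
  }
  genes <- bind_rows(anchored, bg) |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      gene_id = sprintf("gene_%03d", row_number()),
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
      exon_length = config$exon_length
    )
  select(genes, "gene_id", "chrom", "start", "end", "strand", "tss", "exon_length")
}

annotate_nearest_gene <- function(truth, genes) {
  if (nrow(genes) == 0) {
    truth$nearest_gene_id <- NA_character_
    truth$tss_distance <- NA_real_
    return(truth)
  }
  nn <- purrr::map(seq_len(nrow(truth)), function(i) {
    g <- genes[genes$chrom == truth$chrom[i], ]
    if (nrow(g) == 0) return(list(id = NA_character_, d = NA_real_))
    d <- tss_distance(truth$start[i], truth$end[i], g$tss, g$strand)
    j <- order(abs(d), g$start)[1]
    list(id = g$gene_id[j], d = d[j])
  })
  truth$nearest_gene_id <- purrr::map_chr(nn, "id")
  truth$tss_distance <- purrr::map_dbl(nn, "d")
  truth
}

nb_draws <- function(n, mu, dispersion) {
  if (dispersion <= 0) abort("nb_dispersion must be positive")
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate ChIP count matrices
#'
#' Negative-binomial per-site counts for three antibodies: the ZF fusion
#' (enriched at bound sites, scaled by accessibility), Pol V (enriched at
#' recruited sites) and an input control (background everywhere). Background
#' features (`bg_*`, genomic bins away from any site) are appended so that
#' median-of-ratios normalisation anchors on unenriched regions, as it does
#' genome-wide; without them a fully bound site set would normalise its own
#' enrichment away.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param config A [sim_config()].
#' @param n_background Number of background features appended per antibody.
#' @return List: `counts` (named list of tibbles per antibody: `feature_id` +
#'   replicate columns; site rows first, background rows after), `samples`
#'   (sample/antibody map).
#' @export
simulate_chip_counts <- function(truth, config, n_background = 4 * nrow(truth)) {
  if (config$replicates_per_group < 1) abort("replicates_per_group must be >= 1")
  if (config$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  bg <- config$chip_background_mean
  fold <- config$chip_enrichment_fold
  acc <- truth$accessibility / mean(truth$accessibility)
  bgv <- rep(bg, n_background)
  ids <- c(truth$site_id, sprintf("bg_%04d", seq_len(n_background)))
  mu <- list(
    zf = c(ifelse(truth$is_bound, fold * bg * acc, bg), bgv),
    polv = c(ifelse(truth$is_polv_recruited, fold * bg * acc, bg), bgv),
    input = c(rep(bg, nrow(truth)), bgv)
  )
  reps <- seq_len(config$replicates_per_group)
  counts <- with_substream(config$seed, "chip", {
    purrr::imap(mu, function(m, ab) {
      cols <- lapply(reps, function(.) nb_draws(length(m), m, config$nb_dispersion))
      names(cols) <- sprintf("%s_rep%d", ab, reps)
      tibble(feature_id = ids, !!!cols)
    })
  })
  samples <- tidyr::expand_grid(antibody = names(mu), rep = reps) |>
    mutate(sample = sprintf("%s_rep%d", .data$antibody, .data$rep)) |>
    select("sample", "antibody")
  list(counts = counts, samples = samples)
}

# contexts for every position of one chromosome base vector; NA when the
# position is not a C on that strand or the context is unresolvable
contexts_plus <- function(bases) {
  n <- length(bases)
  d1 <- c(bases[-1], NA)
  d2 <- c(bases[-(1:2)], NA, NA)
  ctx <- rep(NA_character_, n)
  isc <- bases == "C"
  d1g <- !is.na(d1) & d1 == "G"
  d2g <- !is.na(d2) & d2 == "G"
  ctx[isc & d1g] <- "CG"
  ctx[isc & !is.na(d1) & !d1g & d2g] <- "CHG"
  ctx[isc & !is.na(d1) & !d1g & !is.na(d2) & !d2g] <- "CHH"
  ctx
}

contexts_minus <- function(bases) {
  n <- length(bases)
  u1 <- c(NA, bases[-n])
  u2 <- c(NA, NA, bases[-((n - 1):n)])
  ctx <- rep(NA_character_, n)
  isc <- bases == "G"
  u1c <- !is.na(u1) & u1 == "C"
  u2c <- !is.na(u2) & u2 == "C"
  ctx[isc & u1c] <- "CG"
  ctx[isc & !is.na(u1) & !u1c & u2c] <- "CHG"
  ctx[isc & !is.na(u1) & !u1c & !is.na(u2) & !u2c] <- "CHH"
  ctx
}

#' Simulate per-cytosine bisulfite counts
#'
#' Generates cytosine-report tables for three sample groups: `fusion`
#' (transgene present: planted gains at hypermethylated sites), `segregant`
#' (transgene segregated away: CG gain retained only at heritable sites) and
#' `control` (baseline methylation). Per-cytosine coverage is Poisson;
#' methylated counts are Binomial with success probability baseline (+
#' planted gain within `meth_gain_span` of a hypermethylated site), mixed
#' with the conversion-failure rate (failure reads report every cytosine
#' methylated).
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()] (default: the one stored in `sim`).
#' @param regions Interval tibble restricting the report (default: site
#'   intervals padded by 1 kb, merged — the universe the anchored DMR caller
#'   inspects).
#' @param groups Which of the three groups to simulate.
#' @return Named list of cytosine-report tibbles (`chrom`, `pos` 1-based,
#'   `strand`, `context`, `count_methylated`, `count_unmethylated`).
#' @export
simulate_bisulfite <- function(sim, config = sim$config, regions = NULL,
                               groups = c("fusion", "segregant", "control")) {
  for (ctx in c("CG", "CHG", "CHH")) {
    top <- config$meth_baseline[[ctx]] + 1.5 * config$meth_gain[[ctx]]
    if (top > 1) abort(sprintf("baseline + gain exceeds 1 in %s context", ctx))
  }
  if (is.null(regions)) {
    regions <- sim$sites |>
      mutate(start = pmax(0, .data$start - 1000),
             end = pmin(sim$chrom_sizes[.data$chrom], .data$end + 1000)) |>
      merge_intervals(max_gap = 0)
  }
  regions <- check_intervals(regions)
  hyper <- filter(sim$truth, .data$is_hypermethylated)

  per_chrom <- purrr::map(names(sim$genome), function(ch) {
    reg <- filter(regions, .data$chrom == ch)
    if (nrow(reg) == 0) return(NULL)
    bases <- strsplit(sim$genome[[ch]], "")[[1]]
    keep <- logical(length(bases))
    for (i in seq_len(nrow(reg))) keep[(reg$start[i] + 1):reg$end[i]] <- TRUE
    cp <- contexts_plus(bases); cm <- contexts_minus(bases)
    pos_p <- which(keep & !is.na(cp)); pos_m <- which(keep & !is.na(cm))
    tb <- tibble(
      chrom = ch,
      pos = c(pos_p, pos_m),                 # 1-based
      strand = rep(c("+", "-"), c(length(pos_p), length(pos_m))),
      context = c(cp[pos_p], cm[pos_m])
    )
    # planted gain vectors per context
    hh <- filter(hyper, .data$chrom == ch)
    gain <- list(CG = numeric(length(bases)), CHG = numeric(length(bases)),
                 CHH = numeric(length(bases)))
    gain_cg_herit <- numeric(length(bases))
    if (nrow(hh) > 0) {
      for (i in seq_len(nrow(hh))) {
        span <- max(1, hh$start[i] - config$meth_gain_span + 1):
          min(length(bases), hh$end[i] + config$meth_gain_span)
        gain$CG[span] <- hh$gain_cg[i]
        gain$CHG[span] <- hh$gain_chg[i]
        gain$CHH[span] <- hh$gain_chh[i]
        if (hh$is_heritable[i]) gain_cg_herit[span] <- hh$gain_cg[i]
      }
    }
    tb$gain <- ifelse(tb$context == "CG", gain$CG[tb$pos],
                      ifelse(tb$context == "CHG", gain$CHG[tb$pos],
                             gain$CHH[tb$pos]))
    tb$gain_herit <- ifelse(tb$context == "CG", gain_cg_herit[tb$pos], 0)
    tb
  }) |> bind_rows() |> arrange(.data$chrom, .data$pos, .data$strand)

  base_p <- unname(unlist(config$meth_baseline)[per_chrom$context])
  r <- config$conversion_failure_rate
  out <- list()
  for (g in groups) {
    p_true <- switch(g,
      fusion = base_p + per_chrom$gain,
      segregant = base_p + per_chrom$gain_herit,
      control = base_p,
      abort(sprintf("unknown group '%s'", g))
    )
    out[[g]] <- with_substream(config$seed, paste0("bisulfite_", g), {
      cov <- rpois(nrow(per_chrom), config$coverage_mean)
      mC <- rbinom(nrow(per_chrom), cov, r + (1 - r) * p_true)
      tibble(
        chrom = per_chrom$chrom, pos = per_chrom$pos,
        strand = per_chrom$strand, context = per_chrom$context,
        count_methylated = mC, count_unmethylated = cov - mC
      )
    })
  }
  out
}

#' Simulate read-level bisulfite calls over a region
#'
#' Emits individual bisulfite reads with per-cytosine methylation calls,
#' including conversion-failure reads in which every cytosine reads
#' methylated — the pattern the consecutive-CHH read filter removes.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,start,end Region (0-based half-open).
#' @param config A [sim_config()]; supplies read length, coverage,
#'   conversion-failure rate and baseline methylation.
#' @param p_meth Optional named per-context methylation probabilities
#'   overriding `config$meth_baseline`.
#' @return Tibble of calls: `read_id`, `chrom`, `pos` (1-based), `strand`,
#'   `context`, `methylated`, `failure` (read-level flag).
#' @export
simulate_bisulfite_reads <- function(genome, chrom, start, end, config,
                                     p_meth = NULL) {
  p_meth <- p_meth %||% config$meth_baseline
  bases <- strsplit(genome[[chrom]], "")[[1]]
  rl <- min(config$read_length, end - start)
  n_reads <- max(1, round((end - start) * config$coverage_mean / rl))
  cp <- contexts_plus(bases); cm <- contexts_minus(bases)
  with_substream(config$seed, "reads", {
    starts <- floor(runif(n_reads, start, end - rl + 1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    failure <- runif(n_reads) < config$conversion_failure_rate
    purrr::map(seq_len(n_reads), function(i) {
      span <- (starts[i] + 1):(starts[i] + rl)
      ctx <- if (strands[i] == "+") cp[span] else cm[span]
      keep <- !is.na(ctx)
      if (!any(keep)) return(NULL)
      p <- unlist(p_meth)[ctx[keep]]
      tibble(
        read_id = sprintf("read_%05d", i), chrom = chrom,
        pos = span[keep], strand = strands[i], context = ctx[keep],
        methylated = failure[i] | runif(sum(keep)) < p,
        failure = failure[i]
      )
    }) |> bind_rows()
  })
}

#' Simulate small-RNA counts over 100-bp bins
#'
#' 100-bp bins tile each site with 1-kb flanks (shared bins deduplicated).
#' The 24-nt size class carries the planted signal: bins overlapping a
#' producing site (padded by `meth_gain_span`) have `sirna_fold` times the
#' background mean in the fusion group. The 21- and 22-nt classes are
#' background in both groups.
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param bin_width,flank Bin and flank geometry in bp.
#' @return List: `bins`, `bin_sites` (bin -> site back-pointers), `counts`
#'   (tibbles `s24`, `s22`, `s21`), `samples`, and `totals` (per-sample read
#'   totals summed over bins and size classes).
#' @export
simulate_sirna_bins <- function(sim, config = sim$config, bin_width = 100,
                                flank = 1000) {
  if (bin_width <= 0) abort("bin width must be positive")
  if (config$replicates_per_group < 1) abort("replicates_per_group must be >= 1")
  wf <- window_flanks(sim$sites, flank = flank, window = bin_width,
                      chrom_sizes = sim$chrom_sizes)
  bins <- wf$windows
  prod_sites <- sim$truth |>
    filter(.data$is_sirna_producing) |>
    mutate(start = pmax(0, .data$start - config$meth_gain_span),
           end = .data$end + config$meth_gain_span)
  hot <- overlaps_any(bins, prod_sites)
  bg <- config$sirna_background_mean
  reps <- seq_len(config$replicates_per_group)
  mu <- list(
    s24 = list(fusion = ifelse(hot, bg * config$sirna_fold, bg),
               control = rep(bg, nrow(bins))),
    s22 = list(fusion = rep(bg / 4, nrow(bins)), control = rep(bg / 4, nrow(bins))),
    s21 = list(fusion = rep(bg / 4, nrow(bins)), control = rep(bg / 4, nrow(bins)))
  )
  counts <- with_substream(config$seed, "sirna", {
    purrr::map(mu, function(cls) {
      cols <- list()
      for (grp in names(cls)) {
        for (r in reps) {
          cols[[sprintf("%s_rep%d", grp, r)]] <-
            nb_draws(nrow(bins), cls[[grp]], config$nb_dispersion)
        }
      }
      tibble(feature_id = bins$window_id, !!!cols)
    })
  })
  samples <- tidyr::expand_grid(group = c("fusion", "control"), rep = reps) |>
    mutate(sample = sprintf("%s_rep%d", .data$group, .data$rep)) |>
    select("sample", "group")
  totals <- Reduce(`+`, lapply(counts, function(x) colSums(count_df_to_matrix(x))))
  list(bins = bins, bin_sites = wf$window_sites, counts = counts,
       samples = samples, totals = totals)
}

#' Simulate gene expression counts
#'
#' Per-gene negative-binomial counts for fusion and control groups. Genes
#' with a hypermethylated site within `repression_window` bp upstream of
#' their TSS have their fusion-group mean divided by `repression_fold`.
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return List: `counts` (gene x sample tibble), `samples`, `genes` (with
#'   `repressed` truth flag).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  if (config$repression_fold < 1) abort("repression_fold must be >= 1")
  genes <- sim$genes
  if (nrow(genes) == 0) abort("no genes annotated")
  hyper <- filter(sim$truth, .data$is_hypermethylated)
  genes$repressed <- vapply(seq_len(nrow(genes)), function(i) {
    hh <- hyper[hyper$chrom == genes$chrom[i], ]
    if (nrow(hh) == 0) return(FALSE)
    d <- tss_distance(hh$start, hh$end, genes$tss[i], genes$strand[i])
    any(d >= -config$repression_window & d <= 0)
  }, logical(1))
  reps <- seq_len(config$replicates_per_group)
  counts <- with_substream(config$seed, "expression", {
    base <- rgamma(nrow(genes), shape = 2, scale = config$expr_base_mean / 2) + 1
    mu_fus <- ifelse(genes$repressed, base / config$repression_fold, base)
    cols <- list()
    for (r in reps) {
      cols[[sprintf("fusion_rep%d", r)]] <-
        nb_draws(nrow(genes), mu_fus, config$nb_dispersion)
    }
    for (r in reps) {
      cols[[sprintf("control_rep%d", r)]] <-
        nb_draws(nrow(genes), base, config$nb_dispersion)
    }
    tibble(feature_id = genes$gene_id, !!!cols)
  })
  samples <- tidyr::expand_grid(group = c("fusion", "control"), rep = reps) |>
    mutate(sample = sprintf("%s_rep%d", .data$group, .data$rep)) |>
    select("sample", "group")
  list(counts = counts, samples = samples, genes = genes)
}

#' Simulate flowering-time phenotypes
#'
#' Rosette + cauline leaf counts at flowering for three genotypes: wild type
#' (early), the unmethylated epiallele (late) and the ZF-fusion line in that
#' background (methylation restored, early).
#'
#' @param config A [sim_config()].
#' @return Tibble: `plant_id`, `genotype`, `leaves`.
#' @export
simulate_phenotypes <- function(config) {
  n <- config$n_plants
  with_substream(config$seed, "phenotypes", {
    tibble(
      genotype = rep(c("wild_type", "epiallele", "fusion"), each = n),
      leaves = pmax(5, round(c(rnorm(n, 13, 2), rnorm(n, 28, 2.5), rnorm(n, 14, 2))))
    ) |>
      mutate(plant_id = sprintf("%s_%02d", .data$genotype,
                                rep(seq_len(n), times = 3))) |>
      select("plant_id", "genotype", "leaves")
  })
}

#' Simulate a complete targeted-methylation dataset
#'
#' Composes the genome, ChIP, small-RNA, bisulfite, expression and phenotype
#' simulators into one dataset with shared ground truth. Identical seed and
#' configuration reproduce the dataset exactly.
#'
#' @param config A [sim_config()].
#' @return An `rddm_dataset` list: `genome`, `chrom_sizes`, `sites`, `genes`,
#'   `truth`, `chip`, `sirna`, `bisulfite`, `expression`, `phenotypes`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  sim$chip <- simulate_chip_counts(sim$truth, config)
  sim$sirna <- simulate_sirna_bins(sim, config)
  sim$bisulfite <- simulate_bisulfite(sim, config)
  expr <- simulate_expression(sim, config)
  sim$expression <- expr[c("counts", "samples")]
  sim$genes <- expr$genes
  sim$phenotypes <- simulate_phenotypes(config)
  structure(sim, class = "rddm_dataset")
}
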