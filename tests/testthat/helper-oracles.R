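# Independent oracles used across tests. These deliberately avoid the code
# paths they verify.

# Two-sided conditional exact p by explicit enumeration over all tables with
# the observed margins, using binomial coefficients directly.
# Table: rows = groups (totals ta, tb), first column = feature counts (a, b).
oracle_exact_p <- function(a, b, ta, tb) {
  c1 <- a + b
  n <- ta + tb
  xs <- max(0, c1 - tb):min(c1, ta)
  prob <- choose(ta, xs) * choose(tb, c1 - xs) / choose(n, c1)
  p_obs <- choose(ta, a) * choose(tb, c1 - a) / choose(n, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg rejection set by the textbook step-up rule:
# largest k with p_(k) <= k * alpha / m, rejecting all p <= p_(k).
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  ok <- which(s <= seq_len(m) * alpha / m)
  if (length(ok) == 0) return(logical(m))
  p <= s[max(ok)]
}

# Small deterministic cytosine-record table builder.
make_records <- function(chrom, pos, context, m, u, strand = "+") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand, context = context,
                 count_methylated = m, count_unmethylated = u)
}

# Tiny simulation config for fast tests; dots override the small defaults.
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 2, chromosome_length = 60000,
               n_sites = 20, n_genes = 20)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
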