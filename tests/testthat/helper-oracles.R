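# Independent oracles used across the suite. Each re-derives the quantity
# under test by a different route (plain loops, brute-force enumeration,
# closed forms) and must stay independent of the package implementation.

# One-criterion-at-a-time re-evaluation of the somatic filters on a single
# call, returning the set of failed criterion labels.
oracle_failed_criteria <- function(call, criteria) {
  failed <- character()
  alt <- call$tumor_alt_fwd + call$tumor_alt_rev
  tot <- alt + call$tumor_ref_fwd + call$tumor_ref_rev
  if (tot < criteria$min_total_reads) failed <- c(failed, "total_reads")
  vaf <- if (tot > 0) alt / tot else 0
  if (vaf < criteria$min_vaf) failed <- c(failed, "low_vaf")
  if (!is.na(criteria$max_germline_alt_reads) &&
      call$normal_alt > criteria$max_germline_alt_reads) {
    failed <- c(failed, "germline_support")
  }
  if (criteria$require_both_strands &&
      (call$tumor_alt_fwd == 0 || call$tumor_alt_rev == 0)) {
    failed <- c(failed, "single_strand")
  }
  if (criteria$exclude_population_db && isTRUE(call$in_population_db)) {
    failed <- c(failed, "population_db")
  }
  failed
}

# Random well-formed candidate calls covering pass/fail regions.
random_variant_calls <- function(n, seed) {
  set.seed(seed)
  alt_fwd <- sample(0:30, n, replace = TRUE)
  alt_rev <- sample(0:30, n, replace = TRUE)
  normal_total <- sample(10:60, n, replace = TRUE)
  data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
             tumor_alt_fwd = alt_fwd, tumor_alt_rev = alt_rev,
             tumor_ref_fwd = sample(0:80, n, replace = TRUE),
             tumor_ref_rev = sample(0:80, n, replace = TRUE),
             normal_alt = pmin(sample(0:6, n, replace = TRUE), normal_total),
             normal_total = normal_total,
             in_population_db = sample(c(TRUE, FALSE), n, replace = TRUE,
                                       prob = c(0.2, 0.8)),
             consequence = sample(c("nonsynonymous", "synonymous", "other"),
                                  n, replace = TRUE))
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration via
# log-binomial coefficients (no distribution functions).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  obs <- logp[support == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# Brute-force mutant 9-mer windows: every window of the mutated sequence
# that covers position p.
oracle_9mers <- function(protein_seq, p, alt_aa) {
  L <- nchar(protein_seq)
  if (L < 9) return(character())
  mutated <- protein_seq
  substr(mutated, p, p) <- alt_aa
  peps <- character()
  for (s in 1:(L - 8)) {
    if (s <= p && p <= s + 8) peps <- c(peps, substr(mutated, s, s + 8))
  }
  peps
}

# Hand product-limit computation for a small sample (loop form).
oracle_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at) break
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

random_protein <- function(L, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}
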