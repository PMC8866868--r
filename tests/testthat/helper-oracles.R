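# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (enumeration, direct probability sums, breakpoint
# simulation) so they share no code path with the implementation.

# All unordered haplotype-pair genotypes over a haplotype set.
all_genotypes <- function(haps) {
  pairs <- expand.grid(h1 = haps, h2 = haps, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$h1 <= pairs$h2, ]
  paste(pairs$h1, pairs$h2, sep = "-")
}

# Exhaustive biallelic trio cases: every mother x father genotype pair
# over the four haplotypes of a two-SNP biallelic locus, crossed with
# every Mendelian child (one haplotype from each parent, tracked so the
# true paternal haplotype is known to the oracle).
enumerate_trio_cases <- function(snp1 = c("C", "T"), snp2 = c("A", "G")) {
  haps <- as.vector(outer(snp1, snp2, paste0))
  gts <- all_genotypes(haps)
  split_haps <- function(g) strsplit(g, "-", fixed = TRUE)[[1]]
  out <- list()
  for (m in gts) for (f in gts) {
    mh <- split_haps(m); fh <- split_haps(f)
    for (hm in mh) for (hf in fh) {
      out[[length(out) + 1]] <- data.frame(
        mother = m, father = f,
        child = paste(sort(c(hm, hf)), collapse = "-"),
        paternal_hap = hf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Direct informativeness definition: the child's (known) paternal SNP1
# allele is absent from the mother's SNP1 genotype.  Equivalent to
# "mother SNP1-homozygous AND transmitted allele differs" for any
# Mendelian-consistent case.
oracle_informative <- function(mother, paternal_hap) {
  m_snp1 <- substr(strsplit(mother, "-", fixed = TRUE)[[1]], 1, 1)
  !(substr(paternal_hap, 1, 1) %in% m_snp1)
}

# P(locus informative) by summing over every HWE maternal genotype and
# every independently transmitted paternal allele.
oracle_prob_informative <- function(p) {
  alleles <- names(p)
  total <- 0
  for (i in alleles) for (j in alleles) for (b in alleles) {
    prob <- p[[i]] * p[[j]] * p[[b]]
    if (i == j && b != i) total <- total + prob
  }
  total
}

# Poisson-binomial mass by exhaustive enumeration of detection patterns.
oracle_poisbinom <- function(p) {
  n <- length(p)
  mass <- numeric(n + 1)
  for (k in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(n)]
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    mass[sum(bits) + 1] <- mass[sum(bits) + 1] + prob
  }
  mass
}

# Survival of an L bp interval under Poisson breakpoints, estimated by
# dropping break points on long molecules and checking a window.
oracle_breakpoint_survival <- function(amplicon_bp, mean_bp, n_molecules,
                                       molecule_bp = 10000) {
  survived <- logical(n_molecules)
  for (i in seq_len(n_molecules)) {
    n_breaks <- rpois(1, molecule_bp / mean_bp)
    breaks <- runif(n_breaks, 0, molecule_bp)
    start <- runif(1, 0, molecule_bp - amplicon_bp)
    survived[i] <- !any(breaks > start & breaks < start + amplicon_bp)
  }
  mean(survived)
}

# Small two-haplotype frequency table for one locus.
biallelic_freqs <- function(p, locus_id = "L1",
                            haps = c("CA", "TG")) {
  tibble::tibble(locus_id = locus_id, haplotype = haps,
                 freq = c(p, 1 - p))
}
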