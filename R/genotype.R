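# Haplotype-pair genotypes at a SNP-SNP microhaplotype locus.
#
# A genotype is written "CA-TG": two two-base haplotypes separated by "-",
# each haplotype giving the SNP1 base then the SNP2 base.  Genotypes are
# unordered pairs: "CA-TG" and "TG-CA" denote the same diplotype.

#' Split genotype strings into haplotype pairs
#'
#' @param genotype Character vector of `"CA-TG"`-style genotypes.
#' @return A list of length-2 character vectors of haplotypes.
#' @keywords internal
genotype_haplotypes <- function(genotype) {
  parts <- strsplit(genotype, "-", fixed = TRUE)
  bad <- vapply(parts, function(h) {
    length(h) != 2 || any(nchar(h) != 2) ||
      !all(strsplit(paste(h, collapse = ""), "")[[1]] %in% dna_bases)
  }, logical(1))
  if (any(bad)) {
    abort_format(sprintf(
      "malformed genotype(s): %s (expected e.g. \"CA-TG\")",
      paste(unique(genotype[bad]), collapse = ", ")
    ))
  }
  parts
}

#' Canonical form of a haplotype-pair genotype
#'
#' Sorts the two haplotypes so that equal diplotypes map to the same
#' string regardless of haplotype order.
#'
#' @param genotype Character vector of genotypes.
#' @return Character vector of canonicalised genotypes.
#' @examples
#' genotype_canonical(c("TG-CA", "CA-TG"))  # both "CA-TG"
#' @export
genotype_canonical <- function(genotype) {
  vapply(genotype_haplotypes(genotype),
         function(h) paste(sort(h), collapse = "-"), character(1))
}

#' Test equality of unordered genotypes
#'
#' @param a,b Character vectors of genotypes.
#' @return Logical vector.
#' @export
genotype_equal <- function(a, b) {
  genotype_canonical(a) == genotype_canonical(b)
}

#' SNP1 genotype of a SNP-SNP diplotype
#'
#' Extracts the first base of each haplotype — the allele pair seen by the
#' allele-specific ARMS primers, which target SNP1 regardless of the SNP2
#' base.
#'
#' @param genotype Character vector of `"CA-TG"`-style genotypes.
#' @return Character vector of sorted allele pairs, e.g. `"C/T"`.
#' @examples
#' snp1_genotype("CA-TG")  # "C/T"
#' snp1_genotype("TG-CA")  # "C/T" (order-insensitive)
#' snp1_genotype("CA-CA")  # "C/C" (homozygous)
#' @export
snp1_genotype <- function(genotype) {
  vapply(genotype_haplotypes(genotype), function(h) {
    paste(sort(substr(h, 1, 1)), collapse = "/")
  }, character(1))
}

#' SNP1 alleles as a list of character vectors
#' @keywords internal
snp1_alleles_of <- function(genotype) {
  lapply(genotype_haplotypes(genotype), function(h) substr(h, 1, 1))
}

snp1_homozygous <- function(genotype) {
  vapply(snp1_alleles_of(genotype), function(a) a[1] == a[2], logical(1))
}

#' Validate a genotype against a locus's declared alleles
#'
#' @param genotype Character vector of genotypes.
#' @param locus One-row data frame with `snp1_alleles` and `snp2_alleles`
#'   columns in `"C/T"` notation (a panel row).
#' @return Invisibly, `genotype`; errors when a base is outside the
#'   locus's declared alleles.
#' @export
validate_genotype <- function(genotype, locus) {
  a1 <- strsplit(locus$snp1_alleles, "/", fixed = TRUE)[[1]]
  a2 <- strsplit(locus$snp2_alleles, "/", fixed = TRUE)[[1]]
  haps <- genotype_haplotypes(genotype)
  ok <- vapply(haps, function(h) {
    all(substr(h, 1, 1) %in% a1) && all(substr(h, 2, 2) %in% a2)
  }, logical(1))
  if (!all(ok)) {
    abort_validation(sprintf(
      "genotype(s) %s carry alleles outside %s's declared alleles (SNP1 %s, SNP2 %s)",
      paste(unique(genotype[!ok]), collapse = ", "),
      locus$locus_id, locus$snp1_alleles, locus$snp2_alleles
    ))
  }
  invisible(genotype)
}

#' Assemble a genotype string from two haplotypes
#' @keywords internal
make_genotype <- function(hap1, hap2) {
  vapply(seq_along(hap1), function(i) {
    paste(sort(c(hap1[i], hap2[i])), collapse = "-")
  }, character(1))
}
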