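#' Canonical diploid genotype classes
#'
#' The ten unordered diploid genotypes over \{A,C,G,T\}, in the fixed
#' canonical order used throughout the package: the four homozygous classes
#' first, then the six heterozygous classes. All posterior vectors, prior
#' rows and confusion-matrix class axes are indexed in this order.
#'
#' @format Character vector of length 10.
#' @export
GENOTYPES <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")

#' Nucleotide alphabet used for observations (fixed A,C,G,T order)
#' @export
BASES <- c("A", "C", "G", "T")

# 10 x 2 allele matrix, rows aligned with GENOTYPES
.GT_ALLELES <- do.call(rbind, strsplit(GENOTYPES, ""))

#' Genotype class index (1-based) from an unordered allele pair
#'
#' @param a1,a2 Single characters in A,C,G,T (order irrelevant).
#' @return Integer index into [GENOTYPES].
#' @examples
#' genotype_index("C", "A")  # "AC"
#' @export
genotype_index <- function(a1, a2) {
  key <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  idx <- match(key, GENOTYPES)
  if (anyNA(idx)) stop("invalid allele pair: ", key[which(is.na(idx))[1]])
  idx
}

#' Alleles of a genotype class
#' @param k Integer class index (1-based) or genotype string.
#' @return Character vector of length 2.
#' @export
genotype_alleles <- function(k) {
  if (is.character(k)) k <- match(k, GENOTYPES)
  .GT_ALLELES[k, , drop = TRUE]
}

#' Is a genotype class heterozygous?
#' @param k Integer class index (vectorized) or genotype string(s).
#' @return Logical vector.
#' @export
genotype_is_het <- function(k) {
  if (is.character(k)) k <- match(k, GENOTYPES)
  .GT_ALLELES[k, 1] != .GT_ALLELES[k, 2]
}

#' Index of the homozygous class for a reference base
#' @param ref_base Character vector over A,C,G,T.
#' @return Integer vector of class indices (1-based).
#' @export
hom_ref_class <- function(ref_base) {
  idx <- match(ref_base, BASES)
  if (anyNA(idx)) stop("ref_base must be one of A,C,G,T")
  idx # hom classes occupy positions 1..4 in base order
}

# 10 x 4 emission-support matrix: expected allele dosage of base b under
# class k for an error-free read (1 for hom match, 0.5 for het allele, 0).
.GT_DOSAGE <- local({
  m <- matrix(0, 10, 4, dimnames = list(GENOTYPES, BASES))
  for (k in seq_len(10)) {
    al <- .GT_ALLELES[k, ]
    for (b in al) m[k, b] <- m[k, b] + 0.5
  }
  m
})
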