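#' @include genetic-code.R codon-counts.R
NULL

#' Whole-gene GC content
#'
#' G+C fraction over all three codon positions of the counted sense codons.
#' Stop codons are excluded; the single-codon amino acids (Met, Trp)
#' contribute, as this is whole-gene base content, not a synonymous-usage
#' statistic.
#'
#' @param counts Named 64-vector of codon counts (or unnamed in canonical
#'   order).
#' @param code A [GeneticCode-class] object.
#' @return Fraction in \[0, 1\], or `NA` if no sense codons were counted.
#' @export
#' @examples
#' gcContent(c(GGC = 1, GCC = 1))
gcContent <- function(counts, code = standardGeneticCode()) {
  counts <- .asCountVector(counts)
  sense <- senseCodons(code)
  n <- sum(counts[sense])
  if (n == 0) return(NA_real_)
  gcPer <- vapply(strsplit(sense, ""), function(b) sum(b %in% c("G", "C")),
                  numeric(1))
  sum(counts[sense] * gcPer) / (3 * n)
}

#' Positional GC content (GC1, GC2, GC3, GC12)
#'
#' Fraction of sense codons carrying G or C at codon position 1, 2 and 3,
#' computed over all sense codons (no synonymous-only restriction, so GC3
#' and GC3s are distinct statistics). GC12 is the mean of GC1 and GC2.
#'
#' @inheritParams gcContent
#' @return Named numeric `c(GC1, GC2, GC3, GC12)`, `NA` when no codons.
#' @export
#' @examples
#' positionalGc(c(GAT = 2, AGC = 2))
positionalGc <- function(counts, code = standardGeneticCode()) {
  counts <- .asCountVector(counts)
  sense <- senseCodons(code)
  n <- sum(counts[sense])
  if (n == 0)
    return(c(GC1 = NA_real_, GC2 = NA_real_, GC3 = NA_real_, GC12 = NA_real_))
  gk <- vapply(1:3, function(k) {
    isGC <- substr(sense, k, k) %in% c("G", "C")
    sum(counts[sense][isGC]) / n
  }, numeric(1))
  c(GC1 = gk[1], GC2 = gk[2], GC3 = gk[3], GC12 = (gk[1] + gk[2]) / 2)
}

#' Synonymous third-position base frequencies (A3s, T3s, G3s, C3s, GC3s)
#'
#' Computed over the synonymous codons only (codons of multi-codon amino
#' acids; Met, Trp and stops excluded). For base X, the numerator is the
#' count of synonymous codons ending in X and the denominator is the count
#' of synonymous codons whose family offers at least one X-ending synonym
#' (the "family-potential" denominator of CodonW). Because the denominators
#' differ per base, A3s+T3s+G3s+C3s routinely exceeds 1. GC3s instead uses
#' all synonymous codons as denominator.
#'
#' @inheritParams gcContent
#' @return Named numeric `c(A3s, T3s, G3s, C3s, GC3s)`; an entry is `NA`
#'   when its denominator is zero.
#' @export
#' @examples
#' synonymousThirdFreqs(c(TTT = 2, GAA = 1, GAG = 1))
synonymousThirdFreqs <- function(counts, code = standardGeneticCode()) {
  counts <- .asCountVector(counts)
  syn <- synonymousCodons(code)
  synCounts <- counts[syn]
  nSyn <- sum(synCounts)
  out <- c(A3s = NA_real_, T3s = NA_real_, G3s = NA_real_, C3s = NA_real_,
           GC3s = NA_real_)
  if (nSyn == 0) return(out)
  aaOf <- codonToAa(code)[syn]
  third <- substr(syn, 3, 3)
  # amino acids whose family contains at least one X-ending codon
  for (b in .BASES) {
    aaWithB <- unique(aaOf[third == b])
    denom <- sum(synCounts[aaOf %in% aaWithB])
    if (denom > 0)
      out[paste0(b, "3s")] <- sum(synCounts[third == b]) / denom
  }
  out["GC3s"] <- sum(synCounts[third %in% c("G", "C")]) / nSyn
  out
}

.profileNames <- c("T3s", "A3s", "G3s", "C3s", "GC3s", "GC",
                   "GC1", "GC2", "GC3", "GC12")

.compositionFromCounts <- function(counts, code) {
  x3 <- synonymousThirdFreqs(counts, code)
  pg <- positionalGc(counts, code)
  c(x3[c("T3s", "A3s", "G3s", "C3s", "GC3s")],
    GC = gcContent(counts, code),
    pg[c("GC1", "GC2", "GC3", "GC12")])[.profileNames]
}

#' Composition profile of a gene or pooled genome
#'
#' The full index vector T3s, A3s, G3s, C3s, GC3s, GC, GC1, GC2, GC3, GC12
#' for one codon-count vector, or per gene for a [CodonCounts-class] object.
#' Pooled-genome profiles should be computed from [pooledCounts()] (count
#' weighting), not by averaging per-gene profiles; both views are standard
#' and they differ.
#'
#' @param x Named 64 count vector or a [CodonCounts-class] object.
#' @param code A [GeneticCode-class] object.
#' @return For a count vector: named numeric of the 10 indices (`NA` =
#'   undefined). For `CodonCounts`: a data.frame with `gene_id` and one
#'   column per index.
#' @export
#' @examples
#' compositionProfile(c(TTT = 2, TTC = 2, GAA = 1, ATG = 1))
setGeneric("compositionProfile",
           function(x, code = standardGeneticCode())
             standardGeneric("compositionProfile"))

#' @rdname compositionProfile
#' @export
setMethod("compositionProfile", "numeric", function(x, code) {
  .compositionFromCounts(x, code)
})

#' @rdname compositionProfile
#' @export
setMethod("compositionProfile", "CodonCounts", function(x, code) {
  m <- codonCounts(x)
  prof <- t(apply(m, 2, .compositionFromCounts, code = code))
  data.frame(gene_id = colnames(m), prof, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Per-gene index table (composition + ENC)
#'
#' Convenience table combining the composition profile with Wright's ENC and
#' the codon count of every gene; the natural input for ENC-plots, PR2 plots,
#' index correlations and ENC-based gene partitioning.
#'
#' @param x A [CodonCounts-class] object.
#' @param code A [GeneticCode-class] object.
#' @return data.frame with columns `gene_id`, the 10 composition indices,
#'   `ENC` and `n_codons`.
#' @export
indexTable <- function(x, code = standardGeneticCode()) {
  stopifnot(is(x, "CodonCounts"))
  prof <- compositionProfile(x, code)
  m <- codonCounts(x)
  prof$ENC <- apply(m, 2, function(v) enc(v, code))
  prof$n_codons <- colSums(m)
  prof
}
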