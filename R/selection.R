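#' @include indices.R
NULL

#' Partition genes into high- and low-bias sets by ENC
#'
#' Genes are ranked by ENC; the lowest-ENC tail (strongest codon bias, the
#' usual proxy for high expression) forms the high-bias dataset and the
#' highest-ENC tail the low-bias dataset. Each tail holds
#' `floor(fraction * n)` genes (at least 1 when n >= 2). Ties at a cut are
#' broken by gene id, so the partition is stable under input reordering.
#'
#' @param encPerGene Named numeric: gene id -> ENC (`NA` entries dropped).
#' @param fraction Tail fraction, default 0.05; must satisfy
#'   0 < fraction <= 0.5.
#' @return List with `highBias`, `lowBias` (character id vectors, disjoint)
#'   and `fraction`.
#' @export
#' @examples
#' e <- setNames(seq(30, 60, length.out = 100), sprintf("g%03d", 1:100))
#' lengths(partitionByEnc(e)[1:2])
partitionByEnc <- function(encPerGene, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 0.5)
  encPerGene <- encPerGene[!is.na(encPerGene)]
  n <- length(encPerGene)
  if (n < 2) stop("need at least 2 genes with defined ENC")
  m <- max(1L, floor(fraction * n))
  if (2L * m > n) stop("tail fraction too large: tails would overlap")
  ord <- order(encPerGene, names(encPerGene))
  ids <- names(encPerGene)[ord]
  list(highBias = ids[seq_len(m)],
       lowBias = ids[seq.int(n - m + 1L, n)],
       fraction = fraction)
}

#' Determine putative optimal codons from ENC-extreme gene sets
#'
#' For each synonymous codon, RSCU is computed from the pooled counts of the
#' high-bias and of the low-bias dataset, and their difference
#' deltaRSCU = RSCU_high - RSCU_low is tested with a two-sample
#' unequal-variance (Welch) t-test on the per-gene RSCU values (genes
#' lacking the amino-acid family contribute no observation). A codon is
#' flagged optimal when deltaRSCU >= `deltaThreshold` (inclusive) and the
#' two-sided p-value is below `alpha` (raw, no multiplicity correction;
#' p-values are reported so users may apply their own).
#'
#' @param counts A [CodonCounts-class] object covering both datasets.
#' @param partition Output of [partitionByEnc()].
#' @param code A [GeneticCode-class] object.
#' @param deltaThreshold Minimum RSCU difference, default 0.08.
#' @param alpha Significance level, default 0.01.
#' @return data.frame with one row per synonymous codon: `codon` (RNA
#'   spelling), `aa`, `rscuHigh`, `rscuLow`, `deltaRscu`, `pValue`, `nHigh`,
#'   `nLow`, `optimal` (logical; `NA` rows are untestable). The number of
#'   optimal codons is attached as attribute `"nOptimal"`.
#' @export
optimalCodons <- function(counts, partition, code = standardGeneticCode(),
                          deltaThreshold = 0.08, alpha = 0.01) {
  stopifnot(is(counts, "CodonCounts"))
  hi <- partition$highBias
  lo <- partition$lowBias
  if (!length(hi) || !length(lo)) stop("both partition sets must be non-empty")
  missing <- setdiff(c(hi, lo), geneIds(counts))
  if (length(missing))
    stop("partition refers to unknown gene id(s): ",
         paste(head(missing, 5), collapse = ", "))
  m <- codonCounts(counts)
  rscuHi <- rscu(rowSums(m[, hi, drop = FALSE]), code)
  rscuLo <- rscu(rowSums(m[, lo, drop = FALSE]), code)
  perGeneHi <- rscu(counts[, hi], code)
  perGeneLo <- rscu(counts[, lo], code)

  syn <- synonymousCodons(code)
  pVal <- vapply(syn, function(cod) {
    a <- perGeneHi[cod, ]
    b <- perGeneLo[cod, ]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (var(a) == 0 && var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))

  delta <- rscuHi - rscuLo
  optimal <- !is.na(delta) & !is.na(pVal) &
    delta >= deltaThreshold & pVal < alpha & rscuHi > rscuLo
  optimal[is.na(delta) | is.na(pVal)] <- NA
  out <- data.frame(
    codon = toRnaCodon(syn),
    aa = unname(codonToAa(code)[syn]),
    rscuHigh = unname(rscuHi[syn]),
    rscuLow = unname(rscuLo[syn]),
    deltaRscu = unname(delta[syn]),
    pValue = unname(pVal[syn]),
    nHigh = length(hi),
    nLow = length(lo),
    optimal = unname(optimal[syn]),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "nOptimal") <- sum(optimal, na.rm = TRUE)
  out
}

#' Classify codons as high- or low-frequency by RSCU
#'
#' RSCU > 1: the codon is used more than its synonymous average ("high
#' frequency"); RSCU < 1: less ("low frequency"); RSCU = 1: unbiased;
#' undefined RSCU (unused family) stays undefined.
#'
#' @param rscuValues Named numeric of RSCU values, e.g.
#'   `rscu(pooledCounts(x))`.
#' @return data.frame with `codon` (RNA spelling), `rscu` and `class`
#'   (one of `"high"`, `"low"`, `"unbiased"`, `"undefined"`); class counts
#'   attached as attribute `"classCounts"`.
#' @export
frequencyClasses <- function(rscuValues) {
  cls <- ifelse(is.na(rscuValues), "undefined",
         ifelse(rscuValues > 1, "high",
         ifelse(rscuValues < 1, "low", "unbiased")))
  out <- data.frame(codon = toRnaCodon(names(rscuValues)),
                    rscu = unname(rscuValues),
                    class = unname(cls),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "classCounts") <- table(factor(cls,
    levels = c("high", "low", "unbiased", "undefined")))
  out
}
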