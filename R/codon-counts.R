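#' @include genetic-code.R
NULL

#' CodonCounts: per-gene codon count matrix
#'
#' An S4 container (extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#' for in-frame codon counts. Rows are the 64 codons in canonical order
#' ([allCodons()]), columns are genes; the single assay `"counts"` holds
#' non-negative integer tallies. All downstream statistics (composition,
#' RSCU, ENC, PR2, P2, optimal codons) are computed from this one object,
#' either per gene or on the pooled (row-summed) vector.
#'
#' @slot ... see `SummarizedExperiment`; `rowData` carries the amino acid and
#'   degeneracy of each codon.
#'
#' @seealso [countCodons()], [pooledCounts()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("CodonCounts", contains = "SummarizedExperiment")

setValidity("CodonCounts", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  msg <- character(0)
  if (nrow(m) != 64L || !identical(rownames(m), allCodons()))
    msg <- c(msg, "rows must be the 64 codons in canonical order")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "genes must have unique ids (column names)")
  if (length(msg)) msg else TRUE
})

#' Construct a CodonCounts object from a count matrix
#'
#' @param counts Numeric matrix (64 codons x genes) with codon rownames, or a
#'   named 64-vector (treated as a single pooled column).
#' @param code A [GeneticCode-class] object used to annotate rows.
#' @return A [CodonCounts-class] object.
#' @export
#' @examples
#' m <- matrix(0L, 64, 2, dimnames = list(allCodons(), c("g1", "g2")))
#' m[c("ATG", "TTT"), 1] <- c(1L, 3L)
#' cc <- CodonCounts(m)
#' pooledCounts(cc)[c("ATG", "TTT")]
CodonCounts <- function(counts, code = standardGeneticCode()) {
  if (is.null(dim(counts))) {
    counts <- matrix(.asCountVector(counts), ncol = 1,
                     dimnames = list(allCodons(), "pooled"))
  }
  counts <- counts[allCodons(), , drop = FALSE]
  storage.mode(counts) <- "integer"
  aa <- codonToAa(code)[rownames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(aa = unname(aa),
                                   degeneracy = ifelse(aa == "*", 0L,
                                     unname(degeneracy(code)[aa]))))
  new("CodonCounts", se)
}

#' Count in-frame codons of coding sequences
#'
#' Tallies the 64 codons of each CDS, reading the sequence in frame from the
#' first base. A terminal stop codon is by default excluded from the tally
#' (a stop can occur only once per CDS and carries no synonymous-usage
#' information); internal stops, if any survived filtering, are counted and
#' left to downstream exclusion rules.
#'
#' @param records A `DNAStringSet` of CDS (lengths divisible by 3, unique
#'   names), e.g. from [readCdsFasta()].
#' @param code A [GeneticCode-class] object.
#' @param dropTerminalStop Logical; drop the final codon when it is a stop.
#' @return A [CodonCounts-class] object with one column per input sequence.
#' @export
#' @examples
#' x <- Biostrings::DNAStringSet(c(g1 = "ATGTTTTAA", g2 = "ATGGAATAG"))
#' colSums(codonCounts(countCodons(x)))
countCodons <- function(records, code = standardGeneticCode(),
                        dropTerminalStop = TRUE) {
  if (!is(records, "DNAStringSet"))
    records <- Biostrings::DNAStringSet(records)
  w <- Biostrings::width(records)
  if (any(w %% 3L != 0L))
    stop("sequence length not divisible by 3 for: ",
         paste(head(names(records)[w %% 3L != 0L], 5), collapse = ", "))
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must carry unique names (gene ids)")
  m <- t(Biostrings::oligonucleotideFrequency(records, width = 3L, step = 3L))
  m <- m[allCodons(), , drop = FALSE]
  if (dropTerminalStop && length(records)) {
    last <- as.character(Biostrings::subseq(records, start = pmax(w - 2L, 1L),
                                            end = w))
    isStop <- w >= 3L & last %in% stopCodons(code)
    for (j in which(isStop)) m[last[j], j] <- m[last[j], j] - 1L
  }
  colnames(m) <- names(records)
  CodonCounts(m, code = code)
}

#' @describeIn CodonCounts-class the codon x gene count matrix.
#' @param x A `CodonCounts` object.
#' @export
codonCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn CodonCounts-class pooled counts: named 64-vector, the row sums
#'   over genes.
#' @export
pooledCounts <- function(x) rowSums(codonCounts(x))

#' @describeIn CodonCounts-class number of genes.
#' @export
nGenes <- function(x) ncol(x)

#' @describeIn CodonCounts-class total number of counted codons, pooled over
#'   genes.
#' @export
totalCodons <- function(x) sum(codonCounts(x))

#' @describeIn CodonCounts-class gene identifiers.
#' @export
geneIds <- function(x) colnames(x)

setMethod("show", "CodonCounts", function(object) {
  cat("CodonCounts:", nGenes(object), "gene(s),",
      totalCodons(object), "codons counted\n")
})
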