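#' @include utils-codons.R
NULL

#' GeneticCode: synonymous-family view of a codon table
#'
#' An S4 class holding the codon-to-amino-acid map together with the derived
#' structures every codon-usage index needs: the synonymous families (amino
#' acid -> ordered codon set), the degeneracy class of each amino acid
#' (1, 2, 3, 4 or 6 in the standard nuclear code) and the stop codons.
#'
#' In the standard code there are 61 sense codons and 3 stops; methionine and
#' tryptophan are the only single-codon amino acids and are excluded (with
#' the stops) from all synonymous-usage statistics, leaving the familiar 59
#' synonymous codons.
#'
#' @slot codonToAa Named character of length 64 mapping DNA codons to
#'   one-letter amino-acid symbols, with `"*"` for stop.
#' @slot families Named list mapping amino-acid symbol to its codons
#'   (alphabetical order).
#' @slot degeneracy Named integer: family size per amino acid.
#' @slot stopCodons Character vector of stop codons.
#'
#' @seealso [standardGeneticCode()]
#' @export
setClass("GeneticCode",
  representation(
    codonToAa  = "character",
    families   = "list",
    degeneracy = "integer",
    stopCodons = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character(0)
  if (length(object@codonToAa) != 64L ||
      !setequal(names(object@codonToAa), allCodons()))
    msg <- c(msg, "codonToAa must cover exactly the 64 codons")
  sense <- object@codonToAa[object@codonToAa != "*"]
  if (length(sense) != 61L) msg <- c(msg, "expected 61 sense codons")
  if (length(object@stopCodons) != 3L) msg <- c(msg, "expected 3 stop codons")
  deg <- object@degeneracy
  if (sum(deg) != 61L) msg <- c(msg, "family sizes must sum to 61")
  if (!identical(sort(names(deg[deg == 1L])), c("M", "W")))
    msg <- c(msg, "Met and Trp must be the only single-codon amino acids")
  multi <- table(factor(deg[deg > 1L], levels = c(2, 3, 4, 6)))
  if (!identical(as.integer(multi), c(9L, 1L, 5L, 3L)))
    msg <- c(msg, "degeneracy classes must be 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold")
  if (length(msg)) msg else TRUE
})

#' The standard nuclear genetic code
#'
#' Builds a [GeneticCode-class] object from the standard codon table
#' (`Biostrings::GENETIC_CODE`).
#'
#' @return A validated `GeneticCode` object.
#' @export
#' @examples
#' gc <- standardGeneticCode()
#' degeneracy(gc)[c("L", "I", "M")]
standardGeneticCode <- function() {
  tab <- Biostrings::GENETIC_CODE
  tab <- tab[allCodons()]
  sense <- tab[tab != "*"]
  fams <- split(names(sense), sense)
  fams <- lapply(fams, sort)
  new("GeneticCode",
      codonToAa  = tab,
      families   = fams,
      degeneracy = vapply(fams, length, integer(1)),
      stopCodons = names(tab)[tab == "*"])
}

#' @describeIn GeneticCode-class codon -> amino-acid map (named character).
#' @param x,object A `GeneticCode` object.
#' @export
codonToAa <- function(x) x@codonToAa

#' @describeIn GeneticCode-class list of synonymous families.
#' @export
synFamilies <- function(x) x@families

#' @describeIn GeneticCode-class family size per amino acid (named integer).
#' @export
degeneracy <- function(x) x@degeneracy

#' @describeIn GeneticCode-class the stop codons.
#' @export
stopCodons <- function(x) x@stopCodons

#' @describeIn GeneticCode-class the 61 sense codons.
#' @export
senseCodons <- function(x) names(x@codonToAa)[x@codonToAa != "*"]

#' @describeIn GeneticCode-class the 59 codons of multi-codon amino acids
#'   (sense codons minus Met and Trp codons).
#' @export
synonymousCodons <- function(x) {
  aa <- x@codonToAa
  multi <- names(x@degeneracy)[x@degeneracy > 1L]
  names(aa)[aa %in% multi]
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode:", length(senseCodons(object)), "sense codons,",
      length(object@stopCodons), "stops;",
      sum(object@degeneracy > 1L), "multi-codon amino acids (",
      length(synonymousCodons(object)), "synonymous codons )\n")
})
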