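#' @import methods
#' @importFrom stats aov anova cor dist hclust qtukey runif rgamma sd setNames t.test var
#' @importFrom utils write.table head
NULL

.BASES <- c("A", "C", "G", "T")

#' All 64 codons in canonical (alphabetical, DNA) order
#'
#' The fixed codon order used for every 64-long count vector in the package:
#' AAA, AAC, AAG, AAT, ACA, ... TTT. This matches the column order of
#' [Biostrings::oligonucleotideFrequency()] at width 3.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' head(allCodons())
allCodons <- function() {
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Convert codons between DNA and RNA spelling
#'
#' Reports in this package print codons in RNA form (UUU) to match common
#' codon-usage tables, while all internal bookkeeping is in DNA form (TTT).
#'
#' @param x Character vector of codons.
#' @return Character vector with T/U interchanged.
#' @export
#' @examples
#' toRnaCodon("TTT")
#' toDnaCodon("UUU")
toRnaCodon <- function(x) chartr("T", "U", x)

#' @rdname toRnaCodon
#' @export
toDnaCodon <- function(x) chartr("U", "T", x)

# split a DNA string into in-frame codons; length must be a multiple of 3
.codonsOf <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

# coerce a user-supplied 64 count vector into canonical order
.asCountVector <- function(counts) {
  cods <- allCodons()
  if (is.null(names(counts))) {
    if (length(counts) != 64L)
      stop("unnamed count vectors must have length 64 (canonical codon order)")
    names(counts) <- cods
    return(counts)
  }
  names(counts) <- toDnaCodon(toupper(names(counts)))
  bad <- setdiff(names(counts), cods)
  if (length(bad))
    stop("unknown codon name(s): ", paste(head(bad, 5), collapse = ", "))
  out <- setNames(numeric(64), cods)
  out[names(counts)] <- out[names(counts)] + counts
  out
}
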