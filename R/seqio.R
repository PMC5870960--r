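#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA of CDS. Sequences are
#' upper-cased and RNA `U` is mapped to `T`, so both DNA and mRNA spellings
#' are accepted. The gene id is the first whitespace-delimited token of the
#' header; the full header is kept as a description.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by gene id, with the full headers in
#'   `mcols(x)$description`. Order of records is preserved.
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicated gene id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' Write coding sequences to FASTA
#'
#' @param records A `DNAStringSet` with names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCdsFasta <- function(records, path) {
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

#' Validate and filter CDS records
#'
#' Applies the minimal quality rules that make codon counting well defined:
#' length divisible by 3, no ambiguous bases, no internal stop codon, and an
#' optional minimum length. Rejections are logged, never raised.
#'
#' @param records A `DNAStringSet` of CDS.
#' @param code A [GeneticCode-class] object (for stop-codon identity).
#' @param requireTriplet Drop sequences whose length is not a multiple of 3.
#' @param dropAmbiguous Drop sequences containing non-ACGT letters.
#' @param dropInternalStop Drop sequences with a stop codon before the final
#'   codon (checked only on sequences that pass the triplet rule).
#' @param minCodons Minimum length in codons (0 = no minimum).
#' @return A list with elements `records` (the retained `DNAStringSet`) and
#'   `log` (data.frame of columns `reason`, `count`, including a
#'   `"retained"` row). Each sequence is charged to the first rule it fails.
#' @export
#' @examples
#' x <- Biostrings::DNAStringSet(c(a = "ATGTTTTAA", b = "ATGTT",
#'                                 c = "ATGTAATTTTAA"))
#' filterCds(x)$log
filterCds <- function(records, code = standardGeneticCode(),
                      requireTriplet = TRUE, dropAmbiguous = TRUE,
                      dropInternalStop = TRUE, minCodons = 0L) {
  w <- Biostrings::width(records)
  reason <- rep(NA_character_, length(records))

  if (requireTriplet)
    reason[is.na(reason) & w %% 3L != 0L] <- "length not divisible by 3"
  if (dropAmbiguous) {
    freq <- Biostrings::alphabetFrequency(records)
    nonACGT <- rowSums(freq[, setdiff(colnames(freq), .BASES), drop = FALSE])
    reason[is.na(reason) & nonACGT > 0L] <- "ambiguous base"
  }
  if (dropInternalStop) {
    ok <- is.na(reason) & w %% 3L == 0L & w >= 6L
    if (any(ok)) {
      sub <- records[ok]
      cod <- Biostrings::oligonucleotideFrequency(sub, width = 3L, step = 3L)
      nStops <- rowSums(cod[, stopCodons(code), drop = FALSE])
      wl <- Biostrings::width(sub)
      lastStop <- as.character(Biostrings::subseq(sub, wl - 2L, wl)) %in%
        stopCodons(code)
      internal <- nStops - as.integer(lastStop) > 0L
      reason[which(ok)[internal]] <- "internal stop"
    }
  }
  if (minCodons > 0L)
    reason[is.na(reason) & w %/% 3L < minCodons] <-
      sprintf("shorter than %d codons", minCodons)

  keep <- is.na(reason)
  reasons <- reason[!keep]
  log <- data.frame(
    reason = c("retained", sort(unique(reasons))),
    count = c(sum(keep),
              as.integer(table(reasons)[sort(unique(reasons))])),
    stringsAsFactors = FALSE)
  list(records = records[keep], log = log)
}

#' Group gene ids into labelled sets by id pattern
#'
#' A lightweight stand-in for annotation-driven grouping (e.g. assigning
#' genes of an allotetraploid to its At/Dt subgenomes by chromosome prefix):
#' each gene is assigned to every label whose regular expression matches its
#' id; genes matching no rule are collected under `"unassigned"`.
#'
#' @param ids Character vector of gene ids (or a named `DNAStringSet`).
#' @param rules Named character vector: label -> regular expression. Labels
#'   must be unique and must not include `"unassigned"`.
#' @return Named list: label -> character vector of member ids.
#' @export
#' @examples
#' splitByPattern(c("Gh_A01G0001", "Gh_D01G0002"),
#'                c(At = "_A", Dt = "_D"))
splitByPattern <- function(ids, rules = character(0)) {
  if (!is.character(ids)) ids <- names(ids)
  if (anyDuplicated(names(rules)))
    stop("duplicated labels in grouping rules")
  if ("unassigned" %in% names(rules))
    stop("'unassigned' is a reserved label")
  sets <- lapply(rules, function(p) ids[grepl(p, ids)])
  matched <- unique(unlist(sets, use.names = FALSE))
  sets$unassigned <- setdiff(ids, matched)
  sets
}
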