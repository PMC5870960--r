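# Independent brute-force oracles for the codon-usage indices.
#
# Each oracle walks the plain codon table (Biostrings::GENETIC_CODE) with
# explicit loops, recomputing every statistic from its definition. They
# deliberately share no code with the package internals so that agreement is
# a genuine cross-check.

.oracleTab <- Biostrings::GENETIC_CODE

.oracleFamilyOf <- function(codon) {
  aa <- .oracleTab[[codon]]
  names(.oracleTab)[vapply(names(.oracleTab), function(d)
    .oracleTab[[d]] == aa, logical(1))]
}

.oracleSynCodons <- function() {
  out <- character(0)
  for (codon in names(.oracleTab)) {
    aa <- .oracleTab[[codon]]
    if (aa == "*") next
    if (sum(.oracleTab == aa) > 1L) out <- c(out, codon)
  }
  sort(out)
}

oracleRscu <- function(counts) {
  syn <- .oracleSynCodons()
  out <- setNames(rep(NA_real_, length(syn)), syn)
  for (codon in syn) {
    fam <- .oracleFamilyOf(codon)
    total <- 0
    for (d in fam) total <- total + counts[[d]]
    if (total > 0) out[[codon]] <- counts[[codon]] * length(fam) / total
  }
  out
}

oracleEnc <- function(counts) {
  aas <- unique(.oracleTab[.oracleTab != "*"])
  Fv <- numeric(0); kv <- integer(0)
  for (aa in aas) {
    fam <- names(.oracleTab)[.oracleTab == aa]
    if (length(fam) == 1L) next
    n <- 0
    for (d in fam) n <- n + counts[[d]]
    f <- NA_real_
    if (n >= 2) {
      ss <- 0
      for (d in fam) ss <- ss + (counts[[d]] / n)^2
      f <- (n * ss - 1) / (n - 1)
    }
    Fv <- c(Fv, f); kv <- c(kv, length(fam))
  }
  Fbar <- c()
  for (k in c(2, 3, 4, 6)) {
    vals <- Fv[kv == k & !is.na(Fv)]
    Fbar[as.character(k)] <- if (length(vals)) sum(vals) / length(vals)
      else NA_real_
  }
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (any(is.na(Fbar)) || any(Fbar == 0, na.rm = TRUE)) return(NA_real_)
  val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  min(val, 61)
}

oracleX3s <- function(counts) {
  syn <- .oracleSynCodons()
  out <- c(A3s = NA_real_, T3s = NA_real_, G3s = NA_real_, C3s = NA_real_,
           GC3s = NA_real_)
  for (b in c("A", "T", "G", "C")) {
    num <- denom <- 0
    for (codon in syn) {
      famThirds <- substr(.oracleFamilyOf(codon), 3, 3)
      if (b %in% famThirds) denom <- denom + counts[[codon]]
      if (substr(codon, 3, 3) == b) num <- num + counts[[codon]]
    }
    if (denom > 0) out[[paste0(b, "3s")]] <- num / denom
  }
  tot <- gcEnd <- 0
  for (codon in syn) {
    tot <- tot + counts[[codon]]
    if (substr(codon, 3, 3) %in% c("G", "C"))
      gcEnd <- gcEnd + counts[[codon]]
  }
  if (tot > 0) out[["GC3s"]] <- gcEnd / tot
  out
}

oracleGcWhole <- function(counts) {
  gc <- tot <- 0
  for (codon in names(.oracleTab)) {
    if (.oracleTab[[codon]] == "*") next
    n <- counts[[codon]]
    tot <- tot + 3 * n
    for (pos in 1:3)
      if (substr(codon, pos, pos) %in% c("G", "C")) gc <- gc + n
  }
  if (tot == 0) NA_real_ else gc / tot
}

oracleP2 <- function(counts) {
  r <- oracleRscu(counts)
  weak <- c("AA", "AT", "TA", "TT")
  strong <- c("CC", "CG", "GC", "GG")
  wwc <- wwu <- ssc <- ssu <- 0
  for (codon in names(r)) {
    pre <- substr(codon, 1, 2)
    third <- substr(codon, 3, 3)
    if (!(third %in% c("C", "T"))) next
    partner <- paste0(pre, if (third == "C") "T" else "C")
    if (.oracleTab[[partner]] != .oracleTab[[codon]]) next
    if (is.na(r[[codon]])) next
    if (pre %in% weak) {
      if (third == "C") wwc <- wwc + r[[codon]] else wwu <- wwu + r[[codon]]
    } else if (pre %in% strong) {
      if (third == "C") ssc <- ssc + r[[codon]] else ssu <- ssu + r[[codon]]
    }
  }
  denom <- wwc + wwu + ssc + ssu
  list(WWC = wwc, WWU = wwu, SSC = ssc, SSU = ssu,
       P2 = if (denom > 0) (wwc + ssu) / denom else NA_real_)
}

# random small count table over the 64 codons (every family usually present)
randomCountTable <- function(lambda = 20) {
  setNames(rpois(64, lambda), allCodons())
}

# short synthetic DNAStringSet helper
dna <- function(...) {
  v <- c(...)
  Biostrings::DNAStringSet(v)
}
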