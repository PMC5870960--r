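#' @include composition.R
NULL

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU is the observed count of a codon divided by the count expected if
#' all codons of its synonymous family were used equally: for codon c of an
#' amino acid with family size k and family total n, RSCU(c) = count(c) *
#' k / n. RSCU = 1 means unbiased usage; > 1 over-represented; < 1
#' under-represented. Codons of unused families are `NA` (undefined, not
#' zero); Met, Trp and stop codons are excluded.
#'
#' @param x Named 64 count vector, or a [CodonCounts-class] object (per-gene
#'   RSCU matrix; use `rscu(pooledCounts(x))` for the pooled table).
#' @param code A [GeneticCode-class] object.
#' @return For a count vector: named numeric over the 59 synonymous codons.
#'   For `CodonCounts`: a 59 x genes matrix.
#' @export
#' @examples
#' rscu(c(TTT = 3, TTC = 1))[c("TTT", "TTC")]
setGeneric("rscu", function(x, code = standardGeneticCode())
  standardGeneric("rscu"))

#' @rdname rscu
#' @export
setMethod("rscu", "numeric", function(x, code) {
  counts <- .asCountVector(x)
  syn <- synonymousCodons(code)
  aaOf <- codonToAa(code)[syn]
  famTotal <- tapply(counts[syn], aaOf, sum)[aaOf]
  k <- degeneracy(code)[aaOf]
  out <- ifelse(famTotal > 0, counts[syn] * k / famTotal, NA_real_)
  setNames(as.numeric(out), syn)
})

#' @rdname rscu
#' @export
setMethod("rscu", "CodonCounts", function(x, code) {
  apply(codonCounts(x), 2, function(v) rscu(v, code))
})

#' Wright's effective number of codons (ENC)
#'
#' ENC measures how far synonymous codon usage departs from uniformity,
#' ranging from 20 (exactly one codon used per amino acid, maximal bias) to
#' 61 (all synonymous codons used evenly, no bias). For each multi-codon
#' amino-acid family with usage n >= 2 the codon homozygosity is estimated
#' as F = (n * sum(p_i^2) - 1) / (n - 1), with p_i the within-family codon
#' fractions; F is averaged within each degeneracy class k to give Fk, and
#'
#'   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.
#'
#' The six-fold families (Leu, Ser, Arg) are treated as single six-membered
#' families. Families with n < 2 contribute no F; if the three-fold class
#' (Ile) is empty it is imputed as F3 = (F2 + F4)/2, while an empty two-,
#' four- or six-fold class (or a zero class mean) leaves ENC undefined.
#' Finite-sample estimates above 61 are reported as 61.
#'
#' @param x Named 64 count vector, or a [CodonCounts-class] object (per-gene
#'   ENC vector).
#' @param code A [GeneticCode-class] object.
#' @param details Logical; for a count vector, also return the class
#'   homozygosities.
#' @return Numeric ENC in \[20, 61\] (`NA` if undefined); with
#'   `details = TRUE`, a list with `enc`, `classHomozygosity` (named by
#'   degeneracy class), `nMissingFamilies` and, when undefined, `reason`.
#' @export
#' @examples
#' enc(setNames(rep(100, 59), synonymousCodons(standardGeneticCode())))
setGeneric("enc", function(x, code = standardGeneticCode(), details = FALSE)
  standardGeneric("enc"))

#' @rdname enc
#' @export
setMethod("enc", "numeric", function(x, code, details) {
  counts <- .asCountVector(x)
  fams <- synFamilies(code)
  deg <- degeneracy(code)
  multi <- names(deg)[deg > 1L]
  Fvals <- rep(NA_real_, length(multi))
  names(Fvals) <- multi
  for (aa in multi) {
    v <- counts[fams[[aa]]]
    n <- sum(v)
    if (n >= 2) {
      p <- v / n
      Fvals[aa] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  classes <- c(2, 3, 4, 6)
  Fk <- vapply(classes, function(k) {
    f <- Fvals[deg[multi] == k]
    if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  }, numeric(1))
  names(Fk) <- classes
  nMissing <- sum(is.na(Fvals))
  reason <- NULL
  if (is.na(Fk["3"]) && !is.na(Fk["2"]) && !is.na(Fk["4"]))
    Fk["3"] <- (Fk["2"] + Fk["4"]) / 2
  if (anyNA(Fk)) {
    reason <- paste("no usable family in degeneracy class",
                    paste(classes[is.na(Fk)], collapse = ","))
    val <- NA_real_
  } else if (any(Fk == 0)) {
    reason <- "zero class homozygosity"
    val <- NA_real_
  } else {
    val <- 2 + 9 / Fk["2"] + 1 / Fk["3"] + 5 / Fk["4"] + 3 / Fk["6"]
    val <- min(unname(val), 61)
  }
  if (details)
    list(enc = val, classHomozygosity = Fk, nMissingFamilies = nMissing,
         reason = reason)
  else val
})

#' @rdname enc
#' @export
setMethod("enc", "CodonCounts", function(x, code, details) {
  apply(codonCounts(x), 2, function(v) enc(v, code))
})

#' Expected ENC under pure compositional (mutational) bias
#'
#' Wright's null curve for the ENC-plot: the ENC a gene would have if its
#' only source of codon bias were its synonymous third-position G+C content
#' S = GC3s,
#'
#'   ENC_expected(S) = 2 + S + 29 / (S^2 + (1 - S)^2).
#'
#' Genes shaped by mutation alone fall on or near this curve; genes under
#' translational selection fall below it.
#'
#' @param s GC3s value(s) in \[0, 1\].
#' @return Expected ENC value(s).
#' @export
#' @examples
#' expectedEnc(c(0, 0.5, 1))
expectedEnc <- function(s) {
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("GC3s values must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' PR2-bias coordinates
#'
#' Parity Rule 2 states that under strand-symmetric mutation with no
#' selection, A = T and G = C at the third codon position. The PR2-bias plot
#' places each gene at x = G3s/(G3s+C3s), y = A3s/(A3s+T3s); the centre
#' (0.5, 0.5) is the PR2-compliant point, and the direction/size of the
#' deviation separates mutational from selective third-position bias.
#'
#' @param x Named 64 count vector, a [CodonCounts-class] object (per-gene
#'   coordinates), or a profile data.frame/vector containing
#'   `A3s`, `T3s`, `G3s`, `C3s`.
#' @param code A [GeneticCode-class] object.
#' @return For a single profile/count vector: named numeric `c(x, y)`. For
#'   `CodonCounts` or a profile table: data.frame with `gene_id`, `x`, `y`.
#'   A coordinate is `NA` when its pair sum is zero or undefined.
#' @export
#' @examples
#' pr2Point(c(A3s = 0.3, T3s = 0.3, G3s = 0.2, C3s = 0.2))
setGeneric("pr2Point", function(x, code = standardGeneticCode())
  standardGeneric("pr2Point"))

.pr2FromX3s <- function(a, t, g, c) {
  xs <- ifelse(!is.na(g) & !is.na(c) & g + c > 0, g / (g + c), NA_real_)
  ys <- ifelse(!is.na(a) & !is.na(t) & a + t > 0, a / (a + t), NA_real_)
  cbind(x = xs, y = ys)
}

#' @rdname pr2Point
#' @export
setMethod("pr2Point", "numeric", function(x, code) {
  if (all(c("A3s", "T3s", "G3s", "C3s") %in% names(x)))
    p <- x
  else
    p <- synonymousThirdFreqs(x, code)
  drop(.pr2FromX3s(p["A3s"], p["T3s"], p["G3s"], p["C3s"]))
})

#' @rdname pr2Point
#' @export
setMethod("pr2Point", "CodonCounts", function(x, code) {
  pr2Point(compositionProfile(x, code))
})

#' @rdname pr2Point
#' @export
setMethod("pr2Point", "data.frame", function(x, code) {
  m <- .pr2FromX3s(x$A3s, x$T3s, x$G3s, x$C3s)
  data.frame(gene_id = if (!is.null(x$gene_id)) x$gene_id else
               seq_len(nrow(x)),
             x = m[, "x"], y = m[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
})

#' P2 from the four aggregate RSCU sums
#'
#' The P2 translational-selection index from its four aggregate inputs:
#' P2 = (WWC + SSU) / (WWC + WWU + SSC + SSU), i.e. the frequency of the
#' energetically "correct" pyrimidine choice at the third position (C after
#' a weak A/U-A/U doublet, U after a strong C/G-C/G doublet). P2 > 0.5
#' indicates translational selection on codon-anticodon interaction
#' strength.
#'
#' @param wwc,ssu,wwu,ssc Non-negative aggregate RSCU sums.
#' @return P2 fraction in \[0, 1\]; `NA` if the denominator is zero.
#' @export
#' @examples
#' p2FromSums(wwc = 3.28, ssu = 5.30, wwu = 4.94, ssc = 2.40)
p2FromSums <- function(wwc, ssu, wwu, ssc) {
  stopifnot(all(c(wwc, ssu, wwu, ssc) >= 0))
  denom <- wwc + wwu + ssc + ssu
  if (denom <= 0) return(NA_real_)
  (wwc + ssu) / denom
}

# codon pairs eligible for P2: prefixes AA, AT, TA, TT (weak-weak) and
# CC, CG, GC, GG (strong-strong) whose family offers both the C- and the
# T-ending synonym within one amino acid
.p2Pairs <- function(code) {
  weak <- c("AA", "AT", "TA", "TT")
  strong <- c("CC", "CG", "GC", "GG")
  aa <- codonToAa(code)
  pairs <- lapply(c(weak, strong), function(pre) {
    cC <- paste0(pre, "C"); cT <- paste0(pre, "T")
    if (aa[cC] != "*" && aa[cC] == aa[cT])
      data.frame(prefix = pre, codonC = cC, codonT = cT,
                 class = if (pre %in% weak) "WW" else "SS",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, pairs)
}

#' P2 translational-selection index from codon counts
#'
#' Computes the aggregate RSCU sums WWC, WWU, SSC, SSU over the codons
#' starting with AA, AU, UA, UU (weak-weak) or CC, CG, GC, GG
#' (strong-strong) whose family offers both pyrimidine endings, then
#' P2 = (WWC + SSU) / (WWC + WWU + SSC + SSU). One value is conventionally
#' reported per genome or gene set, from pooled counts.
#'
#' @param x Named 64 count vector or a [CodonCounts-class] object (pooled).
#' @param code A [GeneticCode-class] object.
#' @return Named list: `WWC`, `WWU`, `SSC`, `SSU`, `P2` and the data.frame
#'   of `codonPairs` used.
#' @export
setGeneric("p2Index", function(x, code = standardGeneticCode())
  standardGeneric("p2Index"))

#' @rdname p2Index
#' @export
setMethod("p2Index", "numeric", function(x, code) {
  r <- rscu(x, code)
  pairs <- .p2Pairs(code)
  ww <- pairs$class == "WW"
  wwc <- sum(r[pairs$codonC[ww]], na.rm = TRUE)
  wwu <- sum(r[pairs$codonT[ww]], na.rm = TRUE)
  ssc <- sum(r[pairs$codonC[!ww]], na.rm = TRUE)
  ssu <- sum(r[pairs$codonT[!ww]], na.rm = TRUE)
  list(WWC = wwc, WWU = wwu, SSC = ssc, SSU = ssu,
       P2 = p2FromSums(wwc, ssu, wwu, ssc), codonPairs = pairs)
})

#' @rdname p2Index
#' @export
setMethod("p2Index", "CodonCounts", function(x, code) {
  p2Index(pooledCounts(x), code)
})
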