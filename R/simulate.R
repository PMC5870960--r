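#' @include compare.R
NULL

#' SimulationConfig: mutation-selection CDS generator settings
#'
#' Parameters of the synthetic coding-sequence generator. Each gene gets a
#' length in codons; each codon position draws an amino acid, then either
#' (with per-gene probability `selectionStrength`) the family's designated
#' preferred codon is emitted (translational selection) or a family codon is
#' chosen through a third-position mutational process: each family codon is
#' weighted by the `mutationThirdBaseProbs` probability of its third base,
#' renormalised within the family, so uniform third-base probabilities give
#' uniform within-family usage. An ATG start and a uniformly chosen stop codon flank the
#' body (both excluded from analysis downstream). The generator produces
#' equilibrium snapshots, not evolutionary trajectories.
#'
#' @slot nGenes Number of genes.
#' @slot lengthMean Mean body length in codons (start/stop excluded).
#' @slot lengthCv Coefficient of variation of gene length (gamma-distributed
#'   lengths, floored at 10 codons); 0 = constant length.
#' @slot aaFrequencies Named amino-acid probabilities (multi-codon amino
#'   acids), normalised.
#' @slot mutationThirdBaseProbs Named probabilities over A, C, G, T at
#'   synonymous third positions, normalised.
#' @slot preferredCodons Named character: one designated codon per
#'   multi-codon amino acid.
#' @slot selectionStrength Per-gene selection probability in \[0, 1\]
#'   (recycled to `nGenes`).
#' @slot seed Integer RNG seed; identical configs give identical output.
#'
#' @seealso [simulationConfig()], [generateCdsSet()]
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    lengthMean = "numeric",
    lengthCv = "numeric",
    aaFrequencies = "numeric",
    mutationThirdBaseProbs = "numeric",
    preferredCodons = "character",
    selectionStrength = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  code <- standardGeneticCode()
  multi <- names(degeneracy(code))[degeneracy(code) > 1L]
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@lengthMean < 10) msg <- c(msg, "lengthMean must be >= 10 codons")
  if (object@lengthCv < 0) msg <- c(msg, "lengthCv must be >= 0")
  if (!setequal(names(object@aaFrequencies), multi) ||
      any(object@aaFrequencies < 0) || sum(object@aaFrequencies) <= 0)
    msg <- c(msg, "aaFrequencies must be non-negative over the 18 multi-codon amino acids")
  if (!setequal(names(object@mutationThirdBaseProbs), .BASES) ||
      any(object@mutationThirdBaseProbs < 0) ||
      abs(sum(object@mutationThirdBaseProbs) - 1) > 1e-8)
    msg <- c(msg, "mutationThirdBaseProbs must be probabilities over A, C, G, T summing to 1")
  pc <- object@preferredCodons
  if (!setequal(names(pc), multi))
    msg <- c(msg, "preferredCodons must name exactly one codon per multi-codon amino acid")
  else if (any(vapply(names(pc), function(a)
      !(pc[[a]] %in% synFamilies(code)[[a]]), logical(1))))
    msg <- c(msg, "each preferred codon must belong to its amino acid's family")
  if (any(object@selectionStrength < 0 | object@selectionStrength > 1))
    msg <- c(msg, "selectionStrength values must lie in [0, 1]")
  if (length(object@selectionStrength) != object@nGenes)
    msg <- c(msg, "selectionStrength must have one value per gene")
  if (length(msg)) msg else TRUE
})

#' Default preferred-codon set
#'
#' One designated codon per multi-codon amino acid: the alphabetically first
#' T-ending codon of the family, or the alphabetically first A-ending codon
#' for families without a T-ending synonym (Lys, Gln, Glu). This mirrors the
#' A/T-ending optimal codons typical of AT-rich plant nuclear genomes.
#'
#' @param code A [GeneticCode-class] object.
#' @return Named character: amino acid -> codon (DNA spelling).
#' @export
defaultPreferredCodons <- function(code = standardGeneticCode()) {
  fams <- synFamilies(code)
  multi <- names(degeneracy(code))[degeneracy(code) > 1L]
  vapply(fams[multi], function(cods) {
    tEnd <- cods[substr(cods, 3, 3) == "T"]
    if (length(tEnd)) sort(tEnd)[1] else sort(cods[substr(cods, 3, 3) == "A"])[1]
  }, character(1))
}

#' Build a validated SimulationConfig
#'
#' @param nGenes Number of genes (default 200).
#' @param lengthMean Mean gene body length in codons (default 360, a typical
#'   plant nuclear CDS length).
#' @param lengthCv Coefficient of variation of length (default 0.3; 0 for
#'   constant lengths).
#' @param aaFrequencies Amino-acid probabilities; default uniform over the
#'   18 multi-codon amino acids, isolating synonymous effects from
#'   amino-acid composition.
#' @param mutationThirdBaseProbs Third-base mutational probabilities;
#'   default uniform (no compositional bias, third-position G+C 0.5).
#' @param preferredCodons Designated preferred codon per amino acid; default
#'   [defaultPreferredCodons()].
#' @param selectionStrength Per-gene selection probability, scalar or
#'   vector; default 0 (neutral).
#' @param seed Integer seed (default 1).
#' @param code A [GeneticCode-class] object.
#' @return A validated [SimulationConfig-class] object.
#' @export
#' @examples
#' cfg <- simulationConfig(nGenes = 5, lengthMean = 50, seed = 7)
#' nGenes(generateCdsSet(cfg)$counts)
simulationConfig <- function(nGenes = 200L, lengthMean = 360, lengthCv = 0.3,
                             aaFrequencies = NULL,
                             mutationThirdBaseProbs = c(A = 0.25, C = 0.25,
                                                        G = 0.25, T = 0.25),
                             preferredCodons = NULL,
                             selectionStrength = 0,
                             seed = 1L,
                             code = standardGeneticCode()) {
  multi <- names(degeneracy(code))[degeneracy(code) > 1L]
  if (is.null(aaFrequencies))
    aaFrequencies <- setNames(rep(1 / length(multi), length(multi)), multi)
  aaFrequencies <- aaFrequencies / sum(aaFrequencies)
  mutationThirdBaseProbs <-
    mutationThirdBaseProbs[.BASES] / sum(mutationThirdBaseProbs)
  if (is.null(preferredCodons)) preferredCodons <- defaultPreferredCodons(code)
  sel <- rep_len(as.numeric(selectionStrength), nGenes)
  obj <- new("SimulationConfig",
             nGenes = as.integer(nGenes), lengthMean = lengthMean,
             lengthCv = lengthCv, aaFrequencies = aaFrequencies,
             mutationThirdBaseProbs = mutationThirdBaseProbs,
             preferredCodons = preferredCodons,
             selectionStrength = sel, seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes, mean length",
      object@lengthMean, "codons, seed", object@seed, "\n")
  cat("  selection strength:",
      paste(format(range(object@selectionStrength)), collapse = " .. "), "\n")
  cat("  third-base mutation probs:",
      paste(names(object@mutationThirdBaseProbs),
            format(object@mutationThirdBaseProbs), collapse = " "), "\n")
})

# per-amino-acid codon emission probabilities under the mutational process:
# each family codon is weighted by the mutational probability of its third
# base, renormalised within the family, so uniform third-base probabilities
# give uniform within-family usage (the neutral limit: RSCU = 1, ENC -> 61)
.mutationCodonProbs <- function(code, thirdProbs) {
  fams <- synFamilies(code)
  multi <- names(degeneracy(code))[degeneracy(code) > 1L]
  lapply(fams[multi], function(cods) {
    p <- thirdProbs[substr(cods, 3, 3)]
    setNames(as.numeric(p / sum(p)), cods)
  })
}

#' Generate a synthetic CDS set with known codon-usage structure
#'
#' Draws coding sequences under the mutation-selection model described in
#' [SimulationConfig-class]. The returned truth table records each gene's
#' selection strength, giving ground truth for ENC, GC3s, RSCU, PR2, P2 and
#' optimal-codon recovery. Output is deterministic given the config seed
#' (the caller's RNG state is left untouched).
#'
#' @param config A [SimulationConfig-class] object.
#' @param code A [GeneticCode-class] object.
#' @return List: `records` (named `DNAStringSet`), `truth` (data.frame
#'   `gene_id`, `length_codons`, `s_g`), `counts` (a [CodonCounts-class]
#'   object, terminal stops dropped) and `config`.
#' @export
generateCdsSet <- function(config, code = standardGeneticCode()) {
  stopifnot(is(config, "SimulationConfig"))
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) suppressWarnings(rm(".Random.seed",
                                              envir = globalenv()))
    else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(config@seed)

  nG <- config@nGenes
  if (config@lengthCv == 0) {
    lens <- rep(round(config@lengthMean), nG)
  } else {
    shape <- 1 / config@lengthCv^2
    lens <- pmax(10L, as.integer(round(
      rgamma(nG, shape = shape, scale = config@lengthMean / shape))))
  }
  aas <- names(config@aaFrequencies)
  mutProbs <- .mutationCodonProbs(code, config@mutationThirdBaseProbs)
  stops <- stopCodons(code)
  sG <- config@selectionStrength

  seqs <- character(nG)
  for (g in seq_len(nG)) {
    L <- lens[g]
    aaSeq <- sample(aas, L, replace = TRUE, prob = config@aaFrequencies)
    useSel <- runif(L) < sG[g]
    codons <- character(L)
    if (any(useSel))
      codons[useSel] <- config@preferredCodons[aaSeq[useSel]]
    for (aa in unique(aaSeq[!useSel])) {
      idx <- which(!useSel & aaSeq == aa)
      p <- mutProbs[[aa]]
      codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    seqs[g] <- paste0("ATG", paste(codons, collapse = ""),
                      sample(stops, 1L))
  }
  ids <- sprintf("sim_g%05d", seq_len(nG))
  records <- Biostrings::DNAStringSet(setNames(seqs, ids))
  truth <- data.frame(gene_id = ids, length_codons = lens, s_g = sG,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth,
       counts = countCodons(records, code = code), config = config)
}

#' Ground-truth recovery summary for a simulated CDS set
#'
#' Quantifies how well the analysis recovers the generator's structure:
#' (a) the Spearman rank correlation between per-gene selection strength and
#' ENC (expected negative: selected genes are more biased), (b) the fraction
#' of designated preferred codons recovered as optimal codons, and (c) the
#' mean absolute deviation of neutral genes (s_g = 0) from the expected-ENC
#' curve at their GC3s.
#'
#' @param truth Truth data.frame from [generateCdsSet()].
#' @param perGene Per-gene [indexTable()] of the generated set (needs
#'   columns `gene_id`, `ENC`, `GC3s`).
#' @param optimalReport Optional [optimalCodons()] report.
#' @param config The [SimulationConfig-class] used (for the preferred set).
#' @return List: `sgEncCorrelation`, `preferredRecovered` (fraction or `NA`
#'   without a report), `recoveredCodons`, `falsePositiveCodons`,
#'   `neutralEncCurveDeviation` (`NA` if no neutral genes).
#' @export
recoveryReport <- function(truth, perGene, optimalReport = NULL,
                           config = NULL) {
  if (!setequal(truth$gene_id, perGene$gene_id))
    stop("gene ids of truth table and index table do not match")
  m <- merge(truth, perGene, by = "gene_id")
  ok <- !is.na(m$ENC)
  rho <- if (sd(m$s_g[ok]) == 0) NA_real_ else
    cor(m$s_g[ok], m$ENC[ok], method = "spearman")
  neutral <- ok & m$s_g == 0 & !is.na(m$GC3s)
  dev <- if (any(neutral))
    mean(abs(m$ENC[neutral] - expectedEnc(m$GC3s[neutral]))) else NA_real_
  recovered <- fp <- character(0)
  frac <- NA_real_
  if (!is.null(optimalReport) && !is.null(config)) {
    preferred <- toRnaCodon(unname(config@preferredCodons))
    flagged <- optimalReport$codon[!is.na(optimalReport$optimal) &
                                     optimalReport$optimal]
    recovered <- intersect(flagged, preferred)
    fp <- setdiff(flagged, preferred)
    frac <- length(recovered) / length(preferred)
  }
  list(sgEncCorrelation = rho,
       preferredRecovered = frac,
       recoveredCodons = recovered,
       falsePositiveCodons = fp,
       neutralEncCurveDeviation = dev)
}
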