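#' @include simulate.R
NULL

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.rscuTsv <- function(rscuValues, code, rnaCodons = TRUE) {
  syn <- names(rscuValues)
  data.frame(codon = if (rnaCodons) toRnaCodon(syn) else syn,
             aa = unname(codonToAa(code)[syn]),
             rscu = unname(rscuValues),
             stringsAsFactors = FALSE)
}

#' Run the full codon-usage-bias analysis and write a table bundle
#'
#' End-to-end pipeline over one CDS collection: filtering, codon counting,
#' per-gene and pooled composition, ENC (with ENC-plot data against the
#' expected curve), PR2 coordinates, pooled RSCU with frequency classes, the
#' P2 summary and the optimal-codon report. With two or more labelled gene
#' sets it additionally writes per-set pooled profiles/RSCU/P2, an ANOVA +
#' Duncan letter table per comparison index, index correlations and the
#' RSCU-based cluster tree (Newick). Every number in the output tables is
#' reproducible by calling the underlying functions on the same inputs.
#'
#' @param records A named `DNAStringSet` of CDS (e.g. [readCdsFasta()]).
#' @param outDir Output directory (created if needed).
#' @param setRules Optional named character of id patterns for
#'   [splitByPattern()]; sets with fewer than 2 retained genes are dropped
#'   from set-level analyses.
#' @param fraction,deltaThreshold,alpha Optimal-codon parameters (ENC tail
#'   fraction 0.05, RSCU difference 0.08, t-test level 0.01).
#' @param duncanAlpha Significance level for Duncan's test, default 0.05.
#' @param compareIndices Per-gene indices compared across sets, default
#'   `c("T3s", "G3s", "GC", "ENC")`.
#' @param code A [GeneticCode-class] object.
#' @param plots Also write ENC-plot and PR2-plot PDFs.
#' @param rnaCodons Print codons in RNA spelling (default) or DNA.
#' @param minCodons Minimum CDS length in codons for filtering, default 30.
#' @return Invisibly, a list of the computed objects (filter log, index
#'   table, reports, file paths).
#' @export
runCubAnalysis <- function(records, outDir, setRules = NULL,
                           fraction = 0.05, deltaThreshold = 0.08,
                           alpha = 0.01, duncanAlpha = 0.05,
                           compareIndices = c("T3s", "G3s", "GC", "ENC"),
                           code = standardGeneticCode(), plots = FALSE,
                           rnaCodons = TRUE, minCodons = 30L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  flt <- filterCds(records, code = code, minCodons = minCodons)
  .writeTsv(flt$log, file.path(outDir, "filter_log.tsv"))
  if (!length(flt$records))
    stop("no CDS retained after filtering; see ",
         file.path(outDir, "filter_log.tsv"))
  counts <- countCodons(flt$records, code = code)

  perGene <- indexTable(counts, code)
  .writeTsv(perGene, file.path(outDir, "per_gene_indices.tsv"))

  pooled <- pooledCounts(counts)
  pooledProfile <- compositionProfile(pooled, code)
  pooledTab <- data.frame(t(c(pooledProfile, ENC = enc(pooled, code),
                              n_genes = nGenes(counts),
                              n_codons = totalCodons(counts))))
  .writeTsv(pooledTab, file.path(outDir, "pooled_composition.tsv"))

  encPlot <- data.frame(gene_id = perGene$gene_id, GC3s = perGene$GC3s,
                        ENC = perGene$ENC,
                        expected_ENC = ifelse(is.na(perGene$GC3s), NA,
                          expectedEnc(pmin(pmax(perGene$GC3s, 0), 1))))
  .writeTsv(encPlot, file.path(outDir, "enc_plot.tsv"))
  pr2 <- pr2Point(perGene)
  .writeTsv(pr2, file.path(outDir, "pr2_plot.tsv"))

  pooledRscu <- rscu(pooled, code)
  .writeTsv(.rscuTsv(pooledRscu, code, rnaCodons),
            file.path(outDir, "rscu_pooled.tsv"))
  .writeTsv(frequencyClasses(pooledRscu),
            file.path(outDir, "frequency_classes.tsv"))

  p2 <- p2Index(pooled, code)
  .writeTsv(data.frame(set = "all", SSU = p2$SSU, WWU = p2$WWU,
                       SSC = p2$SSC, WWC = p2$WWC, P2 = p2$P2),
            file.path(outDir, "p2_summary.tsv"))

  encVec <- setNames(perGene$ENC, perGene$gene_id)
  part <- partitionByEnc(encVec, fraction)
  .writeTsv(data.frame(
    gene_id = c(part$highBias, part$lowBias),
    dataset = rep(c("high_bias", "low_bias"),
                  c(length(part$highBias), length(part$lowBias)))),
    file.path(outDir, "enc_partition.tsv"))
  optRep <- optimalCodons(counts, part, code, deltaThreshold, alpha)
  .writeTsv(optRep, file.path(outDir, "optimal_codons.tsv"))

  setResults <- NULL
  if (!is.null(setRules)) {
    sets <- splitByPattern(geneIds(counts), setRules)
    sets <- sets[setdiff(names(sets), "unassigned")]
    sets <- sets[lengths(sets) >= 2L]
    if (length(sets) >= 2L)
      setResults <- .analyzeSets(counts, sets, perGene, code,
                                 compareIndices, duncanAlpha, outDir,
                                 rnaCodons)
  }

  if (plots) .writePlots(encPlot, pr2, outDir)

  message(sprintf(
    "codon-usage analysis: %d/%d CDS retained, %d codons; %d optimal codons",
    nGenes(counts), length(records), totalCodons(counts),
    attr(optRep, "nOptimal")))
  invisible(list(filterLog = flt$log, counts = counts, perGene = perGene,
                 pooledProfile = pooledProfile, rscu = pooledRscu, p2 = p2,
                 partition = part, optimalCodons = optRep,
                 sets = setResults, outDir = outDir))
}

.analyzeSets <- function(counts, sets, perGene, code, compareIndices,
                         duncanAlpha, outDir, rnaCodons) {
  m <- codonCounts(counts)
  .writeTsv(data.frame(
    label = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE)),
    file.path(outDir, "gene_sets.tsv"))

  pooledBySet <- vapply(sets, function(ids)
    rowSums(m[, ids, drop = FALSE]), numeric(64))
  setProfiles <- t(vapply(names(sets), function(s) {
    v <- pooledBySet[, s]
    c(compositionProfile(v, code), ENC = enc(v, code),
      n_genes = length(sets[[s]]), n_codons = sum(v))
  }, numeric(13)))
  .writeTsv(data.frame(set = rownames(setProfiles), setProfiles,
                       row.names = NULL),
            file.path(outDir, "set_composition.tsv"))

  rscuBySet <- t(vapply(names(sets), function(s)
    rscu(pooledBySet[, s], code), numeric(59)))
  rscuTab <- data.frame(
    codon = if (rnaCodons) toRnaCodon(colnames(rscuBySet)) else
      colnames(rscuBySet),
    aa = unname(codonToAa(code)[colnames(rscuBySet)]),
    t(rscuBySet), row.names = NULL)
  .writeTsv(rscuTab, file.path(outDir, "rscu_by_set.tsv"))

  p2Tab <- do.call(rbind, lapply(names(sets), function(s) {
    p <- p2Index(pooledBySet[, s], code)
    data.frame(set = s, SSU = p$SSU, WWU = p$WWU, SSC = p$SSC,
               WWC = p$WWC, P2 = p$P2)
  }))
  .writeTsv(p2Tab, file.path(outDir, "p2_by_set.tsv"))

  duncan <- list()
  for (idx in compareIndices) {
    groups <- lapply(sets, function(ids)
      perGene[[idx]][match(ids, perGene$gene_id)])
    groups <- lapply(groups, function(v) v[!is.na(v)])
    if (any(lengths(groups) < 2L)) next
    dt <- anovaDuncan(groups, alpha = duncanAlpha)
    tab <- dt$table
    tab$index <- idx
    duncan[[idx]] <- tab
  }
  if (length(duncan))
    .writeTsv(do.call(rbind, duncan),
              file.path(outDir, "duncan_comparisons.tsv"))

  corr <- correlateIndices(perGene[, c("T3s", "A3s", "G3s", "C3s", "GC3s",
                                       "GC", "GC12", "GC3", "ENC")])
  corLong <- do.call(rbind, lapply(rownames(corr$r), function(a)
    data.frame(index1 = a, index2 = colnames(corr$r),
               r = corr$r[a, ], p = corr$p[a, ], n = corr$n[a, ],
               row.names = NULL)))
  .writeTsv(corLong, file.path(outDir, "index_correlations.tsv"))

  tree <- rscuCluster(rscuBySet)
  writeLines(tree$newick, file.path(outDir, "rscu_cluster.nwk"))
  list(pooledBySet = pooledBySet, rscuBySet = rscuBySet, p2 = p2Tab,
       duncan = duncan, correlations = corr, tree = tree)
}

.writePlots <- function(encPlot, pr2, outDir) {
  grDevices::pdf(file.path(outDir, "enc_plot.pdf"), width = 6, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(encPlot$GC3s, encPlot$ENC, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("steelblue", 0.5),
       xlab = "GC3s", ylab = "ENC", xlim = c(0, 1), ylim = c(20, 62))
  s <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(s, expectedEnc(s), lwd = 2)
  grDevices::dev.off()
  grDevices::pdf(file.path(outDir, "pr2_plot.pdf"), width = 5.5, height = 5)
  plot(pr2$x, pr2$y, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("firebrick", 0.5),
       xlab = "G3s / (G3s + C3s)", ylab = "A3s / (A3s + T3s)",
       xlim = c(0, 1), ylim = c(0, 1))
  graphics::abline(h = 0.5, v = 0.5, lty = 2)
  invisible(NULL)
}

#' Simulate a CDS set and write FASTA, truth table and recovery report
#'
#' Thin pipeline around [generateCdsSet()]: writes the generated FASTA and
#' the per-gene truth table, and optionally runs the analysis back over the
#' simulated data to produce a [recoveryReport()].
#'
#' @param config A [SimulationConfig-class] object.
#' @param outDir Output directory (created if needed).
#' @param recovery Also run the index/optimal-codon analysis and write
#'   `recovery_report.tsv`.
#' @param code A [GeneticCode-class] object.
#' @return Invisibly, the [generateCdsSet()] result plus `recovery` when
#'   requested.
#' @export
runCubSimulation <- function(config, outDir, recovery = FALSE,
                             code = standardGeneticCode()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- generateCdsSet(config, code)
  writeCdsFasta(sim$records, file.path(outDir, "simulated_cds.fasta"))
  .writeTsv(sim$truth, file.path(outDir, "truth.tsv"))
  message(sprintf("simulated %d CDS (seed %d) into %s",
                  config@nGenes, config@seed, outDir))
  rec <- NULL
  if (recovery) {
    perGene <- indexTable(sim$counts, code)
    part <- partitionByEnc(setNames(perGene$ENC, perGene$gene_id))
    opt <- optimalCodons(sim$counts, part, code)
    rec <- recoveryReport(sim$truth, perGene, opt, config)
    .writeTsv(data.frame(
      metric = c("sg_enc_spearman", "preferred_recovered_fraction",
                 "neutral_enc_curve_deviation"),
      value = c(rec$sgEncCorrelation, rec$preferredRecovered,
                rec$neutralEncCurveDeviation)),
      file.path(outDir, "recovery_report.tsv"))
  }
  invisible(c(sim, list(recovery = rec)))
}
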