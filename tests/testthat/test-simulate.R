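gcode <- standardGeneticCode()

test_that("simulation config validates its inputs", {
  expect_s4_class(simulationConfig(nGenes = 5, lengthMean = 50), "SimulationConfig")
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(selectionStrength = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(
    mutationThirdBaseProbs = c(A = 1, C = 0, G = 0, T = -1)), "probabilities")
  badPref <- defaultPreferredCodons(gcode)
  badPref[["F"]] <- "GGG"  # not a Phe codon
  expect_error(simulationConfig(preferredCodons = badPref), "family")
  # defaults: preferred codons end in T, or A where no T-ending synonym exists
  pref <- defaultPreferredCodons(gcode)
  expect_length(pref, 18)
  third <- substr(pref, 3, 3)
  expect_true(all(third %in% c("T", "A")))
  expect_identical(unname(pref[c("K", "Q", "E")]), c("AAA", "CAA", "GAA"))
})

test_that("generated CDS have start, stop and the configured lengths", {
  cfg <- simulationConfig(nGenes = 12, lengthMean = 40, lengthCv = 0,
                          seed = 3)
  sim <- generateCdsSet(cfg)
  expect_length(sim$records, 12)
  seqs <- as.character(sim$records)
  expect_true(all(substr(seqs, 1, 3) == "ATG"))
  lastCodon <- substr(seqs, nchar(seqs) - 2, nchar(seqs))
  expect_true(all(lastCodon %in% stopCodons(gcode)))
  expect_true(all(nchar(seqs) == 3 * (40 + 2)))
  expect_identical(sim$truth$gene_id, names(sim$records))
  # terminal stop is excluded from the counts; start codon is counted
  expect_equal(unname(colSums(codonCounts(sim$counts))), rep(41, 12))
})

test_that("the generator is deterministic and leaves the caller's RNG alone", {
  cfg <- simulationConfig(nGenes = 8, lengthMean = 60, seed = 42)
  a <- generateCdsSet(cfg)
  set.seed(12345)
  before <- runif(1)
  set.seed(12345)
  b <- generateCdsSet(cfg)
  after <- runif(1)
  expect_identical(as.character(a$records), as.character(b$records))
  expect_identical(a$truth, b$truth)
  expect_equal(before, after)  # RNG state restored around generation
  c_ <- generateCdsSet(simulationConfig(nGenes = 8, lengthMean = 60,
                                        seed = 43))
  expect_false(identical(as.character(a$records), as.character(c_$records)))
})

test_that("full selection collapses families to the preferred codon, ENC -> 20", {
  cfg <- simulationConfig(nGenes = 5, lengthMean = 400, lengthCv = 0,
                          selectionStrength = 1, seed = 11)
  sim <- generateCdsSet(cfg)
  pooled <- pooledCounts(sim$counts)
  used <- names(pooled)[pooled > 0]
  expect_true(all(used %in% c("ATG", unname(cfg@preferredCodons))))
  expect_equal(unname(enc(sim$counts)), rep(20, 5), tolerance = 1e-9)
})

test_that("neutral genes sit near RSCU = 1 and ENC = 61 at large length", {
  cfg <- simulationConfig(nGenes = 40, lengthMean = 1000, lengthCv = 0,
                          selectionStrength = 0, seed = 8)
  sim <- generateCdsSet(cfg)
  r <- rscu(pooledCounts(sim$counts))
  expect_lt(max(abs(r - 1)), 0.15)  # binomial noise at 40k codons
  expect_gt(mean(enc(sim$counts)), 59)
})

test_that("mutational GC bias propagates to GC3s of the neutral stratum", {
  cfg <- simulationConfig(nGenes = 50, lengthMean = 500, lengthCv = 0,
                          mutationThirdBaseProbs = c(A = 0.15, C = 0.35,
                                                     G = 0.35, T = 0.15),
                          seed = 19)
  sim <- generateCdsSet(cfg)
  gc3s <- indexTable(sim$counts)$GC3s
  # third-base G+C probability 0.7; family structure shifts realised GC3s
  # only mildly, so the gene mean should land close to it
  expect_gt(mean(gc3s), 0.6)
  expect_lt(mean(gc3s), 0.8)
})

test_that("mean ENC decreases across increasing selection strata", {
  strata <- c(0, 0.4, 0.8)
  cfg <- simulationConfig(nGenes = 600, lengthMean = 300, lengthCv = 0,
                          selectionStrength = rep(strata, each = 200),
                          seed = 27)
  sim <- generateCdsSet(cfg)
  e <- enc(sim$counts)
  means <- tapply(e, rep(strata, each = 200), mean)
  expect_true(all(diff(means) < 0))
  # and the rank correlation between s_g and ENC is strongly negative
  tab <- indexTable(sim$counts)
  rec <- recoveryReport(sim$truth, tab)
  expect_lt(rec$sgEncCorrelation, -0.8)
})

test_that("recovery report validates id matching", {
  cfg <- simulationConfig(nGenes = 6, lengthMean = 50, seed = 2)
  sim <- generateCdsSet(cfg)
  tab <- indexTable(sim$counts)
  bad <- tab
  bad$gene_id[1] <- "nope"
  expect_error(recoveryReport(sim$truth, bad), "do not match")
})
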