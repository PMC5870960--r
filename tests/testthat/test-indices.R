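gcode <- standardGeneticCode()

test_that("RSCU follows its defining ratio and family-sum conservation", {
  r <- rscu(c(TTT = 3, TTC = 1))
  expect_equal(r[["TTT"]], 1.5)
  expect_equal(r[["TTC"]], 0.5)
  # uniform within-family usage gives RSCU = 1 everywhere
  u <- rscu(setNames(rep(10, 59), synonymousCodons(gcode)))
  expect_true(all(u == 1))
  # unused family is undefined, not zero
  expect_true(is.na(rscu(c(TTT = 1))[["GGG"]]))

  # family sums equal degeneracy on random tables
  set.seed(21)
  aaOf <- codonToAa(gcode)
  for (i in 1:25) {
    r <- rscu(randomCountTable())
    sums <- tapply(r, aaOf[names(r)], sum)
    deg <- degeneracy(gcode)[names(sums)]
    used <- !is.na(sums)
    expect_equal(as.numeric(sums[used]), unname(as.numeric(deg[used])))
  }
})

test_that("ENC hits its printed extremes and stays within bounds", {
  syn <- synonymousCodons(gcode)
  expect_equal(enc(setNames(rep(1000, 59), syn)), 61)
  onePer <- setNames(rep(1000, 20), vapply(synFamilies(gcode), `[`, "", 1))
  expect_equal(enc(onePer), 20)
  set.seed(5)
  for (i in 1:25) {
    e <- enc(randomCountTable())
    expect_true(is.na(e) || (e >= 20 && e <= 61))
  }
})

test_that("ENC details expose class homozygosities and degenerate-input handling", {
  d <- enc(setNames(rep(1000, 20), vapply(synFamilies(gcode), `[`, "", 1)),
           details = TRUE)
  expect_equal(unname(d$classHomozygosity), rep(1, 4))
  expect_equal(d$nMissingFamilies, 0)
  # Ile (the only three-fold family) absent: F3 imputed from F2 and F4
  counts <- randomCountTable()
  counts[synFamilies(gcode)[["I"]]] <- 0
  d2 <- enc(counts, details = TRUE)
  expect_false(is.na(d2$enc))
  expect_equal(d2$nMissingFamilies, 1)
  # all two-fold families absent: undefined with a reason
  counts2 <- randomCountTable()
  deg <- degeneracy(gcode)
  for (aa in names(deg)[deg == 2]) counts2[synFamilies(gcode)[[aa]]] <- 0
  d3 <- enc(counts2, details = TRUE)
  expect_true(is.na(d3$enc))
  expect_match(d3$reason, "class 2")
})

test_that("expected ENC curve has the right anchor points and envelope", {
  expect_equal(expectedEnc(0), 31)
  expect_equal(expectedEnc(0.5), 60.5)
  expect_equal(expectedEnc(1), 32)
  s <- seq(0, 1, by = 0.01)
  v <- expectedEnc(s)
  expect_true(all(v > 30 & v <= 61))
  expect_equal(s[which.max(v)], 0.5)
  expect_error(expectedEnc(1.2), "0, 1")
})

test_that("PR2 coordinates centre at (0.5, 0.5) only under A=T, G=C", {
  p <- pr2Point(c(A3s = 0.3, T3s = 0.3, G3s = 0.2, C3s = 0.2))
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(pr2Point(c(A3s = 0.3, T3s = 0.6, G3s = 0.2,
                          C3s = 0.2))[["y"]], 1 / 3)
  expect_equal(pr2Point(c(A3s = 0.4, T3s = 0, G3s = 0.2,
                          C3s = 0.2))[["y"]], 1)
  # zero pair sum leaves that coordinate undefined
  p0 <- pr2Point(c(A3s = 0, T3s = 0, G3s = 0.2, C3s = 0.2))
  expect_true(is.na(p0[["y"]]) && !is.na(p0[["x"]]))
})

test_that("P2 arithmetic and symmetry behave as defined", {
  expect_equal(p2FromSums(wwc = 1, ssu = 1, wwu = 1, ssc = 1), 0.5)
  expect_equal(round(p2FromSums(3.28, 5.30, 4.94, 2.40), 4), 0.5389)
  p <- p2Index(setNames(rep(10, 59), synonymousCodons(gcode)))
  # uniform usage: every qualifying RSCU is 1, so 4 weak and 4 strong pairs
  expect_equal(p$WWC, 4)
  expect_equal(p$WWU, 4)
  expect_equal(p$SSC, 4)
  expect_equal(p$SSU, 4)
  expect_equal(p$P2, 0.5)
  expect_equal(nrow(p$codonPairs), 8)
})

test_that("ENC, RSCU and P2 match brute-force oracles on random tables", {
  set.seed(99)
  for (i in 1:30) {
    counts <- randomCountTable()
    expect_equal(enc(counts), oracleEnc(counts), tolerance = 1e-12)
    expect_equal(rscu(counts), oracleRscu(counts), tolerance = 1e-12)
    p <- p2Index(counts)
    o <- oracleP2(counts)
    expect_equal(p$P2, o$P2, tolerance = 1e-12)
    expect_equal(p$WWC, o$WWC, tolerance = 1e-12)
    expect_equal(p$SSU, o$SSU, tolerance = 1e-12)
  }
})

test_that("CodonCounts methods give per-gene matrices consistent with vectors", {
  set.seed(13)
  m <- cbind(g1 = randomCountTable(), g2 = randomCountTable())
  cc <- CodonCounts(m)
  rm_ <- rscu(cc)
  expect_equal(dim(rm_), c(59L, 2L))
  expect_equal(rm_[, "g2"], rscu(m[, "g2"]))
  ev <- enc(cc)
  expect_equal(ev[["g1"]], enc(m[, "g1"]))
  pp <- pr2Point(cc)
  expect_equal(pp$x[1], unname(pr2Point(m[, "g1"])[["x"]]))
  expect_equal(p2Index(cc)$P2, p2Index(m[, "g1"] + m[, "g2"])$P2)
})
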