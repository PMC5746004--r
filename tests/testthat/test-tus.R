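test_that("fold-change classification is a total partition with medium boundaries", {
  expect_equal(classifyExpression(12), "high")
  expect_equal(classifyExpression(3), "medium")
  expect_equal(classifyExpression(10), "medium")
  expect_equal(classifyExpression(1), "low")
  expect_error(classifyExpression(0), "positive")

  fc <- c(seq(0.1, 30, by = 0.37), 3, 10, 10.0001, 2.9999)
  cls <- classifyExpression(fc)
  expect_true(all(cls %in% c("high", "medium", "low")))
  expect_equal(sum(table(cls)), length(fc))
  expect_true(all((fc > 10) == (cls == "high")))
  expect_true(all((fc < 3) == (cls == "low")))
})

test_that("TSS refinement accepts coverage starts within one probe length", {
  genes <- mkGenes(c(200, 2200), c(800, 2800), c("+", "-"))
  segs <- mkSegments(c(100, 2100), c(900, 2900), c("+", "-"), c(12, 5))

  # plus strand: array 100, coverage 125 -> refined (25 <= 60)
  cov <- mkCovIntervals(c(125, 2100), c(890, 2860), c("+", "-"))
  tus <- assembleTUs(segs, cov, genes)
  expect_equal(tus$tss[1], 125L)
  expect_equal(tus$tss_source[1], "both")
  # minus strand: array tss 2900, coverage tss 2860 -> refined
  expect_equal(tus$tss[2], 2860L)

  # coverage start 300 is too far (200 > 60): array kept
  covFar <- mkCovIntervals(300, 890, "+")
  tusFar <- assembleTUs(segs[1], covFar, genes)
  expect_equal(tusFar$tss, 100L)
  expect_equal(tusFar$tss_source, "array")

  # gene membership and UTRs
  expect_equal(unlist(tus$genes[1]), "gene_0001", ignore_attr = TRUE)
  expect_equal(tus$utr5_len[1], 200L - 125L)
  expect_equal(tus$class, c("high", "medium"))
})

test_that("noiseless platforms recover every planted TU exactly", {
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  segs <- segmentProbes(callProbes(m))
  cov <- simulateCoverage(sim$truth, cfg)
  tus <- assembleTUs(segs, detectBoundaries(cov), sim$genes)
  mt <- matchTruth(tus, sim$truth)
  expect_true(all(mt$recovered))
  expect_equal(mt$tss_error, rep(0L, nrow(mt)))   # coverage-refined = truth
  expect_equal(mt$tts_error, rep(0L, nrow(mt)))
  # gene sets match truth
  for (i in seq_along(sim$truth)) {
    planted <- sim$genes$gene_id[
      overlapsAny(sim$genes, sim$truth[i], type = "within") &
      as.character(strand(sim$genes)) == as.character(strand(sim$truth))[i]]
    got <- unlist(tus$genes[tus$tu_id == mt$matched_tu[i]])
    expect_setequal(got, planted)
  }
  # per-TU consistency: UTRs are non-negative and match tss/tts
  plus <- as.character(strand(tus)) == "+"
  gb <- !tus$intergenic
  expect_true(all(tus$utr5_len[gb] >= 0))
  expect_true(all(tus$utr3_len[gb] >= 0))
  expect_equal(tus$utr5_len[gb & plus],
               tus$first_gene_start[gb & plus] - tus$tss[gb & plus])
})

test_that("TSS concordance is signed strand-aware and bounded on simulations", {
  segs <- mkSegments(c(100, 3100), c(900, 3900), c("+", "-"), c(12, 12))
  genes <- mkGenes(c(300, 3200), c(800, 3700), c("+", "-"))
  cov <- mkCovIntervals(c(125, 3100), c(890, 3900), c("+", "-"))
  tus <- assembleTUs(segs, cov, genes)
  conc <- tssConcordance(tus)
  expect_equal(conc$table$discrepancy[1], 25)     # rnaseq downstream
  expect_equal(conc$table$discrepancy[2], 0)      # identical prediction

  cfg <- smallConfig()
  sim <- cachedSim(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  tus2 <- assembleTUs(segmentProbes(callProbes(m)),
                      detectBoundaries(simulateCoverage(sim$truth, cfg)),
                      sim$genes)
  conc2 <- tssConcordance(tus2)
  expect_gte(conc2$median, 0)
  expect_lte(conc2$median, 60)
})

test_that("UTR statistics recover planted class means", {
  segs <- mkSegments(c(100, 1100), c(600, 1600), "+", c(12, 15))
  genes <- mkGenes(c(140, 1160), c(590, 1590), "+")
  tus <- assembleTUs(segs, mkCovIntervals(integer(), integer(), character()),
                     genes)
  u <- utrStats(tus)
  expect_equal(u$per_class$mean_utr5[u$per_class$class == "high"], 50)
  expect_equal(u$per_class$n[u$per_class$class == "high"], 2L)
  expect_false("low" %in% u$per_class$class)   # empty class absent, not 0

  single <- utrStats(tus[1])
  expect_equal(single$mean_utr5, 40)

  # parameter recovery on a clean simulation
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  tus3 <- assembleTUs(segmentProbes(callProbes(m)),
                      detectBoundaries(simulateCoverage(sim$truth, cfg)),
                      sim$genes)
  u3 <- utrStats(tus3)
  for (cl in c("high", "medium", "low")) {
    planted <- sim$truth$utr5[sim$truth$class == cl & !sim$truth$intergenic]
    got <- u3$per_class$mean_utr5[u3$per_class$class == cl]
    se <- sd(planted) / sqrt(length(planted))
    expect_lt(abs(got - mean(planted)), max(3 * se, 1))
  }
})
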