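test_that("seeded generation is reproducible and keeps its bookkeeping", {
  cfg <- simConfig(genomeLength = 50000L,
                   nTUsPerClass = c(high = 5L, medium = 5L, low = 5L),
                   nConvergentPairs = 0L, nIntergenicTUs = 0L, seed = 3L)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))

  expect_length(a$truth, 15L)
  expect_equal(sort(table(a$truth$class)),
               sort(table(c(rep("high", 5), rep("medium", 5), rep("low", 5)))))

  gc <- letterFrequency(a$genome[[1]], "GC", as.prob = TRUE)[[1]]
  expect_lt(abs(gc - cfg@gcFrac), 0.02)

  # intergenic space is more AT rich than coding space
  geneMask <- rep(FALSE, cfg@genomeLength)
  for (i in seq_along(a$genes))
    geneMask[start(a$genes)[i]:end(a$genes)[i]] <- TRUE
  bases <- strsplit(as.character(a$genome[[1]]), "")[[1]]
  gcCoding <- mean(bases[geneMask] %in% c("G", "C"))
  gcInter <- mean(bases[!geneMask] %in% c("G", "C"))
  expect_gt(gcCoding - gcInter, 0.04)
})

test_that("zero degradation plants exact consensus hexamers", {
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  tr <- sim$truth
  for (i in seq_along(tr)) {
    st <- as.character(strand(tr[i]))
    hex <- function(pos) {
      s <- subseq(sim$genome[[1]], pos, pos + 5L)
      if (st == "-") s <- reverseComplement(s)
      as.character(s)
    }
    expect_identical(hex(tr$pos35_start[i]), "TTGACA")
    expect_identical(hex(tr$pos10_start[i]), "TATAAT")
  }
  expect_true(all(tr$spacer_len >= 14 & tr$spacer_len <= 20))
})

test_that("probe signals follow the overlap-weighted fold change", {
  cfg <- simConfig(genomeLength = 2000L,
                   nTUsPerClass = c(high = 0L, medium = 0L, low = 0L),
                   noiseSdLog2 = 0, nConvergentPairs = 0L,
                   nIntergenicTUs = 0L)
  truth <- GRanges("synth_chr", IRanges(c(301, 1201), c(900, 1500)),
                   c("+", "+"), fc = c(12, 10))
  seqlengths(truth) <- c(synth_chr = 2000L)
  probes <- GRanges("synth_chr",
                    IRanges(c(401, 35, 1171), width = 60), "+",
                    probe_id = c("in", "out", "half"))
  seqlengths(probes) <- c(synth_chr = 2000L)
  m <- simulateProbeSignals(probes, truth, cfg)
  ratio <- m$mrna / m$gdna
  expect_equal(ratio[m$probe_id == "in"], 12)      # fully inside fc=12
  expect_equal(ratio[m$probe_id == "out"], 1)      # zero overlap
  expect_equal(ratio[m$probe_id == "half"], 5.5)   # half of fc=10: .5*10+.5*1
  expect_error(simulateProbeSignals(
    GRanges("synth_chr", IRanges(1990, 2049), "+", probe_id = "off"),
    truth, cfg), "outside")
})

test_that("class-conditional probe ratios land inside configured fc ranges", {
  cfg <- smallConfig()
  sim <- cachedSim(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  pg <- GRanges("synth_chr", IRanges(m$start, m$end), m$strand)
  for (cl in c("high", "medium", "low")) {
    tuCl <- sim$truth[sim$truth$class == cl & !sim$truth$intergenic]
    inside <- overlapsAny(pg, tuCl, type = "within")
    ratios <- (m$mrna / m$gdna)[inside]
    se <- sd(ratios) / sqrt(length(ratios))
    rng <- cfg@fcRanges[[cl]]
    expect_gt(mean(ratios), rng[1] - 3 * se)
    expect_lt(mean(ratios), rng[2] + 3 * se)
  }
})

test_that("coverage rises at the TSS, scales with fc, and truncates 5' ends", {
  # clean limit: a step exactly at the TSS
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  cov <- simulateCoverage(sim$truth, cfg)
  for (i in seq_along(sim$truth)) {
    tu <- sim$truth[i]
    st <- as.character(strand(tu))
    x <- cov[[st]]
    tss <- tu$tss
    if (st == "+") {
      expect_gt(x[tss], 0)
      expect_equal(sum(x[max(1, tss - 50):(tss - 1)]), 0)
    } else {
      expect_gt(x[tss], 0)
      expect_equal(sum(x[(tss + 1):min(length(x), tss + 50)]), 0)
    }
  }

  # doubling one TU's fc doubles its mean coverage (same seed)
  cfg2 <- cleanConfig()
  sim2 <- cachedSim(cfg2)
  tr2 <- sim2$truth
  trDouble <- tr2
  trDouble$fc[1] <- tr2$fc[1] * 2
  covA <- simulateCoverage(tr2, cfg2, seed = 99L)
  covB <- simulateCoverage(trDouble, cfg2, seed = 99L)
  st <- as.character(strand(tr2[1]))
  span <- start(tr2[1]):end(tr2[1])
  expect_equal(mean(covB[[st]][span]) / mean(covA[[st]][span]), 2,
               tolerance = 0.05)

  # geometric truncation with mean 20 shifts onsets ~20 bp downstream
  cfgT <- simConfig(genomeLength = 250000L, seed = 5L,
                    fivePrimeTruncationMean = 20,
                    backgroundCoverage = 0)
  simT <- simulateGenome(cfgT)
  covT <- simulateCoverage(simT$truth, cfgT)
  offs <- vapply(seq_along(simT$truth), function(i) {
    tu <- simT$truth[i]
    st <- as.character(strand(tu))
    x <- covT[[st]][start(tu):end(tu)]
    if (st == "-") x <- rev(x)
    which(x > 0)[1] - 1L
  }, numeric(1))
  expect_gte(length(offs), 50L)
  expect_gte(min(offs), 0)
  expect_lt(abs(mean(offs) - 20), 5)
})

test_that("planted terminators always satisfy the detector rule set", {
  for (cfg in list(smallConfig(), cleanConfig())) {
    sim <- cachedSim(cfg)
    tr <- sim$truth
    idx <- which(!is.na(tr$term_stem5_start))
    expect_gt(length(idx), 0L)
    expect_true(all(tr$term_stem_len[idx] >= 6))
    expect_true(all(tr$term_loop_len[idx] >= 3 & tr$term_loop_len[idx] <= 8))
    expect_true(all(tr$term_polyT_len[idx] >= 5))
    for (i in idx) {
      st <- as.character(strand(tr[i]))
      arm <- subseq(sim$genome[[1]], tr$term_stem5_start[i],
                    tr$term_stem5_start[i] + tr$term_stem_len[i] - 1L)
      gc <- letterFrequency(arm, "GC", as.prob = TRUE)[[1]]
      expect_gte(gc, 0.5)
    }
  }
})
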