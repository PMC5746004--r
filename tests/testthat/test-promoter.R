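test_that("EM recovers an exact planted consensus and the spacer mode", {
  set.seed(31)
  win <- vapply(1:75, function(i) consensusWindow(17L), character(1))
  m <- learnPromoterModel(win)
  expect_equal(unname(modelConsensus(m)), c("TTGACA", "TATAAT"))
  expect_equal(spacerMode(m), 17L)
  expect_false(m@lowInformation)

  # variable planted spacers with mode 17 are recovered as mode 17
  set.seed(32)
  spacers <- sample(14:20, 75, replace = TRUE,
                    prob = exp(-abs(14:20 - 17) / 1.2))
  win2 <- vapply(spacers, function(s) paste0(
    randSeq(24 + 20 - s, 0.5), "TTGACA", randSeq(s, 0.5), "TATAAT",
    randSeq(9, 0.5)), character(1))
  m2 <- learnPromoterModel(win2)
  expect_equal(unname(modelConsensus(m2)), c("TTGACA", "TATAAT"))
  expect_equal(spacerMode(m2), 17L)

  expect_error(learnPromoterModel(win[1:9]), "at least 10")
})

test_that("uniform random windows give a flagged low-information model", {
  set.seed(33)
  win <- vapply(1:50, function(i) randSeq(62, gc = 0.5), character(1))
  expect_warning(m <- learnPromoterModel(win), "low-information")
  expect_true(m@lowInformation)
})

test_that("scanning returns the optimal placement with documented tie-breaks", {
  set.seed(34)
  win <- vapply(1:75, function(i) consensusWindow(17L), character(1))
  model <- learnPromoterModel(win)

  # planted optimum: consensus, spacer 17, -10 ending 10 bp before TSS
  probe <- paste0(randSeq(62, 0.5), "TTGACA", randSeq(17, 0.5), "TATAAT",
                  randSeq(9, 0.5))
  call <- scanPromoter(probe, model)
  expect_equal(call$spacer_len, 17L)
  expect_equal(call$dist10_tss, 10L)

  # two exact placements with spacers 16 and 17: the 17 bp one wins
  tie <- paste0("TTGACA", randSeq(16, 0.3), "TATAAT",
                "TTGACA", randSeq(17, 0.3), "TATAAT", randSeq(4, 0.3))
  tie <- paste0(randSeq(100 - nchar(tie), 0.3), tie)
  callTie <- scanPromoter(tie, model)
  expect_equal(callTie$spacer_len, 17L)

  # pure-GC window has no AT-rich box to call
  expect_null(scanPromoter(strrep("GC", 50), model))
  expect_warning(short <- scanPromoter(randSeq(30), model), "shorter")
  expect_null(short)
})

test_that("scan score equals the exhaustive placement oracle", {
  set.seed(35)
  win <- vapply(1:75, function(i) consensusWindow(17L), character(1))
  model <- learnPromoterModel(win)

  oracleBest <- function(window, model) {
    x <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
    L <- length(x)
    best <- -Inf
    for (i35 in seq_len(L)) for (s in 14:20) {
      i10 <- i35 + 6L + s
      if (i10 + 5L > L) next
      sc <- sum(model@logodds35[cbind(x[i35:(i35 + 5L)], 1:6)]) +
        sum(model@logodds10[cbind(x[i10:(i10 + 5L)], 1:6)]) -
        model@spacerPenaltyPerBp * abs(s - 17L)
      if (sc > best) best <- sc
    }
    best
  }
  for (k in 1:20) {
    w <- randSeq(100, gc = 0.55)
    got <- scanPromoter(w, model)
    expected <- oracleBest(w, model)
    if (is.null(got)) {
      expect_lt(expected, model@threshold)
    } else {
      expect_equal(got$score, expected, tolerance = 1e-10)
    }
  }
})

test_that("feature extraction reproduces the 62-bp window arithmetic", {
  # genome with a known promoter: 30 pad + 24 up + TTGACA + 17 + TATAAT + 9
  up <- randSeq(24, 0.5)
  set.seed(36)
  spacer <- randSeq(17, 0.5)
  genomeStr <- paste0(randSeq(30, 0.5), up, "TTGACA", spacer, "TATAAT",
                      randSeq(9, 0.5), randSeq(40, 0.5))
  genome <- DNAStringSet(setNames(genomeStr, "synth_chr"))
  call <- data.frame(pos35 = 55L, pos10 = 78L, spacer_len = 17L)
  tss <- 94L
  f <- extractPromoterFeatures(call, tss, geneStart = 130L, genome, "+")
  expect_equal(f$window_len, 62L)                   # 24 + 6 + 17 + 6 + 9
  expect_equal(f$at_10, 1.0)                        # TATAAT is all AT
  expect_equal(nchar(f$aligned_bases), 62L)
  expect_equal(f$leader_len, 130L - 94L)
  expect_equal(f$spacer_len, 17L)

  # spacer 14: raw window 59 bp, centre-padded with 3 gaps
  genome14 <- DNAStringSet(setNames(
    paste0(randSeq(30, 0.5), up, "TTGACA", randSeq(14, 0.5), "TATAAT",
           randSeq(9, 0.5), randSeq(40, 0.5)), "synth_chr"))
  call14 <- data.frame(pos35 = 55L, pos10 = 75L, spacer_len = 14L)
  f14 <- extractPromoterFeatures(call14, 91L, NA, genome14, "+")
  expect_equal(f14$window_len, 59L)
  expect_equal(nchar(f14$aligned_bases), 62L)
  gaps <- gregexpr("-", f14$aligned_bases)[[1]]
  expect_equal(length(gaps), 3L)
  expect_true(all(gaps > 30 & gaps <= 47))          # inside the spacer block

  expect_error(extractPromoterFeatures(
    data.frame(pos35 = 10L, pos10 = 33L, spacer_len = 17L),
    49L, NA, genome, "+"), "off the contig")
})

test_that("promoter recall decreases from high to low expression class", {
  cfg <- simConfig(genomeLength = 150000L,
                   nTUsPerClass = c(high = 12L, medium = 12L, low = 12L),
                   nConvergentPairs = 0L, nIntergenicTUs = 0L, seed = 8L)
  sim <- simulateGenome(cfg)
  tr <- sim$truth
  # train on the high/medium truth windows, scan all planted TSSs
  hm <- tr[tr$class %in% c("high", "medium")]
  win <- upstreamWindows(sim$genome, hm$tss, as.character(strand(hm)))
  model <- learnPromoterModel(win)
  tuLike <- tr
  tuLike$tss_source <- "both"
  tuLike$first_gene_start <- NA_integer_
  calls <- callPromoters(tuLike, sim$genome, model)
  recall <- vapply(c("high", "medium", "low"), function(cl) {
    ids <- tr$tu_id[tr$class == cl]
    hit <- vapply(ids, function(id) {
      j <- which(calls$tu_id == id)
      length(j) == 1L &&
        abs(calls$pos10[j] - tr$pos10_start[tr$tu_id == id]) <= 3
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(recall[["high"]], recall[["medium"]])
  expect_gte(recall[["medium"]], recall[["low"]])
  expect_gt(recall[["high"]], recall[["low"]])
})
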