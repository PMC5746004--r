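test_that("the canonical bidirectional element is called as such", {
  seqBi <- paste0("AAAAA", "GCGCGCGC", "TTTT", "GCGCGCGC", "TTTTTT")
  calls <- findTerminators(seqBi)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$bidirectional)
  expect_true(calls$has_polyT)
  expect_gte(calls$stem_len, 6L)
  expect_gte(calls$polyT_len, 4L)
  expect_gte(calls$polyA_len, 4L)
  expect_gte(calls$stem_gc, 0.5)

  # without the leading A-run the terminator is still called, one-sided
  seqMono <- paste0("GTCAG", "GCGCGCGC", "TTTT", "GCGCGCGC", "TTTTTT")
  one <- findTerminators(seqMono)
  expect_equal(nrow(one), 1L)
  expect_false(one$bidirectional)
  expect_true(one$has_polyT)

  # no hairpin at all
  expect_equal(nrow(findTerminators(strrep("AC", 50))), 0L)
})

test_that("the detector matches a brute-force hairpin oracle", {
  set.seed(41)
  for (k in 1:50) {
    w <- randSeq(200, gc = 0.59)
    for (req in c(TRUE, FALSE)) {
      got <- findTerminators(w, requirePolyT = req)
      want <- bruteForceTerminators(w, requirePolyT = req)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
  # and on windows containing a planted terminator
  set.seed(42)
  for (k in 1:10) {
    w <- paste0(randSeq(60), "AAAAA", "GGCGCCC", randSeq(4, 0.2),
                "GGGCGCC", "TTTTT", randSeq(60))
    got <- findTerminators(w)
    want <- bruteForceTerminators(w)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    expect_gte(nrow(got), 1L)
  }
})

test_that("termination strategies are classified from TTS context", {
  # hand-built chromosome: TU A ends in hairpin+polyT, TU B in a bare
  # hairpin, convergent pair C/D overlaps 3'-UTRs with no signal
  pad <- function(n) strrep("AC", ceiling(n / 2)) |> substr(1, n)
  term <- paste0("GCGCGCGC", "TTTT", "GCGCGCGC", "TTTTTT")   # full
  bare <- paste0("GGCGCGCC", "ATTA", "GGCGCGCC")             # no polyT
  genomeStr <- paste0(pad(200),                 # 1-200
                      term,                     # 201-226, polyT ends 226
                      pad(200),                 # 227-426
                      bare,                     # 427-446
                      pad(554))                 # 447-1000
  genome <- DNAStringSet(setNames(genomeStr, "synth_chr"))
  tus <- GRanges("synth_chr", IRanges(c(50, 280, 600, 640),
                                      c(226, 446, 700, 740)),
                 c("+", "+", "+", "-"),
                 tu_id = sprintf("tu_%d", 1:4),
                 class = "high",
                 tss = c(50L, 280L, 600L, 740L),
                 tts = c(226L, 446L, 700L, 640L),
                 last_gene_end = c(150L, 400L, 660L, 680L))
  res <- classifyTermination(tus, genome)
  expect_equal(res$tus$termination_class,
               c("rho_independent", "stem_loop_only",
                 "convergent_overlap", "convergent_overlap"))
  expect_true(any(res$calls$has_polyT))

  # synthetic convergent-overlap pair from the generator
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  tr <- sim$truth
  tuLike <- tr
  tuLike$last_gene_end <- NA_integer_
  for (i in seq_along(tr)) {
    g <- sim$genes[overlapsAny(sim$genes, tr[i], type = "within") &
                     as.character(strand(sim$genes)) ==
                     as.character(strand(tr))[i]]
    if (length(g))
      tuLike$last_gene_end[i] <-
        if (as.character(strand(tr))[i] == "+") max(end(g)) else min(start(g))
  }
  res2 <- classifyTermination(tuLike, sim$genome)
  cls <- res2$tus$termination_class
  planted <- !is.na(tr$term_stem5_start)
  # planted rho-independent terminators are all recovered
  expect_true(all(cls[planted] == "rho_independent"))
  # overlap pairs (no planted terminator, tail-to-tail) never become rho
  overlapPair <- tr$pair > 0 & !planted
  expect_false(any(cls[overlapPair] == "rho_independent"))
})

test_that("termination bookkeeping reproduces per-class arithmetic", {
  mkTus <- function(counts) {
    cls <- rep(rep(c("high", "medium", "low"), each = 2),
               times = as.vector(t(counts)))
    term <- rep(rep(c("rho_independent", "none"), 3),
                times = as.vector(t(counts)))
    GRanges("synth_chr", IRanges(seq_along(cls) * 100, width = 50), "+",
            class = cls, termination_class = term)
  }
  counts <- rbind(high = c(70, 13), medium = c(81, 72), low = c(73, 104))
  s <- terminationSummary(mkTus(counts))
  expect_equal(s$total_tus, 413L)
  expect_equal(s$rho_independent_total, 224L)
  expect_equal(s$rho_independent_pct, 54)
  expect_equal(as.vector(s$class_totals), c(83L, 153L, 177L))

  allRho <- mkTus(rbind(high = c(5, 0), medium = c(5, 0), low = c(5, 0)))
  expect_equal(terminationSummary(allRho)$rho_independent_pct, 100)

  empty <- terminationSummary(mkTus(counts)[0])
  expect_equal(empty$total_tus, 0L)
  expect_true(is.na(empty$rho_independent_pct))
})

test_that("planted terminator recall is 100% and precision high on clean data", {
  cfg <- cleanConfig()
  sim <- cachedSim(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  tus <- assembleTUs(segmentProbes(callProbes(m)),
                     detectBoundaries(simulateCoverage(sim$truth, cfg)),
                     sim$genes)
  res <- classifyTermination(tus, sim$genome)
  mt <- matchTruth(res$tus, sim$truth)
  planted <- !is.na(sim$truth$term_polyT_start)
  cls <- res$tus$termination_class[match(mt$matched_tu, res$tus$tu_id)]
  expect_equal(mean(cls[planted] == "rho_independent"), 1)   # recall 100%

  # precision: full calls near a TTS correspond to planted elements
  full <- res$calls[res$calls$has_polyT]
  s5 <- sim$truth$term_stem5_start[planted]
  pT <- sim$truth$term_polyT_start[planted]
  planted3 <- GRanges("synth_chr",
                      IRanges(pmin(s5, pT) - 10, pmax(s5, pT) + 15))
  hit <- overlapsAny(full, planted3, ignore.strand = TRUE)
  expect_gte(mean(hit), 0.9)
})
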