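test_that("probe design tiles both strands with the 60/22 geometry", {
  p <- designProbes(104)
  expect_length(p, 6L)                       # 3 per strand
  expect_equal(start(p[strand(p) == "+"]), c(1, 23, 45))
  expect_equal(start(p[strand(p) == "-"]), c(1, 23, 45))
  expect_true(all(width(p) == 60))

  one <- designProbes(60)
  expect_length(one, 2L)
  expect_equal(c(start(one)[1], end(one)[1]), c(1, 60))

  big <- designProbes(5000)
  expect_equal(length(big), 2L * sum(strand(big) == "+"))

  expect_warning(short <- designProbes(59), "shorter")
  expect_length(short, 0L)
})

test_that("probe calling flags nothing without signal and validates input", {
  m <- data.frame(probe_id = sprintf("p%02d", 1:40), strand = "+",
                  start = seq(1, by = 22, length.out = 40),
                  end = seq(60, by = 22, length.out = 40),
                  gdna = 1000, mrna = 1000)
  calls <- callProbes(m)
  expect_false(any(calls$significant))
  expect_equal(calls$log2_ratio, rep(0, 40))

  bad <- m
  bad$mrna[3] <- 0
  expect_error(callProbes(bad), "p03")

  # q-values are monotone non-decreasing in p-values
  set.seed(1)
  m2 <- m
  m2$mrna <- m$gdna * 2^rnorm(40, 0.3, 0.4)
  c2 <- callProbes(m2)
  o <- order(c2$p)
  expect_true(all(diff(c2$q[o]) >= -1e-12))

  # masked probes are never called
  msk <- GRanges("synth_chr", IRanges(1, 200))
  c3 <- callProbes(m2, mask = msk)
  expect_true(all(c3$masked[c3$start <= 200]))
  expect_false(any(c3$significant & c3$masked))
  expect_true(all(is.na(c3$p[c3$masked])))
})

test_that("significant probes merge into segments under the gap rule", {
  mk <- function(starts, sig, lr = 2) {
    data.frame(probe_id = sprintf("p%03d", seq_along(starts)), strand = "+",
               start = starts, end = starts + 59L,
               gdna = 1000, mrna = 1000,
               log2_ratio = lr, p = 0, q = 0, significant = sig,
               masked = FALSE)
  }
  starts <- seq(101, by = 22, length.out = 12)

  s1 <- segmentProbes(mk(starts[1:3], rep(TRUE, 3)))
  expect_length(s1, 1L)
  expect_equal(c(start(s1), end(s1)), c(101, 145 + 59))   # [101, 204]

  s2 <- segmentProbes(mk(starts[1], TRUE))
  expect_equal(c(start(s2), end(s2)), c(101, 160))

  # two runs separated by 3 non-significant probes stay two segments
  sig <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  s3 <- segmentProbes(mk(starts[1:8], sig), maxGapProbes = 1L)
  expect_length(s3, 2L)
  # ... but a single interior dropout is bridged
  sig4 <- c(TRUE, TRUE, FALSE, TRUE)
  s4 <- segmentProbes(mk(starts[1:4], sig4), maxGapProbes = 1L)
  expect_length(s4, 1L)
  expect_equal(s4$n_probes, 3L)                 # dropout not a member
  expect_equal(s4$mean_fc, 4)                   # mean of 2^2 over members
})

test_that("a planted high-fc TU yields significant internal probes only", {
  cfg <- simConfig(genomeLength = 40000L,
                   nTUsPerClass = c(high = 1L, medium = 0L, low = 0L),
                   fcRanges = list(high = c(12, 12), medium = c(3, 10),
                                   low = c(1.5, 2.8)),
                   nConvergentPairs = 0L, nIntergenicTUs = 0L, seed = 21L)
  sim <- simulateGenome(cfg)
  probes <- designProbes(cfg@genomeLength)
  m <- simulateProbeSignals(probes, sim$truth, cfg)
  calls <- callProbes(m)
  pg <- GRanges("synth_chr", IRanges(calls$start, calls$end), calls$strand)
  internal <- overlapsAny(pg, sim$truth, type = "within")
  touching <- overlapsAny(pg, sim$truth)
  expect_true(all(calls$significant[internal]))
  expect_false(any(calls$significant[!touching]))
})
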