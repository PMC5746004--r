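test_that("negative windows are seeded, intergenic, and promoter-free", {
  cfg <- smallConfig()
  sim <- cachedSim(cfg)
  proms <- GRanges("synth_chr", IRanges(c(1000, 5000), width = 47),
                   c("+", "-"))
  set.seed(77)
  a <- sampleNegatives(sim$genome, sim$genes, proms, n = 100)
  set.seed(77)
  b <- sampleNegatives(sim$genome, sim$genes, proms, n = 100)
  expect_identical(a, b)
  expect_true(all(nchar(a$seq) == 62L))
  win <- GRanges("synth_chr", IRanges(a$start, a$end))
  expect_false(any(overlapsAny(win, sim$genes, ignore.strand = TRUE)))
  expect_false(any(overlapsAny(win, proms, ignore.strand = TRUE)))

  # a fully annotated genome leaves no room
  tiny <- DNAStringSet(setNames(strrep("A", 100), "synth_chr"))
  fullAnn <- GRanges("synth_chr", IRanges(1, 100), "+", gene_id = "g1")
  expect_error(sampleNegatives(tiny, fullAnn, GRanges(), n = 5),
               "insufficient")
})

test_that("feature ranking is deterministic and recovers a planted driver", {
  fm <- simulateFeatureMatrix(nPerClass = 60L, seed = 13L)
  r1 <- trainRank(fm, nTrees = 150L, seed = 5L)
  r2 <- trainRank(fm, nTrees = 150L, seed = 5L)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$oob3, r2$oob3)

  oneClass <- fm[fm$label == "high", ]
  expect_error(trainRank(oneClass), "two classes")

  # class determined by a hard threshold on at_10, everything else noise
  set.seed(14)
  n <- 240L
  at10 <- runif(n)
  lab <- cut(at10, c(-Inf, 0.33, 0.66, Inf),
             labels = c("low", "medium", "high"))
  noise <- matrix(runif(n * 6), n)
  colnames(noise) <- c("spacer_len", "leader_len", "at_up35", "at_35",
                       "at_spacer", "at_down10")
  fmP <- data.frame(label = factor(lab, levels = c("high", "medium", "low")),
                    noise, at_10 = at10)
  rP <- trainRank(fmP, nTrees = 300L, seed = 6L)
  expect_equal(rP$importance$feature[1], "at_10")
})

test_that("default synthetic features rank at_10, spacer, leader in order", {
  fm <- simulateFeatureMatrix(nPerClass = 300L, seed = 11L)
  rep <- trainRank(fm, nTrees = 500L, seed = 42L)
  rank <- function(f) which(rep$importance$feature == f)
  expect_lt(rank("at_10"), rank("spacer_len"))
  expect_lt(rank("spacer_len"), rank("leader_len"))

  # within the -10 block, positions 1, 2 and 6 dominate the core
  imp <- setNames(rep$importance$importance, rep$importance$feature)
  m10 <- imp[sprintf("pos%02d", 48:53)]
  expect_gt(min(m10[c(1, 2, 6)]), max(m10[3:5]))
})

test_that("permuted labels drop the forest to chance-level OOB error", {
  fm <- simulateFeatureMatrix(nPerClass = 150L, seed = 15L)
  set.seed(16)
  fm$label <- sample(fm$label)
  rep <- trainRank(fm, nTrees = 400L, seed = 17L)
  expect_lt(abs(rep$oob3 - 2 / 3), 0.08)   # 3 balanced classes
})
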