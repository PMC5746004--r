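## canonical 62-bp layout (modal 17-bp spacer): 24 up35 | 6 box35 |
## 17 spacer | 6 box10 | 9 down10; -10 block occupies columns 48-53
.LAYOUT <- list(up35 = 1:24, box35 = 25:30, spacer = 31:47,
                box10 = 48:53, down10 = 54:62)

#' Sample negative promoter-sized windows from intergenic space
#'
#' Draws `n` windows of `width` bp uniformly (seeded by the caller's
#' RNG state) from the intergenic complement of the annotation, never
#' overlapping a called promoter footprint.  Windows are oriented on a
#' randomly drawn strand.
#'
#' @param genome `DNAStringSet`.
#' @param annotation gene `GRanges`.
#' @param promoterCalls promoter `GRanges` (footprints excluded); may be
#'   zero-length.
#' @param n number of windows.
#' @param width window width (default 62).
#' @return `data.frame` with `start`, `end`, `strand`, `seq`.
#' @export
sampleNegatives <- function(genome, annotation, promoterCalls, n,
                            width = 62L) {
  stopifnot(n >= 1L)
  gl <- Biostrings::width(genome)[1L]
  blocked <- IRanges::reduce(c(
    IRanges::IRanges(BiocGenerics::start(annotation),
                     BiocGenerics::end(annotation)),
    if (length(promoterCalls))
      IRanges::IRanges(BiocGenerics::start(promoterCalls),
                       BiocGenerics::end(promoterCalls))
    else IRanges::IRanges()))
  free <- IRanges::setdiff(IRanges::IRanges(1L, gl), blocked)
  free <- free[BiocGenerics::width(free) >= width]
  nAvail <- sum(BiocGenerics::width(free) - width + 1L)
  if (nAvail < 1L)
    stop("insufficient intergenic space for negatives (0 candidate ",
         "windows of ", width, " bp available)")
  # draw genomic start positions uniformly over all candidate offsets
  offsets <- sample.int(nAvail, n, replace = nAvail < n)
  cum <- cumsum(BiocGenerics::width(free) - width + 1L)
  block <- findInterval(offsets - 1L, c(0L, head(cum, -1L)),
                        rightmost.closed = FALSE)
  within <- offsets - c(0L, head(cum, -1L))[block]
  starts <- BiocGenerics::start(free)[block] + within - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    .senseSeq(genome, starts[i], starts[i] + width - 1L, strands[i]),
    character(1))
  data.frame(start = starts, end = starts + width - 1L,
             strand = strands, seq = seqs)
}

## features of a bare 62-bp window under the canonical layout
.negativeFeatures <- function(seqs) {
  atF <- function(block) vapply(seqs, function(s) {
    b <- strsplit(substr(s, block[1], block[length(block)]), "")[[1]]
    mean(b %in% c("A", "T"))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(spacer_len = 17L,
             leader_len = NA_integer_,
             at_up35 = atF(.LAYOUT$up35), at_35 = atF(.LAYOUT$box35),
             at_spacer = atF(.LAYOUT$spacer), at_10 = atF(.LAYOUT$box10),
             at_down10 = atF(.LAYOUT$down10),
             aligned_bases = seqs)
}

#' Build the random-forest feature matrix
#'
#' One row per called promoter (label = expression class of its TU) and
#' optionally per negative intergenic window (label `negative`).
#' Columns are the seven scalar classifiers - spacer length, leader
#' length, and the AT fractions of the -35 upstream block, -35 hexamer,
#' spacer, -10 hexamer and -10 downstream block - followed by the 62
#' aligned base positions `pos01`..`pos62` as factors with an explicit
#' gap level.  Negatives inherit `spacer_len` 17 (canonical layout) and
#' a leader length resampled from the positives, so the bookkeeping
#' columns cannot trivially identify them.
#'
#' @param promoterFeatures `data.frame` with a `class` column plus the
#'   columns produced by [extractPromoterFeatures()].
#' @param negatives optional `data.frame` from [sampleNegatives()].
#' @return `data.frame` with `label` (factor) and the fixed feature
#'   columns, rows with missing leader length dropped.
#' @export
buildFeatureMatrix <- function(promoterFeatures, negatives = NULL) {
  scalarCols <- c("spacer_len", "leader_len", "at_up35", "at_35",
                  "at_spacer", "at_10", "at_down10")
  pos <- promoterFeatures[, c("class", scalarCols, "aligned_bases")]
  names(pos)[1] <- "label"
  pos <- pos[!is.na(pos$leader_len), , drop = FALSE]
  if (!is.null(negatives) && nrow(negatives)) {
    neg <- .negativeFeatures(negatives$seq)
    neg$leader_len <- sample(pos$leader_len, nrow(neg), replace = TRUE)
    neg <- cbind(label = "negative", neg[, c(scalarCols, "aligned_bases")])
    pos <- rbind(pos, neg)
  }
  lv <- intersect(c(.CLASSES, "negative"), unique(pos$label))
  out <- data.frame(label = factor(pos$label, levels = lv),
                    pos[, scalarCols, drop = FALSE])
  base <- do.call(rbind, strsplit(pos$aligned_bases, ""))
  colnames(base) <- sprintf("pos%02d", seq_len(ncol(base)))
  for (j in seq_len(ncol(base)))
    out[[colnames(base)[j]]] <- factor(base[, j],
                                       levels = c(.BASES, "-"))
  rownames(out) <- NULL
  out
}

#' Rank promoter features by random-forest importance
#'
#' Fits a random forest (bootstrap rows, random feature subsets per
#' split, balanced per-class sampling) to the feature matrix and ranks
#' features by mean decrease in Gini impurity, with ties broken by
#' column order.  When a `negative` class is present a second forest is
#' fitted on the expressed promoters alone, and the ranking and
#' out-of-bag (OOB) error of this three-class (high/medium/low)
#' sub-problem are reported alongside the full-model OOB error.
#'
#' @param fm `data.frame` from [buildFeatureMatrix()].
#' @param nTrees trees per forest (default 500).
#' @param seed integer RNG seed for reproducible fits.
#' @return list with `importance` (data.frame `feature`, `importance`,
#'   ordered), `oob` (OOB error of the full model), `oob3` (three-class
#'   OOB error), `confusion` (three-class confusion counts), and the
#'   fitted `forest` / `forest3` objects.
#' @export
trainRank <- function(fm, nTrees = 500L, seed = NULL) {
  if (nlevels(droplevels(fm$label)) < 2L)
    stop("feature matrix must contain at least two classes")
  if (!is.null(seed)) set.seed(seed)
  fm$label <- droplevels(fm$label)
  balanced <- function(lab) rep(min(table(lab)), nlevels(lab))
  rf <- randomForest::randomForest(
    label ~ ., data = fm, ntree = nTrees,
    sampsize = balanced(fm$label), strata = fm$label)
  oob <- unname(rf$err.rate[nTrees, "OOB"])
  fm3 <- fm[fm$label != "negative", , drop = FALSE]
  fm3$label <- droplevels(fm3$label)
  if (nlevels(fm3$label) >= 2L && !identical(levels(fm3$label),
                                             levels(fm$label))) {
    rf3 <- randomForest::randomForest(
      label ~ ., data = fm3, ntree = nTrees,
      sampsize = balanced(fm3$label), strata = fm3$label)
  } else {
    rf3 <- rf
  }
  oob3 <- unname(rf3$err.rate[nTrees, "OOB"])
  imp <- randomForest::importance(rf3)[, "MeanDecreaseGini"]
  ord <- order(-imp, seq_along(imp))
  list(importance = data.frame(feature = names(imp)[ord],
                               importance = unname(imp[ord])),
       oob = oob, oob3 = oob3,
       confusion = rf3$confusion,
       forest = rf, forest3 = rf3)
}

#' Simulate a planted promoter feature matrix
#'
#' Draws promoter feature rows directly from the class-conditional
#' distributions the genome generator plants: per-class -10/-35
#' consensus degradation (the AT fraction of the -10 box falls as the
#' class drops), per-class spacer concentration around 17 bp, and
#' per-class leader lengths.  Used to validate feature ranking at a
#' sample size where the ranking is stable.
#'
#' @param nPerClass rows per expression class (default 200).
#' @param config a [SimConfig-class] supplying the class-conditional
#'   parameters.
#' @param seed integer RNG seed.
#' @param leaderNoise when TRUE (default) the leader length carries the
#'   TSS measurement error of the assembly chain: a coverage-refined
#'   start shortens the apparent leader by a geometric 5'-truncation,
#'   while an array-only start lengthens it by the probe overhang.
#' @return `data.frame` as from [buildFeatureMatrix()] (3 classes).
#' @export
simulateFeatureMatrix <- function(nPerClass = 200L, config = simConfig(),
                                  seed = 1L, leaderNoise = TRUE) {
  set.seed(seed)
  bg <- .baseProbs(config@gcFrac - config@gcIntergenicShift)
  pTrunc <- 1 / (config@fivePrimeTruncationMean + 1)
  rows <- list()
  for (cl in .CLASSES) {
    for (r in seq_len(nPerClass)) {
      spacer <- .sampleSpacer(config, cl)
      b10 <- .degradeHexamer(CONSENSUS10, .minus10Rates(config, cl), bg)
      b35 <- .degradeHexamer(
        CONSENSUS35, rep(config@minus35DegradationByClass[[cl]], 6L), bg)
      leader <- .sampleUtr5(config, cl)
      if (leaderNoise) {
        leader <- if (runif(1L) < 0.6)
          max(0L, leader - rgeom(1L, pTrunc))   # coverage-refined start
        else leader + sample(38:57, 1L)         # array probe overhang
      }
      rand <- function(k) sample(.BASES, k, replace = TRUE, prob = bg)
      up35 <- rand(24L); sp <- rand(spacer); down10 <- rand(9L)
      atF <- function(b) mean(b %in% c("A", "T"))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, spacer_len = spacer, leader_len = leader,
        at_up35 = atF(up35), at_35 = atF(b35), at_spacer = atF(sp),
        at_10 = atF(b10), at_down10 = atF(down10),
        aligned_bases = paste0(
          paste(up35, collapse = ""), paste(b35, collapse = ""),
          .alignSpacer(paste(sp, collapse = ""), 17L),
          paste(b10, collapse = ""), paste(down10, collapse = "")))
    }
  }
  buildFeatureMatrix(do.call(rbind, rows))
}
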