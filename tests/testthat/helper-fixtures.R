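suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## small standard configuration reused across files
smallConfig <- function(...) {
  simConfig(genomeLength = 60000L,
            nTUsPerClass = c(high = 4L, medium = 4L, low = 4L),
            nConvergentPairs = 2L, nIntergenicTUs = 1L, seed = 11L, ...)
}

## noiseless/clean conditions: exact platforms, no consensus degradation
cleanConfig <- function(...) {
  simConfig(genomeLength = 80000L,
            nTUsPerClass = c(high = 5L, medium = 5L, low = 5L),
            nConvergentPairs = 2L, nIntergenicTUs = 1L,
            noiseSdLog2 = 0, fivePrimeTruncationMean = 0,
            backgroundCoverage = 0, covBiasAmplitude = 0,
            promoterDegradationByClass = c(high = 0, medium = 0, low = 0),
            minus10MidDegradation = 0,
            minus35DegradationByClass = c(high = 0, medium = 0, low = 0),
            seed = 7L, ...)
}

## memoised simulations (testthat sources helpers once per file)
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(config) {
  key <- paste0("s", config@seed, "_", config@genomeLength, "_",
                config@noiseSdLog2, "_",
                sum(config@promoterDegradationByClass))
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateGenome(config)
  .simCache[[key]]
}

## GRanges builders for hand-made fixtures
mkSegments <- function(start, end, strand, mean_fc, n_probes = 5L) {
  gr <- GenomicRanges::GRanges("synth_chr", IRanges::IRanges(start, end), strand,
                segment_id = sprintf("seg_%03d", seq_along(start)),
                mean_fc = mean_fc, n_probes = n_probes)
  GenomeInfoDb::seqlengths(gr) <- c(synth_chr = 1000000L)
  gr
}

mkCovIntervals <- function(start, end, strand) {
  if (!length(start)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(tss = integer(), tts = integer(),
                                      truncated = logical())
    return(gr)
  }
  GenomicRanges::GRanges("synth_chr", IRanges::IRanges(start, end), strand,
          tss = as.integer(ifelse(strand == "+", start, end)),
          tts = as.integer(ifelse(strand == "+", end, start)),
          truncated = FALSE)
}

mkGenes <- function(start, end, strand,
                    ids = sprintf("gene_%04d", seq_along(start))) {
  GenomicRanges::GRanges("synth_chr", IRanges::IRanges(start, end), strand,
                         gene_id = ids)
}

## brute-force hairpin oracle: enumerates every (stem5_start, stemLen,
## loopLen) triple, requiring matched outer and inner pairs and at most
## one internal mismatch, then applies the same filters and overlap
## resolution as the detector
bruteForceTerminators <- function(sequence, minStem = 6L, minGC = 0.5,
                                  loopRange = c(3L, 10L), minPolyT = 4L,
                                  maxGap = 3L, requirePolyT = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  runAt <- function(i, base) {
    k <- 0L
    while (i + k <= n && x[i + k] == base) k <- k + 1L
    k
  }
  rows <- list()
  for (loopLen in loopRange[1]:loopRange[2]) {
    for (s5 in seq_len(n)) {
      maxStem <- (n - s5 + 1L - loopLen) %/% 2L
      if (maxStem < minStem) next
      for (stemLen in minStem:maxStem) {
        a <- s5 + stemLen - 1L             # innermost 5' base
        b <- a + loopLen + 1L              # innermost 3' base
        s3 <- b + stemLen - 1L
        if (s3 > n) next
        arm5 <- x[s5:a]; arm3 <- x[b:s3]
        ok <- unname(comp[arm5] == rev(arm3))
        # outermost pair must match and at most one mismatch inside
        if (!ok[1L] || sum(!ok) > 1L) next
        gc <- mean(c(arm5, arm3) %in% c("G", "C"))
        if (gc < minGC) next
        gcPairs <- sum(ok & arm5 %in% c("G", "C"))
        polyT <- c(NA_integer_, NA_integer_)
        for (g in 0:maxGap) {
          i <- s3 + 1L + g
          if (i > n) break
          len <- runAt(i, "T")
          if (len >= minPolyT) { polyT <- c(i, len); break }
        }
        polyA <- c(NA_integer_, NA_integer_)
        for (g in 0:maxGap) {
          j <- s5 - 1L - g
          if (j < 1L) break
          if (x[j] != "A") next
          len <- 0L
          while (j - len >= 1L && x[j - len] == "A") len <- len + 1L
          if (len >= minPolyT) { polyA <- c(j - len + 1L, len); break }
        }
        hasT <- !is.na(polyT[1L])
        if (requirePolyT && !hasT) next
        rows[[length(rows) + 1L]] <- data.frame(
          stem5_start = s5, stem_len = stemLen, loop_len = loopLen,
          stem3_end = s3, stem_gc = gc,
          polyT_start = polyT[1L], polyT_len = polyT[2L],
          polyA_start = polyA[1L], polyA_len = polyA[2L],
          bidirectional = hasT && !is.na(polyA[1L]),
          has_polyT = hasT,
          score = stemLen + 2 * gcPairs - 0.5 * loopLen)
      }
    }
  }
  if (!length(rows))
    return(findTerminators("ACACACACAC", requirePolyT = requirePolyT)[0, ])
  tab <- unique(do.call(rbind, rows))
  tab <- tab[order(-tab$has_polyT, -tab$bidirectional, -tab$score,
                   tab$stem5_start), , drop = FALSE]
  occupied <- IRanges::IRanges()
  sel <- list()
  for (r in seq_len(nrow(tab))) {
    span <- IRanges::IRanges(tab$stem5_start[r], tab$stem3_end[r])
    if (!any(IRanges::overlapsAny(span, occupied))) {
      sel[[length(sel) + 1L]] <- tab[r, ]
      occupied <- c(occupied, span)
    }
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out[order(out$stem5_start), , drop = FALSE]
}

## random sequence helper
randSeq <- function(n, gc = 0.59) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## a synthetic 62-bp promoter window: 24 up + TTGACA + spacer + TATAAT + 9
consensusWindow <- function(spacer = 17L, gc = 0.5) {
  paste0(randSeq(24, gc), "TTGACA", randSeq(spacer, gc), "TATAAT",
         randSeq(9, gc))
}
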