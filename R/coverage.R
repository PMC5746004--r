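#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = numReads / ((geneLength / 1000) * (totalReads / 1e6))`:
#' linear in the read count and inversely linear in gene length.
#'
#' @param numReads reads assigned to the gene (vectorized).
#' @param geneLength gene length in bp (> 0).
#' @param totalReads total mapped reads in the library (> 0).
#' @return numeric RPKM values.
#' @examples
#' rpkm(150, 1000, 1e6)   # 150, exactly the expression threshold
#' @export
rpkm <- function(numReads, geneLength, totalReads) {
  if (any(geneLength <= 0)) stop("geneLength must be positive")
  if (any(totalReads <= 0)) stop("totalReads must be positive")
  numReads / ((geneLength / 1000) * (totalReads / 1e6))
}

#' Call expressed genes from per-gene read counts
#'
#' Computes RPKM per gene and flags genes at or above the expression
#' cutoff (default 150 RPKM).
#'
#' @param counts `data.frame` with `gene_id`, `num_reads`, `gene_length`.
#' @param totalReads library size; defaults to `sum(num_reads)`.
#' @param threshold RPKM expression cutoff (default 150).
#' @return the input with `rpkm` and `expressed` columns.
#' @export
callExpressedGenes <- function(counts, totalReads = sum(counts$num_reads),
                               threshold = 150) {
  stopifnot(all(c("gene_id", "num_reads", "gene_length") %in% names(counts)))
  counts$rpkm <- rpkm(counts$num_reads, counts$gene_length, totalReads)
  counts$expressed <- counts$rpkm >= threshold
  counts
}

## mean of the w values starting at index b; NA where the window would
## leave the vector
.rollRight <- function(x, w) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  out <- rep(NA_real_, n)
  i <- seq_len(max(0L, n - w + 1L))
  out[i] <- (cs[i + w] - cs[i]) / w
  out
}

## first index of each maximal run of consecutive TRUE positions
.runFirst <- function(idx) {
  if (!length(idx)) return(integer(0))
  idx[c(TRUE, diff(idx) > 1L)]
}
## last index of each maximal run
.runLast <- function(idx) {
  if (!length(idx)) return(integer(0))
  idx[c(diff(idx) > 1L, TRUE)]
}

#' Detect transcript boundaries from per-base coverage
#'
#' A transcript start is the first covered base `b` (coverage >=
#' `minCov`) where mean coverage over the `window` bases from `b`
#' onwards is at least `minCov` and at least `minRatio` times the mean
#' over the `window` bases before `b`; a transcript end is the mirrored
#' drop, taken at the last base of its candidate run so that an ideal
#' step yields its exact edges.  Starts and ends are paired left to
#' right (in transcription sense) per strand; a start with no matching
#' end before the contig edge yields an interval truncated there and
#' flagged.  Anchoring boundaries on a covered base makes a detected
#' start the first base actually carrying reads, so on simulated data it
#' never lies upstream of the true TSS.
#'
#' @param coverage named list (`+`, `-`) of per-base coverage vectors
#'   (or `Rle`), as produced by [simulateCoverage()] or
#'   [readCoverageBedGraph()].
#' @param window flank size in bp for the step contrast (default 25).
#' @param minCov minimum mean coverage of the transcribed side; default
#'   `max(3, 5 * background)` with the background mean estimated from
#'   the lower half of the strand's coverage distribution.
#' @param minRatio minimum step ratio between the two flanks (default 4).
#' @return a `GRanges` of coverage intervals with strand-aware `tss` /
#'   `tts` columns and a `truncated` flag.
#' @export
detectBoundaries <- function(coverage, window = 25L, minCov = NULL,
                             minRatio = 4) {
  res <- list()
  for (st in c("+", "-")) {
    x <- as.numeric(coverage[[st]])
    if (!length(x)) next
    if (any(x < 0)) stop("coverage must be non-negative")
    n <- length(x)
    if (st == "-") x <- rev(x)          # work in transcription sense
    mc <- minCov
    if (is.null(mc)) {
      bg <- mean(x[x <= quantile(x, 0.5)])   # off-transcript majority
      mc <- max(3, 5 * bg)
    }
    right <- .rollRight(x, window)                # mean over [b, b+w)
    left <- rep(NA_real_, n)                      # mean over [b-w, b)
    if (n > window) {
      idx <- (window + 1L):n
      left[idx] <- right[idx - window]
    }
    leftIn <- rep(NA_real_, n)                    # mean over (b-w, b]
    if (n >= window) leftIn[window:n] <- right[(window:n) - window + 1L]
    rightOut <- rep(NA_real_, n)                  # mean over (b, b+w]
    if (n > 1L) rightOut[seq_len(n - 1L)] <- right[2:n]

    isStart <- x >= mc & !is.na(right) & right >= mc &
      (is.na(left) | left == 0 | right >= minRatio * left)
    # an end needs an observed drop; coverage running into the contig
    # edge yields an unmatched start and a truncation flag instead
    isEnd <- x >= mc & !is.na(leftIn) & leftIn >= mc &
      !is.na(rightOut) & (rightOut == 0 | leftIn >= minRatio * rightOut)
    starts <- .runFirst(which(isStart))
    ends <- .runLast(which(isEnd))
    ints <- .pairBoundaries(starts, ends, n)
    if (nrow(ints)) {
      if (st == "-") { # map sense coordinates back to genomic
        s <- n - ints$end + 1L
        e <- n - ints$start + 1L
        ints$start <- s; ints$end <- e
      }
      ints$strand <- st
      res[[st]] <- ints
    }
  }
  if (!length(res)) {
    gr <- GenomicRanges::GRanges(seqnames = character(),
                                 ranges = IRanges::IRanges(),
                                 strand = character())
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(tss = integer(),
                                                 tts = integer(),
                                                 truncated = logical())
    return(gr)
  }
  tab <- do.call(rbind, res)
  GenomicRanges::GRanges(
    seqnames = .CHROM,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    tss = as.integer(ifelse(tab$strand == "+", tab$start, tab$end)),
    tts = as.integer(ifelse(tab$strand == "+", tab$end, tab$start)),
    truncated = tab$truncated)
}

## leftmost unmatched start opens an interval; the first end at or after
## it closes it; an unmatched trailing start truncates at the edge
.pairBoundaries <- function(starts, ends, n) {
  out <- list()
  i <- 1L
  while (i <= length(starts)) {
    open <- starts[i]
    ends <- ends[ends >= open]
    if (length(ends)) {
      e <- ends[1L]
      out[[length(out) + 1L]] <- data.frame(start = open, end = e,
                                            truncated = FALSE)
      while (i <= length(starts) && starts[i] <= e) i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(start = open, end = n,
                                            truncated = TRUE)
      break
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      truncated = logical()))
  do.call(rbind, out)
}
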