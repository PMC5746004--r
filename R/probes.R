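#' Design tiling probes over a genome
#'
#' Probes of `probeLen` bp are laid from position 1 with a sliding step
#' of `step` bp (defaults 60 / 22, the classic two-channel tiling
#' design); only probes fully inside the genome are kept, and the same
#' tiling is mirrored on the minus strand, so the total probe count is
#' twice the per-strand count.
#'
#' @param genomeLength genome length in bp.
#' @param probeLen probe length in bp (default 60).
#' @param step sliding-window step in bp (default 22).
#' @return a `GRanges` with a `probe_id` column, sorted by strand then
#'   start.
#' @examples
#' designProbes(104)   # 3 probes per strand, starting at 1, 23, 45
#' @export
designProbes <- function(genomeLength, probeLen = 60L, step = 22L) {
  stopifnot(probeLen >= step, step >= 1L)
  genomeLength <- as.integer(genomeLength)
  if (genomeLength < probeLen) {
    warning("genome shorter than one probe; empty design")
    starts <- integer()
  } else {
    starts <- seq.int(1L, genomeLength - probeLen + 1L, by = step)
  }
  n <- length(starts)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges(seqnames = character(),
                                 ranges = IRanges::IRanges(),
                                 strand = character(), probe_id = character())
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = .CHROM,
    ranges = IRanges::IRanges(start = rep(starts, 2L), width = probeLen),
    strand = rep(c("+", "-"), each = n),
    probe_id = c(sprintf("probe_p_%05d", seq_len(n)),
                 sprintf("probe_m_%05d", seq_len(n))))
  GenomeInfoDb::seqlengths(gr) <- setNames(genomeLength, .CHROM)
  gr
}

#' Call significantly transcribed probes against the gDNA baseline
#'
#' Computes per-probe `log2(mRNA / gDNA)` ratios, tests each one-sided
#' against a null whose location and scale are robustly estimated from
#' the genome-wide log-ratio distribution (median / MAD), corrects with
#' Benjamini-Hochberg, and flags probes significant when the q-value is
#' at or below `fdr` *and* the ratio is positive.  Probes overlapping an
#' optional repeat mask are excluded from testing.
#'
#' @param measurements `data.frame` with columns `probe_id`, `strand`,
#'   `start`, `end`, `gdna`, `mrna` (both channels strictly positive).
#' @param fdr FDR threshold on BH q-values (default `1e-4`).
#' @param mask optional `GRanges` of repeat regions; overlapping probes
#'   are flagged `masked` and never called significant.
#' @return the input with added columns `log2_ratio`, `p`, `q`,
#'   `significant`, `masked`.
#' @export
callProbes <- function(measurements, fdr = 1e-4, mask = NULL) {
  req <- c("probe_id", "strand", "start", "end", "gdna", "mrna")
  stopifnot(all(req %in% names(measurements)))
  bad <- measurements$gdna <= 0 | measurements$mrna <= 0
  if (any(bad))
    stop("non-positive channel value for probe(s): ",
         paste(head(measurements$probe_id[bad], 5L), collapse = ", "))
  x <- measurements
  x$masked <- FALSE
  if (!is.null(mask) && length(mask)) {
    gr <- GenomicRanges::GRanges(.CHROM,
                                 IRanges::IRanges(x$start, x$end), x$strand)
    x$masked <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
  }
  x$log2_ratio <- log2(x$mrna / x$gdna)
  use <- !x$masked
  lr <- x$log2_ratio[use]
  loc <- median(lr)
  sc <- mad(lr)
  if (is.na(sc) || sc == 0) sc <- 1e-8   # noiseless input: any excess calls
  z <- (lr - loc) / sc
  p <- pnorm(z, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  x$p <- x$q <- NA_real_
  x$p[use] <- p
  x$q[use] <- q
  x$significant <- FALSE
  x$significant[use] <- q <= fdr & x$log2_ratio[use] > 0
  x
}

#' Merge significant probes into transcribed segments
#'
#' Within each strand, maximal runs of significant probes become
#' transcribed segments; up to `maxGapProbes` consecutive
#' non-significant probes are tolerated inside a run (isolated dropouts).
#' A segment spans from the first base of its first significant probe to
#' the last base of its last significant probe; `mean_fc` is the mean of
#' `2^log2_ratio` over the significant member probes.
#'
#' @param calls output of [callProbes()].
#' @param maxGapProbes maximum run of interior non-significant probes
#'   bridged (default 1).
#' @return a `GRanges` with columns `segment_id`, `mean_fc`, `n_probes`.
#' @export
segmentProbes <- function(calls, maxGapProbes = 1L) {
  segs <- list()
  for (st in c("+", "-")) {
    d <- calls[calls$strand == st, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    sig <- which(d$significant)
    if (!length(sig)) next
    grp <- cumsum(c(1L, diff(sig) > maxGapProbes + 1L))
    for (g in split(sig, grp)) {
      segs[[length(segs) + 1L]] <- data.frame(
        strand = st,
        start = d$start[g[1L]],
        end = d$end[g[length(g)]],
        mean_fc = mean(2^d$log2_ratio[g]),
        n_probes = length(g))
    }
  }
  if (!length(segs)) {
    gr <- GenomicRanges::GRanges(seqnames = character(),
                                 ranges = IRanges::IRanges(),
                                 strand = character())
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(segment_id = character(),
                                                 mean_fc = numeric(),
                                                 n_probes = integer())
    return(gr)
  }
  tab <- do.call(rbind, segs)
  tab <- tab[order(tab$strand, tab$start), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = .CHROM,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    segment_id = sprintf("seg_%03d", seq_len(nrow(tab))),
    mean_fc = tab$mean_fc,
    n_probes = as.integer(tab$n_probes))
}
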