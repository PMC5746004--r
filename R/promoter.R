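## windows (character vector, equal length) -> n x L integer matrix 1..4
.encodeWindows <- function(windows) {
  windows <- toupper(as.character(windows))
  L <- unique(nchar(windows))
  if (length(L) != 1L)
    stop("all windows must have equal length")
  m <- matrix(match(unlist(strsplit(windows, "")), .BASES),
              nrow = length(windows), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("windows must contain only A/C/G/T")
  m
}

## per-window score of every 6-mer start under a 4 x 6 log matrix
.hexamerScores <- function(m, lo) {
  n <- nrow(m); L <- ncol(m)
  nPos <- L - 5L
  s <- matrix(0, n, nPos)
  for (k in 0:5)
    s <- s + matrix(lo[cbind(as.vector(m[, (1L + k):(nPos + k)]),
                             k + 1L)], n, nPos)
  s
}

## legal (i35, spacer, i10) placements inside a window of length L
.placements <- function(L, spacerRange) {
  grid <- expand.grid(i35 = seq_len(L), s = spacerRange[1]:spacerRange[2])
  grid$i10 <- grid$i35 + 6L + grid$s
  grid[grid$i10 + 5L <= L, , drop = FALSE]
}

.informationContent <- function(pwm, bg) {
  sum(pwm * log2(pwm / bg))
}

## one constrained EM run from a given initialization
.emFit <- function(m, pl, bg, sLevels, pwm10, pwm35, pseudocount,
                   maxIter, tol) {
  n <- nrow(m); L <- ncol(m); nP <- nrow(pl)
  spacerP <- setNames(rep(1 / length(sLevels), length(sLevels)), sLevels)
  post <- matrix(1 / nP, n, nP)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lo35 <- log(pwm35 / bg)
    lo10 <- log(pwm10 / bg)
    s35 <- .hexamerScores(m, lo35)
    s10 <- .hexamerScores(m, lo10)
    sc <- s35[, pl$i35, drop = FALSE] + s10[, pl$i10, drop = FALSE] +
      matrix(log(spacerP[as.character(pl$s)]), n, nP, byrow = TRUE)
    mx <- apply(sc, 1L, max)
    w <- exp(sc - mx)
    newPost <- w / rowSums(w)
    ll <- sum(mx + log(rowSums(w)))
    delta <- max(abs(newPost - post))
    post <- newPost
    # M-step: accumulate posterior mass per window x box-start, then
    # read counts off shifted base-indicator matrices
    w35 <- w10 <- matrix(0, n, L)
    for (p in seq_len(nP)) {
      w35[, pl$i35[p]] <- w35[, pl$i35[p]] + post[, p]
      w10[, pl$i10[p]] <- w10[, pl$i10[p]] + post[, p]
    }
    c35 <- c10 <- matrix(pseudocount, 4L, 6L, dimnames = list(.BASES, NULL))
    for (b in 1:4) {
      mb <- m == b
      for (k in 0:5) {
        shift <- cbind(mb[, (1L + k):L, drop = FALSE],
                       matrix(FALSE, n, k))
        c35[b, k + 1L] <- c35[b, k + 1L] + sum(w35 * shift)
        c10[b, k + 1L] <- c10[b, k + 1L] + sum(w10 * shift)
      }
    }
    pwm35 <- sweep(c35, 2L, colSums(c35), "/")
    pwm10 <- sweep(c10, 2L, colSums(c10), "/")
    sTot <- vapply(sLevels, function(s) sum(post[, pl$s == s]),
                   numeric(1)) + pseudocount
    spacerP <- setNames(sTot / sum(sTot), sLevels)
    if (delta < tol || iter >= maxIter) break
  }
  list(pwm35 = pwm35, pwm10 = pwm10, spacerP = spacerP, ll = ll,
       iter = iter)
}

## full fitting procedure (enrichment-seeded restarts + one-column
## shift refinement); used identically for the real windows and for the
## shuffled-input null of the information check
.fitWithRestarts <- function(m, pl, bg, sLevels, pseudocount, maxIter,
                             tol) {
  n <- nrow(m); L <- ncol(m)
  hex <- character()
  for (i in seq_len(n))
    hex <- c(hex, substring(paste(.BASES[m[i, ]], collapse = ""),
                            seq_len(L - 5L), 6:L))
  counts <- table(hex)
  counts <- counts[counts >= max(3L, n %/% 10L)]
  pHex <- vapply(names(counts), function(h)
    prod(bg[strsplit(h, "")[[1]]]), numeric(1))
  enrich <- as.numeric(counts) / (length(hex) * pHex)
  seeds <- head(names(counts)[order(-enrich)], 5L)
  if (!length(seeds))   # tiny inputs: fall back to raw frequency
    seeds <- head(names(sort(table(hex), decreasing = TRUE)), 3L)

  softPwm <- function(hexamer) {
    p <- matrix((1 - 0.7) / 3, 4L, 6L, dimnames = list(.BASES, NULL))
    b <- match(strsplit(hexamer, "")[[1]], .BASES)
    p[cbind(b, 1:6)] <- 0.7
    p
  }
  uniform <- matrix(0.25, 4L, 6L, dimnames = list(.BASES, NULL))

  best <- NULL
  for (seed in seeds) {
    fit <- .emFit(m, pl, bg, sLevels, softPwm(seed), uniform,
                  pseudocount, maxIter, tol)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  # shift refinement: the commonest local optimum misaligns one box by a
  # single column (compensated by the spacer); refit from +/-1-shifted
  # initializations of the best solution and keep the highest likelihood
  shift1 <- function(p, dir) {
    q <- matrix(0.25, 4L, 6L, dimnames = dimnames(p))
    if (dir > 0) q[, 2:6] <- p[, 1:5] else q[, 1:5] <- p[, 2:6]
    q
  }
  for (dir in c(-1L, 1L)) {
    for (box in c("pwm35", "pwm10")) {
      init35 <- if (box == "pwm35") shift1(best$pwm35, dir) else best$pwm35
      init10 <- if (box == "pwm10") shift1(best$pwm10, dir) else best$pwm10
      fit <- .emFit(m, pl, bg, sLevels, init10, init35, pseudocount,
                    min(maxIter, 100L), tol)
      if (fit$ll > best$ll) best <- fit
    }
  }
  best
}

## deterministic base shuffle of each window (null for the information
## check); caller RNG state is left untouched
.shuffleWindows <- function(m) {
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(190283L)
  t(apply(m, 1L, sample))
}

#' Learn a two-box promoter model by constrained EM
#'
#' Fits position-weight matrices for the -35 and -10 hexamers plus an
#' empirical spacer-length distribution to a set of equal-length
#' upstream windows (strand-oriented, ending at the TSS-proximal edge).
#' The E-step enumerates every legal placement of the two boxes with a
#' spacer inside `spacerRange` and computes placement posteriors; the
#' M-step re-estimates both matrices (with pseudocounts) and the spacer
#' distribution.  Iteration stops when placement posteriors move less
#' than `tol`.  Up to five deterministic restarts are seeded from the
#' hexamers most enriched over their background expectation and the
#' highest-likelihood fit is kept, so the same windows always yield the
#' same model.
#'
#' The scan threshold stored in the model is the 5th percentile of the
#' best placement score over the training windows.  Because EM sharpens
#' on some alignment even of pure noise, the low-information flag
#' compares the achieved PWM information content against a fit on
#' base-shuffled windows: a model below 1.2 times that null is flagged
#' (with a warning) as carrying no common two-box motif (shuffled input
#' sits at 1.0 by construction; an exact planted consensus exceeds 3).
#'
#' @param windows character vector or `DNAStringSet` of equal-length
#'   (>= 45 bp) upstream windows; at least 10 are required.  If more
#'   than `nTrain` are supplied the first `nTrain` are used (order the
#'   input by decreasing expression).
#' @param nTrain training-set size (default 75).
#' @param spacerRange allowed spacer lengths (default 14-20 bp).
#' @param pseudocount added to PWM counts (default 0.5).
#' @param maxIter,tol EM iteration cap and posterior-change tolerance.
#' @param spacerPenaltyPerBp scan-time log-odds cost per bp of spacer
#'   deviation from 17 (default 0.25).
#' @param thresholdQuantile quantile of training scores used as the scan
#'   threshold (default 0.05).
#' @return a [PromoterModel-class].
#' @examples
#' win <- replicate(12, paste0(
#'   paste(sample(c("A","C","G","T"), 20, TRUE), collapse = ""),
#'   "TTGACA", paste(sample(c("A","C","G","T"), 17, TRUE), collapse = ""),
#'   "TATAAT", paste(sample(c("A","C","G","T"), 9, TRUE), collapse = "")))
#' modelConsensus(learnPromoterModel(win))
#' @export
learnPromoterModel <- function(windows, nTrain = 75L,
                               spacerRange = c(14L, 20L),
                               pseudocount = 0.5, maxIter = 200L,
                               tol = 1e-6, spacerPenaltyPerBp = 0.25,
                               thresholdQuantile = 0.05) {
  windows <- as.character(windows)
  if (length(windows) < 10L)
    stop("at least 10 training windows are required (got ",
         length(windows), ")")
  if (length(windows) > nTrain) windows <- windows[seq_len(nTrain)]
  m <- .encodeWindows(windows)
  L <- ncol(m)
  if (L < 45L) stop("windows must be at least 45 bp")
  n <- nrow(m)

  bg <- tabulate(m, 4L) + pseudocount
  bg <- bg / sum(bg)
  names(bg) <- .BASES
  pl <- .placements(L, spacerRange)
  nP <- nrow(pl)
  sLevels <- spacerRange[1]:spacerRange[2]

  best <- .fitWithRestarts(m, pl, bg, sLevels, pseudocount, maxIter, tol)

  lo35 <- log2(best$pwm35 / bg)
  lo10 <- log2(best$pwm10 / bg)
  # scan-style best placement score per training window
  s35 <- .hexamerScores(m, lo35)
  s10 <- .hexamerScores(m, lo10)
  pen <- -spacerPenaltyPerBp * abs(pl$s - 17L)
  scanSc <- s35[, pl$i35, drop = FALSE] + s10[, pl$i10, drop = FALSE] +
    matrix(pen, n, nrow(pl), byrow = TRUE)
  trainScores <- apply(scanSc, 1L, max)
  # low-information check: EM always sharpens on *some* alignment, so an
  # absolute information cutoff cannot separate motif-bearing input from
  # noise; instead the achieved information content is compared with the
  # identical fitting procedure applied to base-shuffled windows (same
  # composition, no shared motif), where the ratio sits at 1 by
  # construction.
  ic <- .informationContent(best$pwm10, bg) +
    .informationContent(best$pwm35, bg)
  mShuf <- .shuffleWindows(m)
  nullFit <- .fitWithRestarts(mShuf, pl, bg, sLevels, pseudocount,
                              maxIter, tol)
  icNull <- .informationContent(nullFit$pwm10, bg) +
    .informationContent(nullFit$pwm35, bg)
  lowInfo <- ic < 1.2 * icNull
  if (lowInfo)
    warning("promoter model is low-information (", round(ic, 2),
            " bits vs ", round(icNull, 2), " on shuffled input); the ",
            "windows may carry no common motif")

  new("PromoterModel",
      pwm35 = best$pwm35, pwm10 = best$pwm10,
      logodds35 = lo35, logodds10 = lo10,
      spacerProbs = best$spacerP, background = bg,
      spacerPenaltyPerBp = spacerPenaltyPerBp, spacerModeRef = 17L,
      threshold = unname(quantile(trainScores, thresholdQuantile)),
      trainScores = trainScores,
      lowInformation = lowInfo,
      logLik = best$ll, iterations = best$iter)
}

#' Scan an upstream window for the best two-box promoter placement
#'
#' Scores every legal placement of the -35 and -10 hexamers (spacer
#' within the model's range) as `logodds35 + logodds10 -
#' penalty * |spacer - 17|` and returns the maximum.  Ties are broken
#' toward the spacer closer to 17 bp, then toward the -10 box closer to
#' the TSS-proximal window edge.  No call is returned when the best
#' score falls below the model threshold or the window is shorter than
#' the minimal legal layout.
#'
#' @param window a single character string (or `DNAString`), oriented
#'   5'->3' on the TU strand, ending at the TSS-proximal edge.
#' @param model a [PromoterModel-class].
#' @param spacerRange legal spacer lengths (default 14-20).
#' @return one-row `data.frame` with `pos35`, `pos10` (1-based starts
#'   within the window), `spacer_len`, `dist10_tss` (bp from the -10
#'   hexamer end to the position just past the window end, i.e. the
#'   TSS), and `score`; or `NULL` when no placement qualifies.
#' @export
scanPromoter <- function(window, model, spacerRange = c(14L, 20L)) {
  window <- as.character(window)
  L <- nchar(window)
  if (L < 45L) {
    warning("window shorter than the minimal promoter layout (45 bp)")
    return(NULL)
  }
  m <- .encodeWindows(window)
  pl <- .placements(L, spacerRange)
  s35 <- .hexamerScores(m, model@logodds35)
  s10 <- .hexamerScores(m, model@logodds10)
  sc <- s35[1L, pl$i35] + s10[1L, pl$i10] -
    model@spacerPenaltyPerBp * abs(pl$s - model@spacerModeRef)
  dist10 <- L - (pl$i10 + 5L) + 1L
  ord <- order(-sc, abs(pl$s - model@spacerModeRef), dist10)
  top <- ord[1L]
  if (sc[top] < model@threshold) return(NULL)
  data.frame(pos35 = pl$i35[top], pos10 = pl$i10[top],
             spacer_len = pl$s[top],
             dist10_tss = dist10[top],
             score = sc[top])
}

#' Extract the promoter feature set around a call
#'
#' Assembles the canonical feature window - 24 bp upstream of the -35
#' hexamer through 9 bp downstream of the -10 hexamer, 62 bp at the
#' 17-bp modal spacer - and computes the classifier features: spacer
#' length, leader length (TSS to gene start), AT fractions of the five
#' sub-regions, and the 62-column gapped alignment of the window
#' (spacers shorter than 17 bp are centre-padded with `-`, longer ones
#' centre-trimmed).
#'
#' @param call one-row `data.frame` from [scanPromoter()] whose `pos35`
#'   / `pos10` are *genomic* starts of the hexamers on the TU strand.
#' @param tss TSS genomic position; @param geneStart genomic start of
#'   the first gene (strand-aware); may be `NA` for gene-free units.
#' @param genome a `DNAStringSet` (first sequence used).
#' @param strand `"+"` or `"-"`.
#' @return one-row `data.frame`: `spacer_len`, `leader_len`, `at_up35`,
#'   `at_35`, `at_spacer`, `at_10`, `at_down10`, `aligned_bases`
#'   (62-character string), `window_len`.
#' @export
extractPromoterFeatures <- function(call, tss, geneStart, genome, strand) {
  s <- call$spacer_len
  gl <- Biostrings::width(genome)[1L]
  if (strand == "+") {
    from <- call$pos35 - 24L
    to <- call$pos10 + 5L + 9L
  } else {
    from <- call$pos10 - 9L
    to <- call$pos35 + 5L + 24L
  }
  if (from < 1L || to > gl)
    stop("promoter feature window runs off the contig")
  seq <- .senseSeq(genome, from, to, strand)
  # layout within the sense window
  up35 <- substr(seq, 1L, 24L)
  box35 <- substr(seq, 25L, 30L)
  spacer <- substr(seq, 31L, 30L + s)
  box10 <- substr(seq, 31L + s, 36L + s)
  down10 <- substr(seq, 37L + s, 45L + s)
  atF <- function(x) {
    b <- strsplit(x, "")[[1]]
    mean(b %in% c("A", "T"))
  }
  aligned <- paste0(up35, box35, .alignSpacer(spacer, 17L), box10, down10)
  leader <- if (is.na(geneStart)) NA_integer_
    else as.integer(if (strand == "+") geneStart - tss else tss - geneStart)
  data.frame(spacer_len = s,
             leader_len = leader,
             at_up35 = atF(up35), at_35 = atF(box35),
             at_spacer = atF(spacer), at_10 = atF(box10),
             at_down10 = atF(down10),
             aligned_bases = aligned,
             window_len = nchar(seq))
}

## centre-pad (with '-') or centre-trim a spacer string to `target` cols
.alignSpacer <- function(spacer, target = 17L) {
  s <- nchar(spacer)
  if (s == target) return(spacer)
  if (s < target) {
    left <- ceiling(s / 2)
    paste0(substr(spacer, 1L, left),
           strrep("-", target - s),
           substr(spacer, left + 1L, s))
  } else {
    left <- ceiling(target / 2)
    paste0(substr(spacer, 1L, left),
           substr(spacer, s - (target - left) + 1L, s))
  }
}

## sense-oriented subsequence [from, to] of the first genome sequence
.senseSeq <- function(genome, from, to, strand) {
  x <- Biostrings::subseq(genome[[1L]], from, to)
  if (strand == "-") x <- Biostrings::reverseComplement(x)
  as.character(x)
}

#' Training windows upstream of TU starts
#'
#' Extracts equal-length sense-oriented windows ending at the base just
#' upstream of each TU's TSS, dropping TUs whose window would run off
#' the contig.  Order the input by decreasing fold change to feed
#' [learnPromoterModel()] its high/medium training set.
#'
#' @param genome `DNAStringSet`; @param tss,strand vectors per TU.
#' @param width window width (default 100).
#' @return character vector of windows, named by TU index.
#' @export
upstreamWindows <- function(genome, tss, strand, width = 100L) {
  gl <- Biostrings::width(genome)[1L]
  out <- character(0)
  for (i in seq_along(tss)) {
    if (strand[i] == "+") {
      from <- tss[i] - width; to <- tss[i] - 1L
    } else {
      from <- tss[i] + 1L; to <- tss[i] + width
    }
    if (from < 1L || to > gl) next
    out[as.character(i)] <- .senseSeq(genome, from, to, strand[i])
  }
  out
}

#' Call promoters for a set of TUs
#'
#' Learns nothing: applies [scanPromoter()] to the upstream window of
#' every TU (window ending at the TSS; for TUs whose TSS comes from the
#' array alone the window is extended one probe length downstream, since
#' an array TSS overhangs the true start by up to one probe) and maps
#' calls back to genomic coordinates.
#'
#' @param tus `GRanges` from [assembleTUs()] (or truth).
#' @param genome `DNAStringSet`.
#' @param model [PromoterModel-class].
#' @param windowLen scan window length (default 100).
#' @param probeLen downstream extension for array-only TSSs (default 60).
#' @return `GRanges` of promoter calls (span -35 start to -10 end) with
#'   `tu_id`, `pos35`, `pos10` (genomic hexamer starts), `spacer_len`,
#'   `dist10_tss`, `score` and the feature columns of
#'   [extractPromoterFeatures()].
#' @export
callPromoters <- function(tus, genome, model, windowLen = 100L,
                          probeLen = 60L) {
  gl <- Biostrings::width(genome)[1L]
  rows <- list()
  for (i in seq_along(tus)) {
    st <- as.character(BiocGenerics::strand(tus[i]))
    tss <- tus$tss[i]
    ext <- if (!is.null(tus$tss_source) && tus$tss_source[i] == "array")
      probeLen else 0L
    anchor <- if (st == "+") min(tss + ext, gl + 1L) else max(tss - ext, 0L)
    if (st == "+") { from <- anchor - windowLen; to <- anchor - 1L }
    else { from <- anchor + 1L; to <- anchor + windowLen }
    if (from < 1L || to > gl) next
    win <- .senseSeq(genome, from, to, st)
    call <- scanPromoter(win, model)
    if (is.null(call)) next
    # window index -> genomic start of each hexamer
    if (st == "+") {
      g35 <- from + call$pos35 - 1L
      g10 <- from + call$pos10 - 1L
    } else {
      g35 <- to - (call$pos35 + 5L) + 1L
      g10 <- to - (call$pos10 + 5L) + 1L
    }
    gcall <- data.frame(pos35 = g35, pos10 = g10,
                        spacer_len = call$spacer_len)
    geneStart <- if (!is.null(tus$first_gene_start)) tus$first_gene_start[i]
      else NA_integer_
    feats <- tryCatch(
      extractPromoterFeatures(gcall, tss, geneStart, genome, st),
      error = function(e) NULL)
    if (is.null(feats)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(tu_id = tus$tu_id[i], strand = st,
                 start = min(g35, g10), end = max(g35, g10) + 5L,
                 pos35 = g35, pos10 = g10,
                 dist10_tss = if (st == "+") tss - (g10 + 5L)
                   else g10 - tss,
                 score = call$score,
                 class = if (!is.null(tus$class)) tus$class[i]
                   else NA_character_),
      feats[, setdiff(names(feats), "spacer_len")],
      data.frame(spacer_len = call$spacer_len))
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges(seqnames = character(),
                                 ranges = IRanges::IRanges(),
                                 strand = character())
    return(gr)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = .CHROM,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tab[, setdiff(names(tab), c("strand", "start", "end"))])
  gr
}
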