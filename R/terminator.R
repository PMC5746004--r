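.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## is x[i] a Watson-Crick partner of x[j] (optionally G.T wobble)?
.pairs <- function(a, b, wobble = FALSE) {
  ok <- .COMP[a] == b
  if (wobble)
    ok <- ok | (a == "G" & b == "T") | (a == "T" & b == "G")
  unname(ok)
}

## longest run of `base` starting at position i (0 if x[i] != base)
.runLenAt <- function(x, i, base) {
  n <- 0L
  while (i + n <= length(x) && x[i + n] == base) n <- n + 1L
  n
}

#' Detect rho-independent terminators in a 3' window
#'
#' Enumerates hairpins by seed-and-extend: every loop placement (loop
#' length within `loopRange`) whose innermost flanking bases pair is
#' extended outwards while Watson-Crick pairing holds, allowing at most
#' one internal mismatch, and trimmed to end on a matching pair.
#' Hairpins with stem length >= `minStem` and stem GC fraction >=
#' `minGC` are kept; a full terminator call additionally requires a run
#' of >= `minPolyT` T's (in strand sense) starting at most `maxGap`
#' bases after the 3' stem arm.  A polyA run of >= `minPolyT` ending at
#' most `maxGap` bases before the 5' arm is detected symmetrically and,
#' when present together with the polyT, marks the call bidirectional.
#' Overlapping calls are resolved preferring polyT-bearing, then
#' bidirectional, then maximum-score calls, with
#' `score = stem_len + 2 * (GC pairs) - 0.5 * loop_len` (an alternative
#' fold of the same region can pair the polyA run against the polyT run
#' and would otherwise swallow both signals).
#'
#' @param sequence the 3' window as a character string (or
#'   `DNAString`), already oriented in transcription sense.
#' @param minStem minimum paired stem length (default 6).
#' @param minGC minimum stem GC fraction (default 0.5).
#' @param loopRange allowed loop lengths (default 3-10).
#' @param minPolyT minimum T-run length (default 4).
#' @param maxGap maximum gap between 3' arm and polyT (default 3).
#' @param requirePolyT when FALSE, bare stem-loops (no polyT) are also
#'   returned with `polyT_start = NA` (used to classify pause-like
#'   stem-loop-only termination).
#' @param wobble allow G.T wobble pairs (default FALSE).
#' @return `data.frame`, one row per call, with 1-based window-relative
#'   coordinates: `stem5_start`, `stem_len`, `loop_len`, `stem3_end`,
#'   `stem_gc`, `polyT_start`, `polyT_len`, `polyA_start`, `polyA_len`,
#'   `bidirectional`, `has_polyT`, `score`.
#' @examples
#' findTerminators(paste0("AAAAA", "GCGCGCGC", "TTTT", "GCGCGCGC",
#'                        "TTTTTT"))   # bidirectional
#' @export
findTerminators <- function(sequence, minStem = 6L, minGC = 0.5,
                            loopRange = c(3L, 10L), minPolyT = 4L,
                            maxGap = 3L, requirePolyT = TRUE,
                            wobble = FALSE) {
  x <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(x)
  calls <- list()
  for (loopLen in loopRange[1]:loopRange[2]) {
    for (loopStart in 2:(n - loopLen)) {
      a <- loopStart - 1L          # innermost 5' base
      b <- loopStart + loopLen     # innermost 3' base
      if (b > n) next
      # extend outwards while pairing holds (at most one internal
      # mismatch), emitting a candidate at every matching depth: a
      # hairpin followed by a T-run would otherwise be extended through
      # its own polyA/polyT flanks (A.T pairs) and lose the run
      k <- 0L; mism <- 0L
      matchDepths <- integer()
      while (a - k >= 1L && b + k <= n) {
        if (.pairs(x[a - k], x[b + k], wobble)) {
          matchDepths <- c(matchDepths, k)
        } else {
          mism <- mism + 1L
          if (mism > 1L) break
        }
        k <- k + 1L
      }
      for (lastMatch in matchDepths) {
        stemLen <- lastMatch + 1L
        if (stemLen < minStem) next
        s5 <- a - lastMatch; s3 <- b + lastMatch
        arm5 <- x[s5:a]; arm3 <- x[b:s3]
        gc <- mean(c(arm5, arm3) %in% c("G", "C"))
        if (gc < minGC) next
        gcPairs <- sum(.pairs(arm5, rev(arm3), wobble) &
                         arm5 %in% c("G", "C"))
        score <- stemLen + 2 * gcPairs - 0.5 * loopLen
        # polyT within maxGap after the 3' arm
        polyT <- c(NA_integer_, NA_integer_)
        for (g in 0:maxGap) {
          i <- s3 + 1L + g
          if (i > n) break
          len <- .runLenAt(x, i, "T")
          if (len >= minPolyT) { polyT <- c(i, len); break }
        }
        # polyA ending within maxGap before the 5' arm
        polyA <- c(NA_integer_, NA_integer_)
        for (g in 0:maxGap) {
          j <- s5 - 1L - g         # last base of a candidate A-run
          if (j < 1L) break
          if (x[j] != "A") next
          len <- 0L
          while (j - len >= 1L && x[j - len] == "A") len <- len + 1L
          if (len >= minPolyT) { polyA <- c(j - len + 1L, len); break }
        }
        hasT <- !is.na(polyT[1L])
        if (requirePolyT && !hasT) next
        calls[[length(calls) + 1L]] <- data.frame(
          stem5_start = s5, stem_len = stemLen, loop_len = loopLen,
          stem3_end = s3, stem_gc = gc,
          polyT_start = polyT[1L], polyT_len = polyT[2L],
          polyA_start = polyA[1L], polyA_len = polyA[2L],
          bidirectional = hasT && !is.na(polyA[1L]),
          has_polyT = hasT,
          score = score)
      }
    }
  }
  empty <- data.frame(stem5_start = integer(), stem_len = integer(),
                      loop_len = integer(), stem3_end = integer(),
                      stem_gc = numeric(), polyT_start = integer(),
                      polyT_len = integer(), polyA_start = integer(),
                      polyA_len = integer(), bidirectional = logical(),
                      has_polyT = logical(), score = numeric())
  if (!length(calls)) return(empty)
  tab <- unique(do.call(rbind, calls))
  # resolve overlapping hairpins: a polyT-bearing call beats any bare
  # alternative fold of the same region, a bidirectional call beats a
  # one-sided one (alternative folds eat into the polyA/polyT runs),
  # then higher score wins
  tab <- tab[order(-tab$has_polyT, -tab$bidirectional, -tab$score,
                   tab$stem5_start), , drop = FALSE]
  kept <- logical(0)
  sel <- list()
  occupied <- IRanges::IRanges()
  for (r in seq_len(nrow(tab))) {
    span <- IRanges::IRanges(tab$stem5_start[r], tab$stem3_end[r])
    if (!any(IRanges::overlapsAny(span, occupied))) {
      sel[[length(sel) + 1L]] <- tab[r, ]
      occupied <- c(occupied, span)
    }
  }
  out <- do.call(rbind, sel)
  out[order(out$stem5_start), , drop = FALSE]
}

#' Classify the termination strategy of each TU
#'
#' Searches the 3' region of every TU (from its last gene end, or TTS
#' minus `searchBp` for gene-free units, to `searchBp` past the TTS) for
#' hairpins and classifies: `rho_independent` when a full hairpin+polyT
#' call ends within `ttsWindow` bp of the TTS; `stem_loop_only` when
#' only a bare hairpin does (pause-like GC-rich stem-loops without the
#' polyT); `convergent_overlap` when neither is present but the 3'-UTR
#' overlaps the 3'-UTR of an opposite-strand (tail-to-tail) TU; `none`
#' otherwise.
#'
#' @param tus `GRanges` from [assembleTUs()] (needs `tss`, `tts`,
#'   `last_gene_end`).
#' @param genome `DNAStringSet`.
#' @param searchBp 3' search extension (default 200).
#' @param ttsWindow matching window around the TTS (default 30).
#' @param ... passed to [findTerminators()].
#' @return list with `tus` (the input with `termination_class` filled)
#'   and `calls` (a `GRanges` of terminator calls in genomic
#'   coordinates with `tu_id`, stem/polyT columns and `bidirectional`).
#' @export
classifyTermination <- function(tus, genome, searchBp = 200L,
                                ttsWindow = 30L, ...) {
  gl <- Biostrings::width(genome)[1L]
  classes <- rep("none", length(tus))
  callRows <- list()
  for (i in seq_along(tus)) {
    st <- as.character(BiocGenerics::strand(tus[i]))
    tts <- tus$tts[i]
    lge <- tus$last_gene_end[i]
    if (st == "+") {
      from <- if (!is.na(lge)) lge + 1L else max(1L, tts - searchBp)
      to <- min(gl, tts + searchBp)
    } else {
      to <- if (!is.na(lge)) lge - 1L else min(gl, tts + searchBp)
      from <- max(1L, tts - searchBp)
    }
    if (to - from + 1L < 20L) next
    win <- .senseSeq(genome, from, to, st)
    calls <- findTerminators(win, requirePolyT = FALSE, ...)
    if (nrow(calls)) {
      # window-relative (sense) -> genomic coordinates
      L <- nchar(win)
      sense2gen <- function(p) if (st == "+") from + p - 1L else to - p + 1L
      gEnd3 <- sense2gen(ifelse(calls$has_polyT,
                                calls$polyT_start + calls$polyT_len - 1L,
                                calls$stem3_end))
      near <- abs(gEnd3 - tts) <= ttsWindow |
        abs(sense2gen(calls$stem3_end) - tts) <= ttsWindow
      full <- calls$has_polyT & near
      bare <- !calls$has_polyT & near
      if (any(full)) classes[i] <- "rho_independent"
      else if (any(bare)) classes[i] <- "stem_loop_only"
      keep <- which(if (any(full)) full else near)
      for (r in keep) {
        g1 <- sense2gen(ifelse(is.na(calls$polyA_start[r]),
                               calls$stem5_start[r], calls$polyA_start[r]))
        g2 <- gEnd3[r]
        callRows[[length(callRows) + 1L]] <- data.frame(
          tu_id = tus$tu_id[i], strand = st,
          start = min(g1, g2), end = max(g1, g2),
          stem_len = calls$stem_len[r], loop_len = calls$loop_len[r],
          stem_gc = calls$stem_gc[r],
          has_polyT = calls$has_polyT[r],
          bidirectional = calls$bidirectional[r],
          score = calls$score[r])
      }
    }
  }
  # convergent 3'-UTR overlap for TUs with no terminal signal
  utr3start <- ifelse(as.character(BiocGenerics::strand(tus)) == "+",
                      ifelse(is.na(tus$last_gene_end), tus$tss,
                             tus$last_gene_end),
                      tus$tts)
  utr3end <- ifelse(as.character(BiocGenerics::strand(tus)) == "+",
                    tus$tts,
                    ifelse(is.na(tus$last_gene_end), tus$tss,
                           tus$last_gene_end))
  for (i in which(classes == "none")) {
    for (j in seq_along(tus)) {
      if (j == i) next
      if (as.character(BiocGenerics::strand(tus[i])) ==
          as.character(BiocGenerics::strand(tus[j]))) next
      if (utr3start[i] <= utr3end[j] && utr3start[j] <= utr3end[i]) {
        classes[i] <- "convergent_overlap"
        break
      }
    }
  }
  tus$termination_class <- classes
  if (length(callRows)) {
    tab <- do.call(rbind, callRows)
    calls <- GenomicRanges::GRanges(
      seqnames = .CHROM,
      ranges = IRanges::IRanges(tab$start, tab$end),
      strand = tab$strand)
    S4Vectors::mcols(calls) <- S4Vectors::DataFrame(
      tab[, setdiff(names(tab), c("strand", "start", "end"))])
  } else {
    calls <- GenomicRanges::GRanges(seqnames = character(),
                                    ranges = IRanges::IRanges(),
                                    strand = character())
  }
  list(tus = tus, calls = calls)
}

#' Summarize termination strategies
#'
#' Counts each termination class per expression class and reports the
#' rho-independent total and its percentage of all TUs (rounded to the
#' nearest integer), mirroring the bookkeeping used to report that
#' rho-independent terminators account for about half of termination
#' signals.
#'
#' @param tus `GRanges` with `class` and `termination_class` columns
#'   (may be zero-length).
#' @return list with `by_class` (termination class x expression class
#'   table), `class_totals`, `rho_independent_total`, `total_tus`,
#'   `rho_independent_pct` (NA when empty).
#' @examples
#' # 70/83 + 81/153 + 73/177 rho-independent -> 224 of 413 = 54%
#' @export
terminationSummary <- function(tus) {
  n <- length(tus)
  if (n == 0L)
    return(list(by_class = table(character()), class_totals = table(character()),
                rho_independent_total = 0L, total_tus = 0L,
                rho_independent_pct = NA_real_))
  expr <- factor(tus$class, levels = .CLASSES)
  term <- factor(tus$termination_class,
                 levels = c("rho_independent", "stem_loop_only",
                            "convergent_overlap", "none"))
  byClass <- table(termination = term, expression = expr)
  rho <- sum(term == "rho_independent")
  list(by_class = byClass,
       class_totals = table(expr),
       rho_independent_total = rho,
       total_tus = n,
       rho_independent_pct = round(100 * rho / n))
}
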