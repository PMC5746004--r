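#' Build a simulation configuration
#'
#' Constructor for [SimConfig-class] with desk-scale defaults: a 250 kb
#' chromosome at 59% GC carrying 20 transcriptional units per expression
#' class plus two gene-free sRNA-like units and four convergent pairs.
#' Promoter hexamers are planted as the vegetative consensus TTGACA /
#' TATAAT and degraded per class; rho-independent terminators (GC-rich
#' hairpin + polyT, optionally with a leading polyA) are planted on a
#' per-class fraction of units.
#'
#' The per-class -10 degradation rates (0.05 / 0.20 / 0.40 for high /
#' medium / low) apply to positions 1, 2 and 6 of the hexamer; positions
#' 3-5 are degraded at a class-independent floor so that, as in real
#' sigma-70 promoters, the first, second and sixth base of the -10 box
#' carry the class signal.  Substituted bases are drawn from the local
#' background composition, so degradation lowers the AT fraction of the
#' box on a GC-rich genome.
#'
#' @param genomeLength,gcFrac,seed see [SimConfig-class].
#' @param nTUsPerClass named integer vector over `high`, `medium`, `low`.
#' @param ... any other [SimConfig-class] slot, by name.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(genomeLength = 60000L,
#'                  nTUsPerClass = c(high = 5L, medium = 5L, low = 5L))
#' @export
simConfig <- function(genomeLength = 250000L,
                      gcFrac = 0.59,
                      nTUsPerClass = c(high = 20L, medium = 20L, low = 20L),
                      seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    gcIntergenicShift = 0.08,
    fcRanges = list(high = c(11, 28), medium = c(3, 10), low = c(1.5, 2.8)),
    utr5MeanByClass = c(high = 100, medium = 60, low = 60),
    utr5SdLog = 1.0,
    utr3Mean = 38,
    utr3Sd = 10,
    spacerRange = c(14L, 20L),
    spacerMode = 17L,
    spacerTauByClass = c(high = 0.5, medium = 1.2, low = 5),
    dist10Tss = 10L,
    promoterDegradationByClass = c(high = 0.05, medium = 0.20, low = 0.40),
    minus10MidDegradation = 0.35,
    minus35DegradationByClass = c(high = 0.18, medium = 0.25, low = 0.35),
    fracRhoIndependentByClass = c(high = 70 / 83, medium = 81 / 153,
                                  low = 73 / 177),
    nConvergentPairs = 4L,
    nIntergenicTUs = 2L,
    noiseSdLog2 = 0.2,
    coverageDepth = 10,
    backgroundCoverage = 0.05,
    fivePrimeTruncationMean = 20,
    covBiasPeriod = 300,
    covBiasAmplitude = 0.5,
    geneLenRange = c(400L, 900L),
    genesPerTURange = c(1L, 2L),
    intraGapRange = c(20L, 50L),
    interTUGapRange = c(200L, 450L)
  )
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown simConfig argument(s): ", paste(unknown, collapse = ", "))
  slots <- utils::modifyList(defaults, args)
  intSlots <- c("spacerRange", "spacerMode", "dist10Tss", "nConvergentPairs",
                "nIntergenicTUs", "geneLenRange", "genesPerTURange",
                "intraGapRange", "interTUGapRange")
  for (s in intSlots) slots[[s]] <- as.integer(slots[[s]])
  do.call(new, c(list("SimConfig",
                      genomeLength = as.integer(genomeLength),
                      gcFrac = gcFrac,
                      nTUsPerClass = setNames(
                        as.integer(nTUsPerClass[.CLASSES]), .CLASSES),
                      seed = as.integer(seed)),
                 slots))
}

.CHROM <- "synth_chr"
CONSENSUS35 <- "TTGACA"
CONSENSUS10 <- "TATAAT"

.baseProbs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                             G = gc / 2, T = (1 - gc) / 2)

.revcompChar <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

## substitute each consensus base with probability rate[i]; replacements
## drift toward the GC-rich genome background, so degradation erodes the
## AT content of the box
.degradeHexamer <- function(hex, rates, bgProbs) {
  bases <- strsplit(hex, "")[[1]]
  hit <- runif(6L) < rates
  for (i in which(hit)) {
    alt <- setdiff(c("C", "G"), bases[i])
    p <- bgProbs[alt]
    bases[i] <- if (length(alt) == 1L) alt else sample(alt, 1L, prob = p / sum(p))
  }
  bases
}

.sampleSpacer <- function(config, class) {
  s <- seq(config@spacerRange[1], config@spacerRange[2])
  w <- exp(-abs(s - config@spacerMode) / config@spacerTauByClass[[class]])
  sample(s, 1L, prob = w)
}

.minus10Rates <- function(config, class) {
  r <- rep(config@promoterDegradationByClass[[class]], 6L)
  # weakly conserved core: a high class-independent floor plus a damped
  # class effect, so positions 1, 2 and 6 carry most of the class signal
  r[3:5] <- pmin(0.65, config@minus10MidDegradation + 0.8 * r[3:5])
  r
}

## 5'-UTR lengths are heavy-tailed; log-normal with the configured mean
.sampleUtr5 <- function(config, class) {
  m <- config@utr5MeanByClass[[class]]
  sdl <- config@utr5SdLog
  max(25L, round(stats::rlnorm(1L, log(m) - sdl^2 / 2, sdl)))
}

## sample one hairpin + polyT block (sense orientation), returns a list
## with the base vector and within-block coordinates
.sampleTerminatorBlock <- function(withPolyA) {
  stemLen <- sample(6:8, 1L)
  repeat { # GC-rich stem arm, comfortably above the 0.5 detector minimum
    stem5 <- sample(.BASES, stemLen, replace = TRUE,
                    prob = c(A = .1, C = .4, G = .4, T = .1))
    if (mean(stem5 %in% c("G", "C")) >= 0.75) break
  }
  stem3 <- .revcompChar(stem5)
  loopLen <- sample(3:8, 1L)
  repeat { # loop must not extend the stem: flanks must not pair
    loop <- sample(.BASES, loopLen, replace = TRUE)
    ok <- loop[1] != .revcompChar(stem3[1]) &&
      loop[loopLen] != .revcompChar(stem5[stemLen])[1]
    if (ok) break
  }
  gap <- sample(0:2, 1L)
  gapBases <- if (gap > 0) sample(c("C", "G"), gap, replace = TRUE) else character()
  polyTLen <- sample(5:7, 1L)
  polyA <- if (withPolyA) rep("A", 5L) else character()
  bases <- c(polyA, stem5, loop, stem3, gapBases, rep("T", polyTLen))
  nA <- length(polyA)
  list(bases = bases,
       stemLen = stemLen, loopLen = loopLen,
       stem5Off = nA + 1L,                                  # 1-based offsets
       polyTOff = nA + 2L * stemLen + loopLen + gap + 1L,
       polyTLen = polyTLen,
       hasPolyA = withPolyA,
       len = length(bases))
}

#' Generate a synthetic genome with planted transcriptional truth
#'
#' Lays transcriptional units along a random high-GC chromosome
#' (intergenic regions more AT rich than coding), planting for each unit
#' its genes, a -35/-10 promoter degraded according to the unit's
#' expression class, and - for a per-class fraction of units - a
#' rho-independent terminator whose polyT run ends at the unit's TTS.
#' Convergent tail-to-tail pairs are planted with either a shared
#' bidirectional (polyA-stem-polyT) terminator or overlapping 3'-UTRs and
#' no terminator.  All randomness is governed by `config@seed`, so equal
#' configurations reproduce bit-identical output.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `genome` (a
#'   [Biostrings::DNAStringSet]), `truth` (a `GRanges`, one row per TU
#'   with planted TSS/TTS, class, fold change, promoter and terminator
#'   coordinates), and `genes` (a `GRanges` gene annotation with
#'   `gene_id` and `tu_id`).
#' @examples
#' sim <- simulateGenome(simConfig(genomeLength = 60000L,
#'   nTUsPerClass = c(high = 4L, medium = 4L, low = 4L),
#'   nConvergentPairs = 0L, nIntergenicTUs = 0L))
#' length(sim$truth)
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)

  specs <- .tuSpecs(config)
  layout <- .layoutTUs(specs, config)
  tuTab <- layout$tus
  geneTab <- layout$genes

  seq <- .synthesizeSequence(config, tuTab, geneTab)
  seq <- .plantElements(seq, tuTab, config)

  genome <- Biostrings::DNAStringSet(setNames(paste(seq, collapse = ""), .CHROM))
  truth <- .truthGRanges(tuTab, config@genomeLength)
  genes <- .geneGRanges(geneTab, config@genomeLength)
  list(genome = genome, truth = truth, genes = genes)
}

## one row per TU: class, fc, geometry; pairs get matching pair ids
.tuSpecs <- function(config) {
  classes <- rep(.CLASSES, times = config@nTUsPerClass[.CLASSES])
  n <- length(classes)
  classes <- sample(classes)
  fc <- vapply(classes, function(cl) {
    r <- config@fcRanges[[cl]]
    runif(1L, r[1], r[2])
  }, numeric(1))
  rho <- vapply(classes, function(cl)
    runif(1L) < config@fracRhoIndependentByClass[[cl]], logical(1))
  spec <- data.frame(class = classes, fc = fc, rho = rho,
                     intergenic = FALSE, pair = 0L, pairRole = "",
                     stringsAsFactors = FALSE)
  if (config@nIntergenicTUs > 0L) {
    ig <- data.frame(class = "high", fc = runif(config@nIntergenicTUs, 50, 80),
                     rho = TRUE, intergenic = TRUE, pair = 0L, pairRole = "")
    spec <- rbind(spec, ig)
  }
  nPair <- config@nConvergentPairs
  if (nPair > 0L) {
    if (2L * nPair > sum(!spec$intergenic))
      stop("not enough TUs to form ", nPair, " convergent pairs")
    idx <- which(!spec$intergenic)[seq_len(2L * nPair)]
    spec$pair[idx] <- rep(seq_len(nPair), each = 2L)
    spec$pairRole[idx] <- rep(c("left", "right"), nPair)
    # first half share a bidirectional terminator, second half overlap
    bidir <- spec$pair > 0L & spec$pair <= ceiling(nPair / 2)
    spec$rho[spec$pair > 0L] <- bidir[spec$pair > 0L]
  }
  spec
}

## place TUs left to right; returns per-TU and per-gene coordinate tables
.layoutTUs <- function(spec, config) {
  L <- config@genomeLength
  cur <- 1L
  tus <- list(); genes <- list(); gid <- 0L
  i <- 1L
  n <- nrow(spec)
  while (i <= n) {
    isPair <- spec$pair[i] > 0L
    gap <- sample(config@interTUGapRange[1]:config@interTUGapRange[2], 1L)
    cur <- cur + gap
    if (isPair) {
      bidir <- spec$rho[i]
      built <- .buildConvergentPair(spec[i, ], spec[i + 1L, ], cur, config,
                                    bidir = bidir, firstGeneId = gid)
      i <- i + 2L
    } else {
      built <- .buildSingleTU(spec[i, ], cur, config, firstGeneId = gid)
      i <- i + 1L
    }
    if (built$nextPos > L - 200L)
      stop("genome too short to place all TUs; failed while placing a '",
           spec$class[i - 1L], "' class TU - increase genomeLength")
    gid <- gid + nrow(built$genes)
    tus[[length(tus) + 1L]] <- built$tus
    genes[[length(genes) + 1L]] <- built$genes
    cur <- built$nextPos
  }
  list(tus = do.call(rbind, tus),
       genes = do.call(rbind, genes))
}

.emptyGenes <- function() data.frame(gene_id = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     tu_id = integer())

## geometry of one TU laid on the + strand starting at `at`; strand may be
## flipped afterwards by mirroring within the span (single TUs only)
.tuGeometry <- function(sp, config) {
  cl <- sp$class
  utr5 <- .sampleUtr5(config, cl)
  utr3 <- max(15L, round(rnorm(1L, config@utr3Mean, config@utr3Sd)))
  term <- NULL
  if (sp$rho && !sp$intergenic) {
    term <- .sampleTerminatorBlock(withPolyA = FALSE)
    utr3 <- max(utr3, term$len + 2L)
  }
  if (sp$intergenic) {
    geneLens <- integer()
    bodyLen <- sample(100:350, 1L)          # sRNA body, no CDS
    if (sp$rho) {
      term <- .sampleTerminatorBlock(withPolyA = FALSE)
      utr3 <- max(20L, term$len + 2L)
    }
  } else {
    nGenes <- sample(config@genesPerTURange[1]:config@genesPerTURange[2], 1L)
    geneLens <- sample(config@geneLenRange[1]:config@geneLenRange[2], nGenes,
                       replace = TRUE)
    gaps <- if (nGenes > 1L)
      sample(config@intraGapRange[1]:config@intraGapRange[2], nGenes - 1L,
             replace = TRUE) else integer()
    bodyLen <- sum(geneLens) + sum(gaps)
    attr(geneLens, "gaps") <- gaps
  }
  list(utr5 = utr5, utr3 = utr3, bodyLen = bodyLen,
       geneLens = geneLens, term = term)
}

.spacerAndBoxes <- function(sp, config) {
  spacer <- .sampleSpacer(config, sp$class)
  bg <- .baseProbs(config@gcFrac - config@gcIntergenicShift)
  box10 <- .degradeHexamer(CONSENSUS10, .minus10Rates(config, sp$class), bg)
  box35 <- .degradeHexamer(CONSENSUS35,
                           rep(config@minus35DegradationByClass[[sp$class]], 6L),
                           bg)
  list(spacer = spacer, box10 = box10, box35 = box35)
}

.buildSingleTU <- function(sp, at, config, firstGeneId) {
  g <- .tuGeometry(sp, config)
  strand <- sample(c("+", "-"), 1L)
  span <- g$utr5 + g$bodyLen + g$utr3
  promo <- .spacerAndBoxes(sp, config)

  if (strand == "+") {
    tss <- at; tts <- at + span - 1L
    geneStart <- tss + g$utr5
  } else {
    tts <- at; tss <- at + span - 1L
    geneStart <- tts + g$utr3            # genomic-left end of gene block
  }
  genes <- .placeGenes(g$geneLens, geneStart, strand, firstGeneId)

  row <- .tuRow(sp, strand, tss, tts, promo, g, config)
  list(tus = row, genes = genes, nextPos = at + span)
}

## genomic gene coordinates for a block laid left to right from `from`
.placeGenes <- function(geneLens, from, strand, firstGeneId) {
  if (length(geneLens) == 0L) return(.emptyGenes())
  gaps <- attr(geneLens, "gaps")
  if (strand == "-") { # first gene of the TU is the genomic-rightmost
    geneLens <- rev(geneLens); gaps <- rev(gaps)
  }
  starts <- from + cumsum(c(0L, head(geneLens, -1L) + gaps))
  data.frame(gene_id = sprintf("gene_%04d", firstGeneId + seq_along(geneLens)),
             start = as.integer(starts),
             end = as.integer(starts + geneLens - 1L),
             strand = strand, tu_id = NA_integer_)
}

.tuRow <- function(sp, strand, tss, tts, promo, g, config) {
  d10 <- config@dist10Tss
  if (strand == "+") {
    pos10 <- tss - d10 - 5L              # start of the -10 hexamer
    pos35 <- pos10 - promo$spacer - 6L
  } else {
    pos10 <- tss + d10                   # genomic start of revcomp'd -10
    pos35 <- pos10 + 6L + promo$spacer
  }
  term <- g$term
  if (!is.null(term)) {
    # plant so the polyT run (sense) ends exactly at the TTS
    if (strand == "+") {
      blockStart <- tts - term$len + 1L
      stem5 <- blockStart + term$stem5Off - 1L
      polyT <- blockStart + term$polyTOff - 1L
    } else {
      blockStart <- tts + term$len - 1L  # genomic-right end of block
      stem5 <- blockStart - (term$stem5Off - 1L) - (term$stemLen - 1L)
      polyT <- blockStart - (term$polyTOff - 1L) - (term$polyTLen - 1L)
    }
    termCols <- data.frame(term_stem5_start = as.integer(stem5),
                           term_stem_len = term$stemLen,
                           term_loop_len = term$loopLen,
                           term_polyT_start = as.integer(polyT),
                           term_polyT_len = term$polyTLen,
                           term_has_polyA = term$hasPolyA)
  } else {
    termCols <- data.frame(term_stem5_start = NA_integer_,
                           term_stem_len = NA_integer_,
                           term_loop_len = NA_integer_,
                           term_polyT_start = NA_integer_,
                           term_polyT_len = NA_integer_,
                           term_has_polyA = NA)
  }
  cbind(data.frame(class = sp$class, fc = sp$fc, strand = strand,
                   tss = as.integer(tss), tts = as.integer(tts),
                   intergenic = sp$intergenic, pair = sp$pair,
                   utr5 = g$utr5, utr3 = g$utr3,
                   pos35_start = as.integer(pos35),
                   pos10_start = as.integer(pos10),
                   spacer_len = promo$spacer,
                   box35 = paste(promo$box35, collapse = ""),
                   box10 = paste(promo$box10, collapse = "")),
        termCols,
        data.frame(termBases = I(list(if (is.null(term)) NULL else term)))
  )
}

## how the bidirectional element reads on the opposite strand: the polyA
## run becomes the polyT, the gap moves next to the (mirrored) polyA;
## bases = NULL marks "already planted via the partner TU"
.mirrorTerminatorBlock <- function(term) {
  list(bases = NULL,
       stemLen = term$stemLen, loopLen = term$loopLen,
       stem5Off = term$polyTLen + 1L,
       polyTOff = term$len - 5L + 1L,
       polyTLen = 5L,
       hasPolyA = TRUE,
       len = term$len)
}

## two TUs transcribed head-on (left on +, right on -); bidir = shared
## polyA-stem-polyT element, otherwise overlapping 3'-UTRs, no terminator
.buildConvergentPair <- function(spL, spR, at, config, bidir, firstGeneId) {
  gL <- .tuGeometry(transform(spL, rho = FALSE), config)
  gR <- .tuGeometry(transform(spR, rho = FALSE), config)
  promoL <- .spacerAndBoxes(spL, config)
  promoR <- .spacerAndBoxes(spR, config)

  tssL <- at
  lastGeneEndL <- tssL + gL$utr5 + gL$bodyLen - 1L
  if (bidir) {
    term <- .sampleTerminatorBlock(withPolyA = TRUE)
    blockStart <- lastGeneEndL + max(10L, gL$utr3 - term$len) + 1L
    ttsL <- blockStart + term$len - 1L       # + sense polyT end
    ttsR <- blockStart                       # - sense polyT end = polyA start
    gR$utr3 <- max(gR$utr3, term$len + 2L)   # block inside the R transcript
  } else {
    term <- NULL
    gL$utr3 <- max(gL$utr3, 30L)
    gR$utr3 <- max(gR$utr3, 30L)
    ttsL <- lastGeneEndL + gL$utr3
    ttsR <- ttsL - 40L                       # 3'-UTRs overlap by ~40 bp
  }
  firstGeneStartR <- ttsR + gR$utr3          # genomic-left end of R genes
  genesL <- .placeGenes(gL$geneLens, tssL + gL$utr5, "+", firstGeneId)
  genesR <- .placeGenes(gR$geneLens, firstGeneStartR, "-",
                        firstGeneId + nrow(genesL))
  tssR <- firstGeneStartR + gR$bodyLen - 1L + gR$utr5

  gL2 <- gL; gR2 <- gR
  if (bidir) {
    gL2$term <- term
    gR2$term <- .mirrorTerminatorBlock(term)
    gL2$utr3 <- ttsL - lastGeneEndL
  }
  rowL <- .tuRow(spL, "+", tssL, ttsL, promoL, gL2, config)
  rowR <- .tuRow(spR, "-", tssR, ttsR, promoR, gR2, config)
  list(tus = rbind(rowL, rowR), genes = rbind(genesL, genesR),
       nextPos = tssR + 1L)
}

## random background: coding GC raised so the genome-wide GC meets gcFrac
## despite the more AT-rich intergenic space
.synthesizeSequence <- function(config, tuTab, geneTab) {
  L <- config@genomeLength
  coding <- rep(FALSE, L)
  if (nrow(geneTab))
    for (k in seq_len(nrow(geneTab)))
      coding[geneTab$start[k]:geneTab$end[k]] <- TRUE
  fIg <- mean(!coding)
  gcCoding <- min(0.95, config@gcFrac + config@gcIntergenicShift * fIg)
  gcIg <- gcCoding - config@gcIntergenicShift
  seq <- character(L)
  nC <- sum(coding)
  seq[coding] <- sample(.BASES, nC, replace = TRUE, prob = .baseProbs(gcCoding))
  seq[!coding] <- sample(.BASES, L - nC, replace = TRUE, prob = .baseProbs(gcIg))
  seq
}

## overwrite promoter hexamers and terminator blocks at their coordinates
.plantElements <- function(seq, tuTab, config) {
  for (k in seq_len(nrow(tuTab))) {
    tu <- tuTab[k, ]
    b35 <- strsplit(tu$box35, "")[[1]]
    b10 <- strsplit(tu$box10, "")[[1]]
    if (tu$strand == "+") {
      seq[tu$pos35_start:(tu$pos35_start + 5L)] <- b35
      seq[tu$pos10_start:(tu$pos10_start + 5L)] <- b10
    } else {
      seq[tu$pos35_start:(tu$pos35_start + 5L)] <- .revcompChar(b35)
      seq[tu$pos10_start:(tu$pos10_start + 5L)] <- .revcompChar(b10)
    }
    term <- tu$termBases[[1]]
    if (!is.null(term) && !is.null(term$bases)) {
      if (tu$strand == "+") {
        from <- tu$tts - term$len + 1L
        seq[from:tu$tts] <- term$bases
      } else {
        to <- tu$tts + term$len - 1L
        seq[tu$tts:to] <- .revcompChar(term$bases)
      }
    }
  }
  seq
}

.truthGRanges <- function(tuTab, genomeLength) {
  gr <- GenomicRanges::GRanges(
    seqnames = .CHROM,
    ranges = IRanges::IRanges(start = pmin(tuTab$tss, tuTab$tts),
                              end = pmax(tuTab$tss, tuTab$tts)),
    strand = tuTab$strand)
  GenomeInfoDb::seqlengths(gr) <- genomeLength
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tu_id = sprintf("truth_tu_%03d", seq_len(nrow(tuTab))),
    class = tuTab$class, fc = tuTab$fc,
    tss = tuTab$tss, tts = tuTab$tts,
    intergenic = tuTab$intergenic, pair = tuTab$pair,
    utr5 = tuTab$utr5, utr3 = tuTab$utr3,
    pos35_start = tuTab$pos35_start, pos10_start = tuTab$pos10_start,
    spacer_len = tuTab$spacer_len,
    box35 = tuTab$box35, box10 = tuTab$box10,
    term_stem5_start = tuTab$term_stem5_start,
    term_stem_len = tuTab$term_stem_len,
    term_loop_len = tuTab$term_loop_len,
    term_polyT_start = tuTab$term_polyT_start,
    term_polyT_len = tuTab$term_polyT_len,
    term_has_polyA = tuTab$term_has_polyA)
  gr
}

.geneGRanges <- function(geneTab, genomeLength) {
  if (nrow(geneTab) == 0L) {
    gr <- GenomicRanges::GRanges(seqnames = character(),
                                 ranges = IRanges::IRanges(),
                                 strand = character())
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = .CHROM,
      ranges = IRanges::IRanges(start = geneTab$start, end = geneTab$end),
      strand = geneTab$strand,
      gene_id = geneTab$gene_id)
  }
  GenomeInfoDb::seqlengths(gr) <- setNames(genomeLength, .CHROM)
  gr
}

#' Simulate two-channel tiling-array probe measurements
#'
#' The genomic-DNA channel is an even hybridization baseline with
#' multiplicative log-normal noise; the mRNA channel scales the baseline
#' by the overlap-weighted fold change of the transcriptional units
#' covering the probe (weight = covered fraction of the probe, fold
#' change 1 for uncovered sequence) with its own noise draw.
#'
#' @param probes probe `GRanges` from [designProbes()].
#' @param truth truth `GRanges` from [simulateGenome()].
#' @param config a [SimConfig-class]; `noiseSdLog2` sets the noise.
#' @param baseline gDNA channel mean intensity.
#' @param seed integer; defaults to `config@seed + 1`.
#' @return `data.frame` with columns `probe_id`, `strand`, `start`,
#'   `end`, `gdna`, `mrna`.
#' @export
simulateProbeSignals <- function(probes, truth, config, baseline = 1000,
                                 seed = config@seed + 1L) {
  gl <- GenomeInfoDb::seqlengths(truth)[[.CHROM]]
  if (!is.na(gl) &&
      any(BiocGenerics::end(probes) > gl | BiocGenerics::start(probes) < 1L))
    stop("probe outside genome bounds")
  set.seed(seed)
  n <- length(probes)
  wfc <- rep(1, n)
  hits <- GenomicRanges::findOverlaps(probes, truth)
  if (length(hits)) {
    ov <- IRanges::pintersect(probes[S4Vectors::queryHits(hits)],
                              truth[S4Vectors::subjectHits(hits)])
    frac <- BiocGenerics::width(ov) / BiocGenerics::width(probes[S4Vectors::queryHits(hits)])
    contrib <- frac * (truth$fc[S4Vectors::subjectHits(hits)] - 1)
    add <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    wfc[as.integer(names(add))] <- 1 + as.numeric(add)
  }
  sd <- config@noiseSdLog2
  gdna <- baseline * 2^rnorm(n, 0, sd)
  mrna <- gdna * wfc * 2^rnorm(n, 0, sd)
  data.frame(probe_id = probes$probe_id,
             strand = as.character(BiocGenerics::strand(probes)),
             start = BiocGenerics::start(probes),
             end = BiocGenerics::end(probes),
             gdna = gdna, mrna = mrna)
}

#' Simulate stranded per-base RNA-Seq coverage
#'
#' Coverage over each transcript is Poisson with mean proportional to
#' fold change times `coverageDepth`, modulated by a smooth sinusoidal
#' positional bias (period `covBiasPeriod`, amplitude
#' `covBiasAmplitude`); the first bases of every transcript are zeroed
#' over a geometric 5'-truncation (mean `fivePrimeTruncationMean`),
#' emulating the 5' bases RNA-Seq misses.  Off-transcript background is
#' Poisson with mean `backgroundCoverage`.
#'
#' @param truth truth `GRanges` from [simulateGenome()].
#' @param config a [SimConfig-class].
#' @param seed integer; defaults to `config@seed + 2`.
#' @return named list of two integer vectors (`+`, `-`) of per-base
#'   coverage along the genome.
#' @export
simulateCoverage <- function(truth, config, seed = config@seed + 2L) {
  set.seed(seed)
  L <- config@genomeLength
  cov <- list("+" = rpois(L, config@backgroundCoverage),
              "-" = rpois(L, config@backgroundCoverage))
  pTrunc <- 1 / (config@fivePrimeTruncationMean + 1)
  for (k in seq_along(truth)) {
    tu <- truth[k]
    st <- as.character(BiocGenerics::strand(tu))
    pos <- BiocGenerics::start(tu):BiocGenerics::end(tu)
    phase <- runif(1L, 0, 2 * pi)
    bias <- 1 + config@covBiasAmplitude *
      sin(2 * pi * pos / config@covBiasPeriod + phase)
    lambda <- tu$fc * config@coverageDepth * pmax(bias, 0)
    reads <- rpois(length(pos), lambda)
    tr <- if (config@fivePrimeTruncationMean > 0) rgeom(1L, pTrunc) else 0L
    if (tr > 0L) {
      tr <- min(tr, length(pos))
      if (st == "+") reads[seq_len(tr)] <- 0L
      else reads[seq.int(length(pos), by = -1L, length.out = tr)] <- 0L
    }
    cov[[st]][pos] <- cov[[st]][pos] + reads
  }
  cov
}
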