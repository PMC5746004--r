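#' @import methods
#' @importFrom stats median mad sd p.adjust pnorm quantile rnorm rpois
#'   rgeom runif t.test setNames
#' @importFrom utils head tail write.table read.delim packageVersion
NULL

#' Simulation configuration for the synthetic transcriptional landscape
#'
#' A `SimConfig` bundles every tunable of the synthetic-genome generator:
#' genome size and base composition, the number of transcriptional units
#' (TUs) per expression class with their fold-change ranges, promoter
#' geometry (spacer distribution, distance of the -10 box to the TSS) and
#' per-class consensus degradation, terminator planting fractions,
#' platform noise, and RNA-Seq coverage parameters.  Defaults describe a
#' desk-scale caricature of a high-GC (~59%) bifidobacterial chromosome:
#' three expression classes (high FC > 10, medium 3-10, low < 3), spacers
#' of 14-20 bp peaked at 17, 5'-UTRs averaging ~100 bp for high versus
#' ~60 bp for medium/low expressers, and per-class rho-independent
#' terminator fractions of 70/83, 81/153 and 73/177.
#'
#' @slot genomeLength integer, chromosome length in bp.
#' @slot gcFrac target genome-wide GC fraction.
#' @slot gcIntergenicShift how much lower the intergenic GC fraction is
#'   relative to coding sequence (intergenic regions are more AT rich).
#' @slot nTUsPerClass named integer vector (`high`, `medium`, `low`).
#' @slot fcRanges named list of `c(lo, hi)` fold-change ranges per class.
#' @slot utr5MeanByClass per-class mean 5'-UTR length (bp).
#' @slot utr5SdLog log-scale sd of the (log-normal) 5'-UTR length draw.
#' @slot utr3Mean,utr3Sd mean/sd of 3'-UTR length (bp).
#' @slot spacerRange integer `c(min, max)` promoter spacer range (bp).
#' @slot spacerMode modal spacer length (bp).
#' @slot spacerTauByClass per-class spacer concentration: spacer s is
#'   drawn with weight `exp(-|s - mode| / tau)`; small tau pins the class
#'   to the modal spacer, large tau approaches uniform over the range.
#' @slot dist10Tss planted distance (bp) from the -10 hexamer end to the
#'   TSS.
#' @slot promoterDegradationByClass per-class per-position substitution
#'   probability applied to positions 1, 2 and 6 of the -10 hexamer and
#'   (shifted, see `minus35DegradationByClass`) to the -35 hexamer.
#' @slot minus10MidDegradation class-independent floor for positions
#'   3-5 of the -10 hexamer (the weakly conserved core).
#' @slot minus35DegradationByClass per-class substitution probability for
#'   the -35 hexamer (degrades faster, mirroring its weaker conservation).
#' @slot fracRhoIndependentByClass fraction of TUs per class given a
#'   planted hairpin + polyT terminator.
#' @slot nConvergentPairs number of tail-to-tail TU pairs; half share a
#'   bidirectional (polyA-stem-polyT) terminator, half overlap 3'-UTRs
#'   with no terminator.
#' @slot nIntergenicTUs gene-free highly transcribed TUs (sRNA-like).
#' @slot noiseSdLog2 sd (log2 units) of multiplicative array noise.
#' @slot coverageDepth mean RNA-Seq reads per base at fold-change 1.
#' @slot backgroundCoverage mean off-transcript Poisson coverage.
#' @slot fivePrimeTruncationMean mean (bp) of the geometric 5' coverage
#'   truncation of each transcript.
#' @slot covBiasPeriod,covBiasAmplitude period (bp) and amplitude of the
#'   smooth sinusoidal positional coverage bias.
#' @slot geneLenRange,genesPerTURange,intraGapRange,interTUGapRange
#'   layout geometry (bp / counts).
#' @slot seed integer seed controlling all generator randomness.
#'
#' @seealso [simConfig()], [simulateGenome()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
  genomeLength = "integer",
  gcFrac = "numeric",
  gcIntergenicShift = "numeric",
  nTUsPerClass = "integer",
  fcRanges = "list",
  utr5MeanByClass = "numeric",
  utr5SdLog = "numeric",
  utr3Mean = "numeric",
  utr3Sd = "numeric",
  spacerRange = "integer",
  spacerMode = "integer",
  spacerTauByClass = "numeric",
  dist10Tss = "integer",
  promoterDegradationByClass = "numeric",
  minus10MidDegradation = "numeric",
  minus35DegradationByClass = "numeric",
  fracRhoIndependentByClass = "numeric",
  nConvergentPairs = "integer",
  nIntergenicTUs = "integer",
  noiseSdLog2 = "numeric",
  coverageDepth = "numeric",
  backgroundCoverage = "numeric",
  fivePrimeTruncationMean = "numeric",
  covBiasPeriod = "numeric",
  covBiasAmplitude = "numeric",
  geneLenRange = "integer",
  genesPerTURange = "integer",
  intraGapRange = "integer",
  interTUGapRange = "integer",
  seed = "integer"
))

.CLASSES <- c("high", "medium", "low")

setValidity("SimConfig", function(object) {
  msg <- character()
  chkNames <- function(x, what) {
    if (!identical(sort(names(x)), sort(.CLASSES)))
      msg <<- c(msg, sprintf("%s must be named high/medium/low", what))
  }
  chkNames(object@nTUsPerClass, "nTUsPerClass")
  chkNames(object@fcRanges, "fcRanges")
  chkNames(object@utr5MeanByClass, "utr5MeanByClass")
  chkNames(object@promoterDegradationByClass, "promoterDegradationByClass")
  chkNames(object@fracRhoIndependentByClass, "fracRhoIndependentByClass")
  if (any(object@nTUsPerClass < 0L))
    msg <- c(msg, "TU counts must be >= 0")
  if (object@gcFrac <= 0 || object@gcFrac >= 1)
    msg <- c(msg, "gcFrac must lie in (0, 1)")
  sr <- object@spacerRange
  if (length(sr) != 2L || sr[1] < 14L || sr[2] > 20L || sr[1] > sr[2])
    msg <- c(msg, "spacerRange must lie within [14, 20]")
  if (length(msg) == 0L) {
    # fold-change ranges must respect the class partition
    fr <- object@fcRanges
    if (fr$high[1] <= 10) msg <- c(msg, "high fcRange must exceed 10")
    if (fr$medium[1] < 3 || fr$medium[2] > 10)
      msg <- c(msg, "medium fcRange must lie in [3, 10]")
    if (fr$low[2] >= 3) msg <- c(msg, "low fcRange must stay below 3")
    if (fr$low[1] <= 0) msg <- c(msg, "fold changes must be positive")
  }
  degr <- c(object@promoterDegradationByClass,
            object@minus10MidDegradation,
            object@minus35DegradationByClass,
            object@fracRhoIndependentByClass)
  if (any(degr < 0 | degr > 1))
    msg <- c(msg, "degradation and terminator fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Two-box vegetative promoter model
#'
#' Position-weight matrices for the -35 and -10 hexamers learned by
#' constrained two-box expectation-maximization over upstream windows,
#' together with the empirical spacer-length distribution, the
#' mononucleotide background, the per-bp spacer penalty used when
#' scanning, and the score threshold below which a scan returns no call.
#'
#' @slot pwm35,pwm10 4 x 6 column-stochastic probability matrices
#'   (rows A, C, G, T).
#' @slot logodds35,logodds10 4 x 6 log2-odds matrices versus background.
#' @slot spacerProbs named numeric, probability of each spacer length.
#' @slot background mononucleotide background frequencies (A, C, G, T).
#' @slot spacerPenaltyPerBp log-odds cost per bp of deviation of the
#'   spacer from its modal length when scoring placements.
#' @slot spacerModeRef reference (optimal) spacer length, 17 bp.
#' @slot threshold minimum scan score yielding a call (5th percentile of
#'   best training-placement scores).
#' @slot trainScores best placement score per training window.
#' @slot lowInformation TRUE when the total information content of both
#'   matrices is below 2 bits (uninformative input).
#' @slot logLik final training log-likelihood; @slot iterations EM sweeps.
#' @exportClass PromoterModel
setClass("PromoterModel", representation(
  pwm35 = "matrix", pwm10 = "matrix",
  logodds35 = "matrix", logodds10 = "matrix",
  spacerProbs = "numeric", background = "numeric",
  spacerPenaltyPerBp = "numeric", spacerModeRef = "integer",
  threshold = "numeric", trainScores = "numeric",
  lowInformation = "logical", logLik = "numeric", iterations = "integer"
))

setValidity("PromoterModel", function(object) {
  msg <- character()
  for (nm in c("pwm35", "pwm10")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(4L, 6L))) msg <- c(msg, paste(nm, "must be 4 x 6"))
    else if (any(abs(colSums(m) - 1) > 1e-6))
      msg <- c(msg, paste(nm, "columns must sum to 1"))
  }
  if (any(object@spacerProbs < 0))
    msg <- c(msg, "spacer probabilities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Results container for a full landscape run
#'
#' Holds everything [runPipeline()] produces: the (simulated or supplied)
#' genome, the gene annotation, assembled transcriptional units, promoter
#' and terminator calls, sRNA candidates, the learned promoter model, the
#' random-forest importance report and a summary list.  Accessors:
#' [tus()], [promoters()], [terminators()], [srnaCandidates()],
#' [promoterModel()], [importanceReport()], [runSummary()].
#'
#' @slot genome a [Biostrings::DNAStringSet] of length 1.
#' @slot annotation gene annotation as a [GenomicRanges::GRanges].
#' @slot truth planted-truth `GRanges` (zero-length when not simulated).
#' @slot tus,promoters,terminators,srnas result `GRanges`.
#' @slot model the [PromoterModel-class].
#' @slot importance importance report list from [trainRank()].
#' @slot summary named list of run-level statistics.
#' @exportClass LandscapeRun
setClass("LandscapeRun", representation(
  genome = "DNAStringSet",
  annotation = "GRanges",
  truth = "GRanges",
  tus = "GRanges",
  promoters = "GRanges",
  terminators = "GRanges",
  srnas = "GRanges",
  model = "PromoterModel",
  importance = "list",
  summary = "list"
))
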