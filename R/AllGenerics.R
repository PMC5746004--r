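#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Accessors for LandscapeRun and PromoterModel objects
#'
#' `tus()`, `promoterCalls()`, `terminatorCalls()` and `srnaCandidates()` return
#' the corresponding result `GRanges` of a [LandscapeRun-class];
#' `promoterModel()` the learned [PromoterModel-class];
#' `importanceReport()` the random-forest report; `runSummary()` the
#' summary list.  `modelConsensus()` gives the consensus strings of the
#' two learned hexamer matrices and `spacerMode()` the modal spacer
#' length of a model.
#'
#' @param x a `LandscapeRun` (or `PromoterModel` for the model accessors).
#' @return see individual descriptions.
#' @name accessors
#' @aliases tus promoterCalls terminatorCalls srnaCandidates promoterModel
#'   importanceReport runSummary modelConsensus spacerMode
NULL

#' @rdname accessors
#' @export
setGeneric("tus", function(x) standardGeneric("tus"))
#' @rdname accessors
#' @export
setGeneric("promoterCalls", function(x) standardGeneric("promoterCalls"))
#' @rdname accessors
#' @export
setGeneric("terminatorCalls", function(x) standardGeneric("terminatorCalls"))
#' @rdname accessors
#' @export
setGeneric("srnaCandidates", function(x) standardGeneric("srnaCandidates"))
#' @rdname accessors
#' @export
setGeneric("promoterModel", function(x) standardGeneric("promoterModel"))
#' @rdname accessors
#' @export
setGeneric("importanceReport", function(x) standardGeneric("importanceReport"))
#' @rdname accessors
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))
#' @rdname accessors
#' @export
setGeneric("modelConsensus", function(x) standardGeneric("modelConsensus"))
#' @rdname accessors
#' @export
setGeneric("spacerMode", function(x) standardGeneric("spacerMode"))

#' @rdname accessors
setMethod("tus", "LandscapeRun", function(x) x@tus)
#' @rdname accessors
setMethod("promoterCalls", "LandscapeRun", function(x) x@promoters)
#' @rdname accessors
setMethod("terminatorCalls", "LandscapeRun", function(x) x@terminators)
#' @rdname accessors
setMethod("srnaCandidates", "LandscapeRun", function(x) x@srnas)
#' @rdname accessors
setMethod("promoterModel", "LandscapeRun", function(x) x@model)
#' @rdname accessors
setMethod("importanceReport", "LandscapeRun", function(x) x@importance)
#' @rdname accessors
setMethod("runSummary", "LandscapeRun", function(x) x@summary)

.BASES <- c("A", "C", "G", "T")

#' @rdname accessors
setMethod("modelConsensus", "PromoterModel", function(x) {
  cons <- function(m) paste(.BASES[apply(m, 2, which.max)], collapse = "")
  c(minus35 = cons(x@pwm35), minus10 = cons(x@pwm10))
})

#' @rdname accessors
setMethod("spacerMode", "PromoterModel", function(x) {
  as.integer(names(x@spacerProbs)[which.max(x@spacerProbs)])
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@genomeLength, "bp genome, GC",
      object@gcFrac, "\n  TUs per class:",
      paste(names(object@nTUsPerClass), object@nTUsPerClass,
            sep = "=", collapse = " "),
      "+", object@nIntergenicTUs, "intergenic\n  convergent pairs:",
      object@nConvergentPairs, " seed:", object@seed, "\n")
})

setMethod("show", "PromoterModel", function(object) {
  cons <- modelConsensus(object)
  cat("PromoterModel: -35", cons[["minus35"]], " -10", cons[["minus10"]],
      "\n  spacer mode:", spacerMode(object),
      "bp; score threshold:", round(object@threshold, 2), "\n")
  if (object@lowInformation)
    cat("  [low-information model: total PWM content < 2 bits]\n")
})

setMethod("show", "LandscapeRun", function(object) {
  cls <- table(factor(object@tus$class, levels = .CLASSES))
  cat("LandscapeRun:", length(object@tus), "TUs (",
      paste(names(cls), cls, sep = "=", collapse = " "), ")\n  ",
      length(object@promoters), "promoter calls,",
      length(object@terminators), "terminator calls,",
      length(object@srnas), "sRNA candidates\n")
})
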