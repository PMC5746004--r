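#' Run the full transcriptional-landscape pipeline
#'
#' Simulate (or accept) a genome, then: design probes and simulate the
#' two-channel array -> call significant probes (FDR 1e-4) -> merge into
#' transcribed segments -> simulate stranded coverage -> detect coverage
#' boundaries -> assemble transcriptional units with cross-platform
#' TSS/TTS refinement -> learn the two-box promoter model on the
#' highest-FC units and scan every unit -> detect and classify
#' terminators -> rank promoter features with a random forest (against
#' intergenic negatives) -> report intergenic sRNA candidates, UTR
#' statistics and TSS concordance.
#'
#' The run is pure given `(config, seed)`: repeating it reproduces every
#' numeric output.
#'
#' @param config a [SimConfig-class] (see [simConfig()]); the `desk`
#'   profile is its default values.
#' @param seed overrides `config@seed` when given.
#' @param outdir optional directory; when set, all module outputs
#'   (FASTA/GFF3/TSV/bedGraph/JSON) are written there.
#' @param nTrain promoter training-set size (default 75, capped at the
#'   number of eligible TUs).
#' @param nNegatives intergenic negative windows for the forest
#'   (default 2000).
#' @param nTrees forest size (default 500).
#' @param fdr probe-level FDR threshold (default 1e-4).
#' @param quiet suppress progress messages.
#' @return a [LandscapeRun-class].
#' @examples
#' \donttest{
#' run <- runPipeline(simConfig(genomeLength = 100000L,
#'   nTUsPerClass = c(high = 8L, medium = 8L, low = 8L)), seed = 7)
#' runSummary(run)$tu_counts
#' }
#' @export
runPipeline <- function(config = simConfig(), seed = NULL, outdir = NULL,
                        nTrain = 75L, nNegatives = 2000L, nTrees = 500L,
                        fdr = 1e-4, quiet = FALSE) {
  if (!is.null(seed)) config@seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(...)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  say("simulating genome (", config@genomeLength, " bp, seed ",
      config@seed, ")")
  sim <- simulateGenome(config)

  say("array: designing probes and calling significance")
  probes <- designProbes(config@genomeLength)
  meas <- simulateProbeSignals(probes, sim$truth, config)
  calls <- callProbes(meas, fdr = fdr)
  segments <- segmentProbes(calls)

  say("coverage: simulating reads and detecting boundaries")
  coverage <- simulateCoverage(sim$truth, config)
  covInts <- detectBoundaries(coverage)

  say("assembling transcriptional units")
  tuSet <- assembleTUs(segments, covInts, sim$genes)

  say("promoters: learning model and scanning")
  ord <- order(-tuSet$fc)
  # train on high/medium-expressed units with a coverage-refined start
  trainable <- ord[tuSet$tss_source[ord] == "both" & tuSet$fc[ord] >= 3]
  if (length(trainable) < 10L)
    trainable <- ord[tuSet$tss_source[ord] == "both"]
  if (length(trainable) < 10L) trainable <- ord
  win <- upstreamWindows(sim$genome, tuSet$tss[trainable],
                         as.character(BiocGenerics::strand(tuSet))[trainable])
  model <- learnPromoterModel(win, nTrain = nTrain)
  proms <- callPromoters(tuSet, sim$genome, model)

  say("terminators: hairpin detection and classification")
  term <- classifyTermination(tuSet, sim$genome)
  tuSet <- term$tus

  say("random forest: feature ranking (", nTrees, " trees, ",
      nNegatives, " negatives)")
  set.seed(config@seed + 3L)
  negs <- sampleNegatives(sim$genome, sim$genes, proms, n = nNegatives)
  pf <- as.data.frame(S4Vectors::mcols(proms))
  fm <- buildFeatureMatrix(pf, negs)
  rfRep <- trainRank(fm, nTrees = nTrees, seed = config@seed + 4L)

  say("sRNA candidates and summaries")
  srnas <- findIntergenicExpressed(segments, sim$genes)
  conc <- tssConcordance(tuSet)
  utr <- utrStats(tuSet)
  termSum <- terminationSummary(tuSet)

  summary <- list(
    tu_counts = as.list(table(factor(tuSet$class, levels = .CLASSES))),
    n_tus = length(tuSet),
    n_segments = length(segments),
    n_promoters = length(proms),
    promoter_consensus = as.list(modelConsensus(model)),
    spacer_mode = spacerMode(model),
    termination = list(
      rho_independent_total = termSum$rho_independent_total,
      rho_independent_pct = termSum$rho_independent_pct,
      by_class = as.list(as.data.frame(termSum$by_class))),
    utr = utr[c("mean_utr5", "mean_utr3", "p_high_vs_rest")],
    tss_concordance = conc[c("median", "fraction_25_50")],
    importance_top = head(rfRep$importance, 10L),
    oob = rfRep$oob, oob3 = rfRep$oob3,
    n_srna = length(srnas),
    provenance = list(seed = config@seed,
                      genome_length = config@genomeLength,
                      package = as.character(packageVersion("TUscape")),
                      r_version = as.character(getRversion())))

  run <- new("LandscapeRun",
             genome = sim$genome, annotation = sim$genes,
             truth = sim$truth, tus = tuSet, promoters = proms,
             terminators = term$calls, srnas = srnas, model = model,
             importance = rfRep[c("importance", "oob", "oob3", "confusion")],
             summary = summary)

  if (!is.null(outdir)) {
    say("writing outputs to ", outdir)
    writeSimulation(sim, meas, coverage, outdir)
    writeResultGff3(tuSet, file.path(outdir, "tus.gff3"),
                    type = "transcript")
    writeResultGff3(proms, file.path(outdir, "promoters.gff3"),
                    type = "promoter")
    writeResultGff3(term$calls, file.path(outdir, "terminators.gff3"),
                    type = "terminator")
    writeResultGff3(srnas, file.path(outdir, "srna_candidates.gff3"),
                    type = "ncRNA")
    writeResultGff3(segments, file.path(outdir, "segments.gff3"),
                    type = "transcribed_segment")
    writePromoterModel(model, file.path(outdir, "promoter_model.json"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' Serialize a promoter model to JSON
#'
#' @param model a [PromoterModel-class]; @param path output path.
#' @export
writePromoterModel <- function(model, path) {
  jsonlite::write_json(list(
    pwm35 = model@pwm35, pwm10 = model@pwm10,
    spacer_probs = as.list(model@spacerProbs),
    background = as.list(model@background),
    threshold = model@threshold,
    consensus = as.list(modelConsensus(model))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
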