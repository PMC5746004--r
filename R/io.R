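## File I/O: FASTA and GFF3 via Biostrings/rtracklayer, bedGraph via
## rtracklayer (which converts between 0-based half-open bedGraph and
## the 1-based inclusive coordinates used throughout), TSV via base R.

#' Write the probe measurement table
#'
#' TSV with columns probe_id, strand, start, end, gdna, mrna
#' (coordinates 1-based inclusive).
#'
#' @param measurements `data.frame` from [simulateProbeSignals()].
#' @param path output file.
#' @export
writeProbeTable <- function(measurements, path) {
  writeLines("# coordinates: 1-based inclusive", path)
  suppressWarnings(write.table(measurements, path, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               append = TRUE))
}

#' Read a probe measurement table
#' @param path TSV written by [writeProbeTable()].
#' @return `data.frame`.
#' @export
readProbeTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write stranded coverage as a pair of bedGraph files
#'
#' @param coverage named list (`+`, `-`) of per-base coverage vectors.
#' @param prefix output prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @return invisibly, the two paths.
#' @export
writeCoverageBedGraph <- function(coverage, prefix) {
  paths <- c(paste0(prefix, ".plus.bedGraph"),
             paste0(prefix, ".minus.bedGraph"))
  for (k in 1:2) {
    st <- c("+", "-")[k]
    r <- S4Vectors::Rle(as.numeric(coverage[[st]]))
    gr <- GenomicRanges::GRanges(
      seqnames = .CHROM,
      ranges = IRanges::IRanges(
        start = cumsum(c(1L, head(S4Vectors::runLength(r), -1L))),
        width = S4Vectors::runLength(r)),
      score = S4Vectors::runValue(r))
    GenomeInfoDb::seqlengths(gr) <- length(coverage[[st]])
    rtracklayer::export.bedGraph(gr[gr$score > 0], paths[k])
  }
  invisible(paths)
}

#' Read stranded coverage from a pair of bedGraph files
#'
#' @param plusPath,minusPath bedGraph files per strand.
#' @param genomeLength genome length in bp.
#' @return named list (`+`, `-`) of per-base numeric coverage.
#' @export
readCoverageBedGraph <- function(plusPath, minusPath, genomeLength) {
  readOne <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    x <- numeric(genomeLength)
    if (length(gr)) {
      for (i in seq_along(gr))
        x[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <- gr$score[i]
    }
    x
  }
  list("+" = readOne(plusPath), "-" = readOne(minusPath))
}

#' Write a result GRanges as GFF3 (plus TSV twin)
#'
#' @param gr a `GRanges` whose mcols become GFF3 attributes.
#' @param path output `.gff3` path; a `.tsv` twin is written alongside.
#' @param type GFF3 feature type.
#' @export
writeResultGff3 <- function(gr, path, type = "region") {
  if (length(gr)) {
    gr$type <- type
    # flatten list columns for attribute serialization
    mc <- S4Vectors::mcols(gr)
    for (j in seq_along(mc))
      if (is(mc[[j]], "CharacterList"))
        mc[[j]] <- vapply(mc[[j]], paste, character(1), collapse = ",")
    S4Vectors::mcols(gr) <- mc
  }
  rtracklayer::export(gr, path, format = "gff3")
  tab <- as.data.frame(gr)
  tsv <- sub("\\.gff3?$", ".tsv", path)
  writeLines("# coordinates: 1-based inclusive", tsv)
  suppressWarnings(write.table(tab, tsv, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write all artefacts of a simulation
#'
#' FASTA genome, GFF3 truth and gene annotation, probe TSV, and the two
#' coverage bedGraphs.
#'
#' @param sim list from [simulateGenome()].
#' @param measurements probe table; @param coverage coverage list.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, measurements, coverage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fasta"))
  writeResultGff3(sim$truth, file.path(dir, "truth.gff3"), type = "transcript")
  writeResultGff3(sim$genes, file.path(dir, "genes.gff3"), type = "gene")
  writeProbeTable(measurements, file.path(dir, "probes.tsv"))
  writeCoverageBedGraph(coverage, file.path(dir, "coverage"))
  invisible(dir)
}
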