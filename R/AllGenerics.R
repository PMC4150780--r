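#' @include AllClasses.R
NULL

#' @describeIn DuplexResult-class hybrid free energy (kcal/mol, NA if none)
#' @param x object
#' @export
setGeneric("duplexEnergy", function(x) standardGeneric("duplexEnergy"))

#' @describeIn DuplexResult-class pairing matrix (miRNA index, target index)
#' @export
setGeneric("duplexPairs", function(x) standardGeneric("duplexPairs"))

#' @describeIn DuplexResult-class 0-based half-open target span of the hybrid
#' @export
setGeneric("targetSpan", function(x) standardGeneric("targetSpan"))

#' @describeIn DuplexResult-class three-line text rendering of the hybrid
#' @export
setGeneric("conformation", function(x) standardGeneric("conformation"))

#' @describeIn Ensemble-class natural log of the partition function
#' @param x object
#' @export
setGeneric("logPartition", function(x) standardGeneric("logPartition"))

#' @describeIn Ensemble-class ensemble free energy -RT log Z (kcal/mol)
#' @export
setGeneric("ensembleFreeEnergy", function(x) standardGeneric("ensembleFreeEnergy"))

#' @describeIn Ensemble-class per-nucleotide single-strandedness probability
#' @export
setGeneric("pUnpaired", function(x) standardGeneric("pUnpaired"))

#' @describeIn TranscriptDB-class transcript identifiers
#' @param x object
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @describeIn TranscriptDB-class transcript length(s) in nt
#' @param id transcript identifier(s); default all
#' @export
setGeneric("transcriptLength", function(x, id) standardGeneric("transcriptLength"))

#' @describeIn TranscriptDB-class transcript sequence as RNA character string
#' @export
setGeneric("transcriptSeq", function(x, id) standardGeneric("transcriptSeq"))

#' @describeIn TranscriptDB-class region annotation table
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @describeIn TranscriptDB-class exon block table
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))

setMethod("duplexEnergy", "DuplexResult", function(x) x@dG)
setMethod("duplexPairs", "DuplexResult", function(x) x@pairs)
setMethod("targetSpan", "DuplexResult", function(x) x@targetSpan)

setMethod("logPartition", "Ensemble", function(x) x@logZ)
setMethod("ensembleFreeEnergy", "Ensemble", function(x) x@freeEnergy)
setMethod("pUnpaired", "Ensemble", function(x) x@pUnpaired)

setMethod("transcriptIds", "TranscriptDB", function(x) names(x@seqs))
setMethod("transcriptLength", "TranscriptDB", function(x, id) {
  w <- Biostrings::width(x@seqs)
  names(w) <- names(x@seqs)
  if (missing(id)) w else {
    if (!all(id %in% names(w)))
      stop("unknown transcript id(s): ",
           paste(setdiff(id, names(w)), collapse = ", "))
    w[id]
  }
})
setMethod("transcriptSeq", "TranscriptDB", function(x, id) {
  if (!all(id %in% names(x@seqs)))
    stop("unknown transcript id(s): ",
         paste(setdiff(id, names(x@seqs)), collapse = ", "))
  as.character(x@seqs[id])
})
setMethod("regionTable", "TranscriptDB", function(x) x@regions)
setMethod("exonTable", "TranscriptDB", function(x) x@exons)

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel: nearest-neighbor RNA parameters\n")
  cat(sprintf("  temperature %.2f K, RT %.4f kcal/mol\n",
              object@temperature, object@RT))
  cat(sprintf("  min hairpin %d nt, max loop side %d nt\n",
              object@min_hairpin, object@max_loop_side))
  cat(sprintf("  duplex init %+.2f, terminal AU/GU %+.2f kcal/mol\n",
              object@duplex_init, object@terminal_au))
  cat(sprintf("  multiloop a=%.2f b=%.2f c=%.2f kcal/mol\n",
              object@ml_init, object@ml_branch, object@ml_unpaired))
})

setMethod("show", "DuplexResult", function(object) {
  if (is.na(object@dG)) {
    cat("DuplexResult: no hybrid\n")
    return(invisible(NULL))
  }
  cat(sprintf("DuplexResult: dG_hybrid = %.2f kcal/mol, %d pairs, target span [%d, %d)\n",
              object@dG, nrow(object@pairs),
              object@targetSpan[1], object@targetSpan[2]))
  cat(conformation(object), sep = "\n")
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d nt, lnZ = %.4f, dG_ensemble = %.3f kcal/mol\n",
              nchar(object@sequence), object@logZ, object@freeEnergy))
  if (length(object@pUnpaired))
    cat(sprintf("  mean p(unpaired) = %.3f\n", mean(object@pUnpaired)))
})

setMethod("show", "TranscriptDB", function(object) {
  n <- length(object@seqs)
  cat(sprintf("TranscriptDB: %d transcript(s), total %d nt\n",
              n, sum(Biostrings::width(object@seqs))))
  if (n) {
    shown <- head(names(object@seqs), 5)
    cat("  ", paste(shown, collapse = ", "),
        if (n > 5) ", ..." else "", "\n", sep = "")
  }
})
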