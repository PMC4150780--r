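#' @include energy-model.R AllGenerics.R
NULL

#' Minimum-free-energy miRNA:target duplex
#'
#' Computes the intermolecular minimum-free-energy hybrid between a miRNA
#' and a target segment by dynamic programming over all monotone,
#' non-crossing antiparallel pairings. The model scores stacks, bulges and
#' internal loops (each side at most \code{max_loop_side} nt), a duplex
#' initiation term and terminal AU/GU penalties; intramolecular pairs and
#' multiloops are outside the model. Ties are broken deterministically in
#' favor of the 5'-most target span.
#'
#' @param mirna,target RNA strings over A/C/G/U (T accepted, normalized).
#' @param model an \linkS4class{EnergyModel}; default [defaultEnergyModel()].
#' @return a \linkS4class{DuplexResult}; \code{duplexEnergy()} is \code{NA}
#'   when no pairing is possible or the best hybrid is unfavorable
#'   (\eqn{\Delta G > 0}).
#' @examples
#' d <- duplexMfe("UGAGGUAGUAGGUUGUAUAGUU", "ACUAUACAACCUACUACCUCA")
#' duplexEnergy(d)
#' @export
duplexMfe <- function(mirna, target, model = defaultEnergyModel()) {
  mirna <- normalizeSeq(mirna)
  target <- normalizeSeq(target)
  if (!nchar(mirna) || !nchar(target))
    stop("both sequences must be nonempty")
  res <- cpp_duplex_mfe(encodeRna(mirna), encodeRna(target),
                        modelToList(model))
  if (!res$found)
    return(new("DuplexResult", dG = NA_real_,
               pairs = matrix(integer(), 0, 2), targetSpan = c(0L, 0L),
               mirna = mirna, target = target))
  pm <- res$pairs
  colnames(pm) <- c("mirna", "target")
  span <- c(min(pm[, 2]) - 1L, max(pm[, 2]))
  new("DuplexResult", dG = res$dG, pairs = pm,
      targetSpan = as.integer(span), mirna = mirna, target = target)
}

#' @describeIn DuplexResult-class render the hybrid as a three-line
#'   alignment (target 5'->3' on top, pairing row, miRNA 3'->5' below;
#'   \code{|} Watson-Crick, \code{:} GU wobble).
#' @export
setMethod("conformation", "DuplexResult", function(x) {
  if (is.na(x@dG)) return(c("(no hybrid)", "", ""))
  mi <- strsplit(x@mirna, "")[[1]]
  tg <- strsplit(x@target, "")[[1]]
  # order pairs along the target (ascending j <=> descending miRNA i)
  p <- x@pairs[order(x@pairs[, 2]), , drop = FALSE]
  top <- chr <- bot <- character()
  for (r in seq_len(nrow(p))) {
    if (r > 1) {
      gt <- tg[(p[r - 1, 2] + 1):(p[r, 2] - 1)]
      if (p[r, 2] - p[r - 1, 2] <= 1) gt <- character()
      gm <- if (p[r - 1, 1] - p[r, 1] <= 1) character() else
        rev(mi[(p[r, 1] + 1):(p[r - 1, 1] - 1)])
      w <- max(length(gt), length(gm))
      if (w > 0) {
        top <- c(top, gt, rep("-", w - length(gt)))
        chr <- c(chr, rep(" ", w))
        bot <- c(bot, gm, rep("-", w - length(gm)))
      }
    }
    a <- mi[p[r, 1]]; b <- tg[p[r, 2]]
    top <- c(top, b)
    chr <- c(chr, if (isWatsonCrick(a, b)) "|" else ":")
    bot <- c(bot, a)
  }
  c(paste0("5' ", paste(top, collapse = ""), " 3'  target"),
    paste0("   ", paste(chr, collapse = "")),
    paste0("3' ", paste(bot, collapse = ""), " 5'  miRNA"))
})

#' Boltzmann ensemble of a single RNA sequence
#'
#' Exact partition function over all pseudoknot-free secondary structures
#' (allowed pairs AU/UA/CG/GC/GU/UG, hairpin loops of at least
#' \code{min_hairpin} nt) under the package energy model, computed by
#' inside/outside recursions in log space. Per-nucleotide single-
#' strandedness probabilities come from the outside pass.
#'
#' @inheritParams duplexMfe
#' @param seq RNA string.
#' @return an \linkS4class{Ensemble}.
#' @examples
#' e <- partitionFunction("GGGAAACCCAAAGGGAAACCC")
#' logPartition(e)
#' @export
partitionFunction <- function(seq, model = defaultEnergyModel()) {
  seq <- normalizeSeq(seq)
  if (!nchar(seq)) stop("sequence must be nonempty")
  res <- cpp_pfold(encodeRna(seq), modelToList(model),
                   logical(nchar(seq)), TRUE)
  new("Ensemble", logZ = res$logZ, freeEnergy = -model@RT * res$logZ,
      pUnpaired = as.numeric(res$pUnpaired), sequence = seq)
}

#' Constrained partition function
#'
#' Log partition function restricted to structures in which every
#' nucleotide of \code{interval} is unpaired. Always \code{<=} the
#' unconstrained log partition function.
#'
#' @inheritParams partitionFunction
#' @param interval integer(2), 0-based half-open interval forced
#'   single-stranded; an empty interval returns the full lnZ.
#' @return scalar, \eqn{\ln Z_c}.
#' @export
constrainedLogPartition <- function(seq, interval,
                                    model = defaultEnergyModel()) {
  seq <- normalizeSeq(seq)
  n <- nchar(seq)
  interval <- as.integer(interval)
  if (interval[1] > interval[2] || interval[1] < 0 || interval[2] > n)
    stop("interval must lie within the sequence")
  mask <- logical(n)
  if (interval[2] > interval[1])
    mask[(interval[1] + 1):interval[2]] <- TRUE
  cpp_pfold(encodeRna(seq), modelToList(model), mask, FALSE)$logZ
}

#' Opening energy of a target block
#'
#' Ensemble free-energy cost of forcing a block single-stranded:
#' \eqn{\Delta G_{open} = -RT (\ln Z_c - \ln Z) =
#' -RT \ln P(\mathrm{block\ unpaired})}. Non-negative by construction.
#'
#' @inheritParams constrainedLogPartition
#' @return scalar kcal/mol, \code{>= 0}.
#' @export
openingEnergy <- function(seq, interval, model = defaultEnergyModel()) {
  seq <- normalizeSeq(seq)
  lnZ <- cpp_pfold(encodeRna(seq), modelToList(model),
                   logical(nchar(seq)), FALSE)$logZ
  lnZc <- constrainedLogPartition(seq, interval, model)
  max(0, -model@RT * (lnZc - lnZ))
}

#' Block accessibility
#'
#' Mean probability that each nucleotide of a block is single-stranded in
#' the Boltzmann ensemble.
#'
#' @inheritParams constrainedLogPartition
#' @param interval integer(2), nonempty 0-based half-open block.
#' @param ensemble optionally, a precomputed \linkS4class{Ensemble} for
#'   \code{seq} (avoids refolding).
#' @return fraction in [0, 1].
#' @export
blockAccessibility <- function(seq, interval, model = defaultEnergyModel(),
                               ensemble = NULL) {
  interval <- as.integer(interval)
  if (interval[2] <= interval[1]) stop("block must be nonempty")
  if (is.null(ensemble)) ensemble <- partitionFunction(seq, model)
  pu <- pUnpaired(ensemble)
  if (interval[1] < 0 || interval[2] > length(pu))
    stop("block must lie within the sequence")
  mean(pu[(interval[1] + 1):interval[2]])
}

#' Sample secondary structures from the Boltzmann ensemble
#'
#' Stochastic traceback from the inside matrices: each structure is drawn
#' with its Boltzmann probability. Randomness flows through R's RNG, so
#' \code{set.seed()} makes draws reproducible.
#'
#' @inheritParams partitionFunction
#' @param n number of structures to draw.
#' @param seed integer seed (required; applied via \code{set.seed}).
#' @return character vector of dot-bracket strings, length \code{n}.
#' @export
sampleStructures <- function(seq, n, model = defaultEnergyModel(),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  seq <- normalizeSeq(seq)
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  cpp_sample_structures(encodeRna(seq), modelToList(model), as.integer(n))
}
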