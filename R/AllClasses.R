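#' @include utils.R
NULL

#' Nearest-neighbor RNA energy model
#'
#' Holds the pinned thermodynamic parameter set used by every folding
#' routine: the 6x6 base-pair doublet stacking table (kcal/mol), hairpin /
#' bulge / internal-loop size penalties with a logarithmic extrapolation
#' beyond the tabulated sizes, the affine multiloop model, terminal AU/GU
#' penalty, intermolecular duplex initiation, and the temperature scale.
#' Allowed pairs are AU, UA, CG, GC, GU, UG.
#'
#' @slot stack 6x6 numeric matrix, dimnames the pair codes
#'   (AU, UA, CG, GC, GU, UG); entry \code{[p1, p2]} is the stack
#'   5'-p1-p2-3' in kcal/mol. Must satisfy the strand-reversal symmetry
#'   \code{E[p1,p2] == E[rev(p2),rev(p1)]}.
#' @slot hairpin,bulge,internal numeric vectors of loop penalties by size
#'   (kcal/mol, index = loop size in nt; NA = disallowed size).
#' @slot loop_extrap coefficient of the \code{log(size/max)} extrapolation.
#' @slot terminal_au terminal AU/GU closing penalty (kcal/mol).
#' @slot duplex_init intermolecular duplex initiation (kcal/mol).
#' @slot ml_init,ml_branch,ml_unpaired affine multiloop parameters.
#' @slot temperature kelvin.
#' @slot RT kcal/mol; must equal the gas constant times temperature.
#' @slot min_hairpin minimal hairpin loop size (nt).
#' @slot max_loop_side maximal bulge/internal loop size per side (nt).
#' @exportClass EnergyModel
setClass("EnergyModel",
  representation(
    stack = "matrix",
    hairpin = "numeric",
    bulge = "numeric",
    internal = "numeric",
    loop_extrap = "numeric",
    terminal_au = "numeric",
    duplex_init = "numeric",
    ml_init = "numeric",
    ml_branch = "numeric",
    ml_unpaired = "numeric",
    temperature = "numeric",
    RT = "numeric",
    min_hairpin = "integer",
    max_loop_side = "integer"
  )
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  st <- object@stack
  if (!all(dim(st) == c(6, 6)) ||
      !identical(rownames(st), PAIR_CODES) ||
      !identical(colnames(st), PAIR_CODES))
    msg <- c(msg, "stack must be 6x6 with pair-code dimnames")
  else {
    revp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    for (p1 in PAIR_CODES) for (p2 in PAIR_CODES)
      if (abs(st[p1, p2] - st[revp(p2), revp(p1)]) > 1e-9) {
        msg <- c(msg, "stack table violates strand-reversal symmetry")
        break
      }
  }
  if (any(object@hairpin < 0, na.rm = TRUE) ||
      any(object@bulge < 0, na.rm = TRUE) ||
      any(object@internal < 0, na.rm = TRUE))
    msg <- c(msg, "loop penalties must be non-negative")
  Rgas <- 0.0019872
  if (abs(object@RT - Rgas * object@temperature) > 1e-3)
    msg <- c(msg, "RT must equal gas constant x temperature")
  if (length(msg)) msg else TRUE
})

#' Result of an intermolecular duplex fold
#'
#' The minimum-free-energy hybrid between a miRNA (5'->3') and a target
#' segment, or a "no hybrid" sentinel when no favorable duplex exists.
#'
#' @slot dG hybrid free energy in kcal/mol; \code{NA} when no hybrid.
#' @slot pairs two-column integer matrix of (miRNA index, target index)
#'   pairs, 1-based within the folded sequences, monotone and non-crossing.
#' @slot targetSpan integer(2), 0-based half-open interval on the target
#'   covered by the hybrid (c(0, 0) when no hybrid).
#' @slot mirna,target the folded sequences (RNA strings).
#' @exportClass DuplexResult
setClass("DuplexResult",
  representation(
    dG = "numeric",
    pairs = "matrix",
    targetSpan = "integer",
    mirna = "character",
    target = "character"
  )
)

setValidity("DuplexResult", function(object) {
  p <- object@pairs
  if (nrow(p)) {
    if (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) >= 0))
      return("pairs must be monotone (miRNA ascending, target descending)")
  }
  TRUE
})

#' Boltzmann ensemble of a folded RNA sequence
#'
#' @slot logZ natural log of the partition function (open chain = 1, so
#'   \code{logZ >= 0}).
#' @slot freeEnergy ensemble free energy \code{-RT * logZ} (kcal/mol).
#' @slot pUnpaired per-nucleotide probability of being single-stranded.
#' @slot sequence the folded RNA string.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(
    logZ = "numeric",
    freeEnergy = "numeric",
    pUnpaired = "numeric",
    sequence = "character"
  )
)

setValidity("Ensemble", function(object) {
  msg <- character()
  if (object@logZ < -1e-9) msg <- c(msg, "logZ must be >= 0")
  if (length(object@pUnpaired) &&
      (min(object@pUnpaired) < -1e-9 || max(object@pUnpaired) > 1 + 1e-9))
    msg <- c(msg, "pUnpaired must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Transcript database
#'
#' A set of transcripts: RNA sequences plus, per transcript, the region
#' annotation (5UTR / CDS / 3UTR intervals in transcript coordinates,
#' tiling the transcript) and the ordered genomic exon blocks.
#'
#' @slot seqs named \code{Biostrings::RNAStringSet}.
#' @slot regions data.frame with columns \code{transcript_id},
#'   \code{region} (5UTR/CDS/3UTR), \code{start}, \code{end}
#'   (0-based half-open transcript coordinates).
#' @slot exons data.frame with columns \code{transcript_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; rows ordered 5'->3' on the
#'   genome within each transcript.
#' @exportClass TranscriptDB
setClass("TranscriptDB",
  representation(
    seqs = "ANY",
    regions = "data.frame",
    exons = "data.frame"
  )
)

setValidity("TranscriptDB", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequences must be uniquely named")
  lens <- Biostrings::width(object@seqs)
  names(lens) <- ids
  reg <- object@regions
  for (id in unique(reg$transcript_id)) {
    r <- reg[reg$transcript_id == id, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (!(id %in% ids)) { msg <- c(msg, paste0("regions refer to unknown transcript ", id)); next }
    if (r$start[1] != 0L || r$end[nrow(r)] != lens[[id]] ||
        (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)])))
      msg <- c(msg, paste0("regions of ", id, " must tile [0, length)"))
  }
  ex <- object@exons
  if (nrow(ex)) {
    for (id in unique(ex$transcript_id)) {
      if (!(id %in% ids)) { msg <- c(msg, paste0("exons refer to unknown transcript ", id)); next }
      e <- ex[ex$transcript_id == id, , drop = FALSE]
      if (sum(e$end - e$start) != lens[[id]])
        msg <- c(msg, paste0("exon lengths of ", id, " do not sum to sequence length"))
    }
  }
  if (length(msg)) msg else TRUE
})
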