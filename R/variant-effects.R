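#' @include site-features.R
NULL

#' Place variants relative to located binding sites
#'
#' A variant is \code{within_site} when its reference span intersects the
#' site interval (SNPs and indels); \code{upstream_25} / \code{downstream_25}
#' when it is a SNP inside the corresponding flank block. Indels in flank
#' blocks are dropped with a logged count (the flank analysis is SNP-only,
#' to keep the block length well defined); variants outside all three
#' intervals are unassigned. One row per (variant, chimera) pair.
#'
#' @param variants variant table from [readVcfVariants()].
#' @param features site feature table (\code{chimera_id, transcript_id,
#'   site_start, site_end}) from [siteFeatureTable()].
#' @param flank flank block length in nt (default 25).
#' @return data.frame \code{(variant_id, chimera_id, placement)} with
#'   attribute \code{n_flank_indels_dropped}.
#' @export
placeVariants <- function(variants, features, flank = 25L) {
  rows <- list(); dropped <- 0L
  for (f in seq_len(nrow(features))) {
    tid <- features$transcript_id[f]
    s <- features$site_start[f]; e <- features$site_end[f]
    vv <- variants[variants$transcript_id == tid, , drop = FALSE]
    for (v in seq_len(nrow(vv))) {
      span <- c(vv$pos[v], vv$pos[v] + nchar(vv$ref[v]))
      placement <- NA_character_
      if (intervalsOverlap(span[1], span[2], s, e)) {
        placement <- "within_site"
      } else if (vv$pos[v] >= s - flank && vv$pos[v] < s) {
        if (vv$var_class[v] == "SNP") placement <- "upstream_25"
        else dropped <- dropped + 1L
      } else if (vv$pos[v] >= e && vv$pos[v] < e + flank) {
        if (vv$var_class[v] == "SNP") placement <- "downstream_25"
        else dropped <- dropped + 1L
      }
      if (!is.na(placement))
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vv$id[v], chimera_id = features$chimera_id[f],
          placement = placement, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), chimera_id = character(),
               placement = character(), stringsAsFactors = FALSE)
  attr(out, "n_flank_indels_dropped") <- dropped
  out
}

#' Apply a variant to a transcript sequence
#'
#' Substitutes the alternate allele and returns the mutant sequence with a
#' coordinate map carrying wild-type positions into mutant coordinates
#' (positions downstream of an indel shift by the length difference;
#' positions inside a replaced span clamp into it).
#'
#' @param seq transcript RNA string.
#' @param pos 0-based variant position.
#' @param ref,alt alleles (RNA strings; \code{ref} must match \code{seq}
#'   at \code{pos}).
#' @return list with \code{seq} (mutant string) and \code{map} (vectorized
#'   function wild-type position -> mutant position).
#' @export
applyVariant <- function(seq, pos, ref, alt) {
  pos <- as.integer(pos)
  nref <- nchar(ref); nalt <- nchar(alt)
  obs <- substr0(seq, pos, pos + nref)
  if (obs != ref)
    stop("ref allele ", ref, " does not match sequence (", obs,
         ") at position ", pos)
  mut <- paste0(substr0(seq, 0L, pos), alt,
                substr0(seq, pos + nref, nchar(seq)))
  d <- nalt - nref
  map <- function(x) {
    x <- as.integer(x)
    ifelse(x <= pos, x,
           ifelse(x >= pos + nref, x + d, pos + pmin(x - pos, nalt)))
  }
  list(seq = mut, map = map)
}

# mutant TranscriptDB for one transcript: sequence replaced, region
# boundaries carried through the coordinate map, single synthetic exon
mutantDb <- function(db, transcript_id, mut) {
  newlen <- nchar(mut$seq)
  reg <- regionTable(db)
  reg <- reg[reg$transcript_id == transcript_id, , drop = FALSE]
  reg <- reg[order(reg$start), , drop = FALSE]
  bounds <- c(0L, if (nrow(reg) > 1) mut$map(reg$end[-nrow(reg)]), newlen)
  bounds <- cummax(bounds)
  keep <- which(diff(bounds) > 0)
  reg2 <- data.frame(transcript_id = transcript_id,
                     region = reg$region[keep],
                     start = bounds[keep], end = bounds[keep + 1L],
                     stringsAsFactors = FALSE)
  seqs <- Biostrings::RNAStringSet(setNames(mut$seq, transcript_id))
  ex <- data.frame(transcript_id = transcript_id, chrom = transcript_id,
                   start = 0L, end = newlen, strand = "+",
                   stringsAsFactors = FALSE)
  new("TranscriptDB", seqs = seqs, regions = reg2, exons = ex)
}

#' Five effect measures for one (variant, chimera) pair
#'
#' Builds the mutant transcript, re-localizes the binding site for
#' within-site variants by a fresh duplex scan of the mutated fragment
#' (flank variants keep the mapped site, and their
#' \eqn{\Delta\Delta G_{hybrid}} is identically 0), folds the mutant with
#' the wild-type folding window carried through the coordinate map, and
#' reports mutant-minus-wild-type differences of the five measures.
#'
#' @param variant one-row slice of the variant table.
#' @param chimera one-row slice of the chimera table.
#' @param placement \code{"within_site"}, \code{"upstream_25"} or
#'   \code{"downstream_25"}.
#' @param located [locateSite()] result for the wild-type chimera.
#' @param wt_features matching one-row slice of the site feature table.
#' @param db a \linkS4class{TranscriptDB}.
#' @param model an \linkS4class{EnergyModel}.
#' @param flank flank block length (nt).
#' @param maf_threshold MAF at and above which a variant is common
#'   (default 0.01).
#' @return one-row data.frame: wild-type and mutant values of the five
#'   measures, their deltas, frequency class and flags (\code{site_lost}:
#'   mutant fragment has no hybrid; \code{site_destroyed}: the variant
#'   deletes the whole wild-type site, deltas then refer to the best
#'   remaining hybrid).
#' @export
computeVariantEffect <- function(variant, chimera, placement, located,
                                 wt_features, db,
                                 model = defaultEnergyModel(), flank = 25L,
                                 maf_threshold = 0.01) {
  tid <- variant$transcript_id
  stopifnot(identical(tid, chimera$transcript_id))
  tseq <- transcriptSeq(db, tid)
  mut <- applyVariant(tseq, variant$pos, variant$ref, variant$alt)
  mdb <- mutantDb(db, tid, mut)
  mlen <- nchar(mut$seq)
  site <- c(wt_features$site_start, wt_features$site_end)
  win <- c(wt_features$window_start, wt_features$window_end)
  mwin <- c(mut$map(win[1]), min(mlen, mut$map(win[2])))
  frag <- c(chimera$frag_start, chimera$frag_end)
  mfrag <- c(mut$map(frag[1]), min(mlen, mut$map(frag[2])))
  vspan <- c(variant$pos, variant$pos + nchar(variant$ref))
  site_destroyed <- variant$var_class == "indel" &&
    nchar(variant$alt) < nchar(variant$ref) &&
    vspan[1] <= site[1] && vspan[2] >= site[2]

  site_lost <- FALSE
  if (placement == "within_site") {
    mloc <- locateSite(chimera$mirna_seq, mdb, tid, mfrag, model)
    if (mloc$site_found) {
      msite <- mloc$site
      mut_dG_hybrid <- duplexEnergy(mloc$duplex)
    } else {
      site_lost <- TRUE
      msite <- c(mut$map(site[1]), mut$map(site[2]))
      mut_dG_hybrid <- NA_real_
    }
  } else {
    # flank variant: site sequence untouched, hybrid energy unchanged
    msite <- c(mut$map(site[1]), mut$map(site[2]))
    mut_dG_hybrid <- wt_features$dG_hybrid
  }
  if (msite[2] <= msite[1]) { # degenerate mapped site (full deletion)
    site_lost <- TRUE
    msite <- c(max(0L, msite[1] - 1L), min(mlen, msite[1] + 1L))
  }
  macc <- windowAccess(mut$seq, mlen, msite, mwin, flank, model)
  mut_dG_total <- mut_dG_hybrid + macc$dG_open
  maf <- variant$maf
  freq_class <- if (is.na(maf)) "unknown"
                else if (maf >= maf_threshold) "common" else "rare"
  ddG_hybrid <- if (placement != "within_site") 0.0
                else mut_dG_hybrid - wt_features$dG_hybrid
  data.frame(
    variant_id = variant$id, chimera_id = chimera$chimera_id,
    transcript_id = tid, placement = placement,
    var_class = variant$var_class, maf = maf, freq_class = freq_class,
    wt_dG_hybrid = wt_features$dG_hybrid,
    wt_dG_total = wt_features$dG_total,
    wt_site_access = wt_features$site_access,
    wt_upstream_access = wt_features$upstream_access,
    wt_downstream_access = wt_features$downstream_access,
    mut_dG_hybrid = mut_dG_hybrid,
    mut_dG_total = mut_dG_total,
    mut_site_access = macc$site_access,
    mut_upstream_access = macc$upstream_access,
    mut_downstream_access = macc$downstream_access,
    ddG_hybrid = ddG_hybrid,
    ddG_total = mut_dG_total - wt_features$dG_total,
    d_site_access = macc$site_access - wt_features$site_access,
    d_upstream_access = macc$upstream_access - wt_features$upstream_access,
    d_downstream_access = macc$downstream_access -
      wt_features$downstream_access,
    site_lost = site_lost, site_destroyed = site_destroyed,
    stringsAsFactors = FALSE)
}

#' Effect table for a whole cohort
#'
#' Places every variant against every located site and computes the five
#' effect measures per (variant, chimera) pair.
#'
#' @param variants variant table.
#' @param chimeras chimera table.
#' @param sft result of [siteFeatureTable()].
#' @inheritParams computeVariantEffect
#' @return list with \code{effects} (data.frame), \code{placements}, and
#'   stage counts.
#' @export
variantEffectTable <- function(variants, chimeras, sft, db,
                               model = defaultEnergyModel(), flank = 25L,
                               maf_threshold = 0.01) {
  pl <- placeVariants(variants, sft$features, flank = flank)
  rows <- list()
  for (r in seq_len(nrow(pl))) {
    v <- variants[variants$id == pl$variant_id[r], , drop = FALSE][1, ]
    ch <- chimeras[chimeras$chimera_id == pl$chimera_id[r], , drop = FALSE][1, ]
    ft <- sft$features[sft$features$chimera_id == pl$chimera_id[r], ,
                       drop = FALSE][1, ]
    rows[[length(rows) + 1L]] <- computeVariantEffect(
      v, ch, pl$placement[r], sft$located[[pl$chimera_id[r]]], ft, db,
      model = model, flank = flank, maf_threshold = maf_threshold)
  }
  effects <- if (length(rows)) do.call(rbind, rows) else NULL
  list(effects = effects, placements = pl,
       n_flank_indels_dropped = attr(pl, "n_flank_indels_dropped"),
       n_records = length(rows))
}

#' Does a record alter site accessibility?
#'
#' TRUE when \code{|d_site_access|} exceeds the cutoff \code{theta}.
#'
#' @param records effect table (needs \code{d_site_access}).
#' @param theta positive cutoff (default 0.01).
#' @return logical vector.
#' @export
accessibilityEffectFlag <- function(records, theta = 0.01) {
  if (theta <= 0) stop("theta must be positive")
  abs(records$d_site_access) > theta
}
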