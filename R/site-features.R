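#' @include rna-energy.R formats-io.R
NULL

SEED_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "offset-6mer", "6mer",
                "seedless")

#' Locate the miRNA binding site within a chimera fragment
#'
#' Folds the miRNA against the fragment sequence with [duplexMfe()]; the
#' binding site is the target span of the optimal hybrid, reported in
#' transcript coordinates. Chimeras with no favorable hybrid are flagged
#' site-less (and excluded downstream with a logged count).
#'
#' @param mirna_seq miRNA sequence (5'->3').
#' @param db a \linkS4class{TranscriptDB}.
#' @param transcript_id target transcript.
#' @param frag integer(2), 0-based half-open fragment interval.
#' @param model an \linkS4class{EnergyModel}.
#' @return list with \code{duplex} (\linkS4class{DuplexResult}),
#'   \code{site} (0-based half-open transcript interval or \code{NULL}),
#'   \code{site_found} flag.
#' @export
locateSite <- function(mirna_seq, db, transcript_id, frag,
                       model = defaultEnergyModel()) {
  len <- transcriptLength(db, transcript_id)
  frag <- as.integer(frag)
  if (frag[1] < 0 || frag[2] > len || frag[1] >= frag[2])
    stop("fragment outside transcript bounds")
  fragseq <- substr0(transcriptSeq(db, transcript_id), frag[1], frag[2])
  dup <- duplexMfe(mirna_seq, fragseq, model)
  if (is.na(duplexEnergy(dup)))
    return(list(duplex = dup, site = NULL, site_found = FALSE))
  sp <- targetSpan(dup)
  list(duplex = dup, site = c(frag[1] + sp[1], frag[1] + sp[2]),
       site_found = TRUE)
}

# 0-based target position opposite miRNA nt 1, extrapolated from the
# 5'-most paired miRNA nucleotide (antiparallel register)
seedAnchor <- function(duplex, offset = 0L) {
  p <- duplexPairs(duplex)
  if (!nrow(p)) return(NA_integer_)
  r <- which.min(p[, 1])
  i0 <- p[r, 1]; j0 <- p[r, 2]          # 1-based within target
  as.integer(offset + (j0 - 1L) + (i0 - 1L))
}

#' Classify a binding site into canonical seed classes
#'
#' Classes follow the standard definitions on the target sequence, with
#' Watson-Crick matches only (GU never counts): 6mer = match to miRNA nts
#' 2-7; 7mer-m8 = nts 2-8; 7mer-A1 = nts 2-7 plus a target A opposite nt 1;
#' 8mer = nts 2-8 plus the A; offset-6mer = nts 3-8. The most specific
#' class wins (8mer > 7mer-m8 > 7mer-A1 > offset-6mer > 6mer); anything
#' else is seedless. When the position opposite nt 1 falls outside the
#' transcript, the A1-dependent classes are unavailable but the others are
#' still tested.
#'
#' @param mirna_seq miRNA sequence (5'->3').
#' @param target_seq target (transcript) sequence.
#' @param site 0-based half-open site interval (used only to infer the
#'   register when no \code{duplex}/\code{anchor} is given: miRNA nt 1 is
#'   then assumed opposite the base just 3' of the site).
#' @param duplex optional \linkS4class{DuplexResult} localizing the site;
#'   the register is extrapolated from its 5'-most miRNA pair.
#' @param anchor optional explicit 0-based target position opposite miRNA
#'   nt 1 (overrides both).
#' @param offset 0-based offset of the duplex target within
#'   \code{target_seq} (fragment start), when \code{duplex} is given.
#' @return one of \code{"8mer", "7mer-m8", "7mer-A1", "offset-6mer",
#'   "6mer", "seedless"}.
#' @export
classifySeed <- function(mirna_seq, target_seq, site = NULL, duplex = NULL,
                         anchor = NULL, offset = 0L) {
  mirna_seq <- normalizeSeq(mirna_seq)
  mch <- strsplit(mirna_seq, "")[[1]]
  tch <- strsplit(toupper(target_seq), "")[[1]]
  t1 <- if (!is.null(anchor)) as.integer(anchor)
        else if (!is.null(duplex)) seedAnchor(duplex, offset)
        else if (!is.null(site)) as.integer(site[2])
        else stop("one of anchor, duplex or site is required")
  if (is.na(t1)) return("seedless")
  match_range <- function(k1, k2) {
    if (k2 > length(mch)) return(FALSE)
    for (k in k1:k2) {
      tp <- t1 - (k - 1L)              # 0-based
      if (tp < 0 || tp >= length(tch)) return(FALSE)
      if (!isWatsonCrick(mch[k], tch[tp + 1L])) return(FALSE)
    }
    TRUE
  }
  hasA1 <- t1 >= 0 && t1 < length(tch) && tch[t1 + 1L] == "A"
  if (match_range(2, 8) && hasA1) return("8mer")
  if (match_range(2, 8)) return("7mer-m8")
  if (match_range(2, 7) && hasA1) return("7mer-A1")
  if (match_range(3, 8)) return("offset-6mer")
  if (match_range(2, 7)) return("6mer")
  "seedless"
}

#' Maximal 3' pairing run of a duplex
#'
#' Longest run of consecutive Watson-Crick pairs (GU excluded, and a GU
#' pair breaks a run) among miRNA nucleotides 12 to the 3' end;
#' "consecutive" means adjacent on both strands.
#'
#' @param duplex a \linkS4class{DuplexResult}.
#' @param from first miRNA position counted (default 12).
#' @return integer run length (0 when no qualifying pair).
#' @export
threePrimePairingLength <- function(duplex, from = 12L) {
  p <- duplexPairs(duplex)
  if (!nrow(p)) return(0L)
  mch <- strsplit(duplex@mirna, "")[[1]]
  tch <- strsplit(duplex@target, "")[[1]]
  best <- run <- 0L
  prev <- NULL
  for (r in order(p[, 1])) {
    i <- p[r, 1]; j <- p[r, 2]
    wc <- i >= from && isWatsonCrick(mch[i], tch[j])
    contiguous <- !is.null(prev) && i == prev[1] + 1L && j == prev[2] - 1L
    run <- if (wc && (contiguous && run > 0L)) run + 1L
           else if (wc) 1L else 0L
    best <- max(best, run)
    prev <- c(i, j)
  }
  best
}

#' Mean conservation of a site
#'
#' Arithmetic mean of the per-nucleotide conservation scores over the site
#' interval; missing values are excluded, an all-missing site is missing.
#'
#' @param track numeric score vector for the transcript.
#' @param site 0-based half-open interval.
#' @return mean score in [0, 1] or \code{NA}.
#' @export
conservationScore <- function(track, site) {
  site <- as.integer(site)
  if (site[1] < 0 || site[2] > length(track) || site[1] >= site[2])
    stop("site must be a nonempty interval covered by the track")
  v <- track[(site[1] + 1):site[2]]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

# folding window of `window` nt centered on the site, truncated at ends
defaultWindow <- function(site, len, window) {
  center <- (site[1] + site[2]) %/% 2L
  ws <- max(0L, center - window %/% 2L)
  we <- min(len, ws + window)
  ws <- max(0L, we - window)
  c(ws, we)
}

# region label containing the site midpoint; "spanning" across boundaries
siteRegion <- function(db, transcript_id, site) {
  reg <- regionTable(db)
  reg <- reg[reg$transcript_id == transcript_id, , drop = FALSE]
  hit <- reg[intervalsOverlap(reg$start, reg$end, site[1], site[2]), ,
             drop = FALSE]
  if (nrow(hit) > 1) return("spanning")
  if (nrow(hit) == 1) return(hit$region)
  NA_character_
}

# ensemble accessibility of site + flank blocks within a folding window;
# shared by WT and mutant feature paths
windowAccess <- function(tseq, len, site, win, flank, model) {
  wseq <- substr0(tseq, win[1], win[2])
  ens <- partitionFunction(wseq, model)
  pu <- pUnpaired(ens)
  rel <- function(iv) c(max(0L, iv[1] - win[1]),
                        min(win[2] - win[1], iv[2] - win[1]))
  blockMean <- function(iv) {
    r <- rel(iv)
    if (r[2] <= r[1]) return(NA_real_)
    mean(pu[(r[1] + 1):r[2]])
  }
  up_clip <- c(max(0L, site[1] - flank), site[1])
  dn_clip <- c(site[2], min(len, site[2] + flank))
  list(site_access = blockMean(site),
       upstream_access = blockMean(up_clip),
       downstream_access = blockMean(dn_clip),
       upstream_truncated = up_clip[2] - up_clip[1] < flank,
       downstream_truncated = dn_clip[2] - dn_clip[1] < flank,
       dG_open = openingEnergy(wseq, rel(site), model))
}

#' Thermodynamic and structural features of one located site
#'
#' Folds a transcript window centered on the binding site (Boltzmann
#' ensemble) and computes: hybrid energy, opening energy of the site,
#' total hybridization energy \eqn{\Delta G_{total} = \Delta G_{hybrid} +
#' \Delta G_{open}}, mean accessibility of the site and of the 25-nt
#' blocks immediately 5' (upstream) and 3' (downstream) of it, seed type,
#' 3' pairing run, site conservation, and the region label. Flank blocks
#' truncated by a transcript end use the available nucleotides and are
#' flagged; a flank with no nucleotides is missing.
#'
#' @param located result of [locateSite()] (must have a site).
#' @param db a \linkS4class{TranscriptDB}.
#' @param transcript_id target transcript.
#' @param track optional conservation score vector for the transcript.
#' @param model an \linkS4class{EnergyModel}.
#' @param window folding window size in nt (default 200).
#' @param flank flank block length in nt (default 25).
#' @param window_interval optional explicit 0-based half-open folding
#'   window (overrides centering; used to keep mutant folds comparable).
#' @return one-row data.frame of features.
#' @export
computeSiteFeatures <- function(located, db, transcript_id, track = NULL,
                                model = defaultEnergyModel(), window = 200L,
                                flank = 25L, window_interval = NULL) {
  if (!located$site_found) stop("chimera has no located site")
  site <- located$site
  len <- transcriptLength(db, transcript_id)
  win <- if (is.null(window_interval)) defaultWindow(site, len, window)
         else as.integer(window_interval)
  tseq <- transcriptSeq(db, transcript_id)
  acc <- windowAccess(tseq, len, site, win, flank, model)
  dG_hybrid <- duplexEnergy(located$duplex)
  cons <- if (is.null(track)) NA_real_ else conservationScore(track, site)
  data.frame(
    transcript_id = transcript_id,
    site_start = site[1], site_end = site[2],
    window_start = win[1], window_end = win[2],
    dG_hybrid = dG_hybrid,
    dG_open = acc$dG_open,
    dG_total = dG_hybrid + acc$dG_open,
    site_access = acc$site_access,
    upstream_access = acc$upstream_access,
    downstream_access = acc$downstream_access,
    upstream_truncated = acc$upstream_truncated,
    downstream_truncated = acc$downstream_truncated,
    seed_type = classifySeed(located$duplex@mirna, tseq,
                             duplex = located$duplex,
                             offset = site[1] - targetSpan(located$duplex)[1]),
    three_prime_pairing = threePrimePairingLength(located$duplex),
    conservation = cons,
    region = siteRegion(db, transcript_id, site),
    stringsAsFactors = FALSE)
}

#' Locate and featurize every chimera of a cohort
#'
#' Batch wrapper over [locateSite()] and [computeSiteFeatures()]. Site-less
#' chimeras are excluded and counted.
#'
#' @param chimeras chimera table from [readChimeras()].
#' @param db a \linkS4class{TranscriptDB}.
#' @param tracks named list of conservation vectors (or \code{NULL}).
#' @inheritParams computeSiteFeatures
#' @return list with \code{features} (one row per located chimera, keyed
#'   by \code{chimera_id}, including the conformation string),
#'   \code{located} (named list of [locateSite()] results) and
#'   \code{n_siteless}.
#' @export
siteFeatureTable <- function(chimeras, db, tracks = NULL,
                             model = defaultEnergyModel(), window = 200L,
                             flank = 25L) {
  rows <- list(); located <- list(); n_siteless <- 0L
  for (r in seq_len(nrow(chimeras))) {
    cid <- chimeras$chimera_id[r]
    tid <- chimeras$transcript_id[r]
    loc <- locateSite(chimeras$mirna_seq[r], db, tid,
                      c(chimeras$frag_start[r], chimeras$frag_end[r]), model)
    if (!loc$site_found) { n_siteless <- n_siteless + 1L; next }
    located[[cid]] <- loc
    ft <- computeSiteFeatures(loc, db, tid,
                              track = tracks[[tid]], model = model,
                              window = window, flank = flank)
    ft <- cbind(data.frame(chimera_id = cid,
                           mirna_id = chimeras$mirna_id[r],
                           stringsAsFactors = FALSE), ft)
    ft$conformation <- paste(conformation(loc$duplex), collapse = " / ")
    rows[[length(rows) + 1L]] <- ft
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  list(features = features, located = located, n_siteless = n_siteless)
}
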