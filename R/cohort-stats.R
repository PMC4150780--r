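#' @include variant-effects.R
NULL

# merge overlapping 0-based half-open intervals (matrix with start, end)
mergeIntervals <- function(starts, ends) {
  if (!length(starts)) return(cbind(start = integer(), end = integer()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) me <- max(me, ends[k])
    else { out <- rbind(out, c(ms, me)); ms <- starts[k]; me <- ends[k] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}

.freqClass <- function(maf, maf_threshold) {
  ifelse(is.na(maf), "unknown",
         ifelse(maf >= maf_threshold, "common", "rare"))
}

#' Variant density per region and scope
#'
#' Density = number of variants / region length (variants per nt), for the
#' regions mRNA (entire transcript), CDS and 3'UTR (the 5'UTR is not an
#' analysis region), at three scopes: the whole transcriptome, the
#' transcripts represented by at least one chimera, and the binding sites
#' themselves (overlapping site intervals are merged per transcript before
#' length and membership are computed).
#'
#' @param variants variant table.
#' @param db a \linkS4class{TranscriptDB}.
#' @param chimeras chimera table (defines which transcripts interact).
#' @param features site feature table (needed for the binding-site scope).
#' @param scope one of \code{"whole_transcriptome"},
#'   \code{"clash_transcripts"}, \code{"binding_sites"}.
#' @param freq_class \code{"common"}, \code{"rare"} or \code{"all"}
#'   (variants without MAF are excluded from common/rare strata).
#' @param maf_threshold common/rare boundary (default 0.01).
#' @param dedupe \code{"per_transcript"} (default: each variant record
#'   counts on its transcript) or \code{"per_variant"} (each variant id
#'   counts once, on its first transcript).
#' @return data.frame with one row per region: \code{scope, region,
#'   freq_class, n_variants, total_length, density}.
#' @export
variantDensity <- function(variants, db, chimeras = NULL, features = NULL,
                           scope = c("whole_transcriptome",
                                     "clash_transcripts", "binding_sites"),
                           freq_class = c("all", "common", "rare"),
                           maf_threshold = 0.01,
                           dedupe = c("per_transcript", "per_variant")) {
  scope <- match.arg(scope)
  freq_class <- match.arg(freq_class)
  dedupe <- match.arg(dedupe)
  if (dedupe == "per_variant" && nrow(variants))
    variants <- variants[!duplicated(variants$id), , drop = FALSE]
  if (freq_class != "all" && nrow(variants)) {
    fc <- .freqClass(variants$maf, maf_threshold)
    variants <- variants[fc == freq_class, , drop = FALSE]
  }
  tids <- if (scope == "whole_transcriptome") transcriptIds(db)
          else unique(chimeras$transcript_id)
  reg <- regionTable(db)
  reg <- reg[reg$transcript_id %in% tids, , drop = FALSE]
  sites <- NULL
  if (scope == "binding_sites") {
    if (is.null(features)) stop("binding_sites scope requires features")
    sites <- lapply(split(features, features$transcript_id), function(f)
      mergeIntervals(f$site_start, f$site_end))
  }
  out <- NULL
  for (region in c("mRNA", "CDS", "3UTR")) {
    rr <- if (region == "mRNA") {
      lens <- transcriptLength(db)[tids]
      data.frame(transcript_id = tids, start = 0L,
                 end = as.integer(lens), stringsAsFactors = FALSE)
    } else reg[reg$region == region, c("transcript_id", "start", "end")]
    total <- 0L; nvar <- 0L
    for (k in seq_len(nrow(rr))) {
      tid <- rr$transcript_id[k]
      iv <- c(rr$start[k], rr$end[k])
      if (!is.null(sites)) {
        sm <- sites[[tid]]
        if (is.null(sm)) next
        for (si in seq_len(nrow(sm))) {
          lo <- max(iv[1], sm[si, 1]); hi <- min(iv[2], sm[si, 2])
          if (hi <= lo) next
          total <- total + (hi - lo)
          if (nrow(variants))
            nvar <- nvar + sum(variants$transcript_id == tid &
                               variants$pos >= lo & variants$pos < hi)
        }
      } else {
        total <- total + (iv[2] - iv[1])
        if (nrow(variants))
          nvar <- nvar + sum(variants$transcript_id == tid &
                             variants$pos >= iv[1] & variants$pos < iv[2])
      }
    }
    if (total == 0 && scope != "binding_sites")
      stop("zero-length region ", region, " in scope ", scope)
    out <- rbind(out, data.frame(
      scope = scope, region = region, freq_class = freq_class,
      n_variants = nvar, total_length = total,
      density = if (total > 0) nvar / total else NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric point probabilities at
#' most that of the observed table (the classic fixed-margin construction).
#'
#' @param a,b,c,d non-negative integer cell counts (rows = groups,
#'   columns = variant / non-variant nucleotides).
#' @return p-value in (0, 1].
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x)))
    stop("cells must be non-negative integers")
  stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))$p.value
}

#' Density comparison report
#'
#' Fisher's exact comparisons of variant densities between scopes
#' (transcriptome vs interacting transcripts, interacting transcripts vs
#' binding sites), per region and frequency class. Each 2x2 table is
#' (variant count, region length - variant count) by scope. Raw p-values
#' are reported with a Bonferroni column alongside.
#'
#' @param density_table stacked output of [variantDensity()] over scopes
#'   and classes.
#' @return data.frame of comparisons with \code{p} and \code{p_bonferroni}.
#' @export
densityComparisonReport <- function(density_table) {
  pairs <- list(c("whole_transcriptome", "clash_transcripts"),
                c("clash_transcripts", "binding_sites"))
  out <- NULL
  for (pr in pairs) {
    for (region in unique(density_table$region)) {
      for (fc in unique(density_table$freq_class)) {
        r1 <- density_table[density_table$scope == pr[1] &
                            density_table$region == region &
                            density_table$freq_class == fc, , drop = FALSE]
        r2 <- density_table[density_table$scope == pr[2] &
                            density_table$region == region &
                            density_table$freq_class == fc, , drop = FALSE]
        if (!nrow(r1) || !nrow(r2)) next
        if (is.na(r1$density) || is.na(r2$density)) next
        p <- fisherExact2x2(r1$n_variants, r1$total_length - r1$n_variants,
                            r2$n_variants, r2$total_length - r2$n_variants)
        out <- rbind(out, data.frame(
          scope_a = pr[1], scope_b = pr[2], region = region,
          freq_class = fc,
          density_a = r1$density, density_b = r2$density, p = p,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(out)) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Conservation summary of binding sites
#'
#' Percentage of sites per conservation bin (default decile bins; the
#' bottom bin is closed, \code{[0, 0.1]}, the others half-open
#' \code{(a, b]}) plus, when variants are supplied, the per-bin variant
#' density inside sites for each frequency class.
#'
#' @param features site feature table with a \code{conservation} column.
#' @param variants optional variant table (for per-bin densities).
#' @param bins bin edges over [0, 1].
#' @param maf_threshold common/rare boundary.
#' @return list with \code{bins} (percentages; sum to 100 over
#'   non-missing sites) and \code{density} (per bin and class, or NULL).
#' @export
conservationSummary <- function(features, variants = NULL,
                                bins = seq(0, 1, 0.1),
                                maf_threshold = 0.01) {
  cons <- features$conservation
  f <- cut(cons, breaks = bins, include.lowest = TRUE)
  tab <- table(f)
  pct <- 100 * as.numeric(tab) / sum(!is.na(f))
  bindf <- data.frame(bin = names(tab), n_sites = as.numeric(tab),
                      percent = pct, stringsAsFactors = FALSE)
  dens <- NULL
  if (!is.null(variants) && nrow(features)) {
    for (b in seq_along(levels(f))) {
      sel <- !is.na(f) & as.integer(f) == b
      fs <- features[sel, , drop = FALSE]
      if (!nrow(fs)) {
        dens <- rbind(dens, data.frame(bin = levels(f)[b], freq_class = c("common", "rare"),
                                       n_variants = 0L, total_length = 0L,
                                       density = NA_real_))
        next
      }
      merged <- lapply(split(fs, fs$transcript_id), function(x)
        mergeIntervals(x$site_start, x$site_end))
      total <- sum(vapply(merged, function(m) sum(m[, 2] - m[, 1]),
                          numeric(1)))
      for (fc in c("common", "rare")) {
        vv <- variants[.freqClass(variants$maf, maf_threshold) == fc, ,
                       drop = FALSE]
        nvar <- 0L
        for (tid in names(merged)) {
          m <- merged[[tid]]
          vt <- vv[vv$transcript_id == tid, , drop = FALSE]
          for (si in seq_len(nrow(m)))
            nvar <- nvar + sum(vt$pos >= m[si, 1] & vt$pos < m[si, 2])
        }
        dens <- rbind(dens, data.frame(
          bin = levels(f)[b], freq_class = fc, n_variants = nvar,
          total_length = total,
          density = if (total > 0) nvar / total else NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(bins = bindf, density = dens)
}

.MEASURES <- c("ddG_hybrid", "ddG_total", "d_site_access",
               "d_upstream_access", "d_downstream_access")

defaultBinEdges <- function(measure) {
  if (measure %in% c("ddG_hybrid", "ddG_total"))
    c(-Inf, seq(-10, 10, by = 1), Inf)
  else
    c(seq(-1, -0.05, by = 0.05), -0.01, 0.01, seq(0.05, 1, by = 0.05))
}

#' Histogram and exceedance distribution of an effect measure
#'
#' Histogram with half-open \code{(a, b]} bins (the lowest bin closed), and
#' the fraction of records with \code{|x| >= t} over a threshold grid.
#' Headline fractions follow the effect-sign conventions: for the energy
#' measures a positive value weakens the interaction, so
#' \code{frac_decrease} is the fraction with \code{x >= threshold} and
#' \code{frac_increase} the fraction with \code{x <= -threshold}
#' (threshold 1 kcal/mol); for accessibility measures \code{frac_altered}
#' is the fraction with \code{|x| > 0.01}.
#'
#' @param records effect table.
#' @param measure one of \code{ddG_hybrid, ddG_total, d_site_access,
#'   d_upstream_access, d_downstream_access}.
#' @param bin_edges histogram edges (defaults: 1 kcal/mol bins over
#'   [-10, 10] with open outer bins for energies; 0.05 bins over [-1, 1]
#'   with a central [-0.01, 0.01] bin for accessibilities).
#' @param thresholds exceedance grid (defaults fit the measure).
#' @param energy_threshold,access_cutoff headline thresholds (1 kcal/mol
#'   and 0.01).
#' @return list: \code{measure}, \code{n}, \code{bins} (data.frame),
#'   \code{exceedance} (data.frame), \code{summary} (named fractions).
#' @export
effectDistribution <- function(records, measure, bin_edges = NULL,
                               thresholds = NULL, energy_threshold = 1,
                               access_cutoff = 0.01) {
  if (!(measure %in% .MEASURES)) stop("unknown measure: ", measure)
  x <- records[[measure]]
  x <- x[!is.na(x)]
  if (is.null(bin_edges)) bin_edges <- defaultBinEdges(measure)
  if (is.null(thresholds))
    thresholds <- if (grepl("dG", measure)) seq(0.5, 10, by = 0.5)
                  else seq(0.01, 0.5, by = 0.01)
  f <- cut(x, breaks = bin_edges, include.lowest = TRUE)
  tab <- table(f)
  bins <- data.frame(bin = names(tab), count = as.numeric(tab),
                     stringsAsFactors = FALSE)
  exc <- data.frame(threshold = thresholds,
                    fraction = vapply(thresholds,
                                      function(t) mean(abs(x) >= t),
                                      numeric(1)))
  summary <- if (grepl("dG", measure)) {
    c(frac_decrease = mean(x >= energy_threshold),
      frac_increase = mean(x <= -energy_threshold))
  } else {
    c(frac_altered = mean(abs(x) > access_cutoff))
  }
  list(measure = measure, n = length(x), bins = bins, exceedance = exc,
       summary = summary)
}

#' Exact binomial sign-bias test
#'
#' Tests whether records beyond the effect threshold are equally likely to
#' increase or decrease the measure: two-sided exact binomial test of
#' \code{#(x >= +t)} against \code{#(x <= -t)} at probability 0.5.
#'
#' @param records effect table.
#' @param measure effect measure name.
#' @param threshold effect threshold (default 1 kcal/mol).
#' @return list \code{(n_up, n_down, p)}; \code{p} is \code{NA} (flagged)
#'   when no record passes the threshold.
#' @export
signBiasTest <- function(records, measure = "ddG_hybrid", threshold = 1) {
  x <- records[[measure]]
  x <- x[!is.na(x)]
  up <- sum(x >= threshold); down <- sum(x <= -threshold)
  if (up + down == 0)
    return(list(n_up = 0L, n_down = 0L, p = NA_real_, flagged = TRUE))
  list(n_up = up, n_down = down,
       p = stats::binom.test(up, up + down, 0.5)$p.value, flagged = FALSE)
}

#' Mean MAF stratified by accessibility effect
#'
#' For each cutoff \eqn{\Theta} of the grid, the mean MAF of records that
#' alter site accessibility (\code{|d_site_access| > theta}) and of those
#' that do not. Records without MAF are excluded.
#'
#' @param records effect table.
#' @param theta_grid cutoffs (default 0.01 to 0.2 in steps of 0.01).
#' @return data.frame \code{(theta, n_flagged, mean_maf_flagged,
#'   n_unflagged, mean_maf_unflagged)}; empty strata give \code{NA} means.
#' @export
meanMafByAccessEffect <- function(records,
                                  theta_grid = seq(0.01, 0.2, by = 0.01)) {
  rec <- records[!is.na(records$maf) & !is.na(records$d_site_access), ,
                 drop = FALSE]
  out <- NULL
  for (th in theta_grid) {
    fl <- abs(rec$d_site_access) > th
    out <- rbind(out, data.frame(
      theta = th,
      n_flagged = sum(fl),
      mean_maf_flagged = if (any(fl)) mean(rec$maf[fl]) else NA_real_,
      n_unflagged = sum(!fl),
      mean_maf_unflagged = if (any(!fl)) mean(rec$maf[!fl]) else NA_real_))
  }
  out
}
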