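#' @include synthetic-data.R
NULL

#' Pipeline run configuration
#'
#' Bundles input paths and the analysis parameters with their standard
#' defaults: MAF threshold 1 percent, 25-nt flank blocks, accessibility
#' cutoff 0.01, energy threshold 1 kcal/mol, 200-nt folding window, and an
#' accessibility-cutoff grid from 0.01 to 0.2.
#'
#' @param fasta,bed,chimeras,vcf,conservation input paths (conservation
#'   optional, \code{NULL} to skip).
#' @param outdir output directory for the report bundle.
#' @param maf_threshold,flank,access_cutoff,energy_threshold,window
#'   analysis parameters.
#' @param theta_grid accessibility cutoff grid.
#' @param dedupe variant counting mode for densities.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(fasta, bed, chimeras, vcf, conservation = NULL,
                      outdir = tempfile("mirvar_out"),
                      maf_threshold = 0.01, flank = 25L,
                      access_cutoff = 0.01, energy_threshold = 1,
                      window = 200L, theta_grid = seq(0.01, 0.2, 0.01),
                      dedupe = "per_transcript") {
  stopifnot(maf_threshold > 0, flank > 0, access_cutoff > 0,
            energy_threshold > 0, window > 0)
  cfg <- as.list(environment())
  class(cfg) <- "runConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: load and validate inputs, locate binding sites, compute site
#' features, place variants, compute the five effect measures, and run the
#' cohort statistics. Each stage's record counts are logged; all tables
#' are written as TSVs under \code{config$outdir}.
#'
#' @param config a [runConfig()].
#' @param model an \linkS4class{EnergyModel}.
#' @param quiet suppress progress messages.
#' @return invisible report bundle: all tables plus stage counts.
#' @export
runPipeline <- function(config, model = defaultEnergyModel(),
                        quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  say <- function(...) if (!quiet) message("[mirvar] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  say("load: reading inputs")
  db <- stage("load", {
    fa <- readTranscriptsFasta(config$fasta)
    makeTranscriptDB(fa, readBed12(config$bed))
  })
  chim <- stage("load", readChimeras(config$chimeras, db))
  variants <- stage("load", readVcfVariants(config$vcf, db))
  tracks <- if (!is.null(config$conservation))
    stage("load", readConservation(config$conservation, db)) else NULL
  say("load: ", length(transcriptIds(db)), " transcripts, ",
      nrow(chim), " chimeras, ", nrow(variants), " variants")

  say("sites: locating and featurizing")
  sft <- stage("sites", siteFeatureTable(chim, db, tracks, model,
                                         window = config$window,
                                         flank = config$flank))
  say("sites: ", nrow(sft$features %||% data.frame()), " located, ",
      sft$n_siteless, " site-less (excluded)")

  say("effects: placing variants and computing measures")
  vet <- stage("effects", variantEffectTable(
    variants, chim, sft, db, model, flank = config$flank,
    maf_threshold = config$maf_threshold))
  say("effects: ", vet$n_records, " records, ",
      vet$n_flank_indels_dropped, " flank indels dropped")

  say("stats: densities, conservation, distributions")
  dens <- stage("stats", {
    out <- NULL
    for (scope in c("whole_transcriptome", "clash_transcripts",
                    "binding_sites"))
      for (fc in c("common", "rare"))
        out <- rbind(out, variantDensity(
          variants, db, chim, sft$features, scope, fc,
          maf_threshold = config$maf_threshold, dedupe = config$dedupe))
    out
  })
  cmp <- stage("stats", densityComparisonReport(dens))
  cons <- stage("stats", conservationSummary(
    sft$features, variants, maf_threshold = config$maf_threshold))
  eff <- vet$effects
  dists <- list(); sweeps <- NULL; sweeps_flank <- NULL
  if (!is.null(eff) && nrow(eff)) {
    within <- eff[eff$placement == "within_site", , drop = FALSE]
    for (m in .MEASURES)
      dists[[m]] <- stage("stats", effectDistribution(
        within, m, energy_threshold = config$energy_threshold,
        access_cutoff = config$access_cutoff))
    sweeps <- stage("stats", meanMafByAccessEffect(within,
                                                   config$theta_grid))
    flanks <- eff[eff$placement != "within_site", , drop = FALSE]
    if (nrow(flanks))
      sweeps_flank <- stage("stats", meanMafByAccessEffect(
        flanks, config$theta_grid))
  }

  # --- write the report bundle ----------------------------------------------
  o <- function(f) file.path(config$outdir, f)
  if (!is.null(sft$features)) {
    writeResultsTsv(sft$features, o("site_features.tsv"))
    bedrows <- sprintf("%s\t%d\t%d\t%s\t0\t+",
                       sft$features$transcript_id, sft$features$site_start,
                       sft$features$site_end, sft$features$chimera_id)
    writeLines(bedrows, o("sites.bed"))
  }
  if (!is.null(eff)) {
    for (pl in c("within_site", "upstream_25", "downstream_25")) {
      sub <- eff[eff$placement == pl, , drop = FALSE]
      writeResultsTsv(sub, o(paste0("effects_", sub("_25", "", pl), ".tsv")))
    }
  }
  writeResultsTsv(dens, o("density.tsv"))
  if (!is.null(cmp)) writeResultsTsv(cmp, o("density_comparisons.tsv"))
  writeResultsTsv(cons$bins, o("conservation_bins.tsv"))
  if (!is.null(cons$density))
    writeResultsTsv(cons$density, o("conservation_density.tsv"))
  for (m in names(dists)) {
    writeResultsTsv(dists[[m]]$bins, o(paste0("hist_", m, ".tsv")))
    writeResultsTsv(dists[[m]]$exceedance, o(paste0("exceedance_", m, ".tsv")))
  }
  if (!is.null(sweeps)) writeResultsTsv(sweeps, o("theta_sweep_within.tsv"))
  if (!is.null(sweeps_flank))
    writeResultsTsv(sweeps_flank, o("theta_sweep_flanks.tsv"))

  bundle <- list(config = config, db = db, chimeras = chim,
                 variants = variants, tracks = tracks, sft = sft,
                 effects = eff, placements = vet$placements,
                 density = dens, comparisons = cmp, conservation = cons,
                 distributions = dists, theta_sweep = sweeps,
                 theta_sweep_flanks = sweeps_flank,
                 counts = list(
                   n_transcripts = length(transcriptIds(db)),
                   n_chimeras = nrow(chim), n_variants = nrow(variants),
                   n_sites = nrow(sft$features %||% data.frame()),
                   n_siteless = sft$n_siteless,
                   n_effect_records = vet$n_records,
                   n_flank_indels_dropped = vet$n_flank_indels_dropped))
  smry <- summaryCounts(bundle)
  writeResultsTsv(smry, o("summary.tsv"))
  bundle$summary <- smry
  say("done: reports in ", config$outdir)
  invisible(bundle)
}

#' Common/rare/unknown class shares
#'
#' Totals and percentage shares from printed class counts; percentages are
#' rounded half-up to one decimal. Internal consistency is asserted:
#' total = common + rare + unknown.
#'
#' @param common,rare,unknown class counts.
#' @return list \code{(total, common, rare, unknown, pct_common, pct_rare,
#'   pct_unknown)}; shares are \code{NA} for an empty total.
#' @examples
#' classShares(302797, 652478)  # total 955275, common share 31.7
#' @export
classShares <- function(common, rare, unknown = 0) {
  total <- common + rare + unknown
  pct <- function(x) if (total == 0) NA_real_
                     else roundHalfUp(100 * x / total, 1)
  list(total = total, common = common, rare = rare, unknown = unknown,
       pct_common = pct(common), pct_rare = pct(rare),
       pct_unknown = pct(unknown))
}

#' Headline summary of a report bundle
#'
#' One row per headline number: cohort sizes, located/site-less chimeras,
#' seedless share, per-placement effect-record counts split by frequency
#' class with percentage shares, and the accessibility-alteration and
#' energy-shift fractions at the configured cutoffs. Every number is
#' recomputable from the bundle's tables.
#'
#' @param bundle a [runPipeline()] result (or a compatible list).
#' @return data.frame \code{(metric, value)}.
#' @export
summaryCounts <- function(bundle) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = value,
                                             stringsAsFactors = FALSE)
  cts <- bundle$counts
  for (k in names(cts)) add(k, cts[[k]])
  ft <- bundle$sft$features
  if (!is.null(ft) && nrow(ft)) {
    add("pct_seedless",
        roundHalfUp(100 * mean(ft$seed_type == "seedless"), 1))
  }
  eff <- bundle$effects
  if (!is.null(eff) && nrow(eff)) {
    for (pl in c("within_site", "upstream_25", "downstream_25")) {
      sub <- eff[eff$placement == pl, ]
      sh <- classShares(sum(sub$freq_class == "common"),
                        sum(sub$freq_class == "rare"),
                        sum(sub$freq_class == "unknown"))
      add(paste0("n_", pl, "_total"), sh$total)
      add(paste0("n_", pl, "_common"), sh$common)
      add(paste0("n_", pl, "_rare"), sh$rare)
      add(paste0("n_", pl, "_unknown"), sh$unknown)
      add(paste0("pct_", pl, "_common"), sh$pct_common)
      add(paste0("pct_", pl, "_rare"), sh$pct_rare)
    }
    for (m in names(bundle$distributions)) {
      s <- bundle$distributions[[m]]$summary
      for (k in names(s))
        add(paste0(m, "_", k), roundHalfUp(100 * s[[k]], 1))
    }
  }
  do.call(rbind, rows)
}
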