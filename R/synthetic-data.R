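#' @include cohort-stats.R
NULL

# bases that cannot pair (WC or GU) with miRNA base x
.MISMATCH_SET <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                      G = c("A", "G"), U = c("C", "U"))
mismatchBase <- function(x, rng = FALSE) {
  s <- .MISMATCH_SET[[x]]
  if (rng) sample(s, 1) else s[1]
}
# non-A base that cannot pair miRNA base x (for non-A1 seed classes)
nonA1Base <- function(x, rng = FALSE) {
  s <- setdiff(.MISMATCH_SET[[x]], "A")
  if (rng) sample(s, 1) else s[1]
}

#' Synthetic cohort configuration
#'
#' Defaults define the emulated study conditions: a small transcriptome
#' with 10/50/40 percent 5'UTR/CDS/3'UTR splits, CLASH-style chimeras with
#' 42-119 nt fragments, about 18.7 percent of implanted sites canonical
#' (the rest seedless), region- and class-dependent variant densities
#' (rare variants enriched in CDS at four times their 3'UTR density,
#' common variants enriched in the 3'UTR, interacting transcripts thinner
#' than the background, common site variants thinned with conservation),
#' a rare-skewed MAF mixture (about two thirds of variants rare), and
#' conservation tracks elevated over implanted sites.
#'
#' @param n_transcripts,len_range transcriptome size and length range (nt).
#' @param utr5_frac,cds_frac region fractions (3'UTR takes the rest).
#' @param n_mirnas,mirna_len_range miRNA cohort.
#' @param n_chimeras,frag_len_range chimera count and fragment lengths.
#' @param fraction_seed share of implants with a canonical seed class.
#' @param clash_fraction share of transcripts receiving chimeras.
#' @param clash_multiplier variant-density multiplier on interacting
#'   transcripts.
#' @param frag_3utr_bias probability that a fragment is placed entirely
#'   inside the 3'UTR (sites concentrate in 3'UTRs, as in CLASH data).
#' @param site_common_keep c(a, b): a common variant falling inside a
#'   binding site is kept with probability \code{a + b * (1 -
#'   conservation)} (purifying selection: site density lower and
#'   decreasing with conservation).
#' @param site_rare_keep keep probability for rare variants inside sites
#'   (conservation-independent).
#' @param densities per-region, per-class variant densities (per nt).
#' @param indel_fraction share of variants that are short indels.
#' @param maf_missing_frac share of variants without frequency data.
#' @param rare_maf_range,common_maf_range MAF supports of the two mixture
#'   components (boundary at 1 percent).
#' @param cons_p_high,cons_p_low share of sites with high (>0.9) / low
#'   (<=0.1) conservation targets.
#' @param couple_maf_access couple MAF to computed |d site accessibility|
#'   (large effects get rarer alleles).
#' @param gc background GC content.
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @return a list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(n_transcripts = 120, len_range = c(500, 1200),
                         utr5_frac = 0.10, cds_frac = 0.50,
                         n_mirnas = 12, mirna_len_range = c(19, 24),
                         n_chimeras = 100, frag_len_range = c(42, 119),
                         fraction_seed = 0.187, clash_fraction = 0.25,
                         clash_multiplier = 0.55, frag_3utr_bias = 0.6,
                         site_common_keep = c(0.10, 0.30),
                         site_rare_keep = 0.35,
                         densities = list(
                           `5UTR` = c(common = 0.002, rare = 0.005),
                           CDS = c(common = 0.004, rare = 0.020),
                           `3UTR` = c(common = 0.010, rare = 0.005)),
                         indel_fraction = 0.08, maf_missing_frac = 0.03,
                         rare_maf_range = c(5e-4, 0.01),
                         common_maf_range = c(0.01, 0.5),
                         cons_p_high = 0.43, cons_p_low = 0.21,
                         couple_maf_access = TRUE, gc = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  cfg <- as.list(environment())
  if (any(unlist(densities) < 0)) stop("densities must be non-negative")
  if (frag_len_range[1] <= mirna_len_range[2] + 10)
    stop("fragments must leave room for an implanted site")
  class(cfg) <- "cohortConfig"
  cfg
}

randomRnaStr <- function(n, gc) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

#' Implant a binding site into a target sequence
#'
#' Writes the target-side subsequence that guarantees the requested seed
#' class under the [classifySeed()] definitions: the reverse complement of
#' the miRNA with class-specific seed-region adjustments (a designed A or
#' non-A opposite nt 1, designed mismatches where the class excludes a
#' match; seedless implants mismatch all of nts 1-8 and keep only 3'
#' complementarity). The implant spans one miRNA length and is by
#' construction the dominant duplex in any surrounding fragment.
#'
#' @param seq target RNA string.
#' @param mirna_seq miRNA (5'->3').
#' @param type one of the canonical classes or \code{"seedless"}.
#' @param position 0-based start of the implant.
#' @param rng sample mismatch bases from their allowed sets (used by the
#'   generator's placement screen) instead of the deterministic choice.
#' @return list: \code{seq} (modified), \code{implant} (interval),
#'   \code{true_site} (0-based half-open interval the designed optimal
#'   hybrid covers), \code{anchor} (0-based position opposite miRNA nt 1).
#' @export
implantSite <- function(seq, mirna_seq, type, position, rng = FALSE) {
  type <- match.arg(type, SEED_TYPES)
  m <- strsplit(normalizeSeq(mirna_seq), "")[[1]]
  L <- length(m)
  if (position < 0 || position + L > nchar(seq))
    stop("implant does not fit in the target")
  # s[p] sits opposite miRNA nt (L - p + 1)
  s <- vapply(rev(m), function(b) rnaComplement(b), character(1))
  put <- function(k, base) s[L - k + 1] <<- base
  pairedK <- rep(TRUE, L)
  mark <- function(k) pairedK[k] <<- FALSE
  if (type == "8mer") {
    put(1, "A"); if (m[1] != "U") mark(1)
  } else if (type == "7mer-m8") {
    put(1, nonA1Base(m[1], rng)); mark(1)
  } else if (type == "7mer-A1") {
    put(1, "A"); if (m[1] != "U") mark(1)
    put(8, mismatchBase(m[8], rng)); mark(8)
  } else if (type == "6mer") {
    put(1, nonA1Base(m[1], rng)); mark(1)
    put(8, mismatchBase(m[8], rng)); mark(8)
  } else if (type == "offset-6mer") {
    put(1, nonA1Base(m[1], rng)); mark(1)
    put(2, mismatchBase(m[2], rng)); mark(2)
  } else { # seedless: 3'-only complementarity
    put(1, nonA1Base(m[1], rng)); mark(1)
    for (k in 2:8) { put(k, mismatchBase(m[k], rng)); mark(k) }
  }
  # the optimal hybrid covers the contiguous paired stretch ending at the
  # 3'-most paired miRNA nt (smallest k with a designed pair)
  kmin <- min(which(pairedK))
  true_site <- c(position, position + (L - kmin + 1L))
  out <- paste0(substr0(seq, 0, position), paste(s, collapse = ""),
                substr0(seq, position + L, nchar(seq)))
  list(seq = out, implant = c(position, position + L),
       true_site = as.integer(true_site),
       anchor = as.integer(position + L - 1L), type = type)
}

# inverse of projectGenomicToTranscript for one position
invProject <- function(tpos, exons, strand) {
  total <- sum(exons$end - exons$start)
  if (identical(strand, "-")) tpos <- total - 1L - tpos
  cum <- c(0L, cumsum(exons$end - exons$start))
  k <- findInterval(tpos, cum, rightmost.closed = FALSE)
  exons$start[k] + (tpos - cum[k])
}

# shaped MAF draw: u^(1 + 8 * min(1, |d|/0.2)) pushes large-effect
# variants toward the low end of their class support
.mafDraw <- function(lo, hi, u, d_access = 0) {
  shape <- 1 + 8 * min(1, abs(d_access) / 0.2)
  lo + (hi - lo) * u^shape
}

#' Generate a synthetic CLASH-style cohort
#'
#' Emits a mutually consistent file bundle (FASTA transcriptome, BED12
#' annotation, chimera TSV, VCF, conservation TSV) plus the generating
#' ground truth. Deterministic given \code{config$seed}: identical seeds
#' give byte-identical files.
#'
#' @param config a [cohortConfig()].
#' @param dir output directory (created if needed).
#' @param model energy model (used when MAF-accessibility coupling is on).
#' @return list: \code{paths}, parsed objects (\code{db}, \code{chimeras},
#'   \code{variants}, \code{tracks}) re-read through the package readers,
#'   and \code{truth} (per-chimera true sites and classes, per-variant
#'   generating strata, per-region true densities).
#' @export
generateCohort <- function(config, dir = tempfile("cohort"),
                           model = defaultEnergyModel()) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gc <- config$gc

  # --- miRNAs ---------------------------------------------------------------
  mirnas <- data.frame(
    mirna_id = sprintf("mir-%02d", seq_len(config$n_mirnas)),
    mirna_seq = vapply(seq_len(config$n_mirnas), function(i)
      randomRnaStr(sample(config$mirna_len_range[1]:config$mirna_len_range[2],
                          1), gc), character(1)),
    stringsAsFactors = FALSE)

  # --- transcripts ----------------------------------------------------------
  nt <- config$n_transcripts
  tids <- sprintf("tx%03d", seq_len(nt))
  lens <- sample(config$len_range[1]:config$len_range[2], nt, replace = TRUE)
  seqs <- vapply(lens, randomRnaStr, character(1), gc = gc)
  names(seqs) <- tids
  u5 <- pmax(1L, as.integer(round(lens * config$utr5_frac)))
  cd <- pmax(3L, as.integer(round(lens * config$cds_frac)))
  regions <- do.call(rbind, lapply(seq_len(nt), function(i) data.frame(
    transcript_id = tids[i], region = c("5UTR", "CDS", "3UTR"),
    start = c(0L, u5[i], u5[i] + cd[i]),
    end = c(u5[i], u5[i] + cd[i], lens[i]), stringsAsFactors = FALSE)))
  # synthetic genome layout: 1-3 exons per transcript along one contig
  gcursor <- 1000L
  exons <- NULL
  strands <- sample(c("+", "-"), nt, replace = TRUE, prob = c(0.7, 0.3))
  for (i in seq_len(nt)) {
    nex <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(lens[i] - 1), nex - 1))
    sizes <- diff(c(0L, cuts, lens[i]))
    es <- integer(nex); ee <- integer(nex)
    for (k in seq_len(nex)) {
      es[k] <- gcursor
      ee[k] <- gcursor + sizes[k]
      gcursor <- ee[k] + sample(50:500, 1)
    }
    exons <- rbind(exons, data.frame(
      transcript_id = tids[i], chrom = "chr1", start = es, end = ee,
      strand = strands[i], stringsAsFactors = FALSE))
    gcursor <- gcursor + 200L
  }

  # --- chimeras with implanted sites ---------------------------------------
  clash_pool <- sort(sample(tids, max(1, round(config$clash_fraction * nt))))
  n_seed <- round(config$fraction_seed * config$n_chimeras)
  classes <- c(sample(SEED_TYPES[1:5], n_seed, replace = TRUE),
               rep("seedless", config$n_chimeras - n_seed))
  classes <- sample(classes)
  chim <- NULL
  truth_sites <- NULL
  fragments <- setNames(vector("list", nt), tids)
  implants <- setNames(vector("list", nt), tids)
  for (ci in seq_len(config$n_chimeras)) {
    placed <- FALSE
    for (try in 1:400) {
      tid <- sample(clash_pool, 1)
      i <- match(tid, tids)
      len <- lens[i]
      mr <- mirnas[sample(nrow(mirnas), 1), ]
      L <- nchar(mr$mirna_seq)
      flen <- sample(config$frag_len_range[1]:config$frag_len_range[2], 1)
      # fragment interval, biased into the 3'UTR, away from transcript ends
      utr3_start <- u5[i] + cd[i]
      lo <- 26L; hi <- len - flen - 26L
      if (runif(1) < config$frag_3utr_bias && len - utr3_start >= flen + 27)
        lo <- max(lo, utr3_start)
      if (hi < lo) next
      fs <- sample(lo:hi, 1)
      off <- sample(5:(flen - L - 5), 1)
      ipos <- fs + off
      # fragments may overlap, but an implant must never fall inside any
      # other fragment (it would perturb that chimera's duplex optimum)
      fr <- fragments[[tid]]; im <- implants[[tid]]
      if (!is.null(fr) &&
          any(intervalsOverlap(fr[, 1], fr[, 2], ipos, ipos + L)))
        next
      if (!is.null(im) &&
          any(intervalsOverlap(im[, 1], im[, 2], fs, fs + flen)))
        next
      imp <- implantSite(seqs[[tid]], mr$mirna_seq, classes[ci], ipos,
                         rng = TRUE)
      # energy screen: the fragment's duplex optimum must carry the
      # requested class. Canonical implants must additionally realize the
      # designed span exactly (extensions through flanking pairs are
      # rejected); for seedless implants a favorable extension of the 3'
      # helix into the flank is generic, so the realized optimum defines
      # the true site.
      fragseq <- substr0(imp$seq, fs, fs + flen)
      d <- duplexMfe(mr$mirna_seq, fragseq, model)
      if (is.na(duplexEnergy(d))) next
      got <- as.integer(targetSpan(d) + fs)
      cls_got <- classifySeed(mr$mirna_seq, imp$seq, duplex = d, offset = fs)
      if (cls_got != classes[ci]) next
      if (classes[ci] == "seedless") {
        if (got[1] < fs || got[2] > fs + flen) next
        imp$true_site <- got
      } else if (!identical(got, imp$true_site)) next
      seqs[[tid]] <- imp$seq
      fragments[[tid]] <- rbind(fr, c(fs, fs + flen))
      implants[[tid]] <- rbind(im, imp$implant)
      chim <- rbind(chim, data.frame(
        chimera_id = sprintf("chim%03d", ci), mirna_id = mr$mirna_id,
        mirna_seq = mr$mirna_seq, transcript_id = tid,
        frag_start = fs, frag_end = fs + flen, stringsAsFactors = FALSE))
      truth_sites <- rbind(truth_sites, data.frame(
        chimera_id = sprintf("chim%03d", ci), transcript_id = tid,
        implant_start = imp$implant[1], implant_end = imp$implant[2],
        true_site_start = imp$true_site[1], true_site_end = imp$true_site[2],
        anchor = imp$anchor, seed_class = classes[ci],
        stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place chimera ", ci,
                      " (infeasible configuration)")
  }
  clash_ids <- sort(unique(chim$transcript_id))

  # --- conservation tracks (elevated and structured over sites) -------------
  tracks <- list()
  site_cons <- numeric(nrow(truth_sites))
  for (i in seq_len(nt)) {
    tracks[[tids[i]]] <- pmin(1, pmax(0, rbeta(lens[i], 1.2, 2.5)))
  }
  for (r in seq_len(nrow(truth_sites))) {
    u <- runif(1)
    target <- if (u < config$cons_p_high) runif(1, 0.92, 1)
              else if (u < config$cons_p_high + config$cons_p_low)
                runif(1, 0, 0.08)
              else runif(1, 0.12, 0.9)
    site_cons[r] <- target
    tid <- truth_sites$transcript_id[r]
    iv <- (truth_sites$true_site_start[r] + 1):truth_sites$true_site_end[r]
    tracks[[tid]][iv] <- pmin(1, pmax(0, target + rnorm(length(iv), 0, 0.02)))
  }
  truth_sites$cons_target <- site_cons

  # --- variants -------------------------------------------------------------
  vrows <- NULL
  vid <- 0L
  for (i in seq_len(nt)) {
    tid <- tids[i]
    mult <- if (tid %in% clash_ids) config$clash_multiplier else 1
    reg <- regions[regions$transcript_id == tid, ]
    taken <- integer()
    for (rr in seq_len(nrow(reg))) {
      for (cls in c("common", "rare")) {
        d <- config$densities[[reg$region[rr]]][[cls]] * mult
        span <- reg$end[rr] - reg$start[rr]
        nv <- rbinom(1, span, d)
        if (!nv) next
        cand <- sample(reg$start[rr]:(reg$end[rr] - 1L), nv)
        for (pos in cand) {
          if (pos %in% taken) next
          # thin common site variants with conservation (purifying selection)
          ts <- truth_sites[truth_sites$transcript_id == tid, , drop = FALSE]
          insite <- nrow(ts) && any(pos >= ts$true_site_start &
                                    pos < ts$true_site_end)
          if (insite) {
            if (cls == "common") {
              cons_here <- tracks[[tid]][pos + 1]
              keep <- config$site_common_keep[1] +
                config$site_common_keep[2] * (1 - cons_here)
            } else keep <- config$site_rare_keep
            if (runif(1) > keep) next
          }
          is_indel <- runif(1) < config$indel_fraction
          tseq <- seqs[[tid]]
          if (is_indel && pos < lens[i] - 4) {
            if (runif(1) < 0.5) { # insertion
              ref <- substr0(tseq, pos, pos + 1)
              alt <- paste0(ref, randomRnaStr(sample(1:3, 1), gc))
            } else {              # deletion
              k <- sample(1:3, 1)
              ref <- substr0(tseq, pos, min(lens[i], pos + 1 + k))
              alt <- substr(ref, 1, 1)
            }
          } else {
            ref <- substr0(tseq, pos, pos + 1)
            alt <- sample(setdiff(BASES, ref), 1)
          }
          vid <- vid + 1L
          taken <- c(taken, pos)
          vrows <- rbind(vrows, data.frame(
            id = sprintf("v%05d", vid), transcript_id = tid, pos = pos,
            ref = ref, alt = alt, class_true = cls,
            region_true = reg$region[rr], in_site_true = insite,
            u_maf = runif(1), missing_maf = runif(1) < config$maf_missing_frac,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(vrows)) vrows <- data.frame(
    id = character(), transcript_id = character(), pos = integer(),
    ref = character(), alt = character(), class_true = character(),
    region_true = character(), in_site_true = logical(),
    u_maf = numeric(), missing_maf = logical(), stringsAsFactors = FALSE)

  # --- MAF assignment (optionally coupled to accessibility effects) ---------
  vrows$d_access_true <- rep(0, nrow(vrows))
  if (config$couple_maf_access && nrow(vrows)) {
    flank <- 25L
    wcache <- list()
    for (v in seq_len(nrow(vrows))) {
      tid <- vrows$transcript_id[v]
      ts <- truth_sites[truth_sites$transcript_id == tid, , drop = FALSE]
      if (!nrow(ts)) next
      near <- which(vrows$pos[v] >= ts$true_site_start - flank &
                    vrows$pos[v] < ts$true_site_end + flank)
      if (!length(near)) next
      ts1 <- ts[near[1], ]
      site <- c(ts1$true_site_start, ts1$true_site_end)
      len <- lens[match(tid, tids)]
      win <- defaultWindow(site, len, 200L)
      key <- paste(tid, win[1], win[2], site[1])
      if (is.null(wcache[[key]]))
        wcache[[key]] <- windowAccess(seqs[[tid]], len, site, win, flank,
                                      model)
      wt <- wcache[[key]]
      mut <- applyVariant(seqs[[tid]], vrows$pos[v], vrows$ref[v],
                          vrows$alt[v])
      msite <- c(mut$map(site[1]), mut$map(site[2]))
      if (msite[2] <= msite[1]) next
      mwin <- c(mut$map(win[1]), min(nchar(mut$seq), mut$map(win[2])))
      ma <- windowAccess(mut$seq, nchar(mut$seq), msite, mwin, flank, model)
      vrows$d_access_true[v] <- ma$site_access - wt$site_access
    }
  }
  vrows$maf <- rep(NA_real_, nrow(vrows))
  for (v in seq_len(nrow(vrows))) {
    if (vrows$missing_maf[v]) next
    rg <- if (vrows$class_true[v] == "common") config$common_maf_range
          else config$rare_maf_range
    vrows$maf[v] <- .mafDraw(rg[1], rg[2], vrows$u_maf[v],
                             vrows$d_access_true[v])
  }

  # --- write the bundle -----------------------------------------------------
  paths <- list(fasta = file.path(dir, "transcripts.fa"),
                bed = file.path(dir, "annotation.bed"),
                chimeras = file.path(dir, "chimeras.tsv"),
                vcf = file.path(dir, "variants.vcf"),
                conservation = file.path(dir, "conservation.tsv"))
  writeTranscriptsFasta(seqs, paths$fasta)
  bed <- vapply(seq_len(nt), function(i) {
    e <- exons[exons$transcript_id == tids[i], , drop = FALSE]
    cs <- regions$start[regions$transcript_id == tids[i] &
                        regions$region == "CDS"]
    ce <- regions$end[regions$transcript_id == tids[i] &
                      regions$region == "CDS"]
    g1 <- invProject(cs, e, e$strand[1])
    g2 <- invProject(ce - 1L, e, e$strand[1])
    paste(c("chr1", e$start[1], e$end[nrow(e)], tids[i], 0, e$strand[1],
            min(g1, g2), max(g1, g2) + 1L, "0", nrow(e),
            paste0(paste(e$end - e$start, collapse = ","), ","),
            paste0(paste(e$start - e$start[1], collapse = ","), ",")),
          collapse = "\t")
  }, character(1))
  writeLines(bed, paths$bed)
  writeResultsTsv(chim, paths$chimeras)
  vcf_head <- c("##fileformat=VCFv4.2",
                "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
                paste0("##contig=<ID=", paste(tids, collapse = ">\n##contig=<ID="), ">"),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(vrows$transcript_id, vrows$pos)
  vcf_body <- vapply(ord, function(v) {
    info <- if (is.na(vrows$maf[v])) "."
            else sprintf("AF=%.6f", vrows$maf[v])
    paste(vrows$transcript_id[v], vrows$pos[v] + 1L, vrows$id[v],
          chartr("U", "T", vrows$ref[v]), chartr("U", "T", vrows$alt[v]),
          ".", "PASS", info, sep = "\t")
  }, character(1))
  writeLines(c(vcf_head, vcf_body), paths$vcf)
  cons_df <- do.call(rbind, lapply(tids, function(tid) data.frame(
    transcript_id = tid, pos = seq_along(tracks[[tid]]) - 1L,
    score = round(tracks[[tid]], 4), stringsAsFactors = FALSE)))
  writeResultsTsv(cons_df, paths$conservation)

  # --- read back through the package parsers --------------------------------
  fa <- readTranscriptsFasta(paths$fasta)
  ann <- readBed12(paths$bed)
  db <- makeTranscriptDB(fa, ann)
  truth_density <- do.call(rbind, lapply(names(config$densities), function(rg)
    data.frame(region = rg, freq_class = c("common", "rare"),
               density = as.numeric(config$densities[[rg]]),
               stringsAsFactors = FALSE)))
  list(paths = paths, dir = dir, db = db,
       chimeras = readChimeras(paths$chimeras, db),
       variants = readVcfVariants(paths$vcf, db),
       tracks = readConservation(paths$conservation, db),
       mirnas = mirnas,
       truth = list(sites = truth_sites, variants = vrows,
                    densities = truth_density, clash_ids = clash_ids,
                    regions = regions),
       config = config)
}

#' Generate a null cohort
#'
#' Same machinery as [generateCohort()] but with every engineered effect
#' switched off: one region-independent density shared by all regions and
#' scopes (no interacting-transcript thinning, no conservation coupling,
#' no MAF-accessibility coupling). Also attaches \code{null_effects}, a
#' table of sign-symmetric synthetic effect measures, as the calibration
#' input for the sign-bias test.
#'
#' @param config a [cohortConfig()]; densities are replaced by their mean.
#' @param dir output directory.
#' @param n_null_effects rows of the symmetric effect table.
#' @return as [generateCohort()], plus \code{null_effects}.
#' @export
nullCohort <- function(config, dir = tempfile("nullcohort"),
                       n_null_effects = 200) {
  dmean <- mean(unlist(config$densities))
  flat <- list(`5UTR` = c(common = dmean, rare = dmean),
               CDS = c(common = dmean, rare = dmean),
               `3UTR` = c(common = dmean, rare = dmean))
  cfg <- config
  cfg$densities <- flat
  cfg$clash_multiplier <- 1
  cfg$site_common_keep <- c(1, 0)
  cfg$site_rare_keep <- 1
  cfg$couple_maf_access <- FALSE
  out <- generateCohort(cfg, dir)
  mag <- abs(rnorm(n_null_effects, 0, 2))
  sgn <- ifelse(runif(n_null_effects) < 0.5, -1, 1)
  out$null_effects <- data.frame(
    ddG_hybrid = sgn * mag,
    d_site_access = ifelse(runif(n_null_effects) < 0.5, -1, 1) *
      abs(rnorm(n_null_effects, 0, 0.05)),
    maf = runif(n_null_effects, 5e-4, 0.5))
  out
}
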