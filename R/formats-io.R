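#' @include AllGenerics.R
NULL

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and DNA T is normalized to RNA U. Characters
#' outside A, C, G, T, U, N are rejected; record IDs must be unique and
#' records nonempty.
#'
#' @param path FASTA file.
#' @return a named \code{Biostrings::RNAStringSet}.
#' @export
readTranscriptsFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0)) {
    bad <- ids[Biostrings::width(raw) == 0]
    stop("empty FASTA record(s): ", paste(bad, collapse = ", "))
  }
  chars <- as.character(raw)
  seqs <- character(length(chars))
  for (k in seq_along(chars)) {
    seqs[k] <- tryCatch(normalizeSeq(chars[k], allow_n = TRUE),
                        error = function(e) stop("record ", ids[k], ": ",
                                                 conditionMessage(e),
                                                 call. = FALSE))
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write transcripts to FASTA
#'
#' @param x a \linkS4class{TranscriptDB}, an \code{XStringSet}, or a named
#'   character vector of RNA sequences.
#' @param path output file.
#' @export
writeTranscriptsFasta <- function(x, path) {
  if (is(x, "TranscriptDB")) x <- x@seqs
  if (is.character(x)) x <- Biostrings::RNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED12 transcript annotation
#'
#' One line per transcript: chrom, chromStart, chromEnd, name, score,
#' strand, thickStart, thickEnd (genomic CDS span; equal values mean no
#' CDS), itemRgb, blockCount, blockSizes, blockStarts. Exon blocks and the
#' transcript-coordinate 5UTR/CDS/3UTR intervals are derived from it.
#'
#' @param path BED12 file.
#' @return list with data.frames \code{exons} (transcript_id, chrom, start,
#'   end, strand) and \code{regions} (transcript_id, region, start, end),
#'   all coordinates 0-based half-open.
#' @export
readBed12 <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 12) stop("BED12 requires 12 columns, got ", ncol(tab))
  names(tab)[1:12] <- c("chrom", "chromStart", "chromEnd", "name", "score",
                        "strand", "thickStart", "thickEnd", "itemRgb",
                        "blockCount", "blockSizes", "blockStarts")
  if (anyDuplicated(tab$name))
    stop("duplicate transcript name(s) in BED12: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  exons <- NULL; regions <- NULL
  for (r in seq_len(nrow(tab))) {
    sizes <- as.integer(strsplit(tab$blockSizes[r], ",")[[1]])
    starts <- as.integer(strsplit(tab$blockStarts[r], ",")[[1]])
    if (length(sizes) != tab$blockCount[r] ||
        length(starts) != tab$blockCount[r])
      stop("malformed blocks for transcript ", tab$name[r])
    gs <- tab$chromStart[r] + starts
    ge <- gs + sizes
    if (is.unsorted(gs) || any(gs[-1] < ge[-length(ge)]))
      stop("exon blocks of ", tab$name[r], " must be sorted, non-overlapping")
    ex <- data.frame(transcript_id = tab$name[r], chrom = tab$chrom[r],
                     start = gs, end = ge, strand = tab$strand[r],
                     stringsAsFactors = FALSE)
    len <- sum(sizes)
    ts <- tab$thickStart[r]; te <- tab$thickEnd[r]
    if (te > ts) {
      cs <- projectGenomicToTranscript(ts, ex, tab$strand[r])
      ce <- projectGenomicToTranscript(te - 1L, ex, tab$strand[r])
      if (is.na(cs) || is.na(ce))
        stop("CDS span of ", tab$name[r], " is not exonic")
      lo <- min(cs, ce); hi <- max(cs, ce) + 1L
      reg <- data.frame(
        transcript_id = tab$name[r],
        region = c("5UTR", "CDS", "3UTR"),
        start = c(0L, lo, hi),
        end = c(lo, hi, len),
        stringsAsFactors = FALSE)
      reg <- reg[reg$end > reg$start, , drop = FALSE]
    } else {
      reg <- data.frame(transcript_id = tab$name[r], region = "3UTR",
                        start = 0L, end = len, stringsAsFactors = FALSE)
    }
    exons <- rbind(exons, ex)
    regions <- rbind(regions, reg)
  }
  list(exons = exons, regions = regions)
}

#' Assemble a transcript database
#'
#' @param seqs named \code{RNAStringSet} or character vector (IDs must
#'   match the annotation names).
#' @param annotation list with \code{exons} and \code{regions} data.frames
#'   as returned by [readBed12()].
#' @return a validated \linkS4class{TranscriptDB}.
#' @export
makeTranscriptDB <- function(seqs, annotation) {
  if (is.character(seqs)) seqs <- Biostrings::RNAStringSet(seqs)
  need <- unique(annotation$exons$transcript_id)
  missing_ids <- setdiff(need, names(seqs))
  if (length(missing_ids))
    stop("annotation refers to transcript(s) absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  db <- new("TranscriptDB", seqs = seqs,
            regions = annotation$regions, exons = annotation$exons)
  validObject(db)
  db
}

#' Project a genomic position into transcript coordinates
#'
#' Exonic positions map to their cumulative 5'->3' offset along the
#' transcript (strand-aware: on the minus strand the transcript runs along
#' decreasing genomic coordinates). Intronic or intergenic positions map
#' to \code{NA}. The mapping is a bijection between exonic genomic
#' positions and \code{[0, transcript length)}.
#'
#' @param gpos integer vector of genomic positions (0-based).
#' @param exons data.frame with \code{start}, \code{end} (0-based
#'   half-open), sorted, non-overlapping.
#' @param strand \code{"+"} or \code{"-"}.
#' @return integer vector of transcript positions, \code{NA} where
#'   non-exonic.
#' @export
projectGenomicToTranscript <- function(gpos, exons, strand = "+") {
  starts <- exons$start; ends <- exons$end
  if (is.unsorted(starts)) stop("exons must be sorted")
  cum <- c(0L, cumsum(ends - starts))
  total <- cum[length(cum)]
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_along(starts)) {
    ink <- !is.na(gpos) & gpos >= starts[k] & gpos < ends[k]
    out[ink] <- cum[k] + (gpos[ink] - starts[k])
  }
  if (identical(strand, "-")) out <- ifelse(is.na(out), NA_integer_,
                                            total - 1L - out)
  as.integer(out)
}

# left-aligned minimal representation of an allele pair at `pos` (0-based)
normalizeAllelePair <- function(pos, ref, alt) {
  # trim common suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim common prefix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Read variants from a VCF subset
#'
#' Reads VCF 4.x (SNPs and short indels) carrying an \code{AF} INFO key.
#' 1-based VCF positions are converted to 0-based; multi-allelic records
#' are split into one variant per alternate allele; allele frequencies
#' above 0.5 are folded to MAF = 1 - AF; records without AF keep a missing
#' MAF (retained, but excluded from frequency-stratified statistics).
#' Indels are left-aligned to their minimal representation. Reference
#' alleles are checked against the transcript sequences; a mismatch is an
#' error naming the record.
#'
#' @param path VCF file (plain text).
#' @param db a \linkS4class{TranscriptDB}.
#' @param dialect \code{"transcript"} (CHROM is a transcript ID; default)
#'   or \code{"genome"} (CHROM is a genomic contig; positions are projected
#'   through the exon annotation onto every overlapping transcript).
#' @return data.frame with columns \code{id, transcript_id, pos, ref, alt,
#'   maf, var_class}.
#' @export
readVcfVariants <- function(path, db, dialect = c("transcript", "genome")) {
  dialect <- match.arg(dialect)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(id = character(), transcript_id = character(),
                      pos = integer(), ref = character(),
                      alt = character(), maf = numeric(),
                      var_class = character(), stringsAsFactors = FALSE))
  out <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[r]
    afm <- regmatches(info, regexec("(?:^|;)(?:AF|MAF)=([^;]+)", info))[[1]]
    afs <- if (length(afm) == 2)
      suppressWarnings(as.numeric(strsplit(afm[2], ",")[[1]]))
    else rep(NA_real_, length(alts))
    if (length(afs) == 1 && length(alts) > 1) afs <- rep(afs, length(alts))
    rid <- if (is.na(fix$ID[r]) || fix$ID[r] == ".")
      paste0("var_", fix$CHROM[r], "_", fix$POS[r]) else fix$ID[r]
    pos0 <- as.integer(fix$POS[r]) - 1L
    ref0 <- normalizeSeq(fix$REF[r])
    for (a in seq_along(alts)) {
      alt0 <- normalizeSeq(alts[a])
      maf <- afs[a]
      if (!is.na(maf) && maf > 0.5) maf <- 1 - maf
      targets <- if (dialect == "transcript") {
        if (!(fix$CHROM[r] %in% transcriptIds(db)))
          stop("VCF record ", rid, ": unknown transcript ", fix$CHROM[r])
        data.frame(transcript_id = fix$CHROM[r], pos = pos0,
                   ref = ref0, alt = alt0, stringsAsFactors = FALSE)
      } else {
        mapGenomeVariant(db, fix$CHROM[r], pos0, ref0, alt0, rid)
      }
      for (t in seq_len(nrow(targets))) {
        nm <- normalizeAllelePair(targets$pos[t], targets$ref[t],
                                  targets$alt[t])
        tid <- targets$transcript_id[t]
        tseq <- transcriptSeq(db, tid)
        obs <- substr0(tseq, nm$pos, nm$pos + nchar(nm$ref))
        if (obs != nm$ref)
          stop("VCF record ", rid, ": REF ", nm$ref,
               " does not match transcript ", tid, " (", obs,
               ") at position ", nm$pos)
        cls <- if (nchar(nm$ref) == 1 && nchar(nm$alt) == 1) "SNP" else "indel"
        out[[length(out) + 1L]] <- data.frame(
          id = if (length(alts) > 1) paste0(rid, "_", alts[a]) else rid,
          transcript_id = tid, pos = nm$pos, ref = nm$ref, alt = nm$alt,
          maf = maf, var_class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# map a genome-space variant onto all overlapping transcripts
mapGenomeVariant <- function(db, chrom, pos0, ref, alt, rid) {
  ex <- exonTable(db)
  hits <- NULL
  for (tid in unique(ex$transcript_id[ex$chrom == chrom])) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    strand <- e$strand[1]
    tp <- projectGenomicToTranscript(pos0, e, strand)
    if (is.na(tp)) next
    if (strand == "-") {
      if (nchar(ref) != nchar(alt))
        stop("VCF record ", rid,
             ": minus-strand indels are not supported in genome dialect")
      r2 <- rnaRevComp(ref); a2 <- rnaRevComp(alt)
      tp <- tp - (nchar(ref) - 1L)
      hits <- rbind(hits, data.frame(transcript_id = tid, pos = tp,
                                     ref = r2, alt = a2,
                                     stringsAsFactors = FALSE))
    } else {
      hits <- rbind(hits, data.frame(transcript_id = tid, pos = tp,
                                     ref = ref, alt = alt,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits))
    stop("VCF record ", rid, ": position is not exonic in any transcript")
  hits
}

#' Read CLASH-style chimera records
#'
#' TSV with header columns \code{chimera_id, mirna_id, mirna_seq,
#' transcript_id, frag_start, frag_end} (0-based half-open fragment
#' interval on the transcript). Fragments outside the transcript are an
#' error; fragment lengths outside the typical 42-119 nt chimera range are
#' kept with a warning (the bounds are descriptive, not a filter).
#'
#' @param path TSV file.
#' @param db a \linkS4class{TranscriptDB}.
#' @return data.frame of chimera rows (miRNA sequences normalized to RNA).
#' @export
readChimeras <- function(path, db) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "")
  need <- c("chimera_id", "mirna_id", "mirna_seq", "transcript_id",
            "frag_start", "frag_end")
  if (!all(need %in% names(tab)))
    stop("chimera TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$chimera_id))
    stop("duplicate chimera id(s): ",
         paste(unique(tab$chimera_id[duplicated(tab$chimera_id)]),
               collapse = ", "))
  tab$mirna_seq <- vapply(tab$mirna_seq, normalizeSeq, character(1),
                          USE.NAMES = FALSE)
  lens <- transcriptLength(db)
  for (r in seq_len(nrow(tab))) {
    tid <- tab$transcript_id[r]
    if (!(tid %in% names(lens)))
      stop("chimera ", tab$chimera_id[r], ": unknown transcript ", tid)
    if (tab$frag_start[r] < 0 || tab$frag_end[r] > lens[[tid]] ||
        tab$frag_start[r] >= tab$frag_end[r])
      stop("chimera ", tab$chimera_id[r],
           ": fragment outside transcript bounds")
    flen <- tab$frag_end[r] - tab$frag_start[r]
    if (flen < 42 || flen > 119)
      warning("chimera ", tab$chimera_id[r], ": fragment length ", flen,
              " nt outside the typical 42-119 nt range (kept)")
  }
  tab
}

#' Read per-nucleotide conservation tracks
#'
#' Wig-like TSV with columns \code{transcript_id, pos, score} (0-based
#' positions, scores in [0, 1], \code{NA} allowed). Every transcript
#' present must be covered at all positions; an incomplete track is an
#' error.
#'
#' @param path TSV file.
#' @param db a \linkS4class{TranscriptDB}.
#' @return named list of numeric score vectors (one per transcript).
#' @export
readConservation <- function(path, db) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("transcript_id", "pos", "score")
  if (!all(need %in% names(tab)))
    stop("conservation TSV must have columns: ", paste(need, collapse = ", "))
  lens <- transcriptLength(db)
  out <- list()
  for (tid in unique(tab$transcript_id)) {
    if (!(tid %in% names(lens)))
      stop("conservation track refers to unknown transcript ", tid)
    sub <- tab[tab$transcript_id == tid, ]
    len <- lens[[tid]]
    if (nrow(sub) != len || !setequal(sub$pos, 0:(len - 1)))
      stop("conservation track for ", tid, " covers ", nrow(sub),
           " position(s), transcript has ", len)
    sc <- numeric(len)
    sc[sub$pos + 1L] <- sub$score
    if (any(sc < 0 | sc > 1, na.rm = TRUE))
      stop("conservation scores for ", tid, " must lie in [0, 1]")
    out[[tid]] <- sc
  }
  out
}

#' Write / read a results table
#'
#' Plain TSV with a header, deterministic column order (as given), NA for
#' missing values; numeric values survive a round-trip to at least six
#' decimals.
#'
#' @param df data.frame.
#' @param path output file.
#' @export
writeResultsTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", comment.char = "")
}
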