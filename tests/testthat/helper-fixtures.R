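# shared fixture builders (all fixtures constructed in code)

# single-exon, plus-strand TranscriptDB from named RNA sequences;
# regions split 10/50/40 unless a transcript is shorter than 10 nt
fix_db <- function(seqs, cds = NULL) {
  ids <- names(seqs)
  regions <- NULL; exons <- NULL
  g <- 1000L
  for (id in ids) {
    len <- nchar(seqs[[id]])
    if (is.null(cds)) {
      u5 <- max(1L, round(0.1 * len)); cd <- max(1L, round(0.5 * len))
    } else {
      u5 <- cds[[id]][1]; cd <- cds[[id]][2] - cds[[id]][1]
    }
    regions <- rbind(regions, data.frame(
      transcript_id = id, region = c("5UTR", "CDS", "3UTR"),
      start = c(0L, u5, u5 + cd), end = c(u5, u5 + cd, len),
      stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(
      transcript_id = id, chrom = "chr1", start = g, end = g + len,
      strand = "+", stringsAsFactors = FALSE))
    g <- g + len + 100L
  }
  regions <- regions[regions$end > regions$start, ]
  methods::new("TranscriptDB",
               seqs = Biostrings::RNAStringSet(unlist(seqs)),
               regions = regions, exons = exons)
}

# deterministic chimera row + located site for a transcript with an implant
fix_located <- function(db, tid, mirna, frag, model = defaultEnergyModel()) {
  loc <- locateSite(mirna, db, tid, frag, model)
  list(loc = loc,
       chimera = data.frame(chimera_id = "c1", mirna_id = "m1",
                            mirna_seq = mirna, transcript_id = tid,
                            frag_start = frag[1], frag_end = frag[2],
                            stringsAsFactors = FALSE))
}

# a small, fast cohort configuration for pipeline-level tests
fix_small_config <- function(seed, ...) {
  cohortConfig(n_transcripts = 12, len_range = c(320, 600),
               n_mirnas = 4, n_chimeras = 8, clash_fraction = 0.5,
               frag_3utr_bias = 0.4, couple_maf_access = FALSE,
               densities = list(`5UTR` = c(common = 0.004, rare = 0.008),
                                CDS = c(common = 0.006, rare = 0.024),
                                `3UTR` = c(common = 0.014, rare = 0.007)),
               seed = seed, ...)
}

# write a VCF text fixture
fix_write_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  head <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(head, lines), path)
  path
}

expect_close <- function(x, y, tol = 1e-9) {
  testthat::expect_true(all(abs(x - y) <= tol * pmax(1, abs(y))),
                        label = paste0("max dev ", max(abs(x - y))))
}
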