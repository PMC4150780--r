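test_that("FASTA reading normalizes DNA and rejects bad records", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGT", ">t2", "acguu"), p)
  fa <- readTranscriptsFasta(p)
  expect_equal(as.character(fa[["t1"]]), "ACGU")
  expect_equal(as.character(fa[["t2"]]), "ACGUU")

  writeLines(c(">t1", "ACGR"), p)
  expect_error(readTranscriptsFasta(p), "disallowed")
  writeLines(c(">t1", "ACGU", ">t1", "GGG"), p)
  expect_error(readTranscriptsFasta(p), "duplicate")
  writeLines(c(">t1", "", ">t2", "ACGU"), p)
  expect_error(readTranscriptsFasta(p), "empty")
})

test_that("FASTA write/read round-trips three synthetic transcripts", {
  set.seed(9)
  seqs <- setNames(vapply(1:3, function(i) random_rna(20 + i), character(1)),
                   c("a", "b", "c"))
  p <- tempfile(fileext = ".fa")
  writeTranscriptsFasta(seqs, p)
  back <- readTranscriptsFasta(p)
  expect_identical(as.character(back), seqs)
})

test_that("genomic-to-transcript projection follows the exon walk", {
  ex1 <- data.frame(start = 100L, end = 200L)
  expect_equal(projectGenomicToTranscript(100, ex1, "+"), 0L)
  expect_equal(projectGenomicToTranscript(199, ex1, "+"), 99L)
  expect_true(is.na(projectGenomicToTranscript(200, ex1, "+")))
  # oracle: enumerate exon bases and index
  ex2 <- data.frame(start = c(0L, 20L), end = c(10L, 30L))
  bases <- c(0:9, 20:29)
  for (g in c(0, 5, 9, 25, 29, 15)) {
    want <- if (g %in% bases) match(g, bases) - 1L else NA_integer_
    expect_equal(projectGenomicToTranscript(g, ex2, "+"), want)
  }
  # minus strand: reverse the enumerated base list
  ex3 <- data.frame(start = 100L, end = 110L)
  expect_equal(projectGenomicToTranscript(109, ex3, "-"), 0L)
  expect_equal(projectGenomicToTranscript(100, ex3, "-"), 9L)
})

test_that("projection is a bijection onto [0, transcript length)", {
  ex <- data.frame(start = c(5L, 40L, 90L), end = c(15L, 55L, 95L))
  for (strand in c("+", "-")) {
    gpos <- c(5:14, 40:54, 90:94)
    tpos <- projectGenomicToTranscript(gpos, ex, strand)
    expect_setequal(tpos, 0:29)
    expect_equal(anyDuplicated(tpos), 0L)
  }
})

test_that("BED12 yields tiling regions and strand-aware CDS intervals", {
  p <- tempfile(fileext = ".bed")
  # 30-nt transcript over two blocks, CDS = genomic [110, 135)
  writeLines(paste(c("chr1", 100, 140, "tx1", 0, "+", 110, 135, "0", 2,
                     "20,10,", "0,30,"), collapse = "\t"), p)
  ann <- readBed12(p)
  expect_equal(ann$regions$region, c("5UTR", "CDS", "3UTR"))
  expect_equal(ann$regions$start, c(0L, 10L, 25L))
  expect_equal(ann$regions$end, c(10L, 25L, 30L))
  # same blocks on the minus strand: CDS flips in transcript coordinates
  writeLines(paste(c("chr1", 100, 140, "tx1", 0, "-", 110, 135, "0", 2,
                     "20,10,", "0,30,"), collapse = "\t"), p)
  annm <- readBed12(p)
  cds <- annm$regions[annm$regions$region == "CDS", ]
  expect_equal(c(cds$start, cds$end), c(5L, 20L))
})

test_that("VCF conventions: positions, folding, splitting, errors", {
  db <- fix_db(list(t1 = "ACGUACGUACGUACGUACGU"))
  # POS=5 (1-based) -> internal 4; AF=0.7 folds to 0.3
  p <- fix_write_vcf(c("t1\t5\trs1\tA\tG\t.\tPASS\tAF=0.7",
                       "t1\t2\trs2\tC\tG,T\t.\tPASS\tAF=0.05,0.6",
                       "t1\t3\trs3\tG\tA\t.\tPASS\t."))
  v <- readVcfVariants(p, db)
  expect_equal(v$pos[v$id == "rs1"], 4L)
  expect_equal(v$maf[v$id == "rs1"], 0.3)
  # multi-allelic split into two records with per-allele AF
  expect_equal(sum(grepl("rs2", v$id)), 2L)
  expect_equal(sort(v$maf[grepl("rs2", v$id)]), c(0.05, 0.4))
  # missing AF kept with missing MAF
  expect_true(is.na(v$maf[v$id == "rs3"]))
  expect_equal(v$var_class, rep("SNP", 4))
  # reference mismatch is an error naming the record
  p2 <- fix_write_vcf("t1\t5\trsX\tG\tC\t.\tPASS\tAF=0.1")
  expect_error(readVcfVariants(p2, db), "rsX")
})

test_that("indels are left-aligned to minimal representation", {
  db <- fix_db(list(t1 = "AACCCGGGUUAACCGGUUAA"))
  p <- fix_write_vcf("t1\t3\tdel1\tCCCG\tCCG\t.\tPASS\tAF=0.2")
  v <- readVcfVariants(p, db)
  expect_equal(v$var_class, "indel")
  # CCCG->CCG: common suffix and prefix trim to a 1-nt deletion whose
  # position still matches the transcript
  expect_equal(nchar(v$ref) - nchar(v$alt), 1L)
  expect_equal(unname(substr0(transcriptSeq(db, "t1"), v$pos,
                              v$pos + nchar(v$ref))),
               v$ref)
})

test_that("genome-dialect VCF projects through exons onto transcripts", {
  seqs <- list(t1 = "ACGUACGUACGUACGUACGU")
  db0 <- fix_db(seqs)
  # replace exons: two blocks 1000-1010, 1050-1060
  ex <- data.frame(transcript_id = "t1", chrom = "chr1",
                   start = c(1000L, 1050L), end = c(1010L, 1060L),
                   strand = "+", stringsAsFactors = FALSE)
  db <- methods::new("TranscriptDB", seqs = db0@seqs,
                     regions = regionTable(db0), exons = ex)
  # genomic 1052 -> transcript pos 12 (0-based); base there is A
  p <- fix_write_vcf("chr1\t1053\tg1\tA\tC\t.\tPASS\tAF=0.2")
  v <- readVcfVariants(p, db, dialect = "genome")
  expect_equal(v$transcript_id, "t1")
  expect_equal(v$pos, 12L)
  # intronic position errors
  p2 <- fix_write_vcf("chr1\t1030\tg2\tA\tC\t.\tPASS\tAF=0.2")
  expect_error(readVcfVariants(p2, db, dialect = "genome"), "not exonic")
})

test_that("chimera reader enforces bounds and warns on odd lengths", {
  set.seed(21)
  db <- fix_db(list(t1 = random_rna(300)))
  p <- tempfile(fileext = ".tsv")
  tab <- data.frame(chimera_id = "c1", mirna_id = "m1",
                    mirna_seq = "ugagguaguagguuguauaguu",
                    transcript_id = "t1", frag_start = 10, frag_end = 80)
  writeResultsTsv(tab, p)
  ch <- readChimeras(p, db)
  expect_equal(ch$mirna_seq, "UGAGGUAGUAGGUUGUAUAGUU")
  # fragment length 41: warned but kept
  tab$frag_end <- 51
  writeResultsTsv(tab, p)
  expect_warning(ch2 <- readChimeras(p, db), "42-119")
  expect_equal(nrow(ch2), 1L)
  # out of bounds: error
  tab$frag_end <- 400
  writeResultsTsv(tab, p)
  expect_error(readChimeras(p, db), "bounds")
})

test_that("conservation tracks must cover each transcript completely", {
  set.seed(22)
  db <- fix_db(list(t1 = random_rna(12)))
  p <- tempfile(fileext = ".tsv")
  writeResultsTsv(data.frame(transcript_id = "t1", pos = 0:11,
                             score = round(runif(12), 3)), p)
  tr <- readConservation(p, db)
  expect_length(tr$t1, 12)
  writeResultsTsv(data.frame(transcript_id = "t1", pos = 0:9,
                             score = runif(10)), p)
  expect_error(readConservation(p, db), "covers")
  writeResultsTsv(data.frame(transcript_id = "t1", pos = 0:11,
                             score = c(runif(11), 2)), p)
  expect_error(readConservation(p, db), "0, 1")
})

test_that("results TSVs round-trip numeric values to six decimals", {
  df <- data.frame(id = c("a", "b"), x = c(1.23456789, -0.000012345),
                   y = c(NA, 3.5), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  writeResultsTsv(df, p)
  back <- readResultsTsv(p)
  expect_identical(names(back), names(df))
  expect_true(all(abs(back$x - df$x) < 5e-7))
  expect_true(is.na(back$y[1]) && back$y[2] == 3.5)
})
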