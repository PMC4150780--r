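model <- defaultEnergyModel()

test_that("seed classes follow the canonical definitions (let-7 example)", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  # perfect match to nts 2-8 (CUACCUC read 3'->5' on target) plus target A
  target8 <- paste0("GGGGG", "CUACCUCA", "GGGGG")
  # anchor = 0-based position of the A opposite nt 1 (index 12)
  expect_equal(classifySeed(let7, target8, anchor = 12), "8mer")
  # terminal A replaced by C: still matches 2-8 -> 7mer-m8
  target7 <- paste0("GGGGG", "CUACCUCC", "GGGGG")
  expect_equal(classifySeed(let7, target7, anchor = 12), "7mer-m8")
  # match 2-7 only, with A -> 7mer-A1
  targetA1 <- paste0("GGGGG", "AUACCUCA", "GGGGG")
  expect_equal(classifySeed(let7, targetA1, anchor = 12), "7mer-A1")
  # match 3-8, mismatch at 2 -> offset-6mer
  targetOff <- paste0("GGGGG", "CUACCUAC", "GGGGG")
  expect_equal(classifySeed(let7, targetOff, anchor = 12), "offset-6mer")
  # match 2-7, mismatch at 8, no A -> 6mer
  target6 <- paste0("GGGGG", "AUACCUCC", "GGGGG")
  expect_equal(classifySeed(let7, target6, anchor = 12), "6mer")
  # no complementarity in register -> seedless
  expect_equal(classifySeed(let7, "GGGGGGGGGGGGGGGGGG", anchor = 12),
               "seedless")
})

test_that("classifySeed agrees with the string-matching oracle", {
  set.seed(31)
  for (rep in 1:300) {
    m <- random_rna(sample(19:23, 1))
    t <- random_rna(sample(15:30, 1))
    a1 <- sample(0:(nchar(t) - 1), 1)
    expect_equal(classifySeed(m, t, anchor = a1),
                 oracle_classify_seed(m, t, a1 + 1))
  }
})

test_that("A1-dependent classes are unavailable at the transcript edge", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  # seed match runs to the transcript 3' end; position opposite nt 1 is
  # beyond the sequence -> cannot be 8mer, still 7mer-m8
  target <- paste0("GGGGG", "CUACCUC")
  expect_equal(classifySeed(let7, target, anchor = 12), "7mer-m8")
})

test_that("3' pairing length counts contiguous WC runs from nt 12", {
  mk <- function(pairs, mirna, target)
    methods::new("DuplexResult", dG = -5, pairs = pairs,
                 targetSpan = c(0L, 1L), mirna = mirna, target = target)
  # seed-only duplex: no pair at nt >= 12
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  p <- cbind(2:8, 20:14)
  expect_equal(threePrimePairingLength(mk(p, m, random_rna(25))), 0L)
  # contiguous WC pairs at 13,14,15 plus an isolated pair at 18
  t2 <- rnaRevComp(m)  # full complement target
  p2 <- cbind(c(13L, 14L, 15L, 18L), c(10L, 9L, 8L, 5L))
  expect_equal(threePrimePairingLength(mk(p2, m, t2)), 3L)
})

test_that("a GU pair breaks a 3' Watson-Crick run", {
  m <- "AAAAAAAAAAAGGGGG"          # nts 12-16 are G
  t <- "CCUCC"                      # target with a U opposite nt 14
  # pairs (12,5)..(16,1): G-C G-C G-U G-C G-C
  p <- cbind(12:16, 5:1)
  d <- methods::new("DuplexResult", dG = -5, pairs = p,
                    targetSpan = c(0L, 5L), mirna = m, target = t)
  expect_equal(threePrimePairingLength(d), 2L)
})

test_that("conservation score averages the site, ignoring missing values", {
  expect_equal(conservationScore(rep(0.5, 10), c(2, 6)), 0.5)
  expect_equal(conservationScore(c(1.0, 0.0, 0.8, 0.6), c(0, 4)), 0.6)
  expect_equal(conservationScore(c(0.2, NA, 0.4), c(0, 3)), 0.3)
  expect_true(is.na(conservationScore(c(NA, NA), c(0, 2))))
  expect_error(conservationScore(rep(0.5, 4), c(2, 2)), "nonempty")
})

test_that("locateSite recovers an implanted complement and flags no-hybrid", {
  set.seed(32)
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  bg <- paste(rep("A", 120), collapse = "")
  imp <- implantSite(bg, m, "8mer", 50)
  db <- fix_db(list(t1 = imp$seq))
  loc <- locateSite(m, db, "t1", c(20, 100), model)
  expect_true(loc$site_found)
  expect_equal(loc$site, imp$true_site)
  # all-A fragment vs all-A miRNA: site-less
  db2 <- fix_db(list(t1 = bg))
  loc2 <- locateSite("AAAAAAA", db2, "t1", c(0, 60), model)
  expect_false(loc2$site_found)
})

test_that("site features compose from direct energy calls", {
  set.seed(33)
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  bg <- random_rna(240, gc = 0.55)
  imp <- implantSite(bg, m, "7mer-m8", 110)
  db <- fix_db(list(t1 = imp$seq))
  fx <- fix_located(db, "t1", m, c(80, 180), model)
  skip_if(!fx$loc$site_found)
  ft <- computeSiteFeatures(fx$loc, db, "t1", model = model, window = 120L)
  site <- fx$loc$site
  win <- c(ft$window_start, ft$window_end)
  wseq <- substr0(imp$seq, win[1], win[2])
  rel <- site - win[1]
  expect_equal(ft$dG_hybrid, duplexEnergy(fx$loc$duplex))
  expect_equal(ft$dG_open, openingEnergy(wseq, rel, model), tolerance = 1e-9)
  expect_equal(ft$dG_total, ft$dG_hybrid + ft$dG_open)
  expect_equal(ft$site_access, blockAccessibility(wseq, rel, model),
               tolerance = 1e-9)
  expect_equal(ft$upstream_access,
               blockAccessibility(wseq, rel - c(25, rel[2] - rel[1]), model),
               tolerance = 1e-9)
  expect_gte(ft$dG_total, ft$dG_hybrid)
  expect_equal(ft$seed_type, "7mer-m8")
})

test_that("an unpairable context gives full accessibility and zero opening", {
  # target window contains only A and G (no intramolecular pairs possible):
  # a G island inside A flanks, bound by an all-C miRNA
  m <- paste(rep("C", 9), collapse = "")
  seq <- paste0(strrep("A", 90), strrep("G", 12), strrep("A", 90))
  db <- fix_db(list(t1 = seq))
  fx <- fix_located(db, "t1", m, c(60, 130), model)
  expect_true(fx$loc$site_found)
  ft <- computeSiteFeatures(fx$loc, db, "t1", model = model, window = 120L)
  expect_equal(ft$site_access, 1.0)
  expect_equal(ft$upstream_access, 1.0)
  expect_equal(ft$downstream_access, 1.0)
  expect_equal(ft$dG_open, 0.0)
  expect_equal(ft$dG_total, ft$dG_hybrid)
})

test_that("feature computation is invariant to padding outside the window", {
  set.seed(34)
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  core <- random_rna(260, gc = 0.5)
  imp <- implantSite(core, m, "6mer", 120)
  pad <- random_rna(70)
  db1 <- fix_db(list(t1 = imp$seq))
  db2 <- fix_db(list(t1 = paste0(pad, imp$seq, pad)))
  f1 <- fix_located(db1, "t1", m, c(90, 190), model)
  f2 <- fix_located(db2, "t1", m, c(160, 260), model)
  skip_if(!f1$loc$site_found || !f2$loc$site_found)
  ft1 <- computeSiteFeatures(f1$loc, db1, "t1", model = model, window = 100L)
  ft2 <- computeSiteFeatures(f2$loc, db2, "t1", model = model, window = 100L)
  expect_equal(ft1$site_access, ft2$site_access, tolerance = 1e-9)
  expect_equal(ft1$dG_total, ft2$dG_total, tolerance = 1e-9)
  expect_equal(ft1$upstream_access, ft2$upstream_access, tolerance = 1e-9)
})

test_that("flank blocks truncated at a transcript end are flagged", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  bg <- paste(rep("A", 80), collapse = "")
  imp <- implantSite(bg, m, "8mer", 10)   # only 10 nt upstream available
  db <- fix_db(list(t1 = imp$seq))
  fx <- fix_located(db, "t1", m, c(0, 60), model)
  expect_true(fx$loc$site_found)
  ft <- computeSiteFeatures(fx$loc, db, "t1", model = model, window = 80L)
  expect_true(ft$upstream_truncated)
  expect_false(is.na(ft$upstream_access))
  expect_false(ft$downstream_truncated)
})
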