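model <- defaultEnergyModel()

test_that("variant placement respects site and flank boundaries", {
  features <- data.frame(chimera_id = "c1", transcript_id = "t1",
                         site_start = 100L, site_end = 120L,
                         stringsAsFactors = FALSE)
  mkvar <- function(pos, ref = "A", alt = "G", id = "v")
    data.frame(id = id, transcript_id = "t1", pos = pos, ref = ref,
               alt = alt, maf = 0.1,
               var_class = ifelse(nchar(ref) == nchar(alt), "SNP", "indel"),
               stringsAsFactors = FALSE)
  pl <- function(v) placeVariants(v, features)$placement
  expect_equal(pl(mkvar(100)), "within_site")     # site start included
  expect_equal(pl(mkvar(119)), "within_site")
  expect_equal(pl(mkvar(75)), "upstream_25")      # 25 nt 5' of site start
  expect_length(pl(mkvar(74)), 0)                 # 26 nt 5': unassigned
  expect_equal(pl(mkvar(120)), "downstream_25")
  expect_equal(pl(mkvar(144)), "downstream_25")
  expect_length(pl(mkvar(145)), 0)
  # an indel whose span reaches into the site is within_site
  expect_equal(pl(mkvar(98, ref = "AAA", alt = "A")), "within_site")
  # indels in flank blocks are dropped and counted
  out <- placeVariants(mkvar(110, ref = "AA", alt = "A"), features)
  expect_equal(out$placement, "within_site")
  out2 <- placeVariants(mkvar(130, ref = "AA", alt = "A"), features)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_flank_indels_dropped"), 1L)
})

test_that("applyVariant maps coordinates and reverts as an involution", {
  s <- "AACCGGUUAACCGGUU"
  # SNP: identity map
  snp <- applyVariant(s, 4, "G", "U")
  expect_equal(nchar(snp$seq), nchar(s))
  expect_equal(snp$map(c(0, 4, 10)), c(0, 4, 10))
  back <- applyVariant(snp$seq, 4, "U", "G")
  expect_identical(back$seq, s)
  # insertion before a downstream interval shifts it by +1
  ins <- applyVariant(s, 4, "G", "GA")
  expect_equal(nchar(ins$seq), nchar(s) + 1L)
  expect_equal(ins$map(c(3, 4, 5, 10)), c(3, 4, 6, 11))
  # deletion shifts downstream positions back
  del <- applyVariant(s, 4, "GGU", "G")
  expect_equal(del$map(c(4, 7, 10)), c(4, 5, 8))
  expect_error(applyVariant(s, 4, "C", "A"), "does not match")
})

# build a deterministic effect scenario: implanted site + one variant
fix_effect_case <- function(seed, type = "8mer", vpos_off = 3L,
                            ref_from_seq = TRUE, alt = NULL,
                            placement_target = "within_site") {
  set.seed(seed)
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  bg <- random_rna(300, gc = 0.5)
  imp <- implantSite(bg, m, type, 140)
  db <- fix_db(list(t1 = imp$seq))
  chim <- data.frame(chimera_id = "c1", mirna_id = "m1", mirna_seq = m,
                     transcript_id = "t1", frag_start = 110L,
                     frag_end = 200L, stringsAsFactors = FALSE)
  sft <- siteFeatureTable(chim, db, NULL, model, window = 120L)
  site <- c(sft$features$site_start, sft$features$site_end)
  pos <- if (placement_target == "within_site") site[1] + vpos_off
         else if (placement_target == "upstream_25") site[1] - 5L
         else site[2] + 5L
  ref <- substr0(imp$seq, pos, pos + 1L)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
  v <- data.frame(id = "v1", transcript_id = "t1", pos = pos, ref = ref,
                  alt = alt, maf = 0.25, var_class = "SNP",
                  stringsAsFactors = FALSE)
  list(db = db, chim = chim, sft = sft, variant = v, site = site,
       mirna = m, seq = imp$seq)
}

test_that("a no-op allele gives exactly zero deltas", {
  fx <- fix_effect_case(41)
  v <- fx$variant; v$alt <- v$ref
  rec <- computeVariantEffect(v, fx$chim[1, ], "within_site",
                              fx$sft$located[["c1"]], fx$sft$features[1, ],
                              fx$db, model)
  expect_equal(rec$ddG_hybrid, 0)
  expect_equal(rec$ddG_total, 0)
  expect_equal(rec$d_site_access, 0)
  expect_equal(rec$d_upstream_access, 0)
  expect_equal(rec$d_downstream_access, 0)
})

test_that("flank variants have identically zero hybrid-energy change", {
  for (side in c("upstream_25", "downstream_25")) {
    fx <- fix_effect_case(42, placement_target = side)
    rec <- computeVariantEffect(fx$variant, fx$chim[1, ], side,
                                fx$sft$located[["c1"]],
                                fx$sft$features[1, ], fx$db, model)
    expect_identical(rec$ddG_hybrid, 0)
    expect_equal(rec$mut_dG_hybrid, rec$wt_dG_hybrid)
    # structural deltas are still real numbers in [-1, 1]
    expect_true(abs(rec$d_site_access) <= 1)
  }
})

test_that("a seed-disrupting SNP changes ddG_hybrid by the duplex difference", {
  fx <- fix_effect_case(43, type = "8mer", vpos_off = 16L)
  rec <- computeVariantEffect(fx$variant, fx$chim[1, ], "within_site",
                              fx$sft$located[["c1"]], fx$sft$features[1, ],
                              fx$db, model)
  # independent recomputation from scratch via direct calls
  mut <- applyVariant(fx$seq, fx$variant$pos, fx$variant$ref, fx$variant$alt)
  d_wt <- duplexMfe(fx$mirna, substr0(fx$seq, 110, 200), model)
  d_mut <- duplexMfe(fx$mirna, substr0(mut$seq, 110, 200), model)
  expect_equal(rec$ddG_hybrid,
               duplexEnergy(d_mut) - duplexEnergy(d_wt), tolerance = 1e-9)
  # and the accessibility deltas match direct window folds
  win <- c(fx$sft$features$window_start, fx$sft$features$window_end)
  wseq_wt <- substr0(fx$seq, win[1], win[2])
  wseq_mut <- substr0(mut$seq, win[1], win[2])
  msite <- targetSpan(d_mut) + 110
  expect_equal(rec$d_site_access,
               blockAccessibility(wseq_mut, msite - win[1], model) -
               blockAccessibility(wseq_wt, fx$site - win[1], model),
               tolerance = 1e-9)
  expect_gte(rec$mut_dG_total, rec$mut_dG_hybrid)
  expect_gte(rec$wt_dG_total, rec$wt_dG_hybrid)
})

test_that("swapping wild-type and mutant alleles negates every delta", {
  fx <- fix_effect_case(44, vpos_off = 5L)
  rec <- computeVariantEffect(fx$variant, fx$chim[1, ], "within_site",
                              fx$sft$located[["c1"]], fx$sft$features[1, ],
                              fx$db, model)
  # build the mutant world and the reverse variant
  mut <- applyVariant(fx$seq, fx$variant$pos, fx$variant$ref, fx$variant$alt)
  db2 <- fix_db(list(t1 = mut$seq))
  sft2 <- siteFeatureTable(fx$chim, db2, NULL, model, window = 120L)
  v2 <- fx$variant; v2$ref <- fx$variant$alt; v2$alt <- fx$variant$ref
  rec2 <- computeVariantEffect(v2, fx$chim[1, ], "within_site",
                               sft2$located[["c1"]], sft2$features[1, ],
                               db2, model)
  expect_equal(rec2$ddG_hybrid, -rec$ddG_hybrid, tolerance = 1e-9)
  expect_equal(rec2$ddG_total, -rec$ddG_total, tolerance = 1e-9)
  expect_equal(rec2$d_site_access, -rec$d_site_access, tolerance = 1e-9)
  expect_equal(rec2$d_upstream_access, -rec$d_upstream_access,
               tolerance = 1e-9)
  expect_equal(rec2$d_downstream_access, -rec$d_downstream_access,
               tolerance = 1e-9)
})

test_that("frequency classes follow the MAF threshold", {
  fx <- fix_effect_case(45)
  run <- function(maf) {
    v <- fx$variant; v$maf <- maf
    computeVariantEffect(v, fx$chim[1, ], "within_site",
                         fx$sft$located[["c1"]], fx$sft$features[1, ],
                         fx$db, model)$freq_class
  }
  expect_equal(run(0.01), "common")
  expect_equal(run(0.0099), "rare")
  expect_equal(run(NA_real_), "unknown")
})

test_that("accessibility effect flag is a strict absolute threshold", {
  rec <- data.frame(d_site_access = c(0.005, -0.02, 0.01, 0.3))
  expect_equal(accessibilityEffectFlag(rec, 0.01), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(accessibilityEffectFlag(rec, 0), "positive")
  # flagged set shrinks monotonically along a theta sweep
  set.seed(46)
  rec2 <- data.frame(d_site_access = runif(200, -0.4, 0.4))
  sizes <- vapply(seq(0.01, 0.2, 0.01),
                  function(t) sum(accessibilityEffectFlag(rec2, t)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a deletion spanning the whole site is flagged and rescanned", {
  fx <- fix_effect_case(47)
  site <- fx$site
  pos <- site[1] - 2L
  ref <- substr0(fx$seq, pos, site[2] + 2L)
  v <- data.frame(id = "v1", transcript_id = "t1", pos = pos, ref = ref,
                  alt = substr(ref, 1, 1), maf = 0.002, var_class = "indel",
                  stringsAsFactors = FALSE)
  rec <- computeVariantEffect(v, fx$chim[1, ], "within_site",
                              fx$sft$located[["c1"]], fx$sft$features[1, ],
                              fx$db, model)
  expect_true(rec$site_destroyed)
  # deltas refer to the best remaining hybrid (or a site-lost sentinel)
  expect_true(rec$site_lost || is.finite(rec$ddG_hybrid))
})
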