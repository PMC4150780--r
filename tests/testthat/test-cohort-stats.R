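test_that("variant density is count over length, by scope and class", {
  set.seed(51)
  db <- fix_db(list(t1 = random_rna(1000)), cds = list(t1 = c(100L, 600L)))
  mkv <- function(pos, maf) data.frame(
    id = paste0("v", seq_along(pos)), transcript_id = "t1", pos = pos,
    ref = "A", alt = "G", maf = maf, var_class = "SNP",
    stringsAsFactors = FALSE)
  v <- mkv(seq(50, 950, by = 100), rep(c(0.2, 0.001), 5))
  d <- variantDensity(v, db, freq_class = "all")
  expect_equal(d$density[d$region == "mRNA"], 10 / 1000)
  expect_equal(d$n_variants[d$region == "CDS"],
               sum(v$pos >= 100 & v$pos < 600))
  dc <- variantDensity(v, db, freq_class = "common")
  expect_equal(dc$n_variants[dc$region == "mRNA"], 5)
  # empty variant set: zero density
  d0 <- variantDensity(v[0, ], db, freq_class = "all")
  expect_equal(d0$density, rep(0, 3))
})

test_that("binding-site scope merges overlapping sites and restricts counts", {
  set.seed(52)
  db <- fix_db(list(t1 = random_rna(400)), cds = list(t1 = c(40L, 240L)))
  chim <- data.frame(chimera_id = c("c1", "c2"), transcript_id = "t1")
  features <- data.frame(chimera_id = c("c1", "c2"), transcript_id = "t1",
                         site_start = c(300L, 310L), site_end = c(320L, 330L),
                         stringsAsFactors = FALSE)
  v <- data.frame(id = c("a", "b"), transcript_id = "t1",
                  pos = c(305L, 50L), ref = "A", alt = "G", maf = 0.2,
                  var_class = "SNP", stringsAsFactors = FALSE)
  d <- variantDensity(v, db, chim, features, "binding_sites", "all")
  # merged [300, 330) = 30 nt, one variant inside
  expect_equal(d$total_length[d$region == "mRNA"], 30L)
  expect_equal(d$n_variants[d$region == "mRNA"], 1L)
  expect_equal(d$density[d$region == "mRNA"], 1 / 30)
})

test_that("densities are invariant to row order and duplicate-id handling", {
  set.seed(53)
  db <- fix_db(list(t1 = random_rna(500), t2 = random_rna(500)))
  v <- data.frame(id = c("x", "x", "y"), transcript_id = c("t1", "t2", "t1"),
                  pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                  maf = 0.1, var_class = "SNP", stringsAsFactors = FALSE)
  d1 <- variantDensity(v, db, freq_class = "all")
  d2 <- variantDensity(v[c(3, 1, 2), ], db, freq_class = "all")
  expect_equal(d1, d2)
  dd <- variantDensity(v, db, freq_class = "all", dedupe = "per_variant")
  expect_equal(dd$n_variants[dd$region == "mRNA"], 2L)
})

test_that("Fisher's exact test matches enumeration and handles edge tables", {
  expect_equal(fisherExact2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisherExact2x2(0, 5, 0, 9), 1.0)  # zero margin
  expect_equal(fisherExact2x2(12, 5, 29, 2), oracle_fisher_p(12, 5, 29, 2),
               tolerance = 1e-9)
  set.seed(54)
  for (rep in 1:100) {
    x <- as.integer(rmultinom(1, sample(5:40, 1), rep(0.25, 4)))
    expect_equal(fisherExact2x2(x[1], x[2], x[3], x[4]),
                 oracle_fisher_p(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
  expect_error(fisherExact2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisherExact2x2(1.5, 2, 3, 4), "non-negative")
})

test_that("identical scopes compare with p = 1", {
  dens <- data.frame(scope = c("whole_transcriptome", "clash_transcripts"),
                     region = "mRNA", freq_class = "common",
                     n_variants = c(10L, 10L), total_length = c(1000L, 1000L),
                     density = 0.01, stringsAsFactors = FALSE)
  rep <- densityComparisonReport(dens)
  expect_equal(rep$p, 1.0)
  expect_true("p_bonferroni" %in% names(rep))
})

test_that("conservation summary bins percentages that sum to 100", {
  f <- data.frame(transcript_id = "t1", site_start = 0L, site_end = 10L,
                  conservation = c(1, 1, 1, 1), stringsAsFactors = FALSE)
  cs <- conservationSummary(f)
  expect_equal(sum(cs$bins$percent), 100)
  expect_equal(cs$bins$percent[cs$bins$bin == "(0.9,1]"], 100)
  # uniform scores spread close to bin widths
  set.seed(55)
  f2 <- data.frame(transcript_id = "t1", site_start = 0L, site_end = 10L,
                   conservation = runif(4000), stringsAsFactors = FALSE)
  cs2 <- conservationSummary(f2)
  expect_true(all(abs(cs2$bins$percent - 10) < 3 * sqrt(0.1 * 0.9 / 4000) * 100))
})

test_that("effect histograms follow the interval conventions and count all", {
  rec <- data.frame(ddG_hybrid = c(2, -3, 0.5))
  d <- effectDistribution(rec, "ddG_hybrid")
  expect_equal(sum(d$bins$count), 3)
  expect_equal(unname(d$summary["frac_decrease"]), 1 / 3)
  expect_equal(unname(d$summary["frac_increase"]), 1 / 3)
  # all-zero deltas: zero bin holds everything, nothing exceeds
  z <- data.frame(d_site_access = rep(0, 7))
  dz <- effectDistribution(z, "d_site_access")
  expect_equal(max(dz$bins$count), 7)
  expect_equal(unname(dz$summary["frac_altered"]), 0)
  expect_true(all(dz$exceedance$fraction == 0))
  # boundary membership: (a, b] means a < x <= b
  b <- data.frame(ddG_hybrid = c(1, 1 + 1e-9))
  dbn <- effectDistribution(b, "ddG_hybrid")
  expect_equal(dbn$bins$count[dbn$bins$bin == "(0,1]"], 1)
  expect_equal(dbn$bins$count[dbn$bins$bin == "(1,2]"], 1)
  # exceedance is non-increasing in the threshold
  set.seed(56)
  r2 <- data.frame(ddG_total = rnorm(300, 0, 3))
  e2 <- effectDistribution(r2, "ddG_total")$exceedance
  expect_true(all(diff(e2$fraction) <= 0))
  expect_error(effectDistribution(rec, "nope"), "unknown measure")
})

test_that("sign-bias test is an exact binomial on the two tails", {
  rec <- data.frame(ddG_hybrid = c(rep(2, 5), rep(-2, 5)))
  expect_equal(signBiasTest(rec, "ddG_hybrid")$p, 1.0)
  rec2 <- data.frame(ddG_hybrid = rep(1.5, 15))
  r <- signBiasTest(rec2, "ddG_hybrid")
  expect_equal(r$n_up, 15); expect_equal(r$n_down, 0)
  expect_equal(r$p, 2 * 0.5^15, tolerance = 1e-12)
  # nothing beyond the threshold: missing, flagged
  r0 <- signBiasTest(data.frame(ddG_hybrid = c(0.2, -0.3)), "ddG_hybrid")
  expect_true(is.na(r0$p) && r0$flagged)
  # a strongly asymmetric cohort is detected
  set.seed(57)
  r3 <- data.frame(ddG_hybrid = abs(rnorm(120, 0, 2)) *
                     sample(c(1, -1), 120, TRUE, prob = c(0.85, 0.15)))
  expect_lt(signBiasTest(r3, "ddG_hybrid")$p, 0.01)
})

test_that("mean MAF by accessibility effect stratifies correctly", {
  rec <- data.frame(d_site_access = c(0.15, 0.004), maf = c(0.40, 0.10))
  out <- meanMafByAccessEffect(rec, theta_grid = 0.01)
  expect_equal(out$mean_maf_flagged, 0.40)
  expect_equal(out$mean_maf_unflagged, 0.10)
  # all records unflagged at a high cutoff: unflagged mean = overall mean
  out2 <- meanMafByAccessEffect(rec, theta_grid = 0.2)
  expect_equal(out2$n_flagged, 0L)
  expect_true(is.na(out2$mean_maf_flagged))
  expect_equal(out2$mean_maf_unflagged, 0.25)
  # unknown-MAF records are excluded
  rec3 <- rbind(rec, data.frame(d_site_access = 0.5, maf = NA))
  expect_equal(meanMafByAccessEffect(rec3, 0.01)$n_flagged, 1L)
})
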