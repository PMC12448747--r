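# Meta-analysis: harmonization, fixed-effect pooling, combinations, BH,
# novelty classification, and hypergeometric enrichment.

test_that("harmonization reproduces the z / se identities", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    effect = c(1, -1, 0.5),
                    p = c(0.05, 0.05, 1e-320),
                    stringsAsFactors = FALSE)
  h <- harmonize(tab, standardize = FALSE)
  # p = 0.05 two-sided -> |z| = qnorm(0.975), se = |beta / z|
  z975 <- qnorm(0.975)
  expect_equal(h$z[1], z975, tolerance = 1e-12)
  expect_equal(h$z[2], -z975, tolerance = 1e-12)
  expect_equal(h$se[1], 1 / z975, tolerance = 1e-12)
  expect_equal(h$se[2], 1 / z975, tolerance = 1e-12)
  # p floored at 1e-300; z must remain finite at the floor
  expect_equal(h$p_trunc[3], 1e-300)
  expect_equal(h$z[3], qnorm(5e-301, lower.tail = FALSE), tolerance = 1e-9)
  expect_true(is.finite(h$z[3]))
  # zero effect -> z = 0 -> infinite-SE sentinel
  h0 <- harmonize(data.frame(gene = "D", effect = 0, p = 0.5),
                  standardize = FALSE)
  expect_equal(h0$z, 0)
  expect_false(is.finite(h0$se))
  expect_error(harmonize(data.frame(gene = "E", effect = 1, p = 0)), "p")
})

test_that("harmonization standardizes effect scale when requested", {
  set.seed(41)
  tab <- data.frame(gene = paste0("G", 1:200), effect = rnorm(200, 2, 3),
                    p = runif(200))
  h <- harmonize(tab, standardize = TRUE)
  expect_equal(sd(h$beta_std), 1, tolerance = 1e-12)
  # rescaling the raw effects leaves standardized betas unchanged
  tab2 <- tab; tab2$effect <- tab$effect * 7
  h2 <- harmonize(tab2, standardize = TRUE)
  expect_equal(h2$beta_std, h$beta_std, tolerance = 1e-12)
  expect_equal(h2$se, h$se, tolerance = 1e-12)
})

test_that("fixed-effect pooling reproduces its closed forms", {
  # betas (1, 3) with unit SEs: pooled mean 2, pooled se 1/sqrt(2), Q = 2
  po <- fixed_effect_pool(c(1, 3), c(1, 1))
  expect_equal(po$pooled_beta, 2)
  expect_equal(po$pooled_se, 1 / sqrt(2))
  expect_equal(po$Q, 2)
  expect_equal(po$df, 1L)
  expect_equal(po$I2, (2 - 1) / 2)
  # duplication law: pooling k copies divides the SE by sqrt(k)
  for (k in c(2, 5, 9)) {
    pk <- fixed_effect_pool(rep(1.7, k), rep(0.4, k))
    expect_equal(pk$pooled_beta, 1.7)
    expect_equal(pk$pooled_se, 0.4 / sqrt(k))
    expect_equal(pk$Q, 0)
    expect_equal(pk$I2, 0)
  }
  # weighting identities on random inputs
  set.seed(42)
  b <- rnorm(6); s <- runif(6, 0.2, 2); w <- 1 / s^2
  pr <- fixed_effect_pool(b, s)
  expect_equal(pr$pooled_beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(pr$pooled_se, sum(w)^-0.5, tolerance = 1e-12)
  expect_equal(pr$Q, sum(w * (b - pr$pooled_beta)^2), tolerance = 1e-12)
  # adding a screen can only tighten the pooled SE
  expect_lt(fixed_effect_pool(c(b, 0), c(s, 1))$pooled_se, pr$pooled_se)
  # infinite-SE records are excluded and tallied
  px <- fixed_effect_pool(c(1, 3, 99), c(1, 1, Inf))
  expect_equal(px$pooled_beta, 2)
  expect_equal(px$n_excluded, 1L)
  expect_null(fixed_effect_pool(1, Inf))
})

test_that("fixed-effect pooling matches metafor", {
  skip_if_not_installed("metafor")
  set.seed(43)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k); s <- runif(k, 0.1, 3)
    ours <- fixed_effect_pool(b, s)
    ref <- suppressWarnings(metafor::rma(yi = b, sei = s, method = "FE"))
    expect_equal(ours$pooled_beta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$pooled_se, ref$se, tolerance = 1e-8)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
    expect_equal(ours$p_meta, ref$pval, tolerance = 1e-8)
  }
})

test_that("pooling across screens joins genes and records coverage", {
  s1 <- data.frame(gene = c("A", "B", "C"), effect = c(1, 2, 3),
                   p = c(0.01, 0.02, 0.03))
  s2 <- data.frame(gene = c("B", "C", "D"), effect = c(2, -3, 1),
                   p = c(0.04, 0.05, 0.06))
  h1 <- harmonize(s1, standardize = FALSE)
  h2 <- harmonize(s2, standardize = FALSE)
  pooled <- pool_screens(list(x = h1, y = h2))
  expect_setequal(pooled$gene, c("A", "B", "C", "D"))
  idx <- match(c("A", "B", "C", "D"), pooled$gene)
  expect_equal(pooled$k[idx], c(1L, 2L, 2L, 1L))
  expect_equal(pooled$coverage[idx], c("x", "x,y", "x,y", "y"))
  # a two-screen gene pools to the weighted mean of its harmonized betas
  b <- c(h1$beta_std[h1$gene == "B"], h2$beta_std[h2$gene == "B"])
  s <- c(h1$se[h1$gene == "B"], h2$se[h2$gene == "B"])
  expect_equal(pooled$pooled_beta[pooled$gene == "B"],
               fixed_effect_pool(b, s)$pooled_beta, tolerance = 1e-12)
  expect_true(all(pooled$q_meta >= pooled$p_meta - 1e-15))
  # a gene with no usable record is skipped and reported
  s3 <- data.frame(gene = "E", effect = 0, p = 0.5)
  pooled2 <- pool_screens(list(x = h1, z = harmonize(s3,
                                                     standardize = FALSE)))
  expect_equal(attr(pooled2, "skipped"), "E")
})

test_that("all screen combinations of size >= 2 are produced", {
  set.seed(44)
  screens <- lapply(1:3, function(i)
    data.frame(gene = paste0("G", 1:50), effect = rnorm(50),
               p = runif(50)))
  names(screens) <- c("s1", "s2", "s3")
  combos <- meta_all_combinations(screens, standardize = FALSE)
  expect_setequal(names(combos), c("s1+s2", "s1+s3", "s2+s3", "s1+s2+s3"))
  # each combination equals pooling that subset directly
  direct <- pool_screens(lapply(screens[c("s1", "s3")], harmonize,
                                standardize = FALSE), c("s1", "s3"))
  expect_equal(combos[["s1+s3"]]$pooled_beta, direct$pooled_beta)
  expect_equal(combos[["s1+s3"]]$q_meta, direct$q_meta)
})

test_that("BH q-values match the brute-force definition", {
  set.seed(45)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
  p <- c(0.01, 0.01, 0.5, 0.5, 1)
  expect_equal(bh_fdr(p), bh_brute_force(p))
  expect_error(bh_fdr(c(0.5, 0)), "p")
})

test_that("novelty requires meta significance and no single-screen call", {
  # genes A-D; A and C are meta-significant and quiet in both screens,
  # B is meta-significant but called by screen s1, D is not meta-significant
  s1 <- data.frame(gene = c("A", "B", "C", "D"), effect = c(1, 3, -1, 1),
                   p = c(0.5, 1e-6, 0.8, 0.9))
  s2 <- data.frame(gene = c("A", "B", "C", "D"), effect = c(1, 3, -1, 1),
                   p = c(0.7, 0.6, 0.9, 0.9))
  meta <- data.frame(gene = c("A", "B", "C", "D"),
                     pooled_beta = c(2, 2, -2, 2),
                     q_meta = c(0.01, 0.01, 0.01, 0.2),
                     coverage = "s1,s2", stringsAsFactors = FALSE)
  nov <- classify_novelty(meta, list(s1 = s1, s2 = s2), q_threshold = 0.05)
  expect_equal(nov$novel, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nov$novelty_direction, c("up", NA, "down", NA))
  expect_true(all(nov$novelty_eligible))
})

test_that("LFC outlier filter applies only to designated screens", {
  s1 <- data.frame(gene = c("A", "B", "C", "D"),
                   effect = c(2.5, 0.3, 0.1, -0.1),
                   p = c(0.5, 0.6, 0.8, 0.9))
  s2 <- data.frame(gene = c("A", "B", "C", "D"), effect = c(0, 0.2, 0, 0),
                   p = c(0.6, 0.7, 0.9, 0.9))
  meta <- data.frame(gene = c("A", "B"), pooled_beta = c(2, 2),
                     q_meta = c(0.01, 0.01), coverage = "s1,s2",
                     stringsAsFactors = FALSE)
  nov_none <- classify_novelty(meta, list(s1 = s1, s2 = s2))
  expect_true(all(nov_none$novel))
  # mean(s1$effect) = 0.7: A passes |2.5 - 0.7| >= 1, B fails |0.3 - 0.7|
  nov_lfc <- classify_novelty(meta, list(s1 = s1, s2 = s2),
                              lfc_screens = "s1")
  expect_equal(nov_lfc$novel, c(TRUE, FALSE))
})

test_that("meta-analysis detects more planted hits than any single screen", {
  cfg <- meta_sim_config(n_screens = 3, n_genes = 1500,
                         shared_hit_count = 80,
                         screen_specific_hit_count = 30,
                         shared_effect = 3, screen_se = 1, seed = 46)
  sim <- simulate_screen_summaries(cfg)
  names(sim$summaries) <- paste0("s", seq_along(sim$summaries))
  pooled <- pool_screens(lapply(sim$summaries, harmonize))
  shared <- sim$truth$gene[sim$truth$class == "shared"]
  single_best <- max(vapply(sim$summaries, function(s)
    sum(bh_fdr(s$p)[match(shared, s$gene)] < 0.05), numeric(1)))
  meta_found <- sum(pooled$q_meta[match(shared, pooled$gene)] < 0.05)
  expect_gte(meta_found, 1.5 * single_best)
  # pooled direction matches the planted sign for detected shared hits
  det <- pooled$gene %in% shared & pooled$q_meta < 0.05
  expect_true(all(pooled$pooled_beta[det] > 0))
})

test_that("hypergeometric enrichment matches choose-ratio closed forms", {
  # 3 draws from an urn of 10 with 5 special, all 3 special:
  # p = C(5,3) C(5,0) / C(10,3) = 10 / 120
  uni <- paste0("G", 1:10)
  res <- hypergeom_enrichment(hits = paste0("G", 1:3),
                              term_genes = list(TERM = paste0("G", 1:5)),
                              universe = uni, n_perm = 0)
  expect_equal(res$p_hyper, 10 / 120, tolerance = 1e-12)
  expect_equal(res$k, 3L)
  # term equal to the universe is never enriched
  res_u <- hypergeom_enrichment(hits = paste0("G", 1:3),
                                term_genes = list(ALL = uni),
                                universe = uni, n_perm = 0)
  expect_equal(res_u$p_hyper, 1, tolerance = 1e-12)
  # phyper cross-check on random instances
  set.seed(47)
  uni <- paste0("G", 1:200)
  for (i in 1:10) {
    term <- sample(uni, 40)
    hits <- sample(uni, 25)
    r <- hypergeom_enrichment(hits, list(T = term), uni, n_perm = 0)
    k <- length(intersect(hits, term))
    expect_equal(r$p_hyper,
                 phyper(k - 1, 40, 160, 25, lower.tail = FALSE) +
                   .Machine$double.xmin,
                 tolerance = 1e-12)
  }
  # empty hit list -> empty table
  expect_equal(nrow(hypergeom_enrichment(character(0), list(T = uni[1:5]),
                                         uni)), 0L)
})

test_that("permutation FDR separates planted from random enrichment", {
  set.seed(48)
  uni <- paste0("G", 1:500)
  sets <- lapply(1:20, function(i) sample(uni, 30))
  names(sets) <- paste0("T", 1:20)
  res <- hypergeom_enrichment(hits = sets$T1[1:20], term_genes = sets,
                              universe = uni, n_perm = 200, seed = 49)
  expect_lt(res$perm_fdr[res$term == "T1"], 0.1)
  expect_true(all(res$perm_fdr >= 0 & res$perm_fdr <= 1))
  # deterministic under the seed
  res2 <- hypergeom_enrichment(hits = sets$T1[1:20], term_genes = sets,
                               universe = uni, n_perm = 200, seed = 49)
  expect_identical(res, res2)
})

test_that("GMT round trip preserves sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc one\tG1\tG2\tG3",
               "SET2\t\tG4"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(SET1 = c("G1", "G2", "G3"), SET2 = "G4"))
  unlink(path)
})
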