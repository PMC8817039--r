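test_that("split_sample halves are disjoint, exhaustive, reproducible", {
  gm10 <- gm_fixture(matrix(rbinom(10 * 3, 2, 0.3), 10, 3))
  s <- split_sample(gm10, seed = 3)
  expect_length(s$a, 5L); expect_length(s$b, 5L)
  expect_length(intersect(s$a, s$b), 0L)
  expect_setequal(c(s$a, s$b), gm10$individuals)
  gm11 <- gm_fixture(matrix(rbinom(11 * 3, 2, 0.3), 11, 3))
  s11 <- split_sample(gm11, seed = 1)
  expect_lte(abs(length(s11$a) - length(s11$b)), 1L)
  expect_identical(split_sample(gm11, seed = 9), split_sample(gm11, seed = 9))
})

test_that("clumping window and r2 semantics", {
  set.seed(14)
  g <- rbinom(800, 2, 0.3)
  noisy <- function(x, k) { i <- sample(800, k); x[i] <- rbinom(k, 2, 0.3); x }
  # two correlated variants 1 kb apart -> smaller p retained
  gm <- gm_fixture(cbind(g, noisy(g, 200)), pos = c(1000L, 2000L))
  expect_equal(clump(gm, gm$variants$id, c(1e-8, 1e-4), r2 = 0.5, kb = 10),
               "v001")
  expect_equal(clump(gm, gm$variants$id, c(1e-4, 1e-8), r2 = 0.5, kb = 10),
               "v002")
  # same correlation but 20,000 kb apart -> both retained
  gm_far <- gm_fixture(cbind(g, g), pos = c(1000L, 2e10))
  expect_length(clump(gm_far, gm_far$variants$id, c(1e-8, 1e-4),
                      r2 = 0.001, kb = 10000), 2L)
})

test_that("clumping post-condition verified by exhaustive re-check", {
  cfg <- sim_config(n_individuals = 500, n_variants = 60, n_ld_blocks = 6,
                    rho = 0.85, seed = 19)
  gm <- simulate_genotypes(cfg)
  set.seed(19)
  pvals <- runif(60)
  kept <- clump(gm, gm$variants$id, pvals, r2 = 0.2, kb = 5)
  idx <- match(kept, gm$variants$id)
  pos <- gm$variants$pos[idx]
  r2m <- cor(gm$dosages[, idx])^2
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i < j && abs(pos[i] - pos[j]) <= 5000)
      expect_lte(r2m[i, j], 0.2)
  }
  # every discarded variant is within window and r2 of some retained one
  # with a smaller p (greedy invariant)
  dropped <- setdiff(seq_len(60), idx)
  for (d in dropped) {
    close_kept <- idx[abs(gm$variants$pos[idx] - gm$variants$pos[d]) <= 5000 &
                        pvals[idx] <= pvals[d]]
    r2d <- cor(gm$dosages[, d], gm$dosages[, close_kept])^2
    expect_gt(max(r2d), 0.2)
  }
})

test_that("IVW equals the Wald ratio for one IV and a WLS oracle for many", {
  one <- iv_fixture(beta_exp = 0.5, beta_out = 0.25, se_out = 0.1)
  res <- mr_ivw(one)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.2)
  # all-null outcome effects -> estimate 0
  null_ <- iv_fixture(beta_exp = c(0.2, 0.4, 0.3), beta_out = rep(0, 3),
                      se_out = 0.1)
  expect_equal(mr_ivw(null_)$estimate, 0)
  # 20 IVs: match an independently coded zero-intercept WLS to 1e-10
  set.seed(23)
  bx <- rnorm(20, 0.3, 0.1)
  sy <- runif(20, 0.02, 0.08)
  by <- 0.3 * bx + rnorm(20, 0, sy)
  iv <- iv_fixture(bx, by, sy)
  res <- mr_ivw(iv)
  w <- 1 / sy^2
  wls_slope <- sum(w * bx * by) / sum(w * bx^2)
  wls_se <- 1 / sqrt(sum(w * bx^2))
  expect_equal(res$estimate, wls_slope, tolerance = 1e-10)
  expect_equal(res$se, wls_se, tolerance = 1e-10)
  expect_lt(abs(res$estimate - 0.3), 0.05)
})

test_that("IVW is invariant under allele-coding flips and drops null IVs", {
  set.seed(24)
  bx <- rnorm(12, 0.4, 0.1); sy <- runif(12, 0.03, 0.06)
  by <- 0.2 * bx + rnorm(12, 0, sy)
  base <- mr_ivw(iv_fixture(bx, by, sy))
  flip <- rep(c(1, -1), 6)
  flipped <- mr_ivw(iv_fixture(bx * flip, by * flip, sy))
  expect_equal(flipped$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(flipped$se, base$se, tolerance = 1e-12)
  expect_warning(res <- mr_ivw(iv_fixture(c(0, 0.5), c(0.1, 0.25), 0.1)),
                 "beta_exp = 0")
  expect_equal(res$n_iv, 1L)
  expect_error(suppressWarnings(mr_ivw(iv_fixture(0, 0.1, 0.1))),
               "no usable")
})

test_that("Egger recovers a planted pleiotropy offset; 2 IVs not estimable", {
  set.seed(25)
  bx <- runif(20, 0.2, 0.6)
  sy <- rep(0.02, 20)
  by <- 0.1 + 0.4 * bx + rnorm(20, 0, sy)
  eg <- mr_egger(iv_fixture(bx, by, sy))
  expect_true(eg$estimable)
  expect_lt(abs(eg$intercept - 0.1), 0.03)
  expect_lt(abs(eg$slope - 0.4), 0.08)
  expect_lt(eg$p_intercept, 0.05)
  two <- mr_egger(iv_fixture(c(0.3, 0.4), c(0.1, 0.2), 0.05))
  expect_false(two$estimable)
  expect_true(is.na(two$slope))
})

test_that("Egger intercept CI covers 0 under no pleiotropy", {
  set.seed(26)
  cover <- vapply(1:200, function(r) {
    bx <- runif(20, 0.2, 0.6)
    sy <- rep(0.03, 20)
    by <- 0.4 * bx + rnorm(20, 0, sy)
    eg <- mr_egger(iv_fixture(bx, by, sy))
    abs(eg$intercept) < qt(0.975, 18) * eg$intercept_se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("weighted median: exact cases and contamination robustness", {
  three <- iv_fixture(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.3, 0.9),
                      se_out = 1)
  expect_equal(mr_weighted_median(three)$estimate, 0.3)
  # weights concentrated on one IV return its ratio
  conc <- iv_fixture(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.3, 0.9),
                     se_out = c(1e4, 1e4, 0.001))
  expect_equal(mr_weighted_median(conc)$estimate, 0.9, tolerance = 1e-6)
  expect_false(mr_weighted_median(iv_fixture(0.3, 0.1, 0.1))$estimable)
  # 30% corrupted IVs: median stays near truth, IVW drifts further
  set.seed(27)
  bx <- runif(30, 0.3, 0.5)
  sy <- rep(0.01, 30)
  by <- 0.3 * bx + rnorm(30, 0, sy)
  bad <- 1:9
  by[bad] <- 1.2 * bx[bad]
  iv <- iv_fixture(bx, by, sy)
  med <- mr_weighted_median(iv)
  ivw <- mr_ivw(iv)
  expect_lt(abs(med$estimate - 0.3), 0.05)
  expect_gt(abs(ivw$estimate - 0.3), abs(med$estimate - 0.3))
  # bootstrap se is seeded
  expect_equal(mr_weighted_median(iv, seed = 5)$se,
               mr_weighted_median(iv, seed = 5)$se)
})

test_that("IVW p-values are calibrated under the global null", {
  set.seed(28)
  pvals <- vapply(1:200, function(r) {
    bx <- rnorm(20, 0.3, 0.05)
    sy <- runif(20, 0.02, 0.05)
    by <- rnorm(20, 0, sy)
    mr_ivw(iv_fixture(bx, by, sy))$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(frac - 0.05), band)
})

test_that("causal map: empty network, untestable pairs, direction calls", {
  empty_net <- build_phenotype_network(
    extract_cpa(run_fixture("v1", "A", 0.5)))
  res <- causal_map(empty_net, NULL, NULL, NULL, NULL)
  expect_equal(nrow(res$results), 0L)
  expect_equal(nrow(res$pairs), 0L)
  # one full pipeline run: chain gives forward, pleiotropy gives none
  coh <- chain_cohort(1)
  cm <- mr_pipeline(coh, seed = 1)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(cm$pairs$direction, "forward")
  fwd <- cm$results[cm$results$exposure == "traitA"]
  expect_lt(abs(fwd$ivw_estimate - 0.5), 0.15)
  cohp <- chain_cohort(1, pleiotropy_only = TRUE)
  cmp_ <- mr_pipeline(cohp, seed = 1)
  expect_equal(cmp_$pairs$direction, "none")
  path <- file.path(tempdir(), "cmap.tsv")
  write_causal_map(cm, path)
  expect_equal(nrow(data.table::fread(path)), 2L)
})

test_that("instrument selection applies the outcome screen and clumping", {
  coh <- chain_cohort(2)
  run_full <- run_phewas(coh$genotypes, coh$phenotypes)
  halves <- split_sample(coh$genotypes, seed = 2)
  run_a <- run_phewas(subset_genotypes(coh$genotypes, halves$a),
                      subset_phenotypes(coh$phenotypes, halves$a))
  run_b <- run_phewas(subset_genotypes(coh$genotypes, halves$b),
                      subset_phenotypes(coh$phenotypes, halves$b))
  iv <- select_instruments("traitA", "traitB", run_full, run_a, run_b,
                           coh$genotypes)
  rec <- run_full$records
  for (v in iv$variant_id) {
    expect_lt(rec[rec$phenotype == "traitA" & rec$variant_id == v]$p, 1e-4)
    expect_gte(rec[rec$phenotype == "traitB" & rec$variant_id == v]$p, 0.01)
  }
  # the large-effect loci that form the network edge are screened out
  big <- sprintf("v%05d", (1:5 - 1) * 3 + 2)
  expect_length(intersect(iv$variant_id, big), 0L)
})
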