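test_that("PCs recover planted population structure and are orthogonal", {
  set.seed(9)
  n <- 1000; m <- 500
  cfg <- sim_config(n_individuals = n, n_variants = m, n_ld_blocks = m,
                    rho = 0, maf_range = c(0.1, 0.4), seed = 9)
  gm <- simulate_genotypes(cfg)
  # plant a two-subpopulation allele-frequency shift on half the variants
  pop <- rep(c(0L, 1L), each = n / 2)
  shift_vars <- seq_len(m / 2)
  d <- gm$dosages
  for (j in shift_vars) {
    p1 <- min(gm$variants$maf[j] + 0.15, 0.95)
    d[pop == 1, j] <- rbinom(n / 2, 2, p1)
  }
  gm2 <- genotype_matrix(d, gm$variants, gm$individuals)
  pcs <- compute_pcs(gm2, k = 3)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])),
            1e-8 * sqrt(sum(pcs[, 1]^2)) * sqrt(sum(pcs[, 2]^2)))
})

test_that("degenerate genotype input is rejected by PCA", {
  gm <- gm_fixture(matrix(1, 10, 4))
  expect_error(compute_pcs(gm, 2), "zero variance")
})

test_that("linear engine p-values match the closed-form t-test", {
  g <- c(0, 0, 1, 1, 2, 2, 1)
  y <- c(0.3, -0.2, 0.5, 1.1, 1.4, 0.9, 0.2)
  gm <- gm_fixture(matrix(g, ncol = 1))
  pt_ <- pt_fixture(data.frame(y = y), c(y = "continuous"))
  run <- run_phewas(gm, pt_, covariates = character())
  # closed form: t = r sqrt(n-2) / sqrt(1 - r^2), two-sided
  r <- cor(g, y)
  t_oracle <- r * sqrt(5) / sqrt(1 - r^2)
  p_oracle <- 2 * pt(-abs(t_oracle), 5)
  expect_equal(run$records$p, p_oracle, tolerance = 1e-10)
  b_oracle <- cov(g, y) / var(g)
  expect_equal(run$records$effect, b_oracle, tolerance = 1e-10)
})

test_that("engine agrees with lm/glm including covariates", {
  set.seed(4)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  age <- sample(35:65, n, TRUE); sex <- rbinom(n, 1, 0.5)
  y <- 0.4 * g + 0.02 * age + 0.3 * sex + rnorm(n)
  yb <- rbinom(n, 1, plogis(-1 + 0.5 * g + 0.2 * sex))
  gm <- gm_fixture(matrix(g, ncol = 1))
  df <- data.frame(y = y, yb = yb, age = age, sex = sex)
  pt_ <- pt_fixture(df, c(y = "continuous", yb = "binary"))
  run <- run_phewas(gm, pt_)
  lin <- summary(lm(y ~ g + age + sex))$coefficients["g", ]
  rl <- run$records[run$records$phenotype == "y"]
  expect_equal(rl$effect, lin[["Estimate"]], tolerance = 1e-10)
  expect_equal(rl$se, lin[["Std. Error"]], tolerance = 1e-10)
  expect_equal(rl$p, lin[["Pr(>|t|)"]], tolerance = 1e-10)
  log_ <- summary(glm(yb ~ g + age + sex, family = binomial()))$coefficients["g", ]
  rb <- run$records[run$records$phenotype == "yb"]
  expect_equal(rb$effect, log_[["Estimate"]], tolerance = 1e-6)
  expect_equal(rb$se, log_[["Std. Error"]], tolerance = 1e-6)
  expect_equal(rb$p, log_[["Pr(>|z|)"]], tolerance = 1e-6)
})

test_that("missing dosages fall back to complete-case fits", {
  set.seed(12)
  n <- 150
  g <- rbinom(n, 2, 0.4); g[sample(n, 20)] <- NA
  y <- 0.5 * ifelse(is.na(g), 0, g) + rnorm(n)
  gm <- gm_fixture(matrix(g, ncol = 1))
  pt_ <- pt_fixture(data.frame(y = y), c(y = "continuous"))
  run <- run_phewas(gm, pt_, covariates = character())
  ok <- !is.na(g)
  ora <- summary(lm(y[ok] ~ g[ok]))$coefficients[2, ]
  expect_equal(run$records$n, sum(ok))
  expect_equal(run$records$effect, ora[["Estimate"]], tolerance = 1e-10)
  expect_equal(run$records$p, ora[["Pr(>|t|)"]], tolerance = 1e-10)
})

test_that("degenerate phenotypes and variants are skipped, separation flagged", {
  set.seed(5)
  n <- 80
  g <- rbinom(n, 2, 0.3)
  df <- data.frame(all_case = rep(1, n),
                   sep = as.integer(g > 0),
                   y = rnorm(n))
  gm <- gm_fixture(cbind(g = g, mono = rep(1, n)), ids = c("vg", "vmono"))
  pt_ <- pt_fixture(df, c(all_case = "binary", sep = "binary",
                          y = "continuous"))
  expect_message(run <- run_phewas(gm, pt_, covariates = character()),
                 "no controls")
  expect_false("all_case" %in% run$records$phenotype)
  expect_equal(unname(run$skipped["degenerate_phenotype"]), 1L)
  expect_gte(unname(run$skipped["monomorphic"]), 2L)
  sep_rec <- run$records[run$records$phenotype == "sep"]
  expect_equal(sep_rec$flag, "separation")
  expect_true(is.na(sep_rec$p))
})

test_that("planted effect is recovered and power grows with effect size", {
  set.seed(21)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  gm <- gm_fixture(matrix(g, ncol = 1))
  pt_ <- pt_fixture(data.frame(y = y), c(y = "continuous"))
  run <- run_phewas(gm, pt_, covariates = character())
  expect_lt(abs(run$records$effect - 0.5), 0.07)

  power_at <- function(beta) {
    hits <- vapply(1:20, function(r) {
      g <- rbinom(300, 2, 0.3)
      y <- beta * g + rnorm(300)
      gmr <- gm_fixture(matrix(g, ncol = 1))
      ptr <- pt_fixture(data.frame(y = y), c(y = "continuous"))
      run_phewas(gmr, ptr, covariates = character())$records$p < 0.05
    }, logical(1))
    mean(hits)
  }
  pw <- vapply(c(0.03, 0.25, 0.7), power_at, numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], pw[1])
})

test_that("permuting phenotype labels destroys planted associations", {
  set.seed(31)
  cfg <- sim_config(n_individuals = 800, n_variants = 500, n_ld_blocks = 100,
                    rho = 0.3, seed = 31,
                    phenotypes = list(
                      phenotype_spec("tr", "continuous", h2 = 0.5,
                                     causal_variants = sprintf("v%05d",
                                                               seq(3, 500, 5)))))
  coh <- simulate_cohort(cfg)
  pt_ <- coh$phenotypes
  bonf <- 0.01 / 500
  hits <- vapply(1:20, function(r) {
    perm <- pt_
    perm$data$tr <- sample(perm$data$tr)
    run <- run_phewas(coh$genotypes, perm, covariates = character())
    min(run$records$p) >= bonf
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("greedy pruning satisfies its post-condition (brute force)", {
  # perfect LD collapses to one variant; independence keeps all
  g <- rbinom(500, 2, 0.4)
  gm_perfect <- gm_fixture(cbind(g, g, g))
  expect_length(ld_prune(gm_perfect, 0.3), 1L)
  set.seed(8)
  gm_indep <- gm_fixture(matrix(rbinom(500 * 5, 2, 0.4), 500, 5))
  expect_length(ld_prune(gm_indep, 0.3), 5L)
  # random 50-variant correlated block: retained pairwise max r^2 <= 0.3
  cfg <- sim_config(n_individuals = 400, n_variants = 50, n_ld_blocks = 5,
                    rho = 0.8, seed = 77)
  gm <- simulate_genotypes(cfg)
  kept <- ld_prune(gm, 0.3, window = 50)
  expect_gt(length(kept), 1L)
  kc <- cor(gm$dosages[, kept])^2
  expect_lte(max(kc[upper.tri(kc)]), 0.3)
  # pruning is deterministic
  expect_identical(kept, ld_prune(gm, 0.3, window = 50))
})

test_that("LD-aware Bonferroni threshold arithmetic", {
  expect_equal(ld_aware_threshold(1, 1), 0.05)
  expect_equal(ld_aware_threshold(100, 10), 5e-5)
  expect_error(ld_aware_threshold(0, 10), ">= 1")
})

test_that("BH adjustment matches hand-computed values", {
  # sorted p (0.01, 0.02, 0.03): q_i = min_{j>=i} p_j * 3 / j = 0.03 each
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.4, 0.04, 1)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})
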