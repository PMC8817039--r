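# Small fixture builders shared across the suite.  Everything is generated
# in code; no binary fixtures.

# genotype matrix from a literal dosage matrix (individuals x variants)
gm_fixture <- function(dosages, chrom = "1", pos = NULL, ids = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  variant_meta <- data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                             ref = "A", alt = "G", maf = NA_real_)
  genotype_matrix(dosages, variant_meta,
                  sprintf("s%03d", seq_len(nrow(dosages))))
}

# phenotype table around given columns; covariates filled with constants
pt_fixture <- function(df, types, categories = NULL) {
  if (is.null(categories))
    categories <- setNames(rep("AM", length(types)), names(types))
  n <- nrow(df)
  if (!"age" %in% names(df)) df$age <- rep(50L, n)
  if (!"sex" %in% names(df)) df$sex <- rep(c(0L, 1L), length.out = n)
  phenotype_table(df, sprintf("s%03d", seq_len(n)), types, categories)
}

# a phewas_run built directly from association fields (bypasses the scan)
run_fixture <- function(variant_id, phenotype, p,
                        effect = 0.1, se = 0.05,
                        exploratory = 1e-4) {
  k <- length(p)
  rec <- association_records(variant_id, phenotype,
                             rep_len(effect, k), rep_len(se, k), p,
                             rep_len(1000L, k), rep_len("linear", k))
  rec$flag <- ""
  structure(list(records = rec,
                 thresholds = list(genomewide = 4.92e-10,
                                   exploratory = exploratory),
                 covariate_names = character(), n_phenotypes = NA_integer_,
                 n_variants = NA_integer_,
                 skipped = c(monomorphic = 0L, degenerate_phenotype = 0L)),
            class = "phewas_run")
}

# gene table with optional coding subintervals given as list of matrices
genes_fixture <- function(symbols, start, end, chrom = "1", strand = "+",
                          coding = NULL) {
  gene_table(symbols, rep_len(chrom, length(symbols)), start, end,
             rep_len(strand, length(symbols)), coding)
}

# instrument set from raw vectors
iv_fixture <- function(beta_exp, beta_out, se_out, se_exp = 0.05) {
  dt <- data.table::data.table(
    variant_id = sprintf("iv%03d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)))
  phewasnet:::as_instruments(dt)
}

# standard small cohort with one planted pleiotropic variant
pleiotropy_cohort <- function(n = 3000, seed = 1, effect = 1.5) {
  vid <- sprintf("v%05d", 25)
  cfg <- sim_config(
    n_individuals = n, n_variants = 50, n_ld_blocks = 10, rho = 0.2,
    maf_range = c(0.2, 0.5), seed = seed,
    phenotypes = list(
      phenotype_spec("traitA", "continuous", "AM", h2 = 0.1,
                     causal_variants = vid, effect_sizes = effect),
      phenotype_spec("traitB", "continuous", "CV", h2 = 0.1,
                     causal_variants = vid, effect_sizes = effect),
      phenotype_spec("traitC", "continuous", "EM", h2 = 0)))
  simulate_cohort(cfg)
}

# Cohort with either a causal chain A -> B (gamma) or pure pleiotropy
# (shared large-effect loci, no phenotype-on-phenotype effect).
# Architecture: 100 independent-ish LD blocks of 3 variants; each trait's
# causal variants sit at block centers.  A few large effects create the
# cross-phenotype network edge (and are then removed by the MR outcome
# screen); many moderate effects provide surviving instruments.
chain_cohort <- function(seed, n = 6000, gamma = 0.5,
                         pleiotropy_only = FALSE) {
  centers <- function(blocks) sprintf("v%05d", (blocks - 1) * 3 + 2)
  a_big <- centers(1:5); a_mod <- centers(6:40)
  b_big <- if (pleiotropy_only) a_big else centers(41:45)
  b_mod <- centers(51:85)
  specA <- phenotype_spec("traitA", "continuous", "AM", h2 = 0.25,
                          causal_variants = c(a_big, a_mod),
                          effect_sizes = c(rep(3, 5), rep(1, 35)))
  specB <- phenotype_spec(
    "traitB", "continuous", "CV", h2 = 0.25,
    causal_variants = c(b_big, b_mod),
    effect_sizes = c(rep(3, 5), rep(1.5, 35)),
    parents = if (pleiotropy_only) numeric() else c(traitA = gamma))
  cfg <- sim_config(n_individuals = n, n_variants = 300, n_ld_blocks = 100,
                    rho = 0.4, maf_range = c(0.15, 0.5), seed = seed,
                    phenotypes = list(specA, specB))
  simulate_cohort(cfg)
}

# Full split-sample MR pipeline on a cohort; returns the causal_map result
mr_pipeline <- function(coh, seed = 1L) {
  run_full <- run_phewas(coh$genotypes, coh$phenotypes)
  halves <- split_sample(coh$genotypes, seed = seed)
  run_a <- run_phewas(subset_genotypes(coh$genotypes, halves$a),
                      subset_phenotypes(coh$phenotypes, halves$a))
  run_b <- run_phewas(subset_genotypes(coh$genotypes, halves$b),
                      subset_phenotypes(coh$phenotypes, halves$b))
  net <- build_phenotype_network(extract_cpa(run_full))
  causal_map(net, run_full, run_a, run_b, coh$genotypes)
}
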