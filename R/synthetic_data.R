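#' Simulation configuration for a synthetic cohort
#'
#' Describes a cohort with known genetic architecture: block-wise LD
#' genotypes in Hardy-Weinberg equilibrium, additive polygenic continuous
#' traits, liability-threshold binary traits, shared (pleiotropic) causal
#' variants, phenotype-on-phenotype causal effects and age/sex covariate
#' effects.  The generator is the ground-truth oracle for every downstream
#' stage.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of bi-allelic variants.
#' @param n_ld_blocks number of mutually independent LD blocks; variants are
#'   split evenly, last block shorter if needed.
#' @param rho target adjacent-variant genotype correlation within a block,
#'   in `[0, 1)`; a vector is recycled across blocks, giving a genome with
#'   heterogeneous LD strength (and hence a spread of LD scores, as real
#'   genomes have).
#' @param maf_range per-variant MAF drawn uniformly from this range.
#' @param phenotypes list of specs from [phenotype_spec()].
#' @param covariate_effects named vector `c(age=, sex=)` added to every
#'   trait's liability/value.
#' @param age_range inclusive integer range ages are drawn from (discrete
#'   uniform).
#' @param sex_prob probability of sex code 1.
#' @param spacing_bp physical spacing between consecutive variants (one
#'   chromosome, positions `spacing_bp * 1:n_variants`).
#' @param seed RNG seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000, n_variants = 1000,
                       n_ld_blocks = 20, rho = 0.8,
                       maf_range = c(0.05, 0.5), phenotypes = list(),
                       covariate_effects = c(age = 0.02, sex = 0.2),
                       age_range = c(35L, 65L), sex_prob = 0.585,
                       spacing_bp = 1000L, seed = 1L) {
  stopifnot(n_individuals >= 2, n_variants >= 1, n_ld_blocks >= 1,
            all(rho >= 0), all(rho < 1),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  names_ <- vapply(phenotypes, `[[`, character(1), "name")
  if (anyDuplicated(names_)) stop("duplicate phenotype names")
  for (sp in phenotypes) {
    bad <- setdiff(names(sp$parents), names_)
    if (length(bad))
      stop("unknown parent phenotype(s) for '", sp$name, "': ",
           paste(bad, collapse = ", "))
  }
  topo_order_phenotypes(phenotypes)  # errors on cycles
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 n_ld_blocks = as.integer(n_ld_blocks), rho = rho,
                 maf_range = maf_range, phenotypes = phenotypes,
                 covariate_effects = covariate_effects,
                 age_range = as.integer(age_range), sex_prob = sex_prob,
                 spacing_bp = as.integer(spacing_bp), seed = as.integer(seed)),
            class = "sim_config")
}

#' Specification of one simulated phenotype
#'
#' @param name phenotype name.
#' @param type `"continuous"` or `"binary"`.
#' @param category two-letter category code.
#' @param h2 target genetic variance fraction in `[0, 1)`; with `h2 = 0`
#'   the trait carries no genetic signal.
#' @param causal_variants variant ids (e.g. `"v000123"`) with direct effects.
#' @param effect_sizes optional per-causal-variant effects on the
#'   standardized-dosage scale; drawn `N(0, 1)` if omitted (the realized
#'   noise scale enforces `h2` either way).
#' @param prevalence case fraction for binary traits (liability threshold at
#'   the `1 - prevalence` quantile).
#' @param parents named numeric vector of causal coefficients `gamma` on
#'   parent phenotypes (phenotype-on-phenotype effects; must be acyclic).
#' @export
phenotype_spec <- function(name, type = c("continuous", "binary"),
                           category = "AM", h2 = 0.2,
                           causal_variants = character(),
                           effect_sizes = NULL, prevalence = 0.2,
                           parents = numeric()) {
  type <- match.arg(type)
  stopifnot(h2 >= 0, h2 < 1)
  if (type == "binary" && (prevalence <= 0 || prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  if (!is.null(effect_sizes) && length(effect_sizes) != length(causal_variants))
    stop("effect_sizes must match causal_variants in length")
  list(name = name, type = type, category = category, h2 = h2,
       causal_variants = as.character(causal_variants),
       effect_sizes = effect_sizes, prevalence = prevalence,
       parents = parents)
}

topo_order_phenotypes <- function(specs) {
  nm <- vapply(specs, `[[`, character(1), "name")
  deps <- lapply(specs, function(sp) names(sp$parents))
  order_ <- character()
  remaining <- nm
  while (length(remaining)) {
    ready <- remaining[vapply(match(remaining, nm), function(i)
      all(deps[[i]] %in% order_), logical(1))]
    if (!length(ready))
      stop("cyclic parent relations among phenotypes: ",
           paste(remaining, collapse = ", "))
    order_ <- c(order_, ready)
    remaining <- setdiff(remaining, ready)
  }
  match(order_, nm)
}

# Bivariate-normal upper-orthant probability P(Z1 > t1, Z2 > t2 | cor = a),
# vectorized over (t1, t2, a) via 40-node Gauss-Legendre quadrature on z1.
binorm_upper <- function(t1, t2, a) {
  k <- 40
  # Legendre nodes/weights on [-1, 1] from the symmetric tridiagonal form
  gl <- gauss_legendre(k)
  hi <- 8.5
  mid <- (hi + t1) / 2; half <- (hi - t1) / 2
  out <- numeric(length(t1))
  s <- sqrt(pmax(1 - a^2, 1e-12))
  for (i in seq_len(k)) {
    z <- mid + half * gl$nodes[i]
    out <- out + gl$weights[i] * stats::dnorm(z) *
      stats::pnorm((a * z - t2) / s)
  }
  out * half
}

gauss_legendre <- function(k) {
  if (!is.null(.phewasnet_cache$gl[[as.character(k)]]))
    return(.phewasnet_cache$gl[[as.character(k)]])
  i <- seq_len(k - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, k)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .phewasnet_cache$gl[[as.character(k)]] <- res
  res
}

.phewasnet_cache <- new.env(parent = emptyenv())
.phewasnet_cache$gl <- list()

# For each adjacent pair, find the latent (haplotype-level) Gaussian
# correlation a such that the thresholded alleles have Pearson correlation
# rho.  Thresholding attenuates correlation, so a >= rho; bisection on the
# orthant probability, vectorized over pairs.
calibrate_latent_rho <- function(p1, p2, rho, iter = 40) {
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  target <- rho * denom + p1 * p2      # required P(both alleles = 1)
  lo <- pmax(rep_len(rho, length(p1)) - 0.02, 0)
  hi <- rep(0.9999, length(p1))
  # cap targets above the Frechet bound (attainable only as a -> 1)
  maxp <- binorm_upper(t1, t2, hi)
  target <- pmin(target, maxp - 1e-9)
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    val <- binorm_upper(t1, t2, mid)
    up <- val < target
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Simulate Hardy-Weinberg genotypes with block-wise LD
#'
#' Two independent haplotypes per individual are generated from a latent
#' first-order autoregressive Gaussian chain per LD block and thresholded at
#' the allele-frequency quantile, which yields HWE genotypes.  The latent
#' autocorrelation of each adjacent pair is calibrated so the realized
#' genotype correlation is `rho`; blocks are mutually independent and
#' correlation decays approximately as `rho^distance` within a block.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] with MAFs recorded in the variant metadata.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals; m <- config$n_variants
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- rep(seq_len(config$n_ld_blocks),
               each = ceiling(m / config$n_ld_blocks))[seq_len(m)]
  block_rho <- rep_len(config$rho, config$n_ld_blocks)
  thr <- qnorm(1 - maf)
  # per-adjacent-pair latent correlation (0 at block boundaries)
  a <- numeric(m); a[1] <- 0
  if (m > 1) {
    idx <- 2:m
    same <- block[idx] == block[idx - 1]
    a[idx][!same] <- 0
    rho_pair <- block_rho[block[idx]]
    w <- idx[same & rho_pair > 0]
    if (length(w))
      a[w] <- calibrate_latent_rho(maf[w - 1], maf[w],
                                   block_rho[block[w]])
  }
  dos <- matrix(0, n, m)
  for (h in 1:2) {
    z_prev <- rnorm(n)
    for (j in seq_len(m)) {
      z <- if (a[j] > 0) a[j] * z_prev + sqrt(1 - a[j]^2) * rnorm(n)
      else rnorm(n)
      dos[, j] <- dos[, j] + (z > thr[j])
      z_prev <- z
    }
  }
  ids <- sprintf("v%05d", seq_len(m))
  vt <- data.table(id = ids, chrom = "1",
                   pos = config$spacing_bp * seq_len(m),
                   ref = "A", alt = "G", maf = maf)
  genotype_matrix(dos, vt, sprintf("ind%05d", seq_len(n)))
}

#' Simulate phenotypes with known causal architecture
#'
#' Continuous traits are built as `sum(beta_i * standardized dosage_i) +
#' sum(gamma_p * parent_p) + covariate terms + Gaussian noise`, with the
#' noise variance scaled so the direct genetic variance fraction (genetic
#' over genetic-plus-noise, excluding covariate and parent contributions)
#' equals the `h2` target.  Binary traits threshold the same liability at
#' its empirical `1 - prevalence` quantile.
#'
#' @param gm a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return A list with elements `phenotypes` (a [phenotype_table()]) and
#'   `truth` (per-phenotype causal sets and effects, phenotype-pair causal
#'   edges and the pleiotropic variant -> phenotype-set map).
#' @export
simulate_phenotypes <- function(gm, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(gm$individuals)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  sex <- rbinom(n, 1, config$sex_prob)
  cov_term <- config$covariate_effects[["age"]] * (age - mean(age)) +
    config$covariate_effects[["sex"]] * sex
  S <- scale(gm$dosages)
  S[, attr(S, "scaled:scale") == 0] <- 0
  data <- data.frame(age = age, sex = sex, row.names = NULL)
  ord <- topo_order_phenotypes(config$phenotypes)
  truth_effects <- list(); causal_edges <- list()
  latent <- list()  # continuous value / liability per phenotype
  for (i in ord) {
    sp <- config$phenotypes[[i]]
    idx <- match(sp$causal_variants, gm$variants$id)
    if (anyNA(idx))
      stop("unknown causal variant id(s) for '", sp$name, "'")
    if (sp$h2 > 0 && length(idx)) {
      beta <- if (is.null(sp$effect_sizes)) rnorm(length(idx))
      else sp$effect_sizes
      g <- as.vector(S[, idx, drop = FALSE] %*% beta)
      vg <- var(g)
      sigma <- sqrt(vg * (1 - sp$h2) / sp$h2)
    } else {
      beta <- numeric(0); idx <- integer(0)
      g <- rep(0, n); sigma <- 1
    }
    parent_term <- rep(0, n)
    for (pnm in names(sp$parents))
      parent_term <- parent_term + sp$parents[[pnm]] * latent[[pnm]]
    y <- g + parent_term + cov_term + rnorm(n, sd = sigma)
    if (sp$type == "binary") {
      cutoff <- quantile(y, 1 - sp$prevalence, type = 1)
      obs <- as.integer(y > cutoff)
    } else obs <- y
    latent[[sp$name]] <- obs  # children act on the observed value
    data[[sp$name]] <- obs
    truth_effects[[sp$name]] <- data.frame(
      variant_id = gm$variants$id[idx],
      effect = beta, stringsAsFactors = FALSE)
    for (pnm in names(sp$parents))
      causal_edges[[length(causal_edges) + 1L]] <-
        data.frame(exposure = pnm, outcome = sp$name,
                   gamma = sp$parents[[pnm]], stringsAsFactors = FALSE)
  }
  nm <- vapply(config$phenotypes, `[[`, character(1), "name")
  types <- setNames(vapply(config$phenotypes, `[[`, character(1), "type"), nm)
  cats <- setNames(vapply(config$phenotypes, `[[`, character(1), "category"),
                   nm)
  pt <- phenotype_table(data, gm$individuals, types, cats)
  # pleiotropy map: variant -> set of phenotypes it directly affects
  all_eff <- do.call(rbind, lapply(names(truth_effects), function(ph) {
    te <- truth_effects[[ph]]
    if (!nrow(te)) return(NULL)
    data.frame(variant_id = te$variant_id, phenotype = ph,
               stringsAsFactors = FALSE)
  }))
  pleio <- if (is.null(all_eff)) list() else {
    sp_ <- split(all_eff$phenotype, all_eff$variant_id)
    Filter(function(x) length(x) >= 2, sp_)
  }
  truth <- structure(list(
    effects = truth_effects,
    causal_edges = if (length(causal_edges)) do.call(rbind, causal_edges)
    else data.frame(exposure = character(), outcome = character(),
                    gamma = numeric()),
    pleiotropy = pleio), class = "ground_truth")
  list(phenotypes = pt, truth = truth)
}

#' One-call synthetic cohort
#' @param config a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  gm <- simulate_genotypes(config)
  ph <- simulate_phenotypes(gm, config)
  list(genotypes = gm, phenotypes = ph$phenotypes, truth = ph$truth)
}
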