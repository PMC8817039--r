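#' Split a cohort into two disjoint halves
#'
#' Random assignment of samples into two equal sets (sizes differ by at
#' most one), used to avoid sample overlap between exposure and outcome
#' summary statistics in Mendelian randomization.
#'
#' @param gm a [genotype_matrix()].
#' @param seed RNG seed; the assignment is reproducible given the seed.
#' @return List with character vectors `a` and `b` of sample ids.
#' @export
split_sample <- function(gm, seed = 1L) {
  ids <- gm$individuals
  if (length(ids) < 2) stop("need at least 2 individuals")
  set.seed(seed)
  na <- ceiling(length(ids) / 2)
  a <- sort(sample(ids, na))
  list(a = a, b = sort(setdiff(ids, a)))
}

#' Subset a genotype matrix by individuals and/or variants
#' @param gm a [genotype_matrix()].
#' @param individuals,variants identifiers to keep (NULL keeps all).
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, individuals = NULL, variants = NULL) {
  ri <- if (is.null(individuals)) seq_along(gm$individuals)
  else match(individuals, gm$individuals)
  cj <- if (is.null(variants)) seq_len(nrow(gm$variants))
  else match(variants, gm$variants$id)
  if (anyNA(ri) || anyNA(cj)) stop("unknown identifiers in subset")
  genotype_matrix(gm$dosages[ri, cj, drop = FALSE],
                  gm$variants[cj, ], gm$individuals[ri])
}

#' Subset a phenotype table by individuals
#' @param pt a [phenotype_table()].
#' @param individuals sample ids to keep.
#' @export
subset_phenotypes <- function(pt, individuals) {
  ri <- match(individuals, pt$individuals)
  if (anyNA(ri)) stop("unknown individuals in subset")
  phenotype_table(pt$data[ri, , drop = FALSE], pt$individuals[ri],
                  pt$types, pt$categories, pt$covariates)
}

#' Greedy LD clumping
#'
#' P-value-ranked index-variant selection: repeatedly retain the variant
#' with the smallest p-value and discard all variants within `kb` kilobases
#' of it whose squared correlation with it exceeds `r2`.
#'
#' @param gm a [genotype_matrix()] providing dosages and positions.
#' @param variant_ids candidate variants.
#' @param p_values p-values aligned with `variant_ids` (ranking).
#' @param r2 squared-correlation cutoff (default 0.001, the strict MR
#'   instrument setting).
#' @param kb distance window in kilobases (default 10000).
#' @return Character vector of retained index variant ids.
#' @export
clump <- function(gm, variant_ids, p_values, r2 = 0.001, kb = 10000) {
  stopifnot(length(variant_ids) == length(p_values))
  if (!length(variant_ids)) return(character(0))
  vj <- match(variant_ids, gm$variants$id)
  if (anyNA(vj)) stop("unknown variant id(s)")
  pos <- gm$variants$pos[vj]
  chrom <- gm$variants$chrom[vj]
  X <- gm$dosages[, vj, drop = FALSE]
  ord <- order(p_values)
  alive <- rep(TRUE, length(vj))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    near <- which(alive & chrom == chrom[i] &
                    abs(pos - pos[i]) <= kb * 1000)
    near <- setdiff(near, i)
    if (length(near)) {
      r <- suppressWarnings(cor(X[, i], X[, near, drop = FALSE],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      alive[near[r^2 > r2]] <- FALSE
    }
    alive[i] <- FALSE
  }
  variant_ids[sort(kept)]
}

#' Assemble an instrument set for one exposure-outcome pair
#'
#' Instrument discovery follows the split-sample hybrid: candidate IVs are
#' variants with exposure p below `iv_p` in the full-sample scan; variants
#' with outcome p below `outcome_p` in the full-sample scan are removed
#' (an IV must not be directly associated with the outcome); survivors are
#' LD-clumped on the exposure p-values.  Effect estimates then come from
#' the half-sample scans: exposure effects from split A, outcome effects
#' from split B.
#'
#' @param exposure,outcome phenotype names.
#' @param run_full,run_a,run_b `phewas_run`s on the full cohort and the two
#'   halves.
#' @param gm genotypes (for clumping LD).
#' @param iv_p exposure selection threshold (default 1e-4).
#' @param outcome_p outcome-association removal threshold (default 0.01).
#' @param clump_r2,clump_kb clumping parameters (defaults 0.001, 10000).
#' @return A `data.table` (class `instrument_set`) with one row per IV:
#'   `variant_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`; zero rows
#'   when no instrument survives.
#' @export
select_instruments <- function(exposure, outcome, run_full, run_a, run_b,
                               gm, iv_p = 1e-4, outcome_p = 0.01,
                               clump_r2 = 0.001, clump_kb = 10000) {
  full <- run_full$records
  exp_hits <- full[phenotype == exposure & !is.na(p) & p < iv_p]
  out_sig <- full[phenotype == outcome & !is.na(p) & p < outcome_p,
                  variant_id]
  exp_hits <- exp_hits[!variant_id %in% out_sig]
  empty <- data.table(variant_id = character(), beta_exp = numeric(),
                      se_exp = numeric(), beta_out = numeric(),
                      se_out = numeric())
  if (!nrow(exp_hits)) return(as_instruments(empty))
  kept <- clump(gm, exp_hits$variant_id, exp_hits$p,
                r2 = clump_r2, kb = clump_kb)
  a <- run_a$records[phenotype == exposure & variant_id %in% kept]
  b <- run_b$records[phenotype == outcome & variant_id %in% kept]
  iv <- merge(a[, .(variant_id, beta_exp = effect, se_exp = se)],
              b[, .(variant_id, beta_out = effect, se_out = se)],
              by = "variant_id")
  iv <- iv[stats::complete.cases(iv)]
  as_instruments(iv)
}

as_instruments <- function(dt) {
  setattr(dt, "class", unique(c("instrument_set", class(dt))))
  dt[]
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effect IVW: the weighted mean of per-IV Wald ratios
#' `beta_out / beta_exp` with weights `(beta_exp / se_out)^2`, equivalent
#' to zero-intercept weighted regression of outcome effects on exposure
#' effects with weights `1 / se_out^2`.  With a single IV this is exactly
#' the Wald ratio with `se = se_out / |beta_exp|`.
#'
#' @param iv an [select_instruments()] table (>= 1 IV).
#' @return List `estimate`, `se`, `p` (two-sided normal), `n_iv`.
#' @export
mr_ivw <- function(iv) {
  iv <- drop_null_exposure(iv)
  if (!nrow(iv)) stop("no usable instruments (all beta_exp = 0)")
  w <- (iv$beta_exp / iv$se_out)^2
  ratio <- iv$beta_out / iv$beta_exp
  est <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)),
       n_iv = nrow(iv))
}

drop_null_exposure <- function(iv) {
  bad <- iv$beta_exp == 0
  if (any(bad))
    warning(sum(bad), " instrument(s) with beta_exp = 0 excluded")
  iv[!bad]
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1 / se_out^2`), after orienting every IV so
#' `beta_exp > 0`.  The intercept measures directional pleiotropy.  With
#' fewer than 3 instruments the result is declared not estimable
#' (`estimable = FALSE`), not an error.
#'
#' @param iv an [select_instruments()] table.
#' @return List `estimable`, `slope`, `slope_se`, `p_slope`, `intercept`,
#'   `intercept_se`, `p_intercept`, `n_iv`.
#' @export
mr_egger <- function(iv) {
  iv <- drop_null_exposure(iv)
  if (nrow(iv) < 3)
    return(list(estimable = FALSE, slope = NA_real_, slope_se = NA_real_,
                p_slope = NA_real_, intercept = NA_real_,
                intercept_se = NA_real_, p_intercept = NA_real_,
                n_iv = nrow(iv)))
  flip <- sign(iv$beta_exp)
  bx <- iv$beta_exp * flip
  by <- iv$beta_out * flip
  w <- 1 / iv$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  list(estimable = TRUE,
       slope = sm["bx", 1], slope_se = sm["bx", 2],
       p_slope = sm["bx", 4],
       intercept = sm["(Intercept)", 1], intercept_se = sm["(Intercept)", 2],
       p_intercept = sm["(Intercept)", 4],
       n_iv = nrow(iv))
}

#' Weighted-median causal estimate
#'
#' The inverse-variance weighted median of the per-IV Wald ratios:
#' consistent when at least half the weight comes from valid instruments.
#' The standard error is a seeded bootstrap over instruments.
#'
#' @param iv an [select_instruments()] table (>= 3 IVs, else not
#'   estimable).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return List `estimable`, `estimate`, `se`, `p`, `n_iv`.
#' @export
mr_weighted_median <- function(iv, n_boot = 1000, seed = 1L) {
  iv <- drop_null_exposure(iv)
  if (nrow(iv) < 3)
    return(list(estimable = FALSE, estimate = NA_real_, se = NA_real_,
                p = NA_real_, n_iv = nrow(iv)))
  ratio <- iv$beta_out / iv$beta_exp
  w <- (iv$beta_exp / iv$se_out)^2
  est <- weighted_median(ratio, w)
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(length(ratio), replace = TRUE)
    weighted_median(ratio[idx], w[idx])
  })
  se <- sd(boot)
  list(estimable = TRUE, estimate = est, se = se,
       p = 2 * pnorm(-abs(est / se)), n_iv = nrow(iv))
}

# weighted median: sort by value, interpolate standardized cumulative
# weights at 1/2
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Network-wide causal inference map
#'
#' Runs Mendelian randomization for both orderings of every edge of the
#' phenotype network, adjusts all IVW p-values jointly by
#' Benjamini-Hochberg, and calls a direction per unordered pair:
#' `forward` if only A->B is significant at `fdr_cutoff`, `reverse` if only
#' B->A, `bidirectional` if both, `none` otherwise.  Pairs with no
#' surviving instruments in a given ordering are recorded as untestable
#' (`n_iv = 0`).
#'
#' @param network a [build_phenotype_network()] graph.
#' @param run_full,run_a,run_b full- and half-sample `phewas_run`s.
#' @param gm genotypes for clumping.
#' @param fdr_cutoff q-value significance cutoff (default 0.05).
#' @param iv_p,outcome_p,clump_r2,clump_kb instrument-selection parameters,
#'   see [select_instruments()].
#' @return List with `results` (one row per ordered test: estimates, q
#'   values, `n_iv`) and `pairs` (one row per unordered pair with
#'   `direction` in forward/reverse/bidirectional/none, orientation `A->B`
#'   with `A < B` alphabetically).
#' @export
causal_map <- function(network, run_full, run_a, run_b, gm,
                       fdr_cutoff = 0.05, iv_p = 1e-4, outcome_p = 0.01,
                       clump_r2 = 0.001, clump_kb = 10000) {
  if (!igraph::ecount(network))
    return(list(results = data.table(), pairs = data.table()))
  ends <- igraph::as_edgelist(network)
  rows <- list()
  for (e in seq_len(nrow(ends))) {
    pair <- sort(ends[e, ])
    for (d in 1:2) {
      expo <- if (d == 1) pair[1] else pair[2]
      outc <- if (d == 1) pair[2] else pair[1]
      iv <- select_instruments(expo, outc, run_full, run_a, run_b, gm,
                               iv_p, outcome_p, clump_r2, clump_kb)
      iv <- iv[iv$beta_exp != 0]
      base <- data.table(exposure = expo, outcome = outc, n_iv = nrow(iv),
                         ivw_estimate = NA_real_, ivw_se = NA_real_,
                         ivw_p = NA_real_, egger_estimate = NA_real_,
                         egger_intercept = NA_real_,
                         egger_p = NA_real_, egger_intercept_p = NA_real_,
                         median_estimate = NA_real_, median_p = NA_real_,
                         untestable = nrow(iv) == 0)
      if (nrow(iv)) {
        ivw <- mr_ivw(iv)
        base[, `:=`(ivw_estimate = ivw$estimate, ivw_se = ivw$se,
                    ivw_p = ivw$p)]
        eg <- mr_egger(iv)
        if (eg$estimable)
          base[, `:=`(egger_estimate = eg$slope, egger_p = eg$p_slope,
                      egger_intercept = eg$intercept,
                      egger_intercept_p = eg$p_intercept)]
        md <- mr_weighted_median(iv, seed = 1L)
        if (md$estimable)
          base[, `:=`(median_estimate = md$estimate, median_p = md$p)]
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  res <- rbindlist(rows)
  tested <- !is.na(res$ivw_p)
  res[, q_value := NA_real_]
  if (any(tested)) res$q_value[tested] <- fdr_adjust(res$ivw_p[tested])
  sig <- !is.na(res$q_value) & res$q_value < fdr_cutoff
  pairs <- unique(res[, .(a = pmin(exposure, outcome),
                          b = pmax(exposure, outcome))])
  dir_call <- function(a, b) {
    fwd <- any(sig & res$exposure == a & res$outcome == b)
    rev_ <- any(sig & res$exposure == b & res$outcome == a)
    if (fwd && rev_) "bidirectional" else if (fwd) "forward"
    else if (rev_) "reverse" else "none"
  }
  pairs[, direction := mapply(dir_call, a, b)]
  list(results = res[], pairs = pairs[])
}

#' Export a causal map as a TSV edge table
#' @param cmap a [causal_map()] result.
#' @param path output path.
#' @export
write_causal_map <- function(cmap, path) {
  fwrite(cmap$results, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
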