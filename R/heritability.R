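#' Windowed LD scores
#'
#' For each variant, `l_j = 1 + sum of r^2` with every other variant within
#' `window_kb` kilobases on the same chromosome (the self term contributes
#' the 1).  Scores are computed in-sample from the analyzed genotypes; use
#' [read_ld_scores()] for externally supplied reference tables.
#'
#' @param gm a [genotype_matrix()].
#' @param window_kb window half-width in kilobases (default 1000).
#' @return A `data.table` (class `ld_score_table`) with `variant_id`,
#'   `chrom`, `pos`, `ld_score` (every score >= 1).
#' @export
compute_ld_scores <- function(gm, window_kb = 1000) {
  X <- gm$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  vj <- colMeans(X^2) - colMeans(X)^2
  Z <- scale(X)
  Z[, vj <= 1e-12] <- 0
  n <- nrow(Z)
  m <- ncol(Z)
  pos <- gm$variants$pos
  chrom <- gm$variants$chrom
  ell <- rep(1, m)
  win <- window_kb * 1000
  chunk <- 256L
  ord <- order(chrom, pos)
  Z <- Z[, ord, drop = FALSE]
  pos_o <- pos[ord]; chrom_o <- chrom[ord]
  ell_o <- rep(1, m)
  for (s in seq(1, m, by = chunk)) {
    e <- min(s + chunk - 1, m)
    # neighbors possibly within window of any chunk member
    lo <- findInterval(pos_o[s] - win, pos_o) # rough bound; refine below
    cand <- which(chrom_o %in% unique(chrom_o[s:e]) &
                    pos_o >= min(pos_o[s:e]) - win &
                    pos_o <= max(pos_o[s:e]) + win)
    R <- crossprod(Z[, s:e, drop = FALSE], Z[, cand, drop = FALSE]) / (n - 1)
    for (j in s:e) {
      within <- chrom_o[cand] == chrom_o[j] &
        abs(pos_o[cand] - pos_o[j]) <= win & cand != j
      ell_o[j] <- 1 + sum(R[j - s + 1, within]^2)
    }
  }
  ell[ord] <- ell_o
  lt <- data.table(variant_id = gm$variants$id, chrom = chrom, pos = pos,
                   ld_score = ell)
  setattr(lt, "class", c("ld_score_table", class(lt)))
  lt[]
}

#' Read an externally supplied LD-score table
#' @param path TSV with columns `variant_id` and `ld_score` (optionally
#'   `chrom`, `pos`).
#' @export
read_ld_scores <- function(path) {
  dt <- fread(path, sep = "\t")
  if (!all(c("variant_id", "ld_score") %in% names(dt)))
    stop("LD-score file needs columns variant_id, ld_score")
  if (any(dt$ld_score < 1)) stop("LD scores must be >= 1")
  setattr(dt, "class", c("ld_score_table", class(dt)))
  dt[]
}

#' Simplified single-component LD-score regression
#'
#' Regresses per-variant association chi-squared statistics on LD scores;
#' under a polygenic model `E[chi2_j] = 1 + N h2 l_j / M`, so
#' `h2 = slope * M / N`.  Weights are the heteroskedasticity weights
#' `1 / (1 + N h2 l_j / M)^2`, iterated twice from an unweighted start.
#' The standard error is a delete-one block jackknife over contiguous
#' variant blocks.  Estimates outside `[0, 1]` are still reported, with
#' `flagged = TRUE`.
#'
#' @param chi2 per-variant chi-squared statistics (`(effect/se)^2` from the
#'   scan), aligned with `ld_scores`.
#' @param ld_scores an [compute_ld_scores()] table (or numeric vector).
#' @param N sample size of the scan.
#' @param M number of variants.
#' @param n_blocks jackknife blocks (default 20; reduced with a warning if
#'   there are fewer variants than blocks).
#' @param phenotype optional label stored on the estimate.
#' @return List (class `h2_estimate`): `phenotype`, `h2`, `se`,
#'   `intercept`, `N`, `M`, `flagged`.
#' @export
ldsc_h2 <- function(chi2, ld_scores, N, M = length(chi2), n_blocks = 20,
                    phenotype = NA_character_) {
  ell <- if (is.numeric(ld_scores)) ld_scores else ld_scores$ld_score
  stopifnot(length(chi2) == length(ell))
  ok <- !is.na(chi2) & !is.na(ell)
  chi2 <- chi2[ok]; ell <- ell[ok]
  m <- length(chi2)
  if (m < 3) stop("need at least 3 variants")
  if (m < n_blocks) {
    warning("fewer variants than jackknife blocks; reducing to ", m)
    n_blocks <- m
  }
  if (max(ell) - min(ell) < 1e-12)
    stop("LD scores are constant; the regression slope is not identifiable")
  fit_wls <- function(keep, w) {
    X <- cbind(1, ell[keep])
    wk <- w[keep]
    XtWX <- crossprod(X * sqrt(wk))
    XtWy <- crossprod(X * wk, chi2[keep])
    drop(solve(XtWX, XtWy))
  }
  all_idx <- rep(TRUE, m)
  w <- rep(1, m)
  co <- fit_wls(all_idx, w)
  for (it in 1:2) {
    h2_cur <- max(co[2] * M / N, 0)
    w <- 1 / (1 + N * h2_cur * ell / M)^2
    co <- fit_wls(all_idx, w)
  }
  h2 <- co[2] * M / N
  blocks <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  jack <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks != b
    fit_wls(keep, w)[2] * M / N
  }, numeric(1))
  B <- n_blocks
  se <- sqrt((B - 1) / B * sum((jack - mean(jack))^2))
  structure(list(phenotype = phenotype, h2 = h2, se = se,
                 intercept = co[1], N = N, M = M,
                 flagged = (h2 < -1e-9 || h2 > 1 + 1e-9)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat("h2 =", format(x$h2, digits = 4), "(se", format(x$se, digits = 3),
      ") intercept", format(x$intercept, digits = 4),
      if (x$flagged) "[outside [0,1], flagged]" else "", "\n")
  invisible(x)
}

#' Per-variant chi-squared statistics from a scan
#' @param run a `phewas_run`.
#' @param phenotype phenotype name.
#' @param variant_ids ordering of the output (default: the run's order).
#' @return Named numeric vector `(effect/se)^2`.
#' @export
association_chi2 <- function(run, phenotype, variant_ids = NULL) {
  rec <- run$records[run$records$phenotype == phenotype]
  chi2 <- setNames((rec$effect / rec$se)^2, rec$variant_id)
  if (!is.null(variant_ids)) chi2 <- chi2[variant_ids]
  chi2
}

#' Correlation between annotation impact and heritability
#'
#' For each phenotype, the fraction of its sub-threshold loci annotated in
#' the `moderate-high` impact group is computed; the Pearson correlation of
#' that fraction with the per-phenotype h2 across phenotypes is returned
#' with a Fisher-z confidence interval.  If the fractions (or h2 values)
#' are constant the correlation is undefined and a degenerate result is
#' returned rather than an error.
#'
#' @param annotations a [map_variants_to_genes()] table.
#' @param h2_by_phenotype named numeric vector phenotype -> h2.
#' @param loci_by_phenotype named list phenotype -> character vector of its
#'   sub-threshold variant ids (each phenotype needs >= 1 locus).
#' @param conf_level CI level (default 0.95).
#' @return List `r`, `ci`, `p`, `n`, `fractions`, `degenerate`.
#' @export
impact_heritability_correlation <- function(annotations, h2_by_phenotype,
                                            loci_by_phenotype,
                                            conf_level = 0.95) {
  phens <- intersect(names(h2_by_phenotype), names(loci_by_phenotype))
  if (length(phens) < 3) stop("need at least 3 phenotypes")
  imp <- setNames(annotations$impact_group, annotations$variant_id)
  frac <- vapply(phens, function(ph) {
    loci <- loci_by_phenotype[[ph]]
    if (!length(loci)) stop("phenotype '", ph, "' has no loci")
    mean(imp[loci] == "moderate-high", na.rm = TRUE)
  }, numeric(1))
  h2 <- h2_by_phenotype[phens]
  if (sd(frac) == 0 || sd(h2) == 0)
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = length(phens), fractions = frac, degenerate = TRUE))
  ct <- cor.test(frac, h2, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(phens), fractions = frac,
       degenerate = FALSE)
}

#' Write h2 estimates as TSV
#' @param estimates list of [ldsc_h2()] results.
#' @param path output path.
#' @export
write_h2_table <- function(estimates, path) {
  dt <- rbindlist(lapply(estimates, function(e)
    data.table(phenotype = e$phenotype, h2 = e$h2, se = e$se,
               intercept = e$intercept, N = e$N, M = e$M,
               flagged = e$flagged)))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
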