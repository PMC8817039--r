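#' Genotype principal components
#'
#' Top-`k` principal-component scores of the column-standardized dosage
#' matrix (missing dosages mean-imputed per variant before standardizing;
#' zero-variance variants excluded with a warning).  Component signs are
#' fixed so each component's largest-magnitude variant loading is positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (default 3, the usual confounder
#'   adjustment set alongside age and sex).
#' @return An `n x k` score matrix (class `pc_scores`), columns `PC1..PCk`.
#' @export
compute_pcs <- function(gm, k = 3) {
  stopifnot(k >= 1)
  X <- gm$dosages
  if (nrow(X) < k + 1) stop("need at least k+1 individuals")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  v <- colMeans(X^2) - colMeans(X)^2
  drop <- v <= 1e-12 | is.na(v)
  if (all(drop)) stop("all variants have zero variance")
  if (any(drop))
    warning(sum(drop), " zero-variance variant(s) excluded from PCA")
  X <- scale(X[, !drop, drop = FALSE])
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    top <- which.max(abs(sv$v[, j]))
    if (sv$v[top, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- gm$individuals
  class(scores) <- c("pc_scores", class(scores))
  scores
}

#' Run the phenome-wide association scan
#'
#' For every (variant, phenotype) pair fits
#' `outcome ~ dosage + covariates (+ PCs)` — linear regression for
#' continuous outcomes, maximum-likelihood logistic regression for binary
#' ones — and records the dosage effect, its standard error and the Wald
#' p-value.  Individuals with a missing outcome, covariate or dosage are
#' dropped per test (complete-case).  Monomorphic variants are skipped;
#' logistic fits with detected separation are flagged and their p set
#' missing; binary phenotypes with no cases (or no controls) after
#' filtering are skipped with a message.
#'
#' @param gm a [genotype_matrix()].
#' @param pt a [phenotype_table()].
#' @param pcs optional [compute_pcs()] score matrix appended to the
#'   covariates.
#' @param model_map optional named override phenotype -> `"linear"` /
#'   `"logistic"`; defaults follow the phenotype type tags.
#' @param covariates covariate column names from `pt` (default its own
#'   covariate set; use `character()` for an unadjusted scan).
#' @param phenotypes,variants optional subsets to scan.
#' @param thresholds list with `genomewide` and `exploratory` p-value
#'   thresholds stored on the run (defaults 4.92e-10 and 1e-4; the
#'   genome-wide one is recomputable via [ld_aware_threshold()]).
#' @return A `phewas_run`: list with `records` ([association_records()]
#'   plus a `flag` column), `thresholds`, `covariate_names`, `n_phenotypes`,
#'   `n_variants`, `skipped` (named counts).
#' @export
run_phewas <- function(gm, pt, pcs = NULL, model_map = NULL,
                       covariates = pt$covariates,
                       phenotypes = phenotype_names(pt),
                       variants = gm$variants$id,
                       thresholds = list(genomewide = 4.92e-10,
                                         exploratory = 1e-4)) {
  stopifnot(thresholds$genomewide <= thresholds$exploratory)
  shared <- intersect(gm$individuals, pt$individuals)
  if (!length(shared)) stop("no shared individuals")
  gi <- match(shared, gm$individuals)
  pi_ <- match(shared, pt$individuals)
  vj <- match(variants, gm$variants$id)
  if (anyNA(vj)) stop("unknown variant id(s)")
  G <- gm$dosages[gi, vj, drop = FALSE]
  C <- cbind(`(Intercept)` = 1,
             as.matrix(pt$data[pi_, covariates, drop = FALSE]))
  if (!is.null(pcs)) {
    pcm <- as.matrix(pcs)
    rows <- if (!is.null(rownames(pcm))) match(shared, rownames(pcm))
    else pi_
    C <- cbind(C, pcm[rows, , drop = FALSE])
  }
  cov_names <- colnames(C)[-1]
  models <- setNames(ifelse(pt$types[phenotypes] == "binary",
                            "logistic", "linear"), phenotypes)
  if (!is.null(model_map)) models[names(model_map)] <- model_map
  skipped <- c(monomorphic = 0L, degenerate_phenotype = 0L)
  out <- vector("list", length(phenotypes))
  for (pidx in seq_along(phenotypes)) {
    ph <- phenotypes[pidx]
    y_all <- pt$data[pi_, ph]
    keep0 <- complete.cases(cbind(y_all, C))
    if (models[ph] == "logistic") {
      tab <- table(factor(y_all[keep0], levels = c(0, 1)))
      if (any(tab == 0)) {
        message("phenotype '", ph, "' skipped: no ",
                if (tab[1] == 0) "controls" else "cases",
                " after complete-case filtering")
        skipped["degenerate_phenotype"] <-
          skipped["degenerate_phenotype"] + 1L
        next
      }
    }
    res <- if (models[ph] == "linear")
      scan_linear(G, y_all, C, keep0) else scan_logistic(G, y_all, C, keep0)
    skipped["monomorphic"] <- skipped["monomorphic"] + res$n_monomorphic
    ok <- !is.na(res$n)
    if (!any(ok)) next
    out[[pidx]] <- data.table(
      variant_id = colnames(G)[ok], phenotype = ph,
      effect = res$beta[ok], se = res$se[ok], p = res$p[ok],
      n = res$n[ok], model = models[[ph]], flag = res$flag[ok])
  }
  records <- rbindlist(out)
  if (nrow(records))
    setattr(records, "class", c("association_records", class(records)))
  structure(list(records = records, thresholds = thresholds,
                 covariate_names = cov_names,
                 n_phenotypes = length(phenotypes),
                 n_variants = length(variants), skipped = skipped),
            class = "phewas_run")
}

#' @export
print.phewas_run <- function(x, ...) {
  cat("phewas_run:", nrow(x$records), "tests over", x$n_variants,
      "variants x", x$n_phenotypes, "phenotypes\n")
  cat("  thresholds: genome-wide", format(x$thresholds$genomewide),
      "/ exploratory", format(x$thresholds$exploratory), "\n")
  invisible(x)
}

# Linear scan.  Fully observed variants go through the Frisch-Waugh fast
# path (residualize y and G on the covariates once, then per-variant simple
# regression on the residuals), which is numerically identical to the full
# OLS fit including the covariates.  Variants with missing dosages fall
# back to a per-variant least-squares fit on their complete cases.
scan_linear <- function(G, y_all, C, keep0) {
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  nvec <- rep(NA_integer_, m)
  flag <- character(m)
  mono <- 0L
  y <- y_all[keep0]; Ck <- C[keep0, , drop = FALSE]
  Gk <- G[keep0, , drop = FALSE]
  has_na <- colSums(is.na(Gk)) > 0
  full <- which(!has_na)
  if (length(full)) {
    qrC <- qr(Ck)
    ry <- qr.resid(qrC, y)
    RG <- qr.resid(qrC, Gk[, full, drop = FALSE])
    gss <- colSums(RG^2)
    # monomorphic (or covariate-collinear) variants have no residual spread
    poly <- gss > 1e-8
    mono <- mono + sum(!poly)
    idx <- full[poly]
    if (length(idx)) {
      gss <- gss[poly]
      bj <- colSums(RG[, poly, drop = FALSE] * ry) / gss
      df <- length(y) - ncol(Ck) - 1
      rss <- sum(ry^2) - bj^2 * gss
      s2 <- rss / df
      sej <- sqrt(s2 / gss)
      tj <- bj / sej
      beta[idx] <- bj; se[idx] <- sej
      p[idx] <- 2 * pt(-abs(tj), df)
      nvec[idx] <- length(y)
    }
  }
  for (j in which(has_na)) {
    ok <- keep0 & !is.na(G[, j])
    g <- G[ok, j]
    if (sd(g) == 0) { mono <- mono + 1L; next }
    fit <- lm.fit(cbind(C[ok, , drop = FALSE], g = g), y_all[ok])
    df <- length(g) - fit$rank
    s2 <- sum(fit$residuals^2) / df
    XtX <- chol2inv(chol(crossprod(cbind(C[ok, , drop = FALSE], g))))
    sej <- sqrt(s2 * XtX[nrow(XtX), nrow(XtX)])
    bj <- fit$coefficients[["g"]]
    beta[j] <- bj; se[j] <- sej
    p[j] <- 2 * pt(-abs(bj / sej), df)
    nvec[j] <- length(g)
  }
  list(beta = beta, se = se, p = p, n = nvec, flag = flag,
       n_monomorphic = mono)
}

scan_logistic <- function(G, y_all, C, keep0) {
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  nvec <- rep(NA_integer_, m)
  flag <- character(m)
  mono <- 0L
  for (j in seq_len(m)) {
    ok <- keep0 & !is.na(G[, j])
    g <- G[ok, j]
    if (length(unique(g)) < 2) { mono <- mono + 1L; next }
    X <- cbind(C[ok, , drop = FALSE], g = g)
    y <- y_all[ok]
    fit <- suppressWarnings(
      glm.fit(X, y, family = stats::binomial(), control = list(maxit = 50)))
    mu <- fit$fitted.values
    sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || !fit$converged
    co <- fit$coefficients[["g"]]
    W <- mu * (1 - mu)
    info <- crossprod(X * sqrt(W))
    sej <- tryCatch(sqrt(chol2inv(chol(info))[ncol(X), ncol(X)]),
                    error = function(e) NA_real_)
    nvec[j] <- length(y)
    beta[j] <- co
    se[j] <- sej
    if (sep || is.na(sej)) {
      flag[j] <- "separation"
      p[j] <- NA_real_
    } else {
      p[j] <- 2 * pnorm(-abs(co / sej))
    }
  }
  list(beta = beta, se = se, p = p, n = nvec, flag = flag,
       n_monomorphic = mono)
}

#' Greedy LD pruning
#'
#' Scans variants in position order; a variant is retained unless its
#' squared Pearson correlation with any already-retained variant among the
#' previous `window` variants exceeds `r2_threshold`.  Deterministic given
#' the input order.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_threshold squared-correlation cutoff in `(0, 1)`; 0.3 is the
#'   East Asian reference value used for the LD-aware Bonferroni
#'   correction.
#' @param window lookback window in variant count (default 500).
#' @return Character vector of retained (independent) variant ids.
#' @export
ld_prune <- function(gm, r2_threshold = 0.3, window = 500) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  m <- nrow(gm$variants)
  if (!m) return(character(0))
  ord <- order(gm$variants$chrom, gm$variants$pos)
  X <- gm$dosages[, ord, drop = FALSE]
  chrom <- gm$variants$chrom[ord]
  keep <- logical(m)
  kept_idx <- integer(0)
  for (j in seq_len(m)) {
    recent <- kept_idx[kept_idx > j - window & chrom[kept_idx] == chrom[j]]
    ok <- TRUE
    if (length(recent)) {
      r <- suppressWarnings(
        cor(X[, j], X[, recent, drop = FALSE],
            use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      ok <- all(r^2 <= r2_threshold)
    }
    if (ok) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  gm$variants$id[ord][keep]
}

#' LD-aware Bonferroni threshold
#'
#' `alpha / (n_independent * n_phenotypes)`: the Bonferroni denominator
#' counts independent SNPs (after LD pruning) times phenotypes rather than
#' all tested SNPs.
#'
#' @param n_independent number of independent variants (post-pruning).
#' @param n_phenotypes number of phenotypes scanned.
#' @param alpha family-wise error rate (default 0.05).
#' @return The genome-wide p-value threshold.
#' @export
ld_aware_threshold <- function(n_independent, n_phenotypes, alpha = 0.05) {
  if (n_independent < 1 || n_phenotypes < 1)
    stop("counts must be >= 1")
  alpha / (n_independent * n_phenotypes)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values; monotone after sorting and
#' `q >= p` elementwise.
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
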