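#' Harmonize variants between two summary-statistics cohorts
#'
#' Matches variants on (chromosome, position, allele set), flipping ref/alt
#' when needed (the flipped cohort-2 effect changes sign).  Strand-ambiguous
#' A/T and C/G variants are dropped by default since a flip cannot be told
#' from a strand difference.
#'
#' @param v1,v2 [variant_table()]s from the two cohorts.
#' @param drop_ambiguous drop A/T and C/G sites (default `TRUE`).
#' @return `data.table` with `id1`, `id2`, `flip` (logical: cohort-2 effect
#'   must be negated).
#' @export
harmonize_variants <- function(v1, v2, drop_ambiguous = TRUE) {
  v1 <- as.data.table(v1); v2 <- as.data.table(v2)
  ambiguous <- function(r, a) (r == "A" & a == "T") | (r == "T" & a == "A") |
    (r == "C" & a == "G") | (r == "G" & a == "C")
  if (drop_ambiguous) {
    v1 <- v1[!ambiguous(ref, alt)]
    v2 <- v2[!ambiguous(ref, alt)]
  }
  m <- merge(v1[, .(id1 = id, chrom, pos, ref1 = ref, alt1 = alt)],
             v2[, .(id2 = id, chrom, pos, ref2 = ref, alt2 = alt)],
             by = c("chrom", "pos"), allow.cartesian = TRUE)
  same <- m$ref1 == m$ref2 & m$alt1 == m$alt2
  flip <- m$ref1 == m$alt2 & m$alt1 == m$ref2
  out <- m[same | flip, .(id1, id2, flip = flip[same | flip])]
  out[]
}

#' Trans-cohort locus-overlap summaries
#'
#' For each matched phenotype, partitions the union of significant loci
#' into cohort-1-only, shared, and cohort-2-only, with the three ratios
#' (percent of the union) summing to 100.
#'
#' @param stats1,stats2 [association_records()] tables with harmonized
#'   variant identifiers.
#' @param p_threshold significance filter (default 1e-4).
#' @param matched_phenotypes named character vector cohort-1 phenotype ->
#'   cohort-2 phenotype (default: identity over shared names).
#' @return `data.table` with per-phenotype counts and ratios; phenotypes
#'   absent from one cohort are skipped with a message.
#' @export
locus_overlap <- function(stats1, stats2, p_threshold = 1e-4,
                          matched_phenotypes = NULL) {
  if (is.null(matched_phenotypes)) {
    shared <- intersect(unique(stats1$phenotype), unique(stats2$phenotype))
    matched_phenotypes <- setNames(shared, shared)
  }
  rows <- list()
  for (ph1 in names(matched_phenotypes)) {
    ph2 <- matched_phenotypes[[ph1]]
    if (!ph1 %in% stats1$phenotype || !ph2 %in% stats2$phenotype) {
      message("phenotype '", ph1, "' absent from one cohort; skipped")
      next
    }
    s1 <- unique(stats1$variant_id[stats1$phenotype == ph1 &
                                     !is.na(stats1$p) &
                                     stats1$p < p_threshold])
    s2 <- unique(stats2$variant_id[stats2$phenotype == ph2 &
                                     !is.na(stats2$p) &
                                     stats2$p < p_threshold])
    shared_n <- length(intersect(s1, s2))
    only1 <- length(setdiff(s1, s2))
    only2 <- length(setdiff(s2, s1))
    tot <- only1 + shared_n + only2
    if (!tot) next
    rows[[length(rows) + 1L]] <- data.table(
      phenotype = ph1, n_only_cohort1 = only1, n_shared = shared_n,
      n_only_cohort2 = only2,
      pct_only_cohort1 = 100 * only1 / tot,
      pct_shared = 100 * shared_n / tot,
      pct_only_cohort2 = 100 * only2 / tot)
  }
  rbindlist(rows)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-cohort effects with weights `1/se^2`:
#' `meta_effect = sum(w * beta) / sum(w)`, `meta_se = 1/sqrt(sum(w))`,
#' two-sided normal p.  Each (variant, phenotype) present in at least two
#' cohorts is combined; a novelty flag compares meta significance with
#' per-cohort significance at `genomewide`.
#'
#' @param stats_list list of [association_records()] tables on a common
#'   allele orientation.
#' @param genomewide significance threshold for the novelty flag
#'   (default 4.92e-10).
#' @return `data.table` with meta effect/se/p, per-cohort minimum p and
#'   `novelty` in `significant-in-meta-only` / `significant-in-single` /
#'   `both` / `neither`.
#' @export
meta_analyze <- function(stats_list, genomewide = 4.92e-10) {
  stopifnot(length(stats_list) >= 2)
  all_ <- rbindlist(lapply(seq_along(stats_list), function(i) {
    s <- stats_list[[i]]
    data.table(variant_id = s$variant_id, phenotype = s$phenotype,
               effect = s$effect, se = s$se, p = s$p, cohort = i)
  }))
  meta <- all_[, {
    w <- 1 / se^2
    me <- sum(w * effect) / sum(w)
    ms <- 1 / sqrt(sum(w))
    .(n_cohorts = .N, meta_effect = me, meta_se = ms,
      meta_p = 2 * pnorm(-abs(me / ms)),
      min_cohort_p = min(p, na.rm = TRUE))
  }, by = .(variant_id, phenotype)]
  meta <- meta[n_cohorts >= 2]
  meta[, novelty := {
    meta_sig <- meta_p < genomewide
    single_sig <- min_cohort_p < genomewide
    ifelse(meta_sig & single_sig, "both",
           ifelse(meta_sig, "significant-in-meta-only",
                  ifelse(single_sig, "significant-in-single", "neither")))
  }]
  meta[]
}

#' Pairwise phenotype association scan of an EHR table
#'
#' Tests every unordered phenotype pair: Pearson correlation for
#' continuous-continuous and mixed (point-biserial) pairs, chi-squared on
#' the 2x2 table for binary-binary pairs.  P-values are adjusted by
#' Benjamini-Hochberg across all tested pairs.
#'
#' @param pt a [phenotype_table()].
#' @param phenotypes phenotypes to test (default all).
#' @return `data.table` with `a`, `b`, `method`, `p`, `q`.
#' @export
ehr_pair_scan <- function(pt, phenotypes = phenotype_names(pt)) {
  prs <- utils::combn(sort(phenotypes), 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    xa <- pt$data[[a]]; xb <- pt$data[[b]]
    ok <- !is.na(xa) & !is.na(xb)
    both_binary <- pt$types[[a]] == "binary" && pt$types[[b]] == "binary"
    if (both_binary) {
      tab <- table(factor(xa[ok], levels = 0:1), factor(xb[ok], levels = 0:1))
      pv <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                     error = function(e) NA_real_)
      method <- "chi-squared"
    } else {
      pv <- if (sd(xa[ok]) == 0 || sd(xb[ok]) == 0) NA_real_
      else cor.test(xa[ok], xb[ok])$p.value
      method <- if (pt$types[[a]] == pt$types[[b]]) "pearson"
      else "point-biserial"
    }
    data.table(a = a, b = b, method = method, p = pv)
  })
  out <- rbindlist(rows)
  out[, q := NA_real_]
  ok <- !is.na(out$p)
  out$q[ok] <- fdr_adjust(pmin(pmax(out$p[ok], .Machine$double.xmin), 1))
  out[]
}

#' Concordance of PheWAS-driven and EHR-driven phenotype pairs
#'
#' PheWAS-driven pairs are the phenotype-network edges (shared
#' sub-threshold loci); EHR-driven pairs are phenotype pairs whose pairwise
#' association survives BH-FDR at `alpha` in an independent (or the same)
#' clinical table.  Both sides are restricted to `shared_phenotypes`.
#' Reports per-phenotype overlap percent (`NA`, not 0, for phenotypes with
#' zero PheWAS pairs), per-category mean percent and the overall percent
#' `100 * |shared pairs| / |PheWAS pairs|`.
#'
#' @param phewas_pairs two-column matrix/data.frame of phenotype pairs, or
#'   a `phenotype_network` graph.
#' @param ehr_pt a [phenotype_table()] scanned via [ehr_pair_scan()], or a
#'   precomputed two-column pair set (then `alpha` is ignored).
#' @param alpha BH-FDR level for the EHR scan (default 0.05).
#' @param shared_phenotypes phenotypes present in both sources (default:
#'   all phenotypes appearing in `phewas_pairs`).
#' @param categories optional named vector phenotype -> category code for
#'   the per-category summary.
#' @return List `per_phenotype`, `per_category`, `overall_percent`,
#'   `n_phewas_pairs`, `n_ehr_pairs`, `n_shared`.
#' @export
ehr_pair_concordance <- function(phewas_pairs, ehr_pt, alpha = 0.05,
                                 shared_phenotypes = NULL,
                                 categories = NULL) {
  pw <- as_pair_keys(phewas_pairs)
  ehr <- if (inherits(ehr_pt, "phenotype_table")) {
    scan <- ehr_pair_scan(ehr_pt)
    hits <- scan[!is.na(scan$q) & scan$q < alpha]
    paste(hits$a, hits$b, sep = "\r")
  } else as_pair_keys(ehr_pt)
  if (is.null(shared_phenotypes))
    shared_phenotypes <- sort(unique(unlist(strsplit(pw, "\r"))))
  keep_pair <- function(keys) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    keys[vapply(parts, function(x) all(x %in% shared_phenotypes),
                logical(1))]
  }
  pw <- unique(keep_pair(pw)); ehr <- unique(keep_pair(ehr))
  if (!length(pw)) stop("no PheWAS pairs among the shared phenotypes")
  shared_pairs <- intersect(pw, ehr)
  per_ph <- rbindlist(lapply(shared_phenotypes, function(ph) {
    mine <- pw[vapply(strsplit(pw, "\r"), function(x) ph %in% x,
                      logical(1))]
    n_mine <- length(mine)
    n_sh <- length(intersect(mine, ehr))
    data.table(phenotype = ph, n_phewas_pairs = n_mine,
               n_shared_with_ehr = n_sh,
               overlap_percent = if (n_mine) 100 * n_sh / n_mine
               else NA_real_,
               category = if (is.null(categories)) NA_character_
               else unname(categories[ph]))
  }))
  per_cat <- if (is.null(categories)) NULL else
    per_ph[!is.na(overlap_percent),
           .(mean_overlap_percent = mean(overlap_percent)), by = category]
  list(per_phenotype = per_ph[], per_category = per_cat,
       overall_percent = 100 * length(shared_pairs) / length(pw),
       n_phewas_pairs = length(pw), n_ehr_pairs = length(ehr),
       n_shared = length(shared_pairs))
}

as_pair_keys <- function(x) {
  if (inherits(x, "igraph")) {
    if (!igraph::ecount(x)) return(character(0))
    em <- igraph::as_edgelist(x)
  } else {
    em <- as.matrix(x)[, 1:2, drop = FALSE]
  }
  unique(paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "\r"))
}
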