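#' @importFrom data.table data.table as.data.table setDT setkey := rbindlist
#'   fread fwrite setattr setnames
#' @importFrom stats cor pnorm pt qnorm quantile rnorm rbinom runif sd var lm coef
#'   p.adjust complete.cases median pchisq cor.test chisq.test binom.test ks.test
#'   integrate uniroot weighted.mean setNames
#' @importFrom utils head tail
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", "variant_id", "phenotype", "p", "effect", "se", "n", "model",
  "gene", "q_value", "exposure", "outcome", "chrom", "pos", "maf", "coding",
  "phenotypes", "genes", "a", "b", "direction", "q", "n_cohorts", "meta_p",
  "min_cohort_p", "novelty", "category", "overlap_percent", "beta_exp",
  "se_exp", "beta_out", "se_out", "id", "ref", "alt", "id1", "id2", "flip"
))

#' Construct a variant table
#'
#' Variants are the unit of analysis of the association scan: one row per
#' bi-allelic site with a stable identifier, 1-based position and REF/ALT
#' alleles.  Minor-allele frequency is optional and may be `NA`.
#'
#' @param id character vector of unique variant identifiers.
#' @param chrom chromosome labels (character).
#' @param pos 1-based positions (integer, `>= 1`).
#' @param ref,alt reference and alternate alleles; must differ row-wise.
#' @param maf optional minor-allele frequencies in `[0, 1]`.
#' @return A `data.table` with class `variant_table`.
#' @export
variant_table <- function(id, chrom, pos, ref, alt, maf = NA_real_) {
  vt <- data.table(id = as.character(id), chrom = as.character(chrom),
                   pos = as.integer(pos), ref = as.character(ref),
                   alt = as.character(alt), maf = as.numeric(maf))
  if (anyDuplicated(vt$id)) stop("duplicate variant ids")
  if (any(vt$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (any(vt$ref == vt$alt)) stop("ref and alt alleles must differ")
  if (any(!is.na(vt$maf) & (vt$maf < 0 | vt$maf > 1)))
    stop("maf must lie in [0, 1]")
  setattr(vt, "class", c("variant_table", class(vt)))
  vt[]
}

#' Construct a genotype matrix
#'
#' An individuals-by-variants additive dosage matrix (counts of the ALT
#' allele, values 0/1/2 or `NA` for missing) plus variant metadata.
#'
#' @param dosages numeric matrix, `n_individuals x n_variants`.
#' @param variants a [variant_table()] (or coercible data.frame) with one row
#'   per column of `dosages`.
#' @param individuals character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.table(variants)
  individuals <- as.character(individuals)
  if (nrow(dosages) != length(individuals))
    stop("dosage rows (", nrow(dosages), ") != individuals (",
         length(individuals), ")")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != variants (",
         nrow(variants), ")")
  if (anyDuplicated(individuals)) stop("duplicate sample identifiers")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be in {0, 1, 2, NA}")
  dimnames(dosages) <- list(individuals, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat("  missingness:", format(miss, digits = 3), "\n")
  invisible(x)
}

#' Per-variant missingness fraction
#' @param gm a `genotype_matrix`.
#' @return named numeric vector, one entry per variant.
#' @export
variant_missingness <- function(gm) colMeans(is.na(gm$dosages))

#' Construct a phenotype table
#'
#' Holds per-individual phenotype values (continuous or binary), the
#' covariates used by the association scan (age in years, sex coded 0/1) and
#' a biological-category code per phenotype (the two-letter system codes,
#' e.g. `AM` anthropometric, `CV` cerebro-cardio-vascular, `EM` endocrine and
#' metabolism).
#'
#' @param data data.frame with one row per individual; must contain every
#'   phenotype column plus the covariate columns.
#' @param individuals sample identifiers aligned with `data` rows.
#' @param types named character vector mapping each phenotype column to
#'   `"continuous"` or `"binary"`.
#' @param categories named character vector mapping each phenotype to its
#'   category code.
#' @param covariates names of covariate columns present in `data`
#'   (default `c("age", "sex")`).
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(data, individuals, types, categories,
                            covariates = c("age", "sex")) {
  data <- as.data.frame(data)
  individuals <- as.character(individuals)
  if (nrow(data) != length(individuals))
    stop("data rows != individuals")
  if (anyDuplicated(individuals)) stop("duplicate sample identifiers")
  phen <- names(types)
  if (is.null(phen) || !length(phen)) stop("`types` must be a named vector")
  missing_cols <- setdiff(c(phen, covariates), names(data))
  if (length(missing_cols))
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  if (!all(types %in% c("continuous", "binary")))
    stop("types must be 'continuous' or 'binary'")
  if (!all(phen %in% names(categories)))
    stop("every phenotype needs a category code")
  for (ph in phen[types == "binary"]) {
    v <- data[[ph]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad))
      stop("binary phenotype '", ph, "' has non-{0,1} values: ",
           paste(unique(v[bad]), collapse = ", "))
  }
  structure(list(data = data, individuals = individuals,
                 types = types[phen], categories = categories[phen],
                 covariates = covariates),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", length(x$individuals), "individuals,",
      length(x$types), "phenotypes (",
      sum(x$types == "continuous"), "continuous /",
      sum(x$types == "binary"), "binary )\n")
  invisible(x)
}

#' Phenotype names of a phenotype table
#' @param pt a `phenotype_table`.
#' @export
phenotype_names <- function(pt) names(pt$types)

#' Query phenotypes by category code
#' @param pt a `phenotype_table`.
#' @param code two-letter category code, e.g. `"AM"`.
#' @return character vector of phenotype names in that category.
#' @export
phenotypes_in_category <- function(pt, code) {
  names(pt$categories)[pt$categories == code]
}

#' Construct a gene-interval table
#'
#' One row per gene with 1-based inclusive coordinates and an optional list
#' of coding subintervals (CDS), each nested within the gene body.
#'
#' @param gene_symbol,chrom,start,end,strand per-gene fields; `strand` is
#'   `"+"` or `"-"`.
#' @param coding optional list (one element per gene) of two-column matrices
#'   of coding (start, end) pairs.
#' @return A `data.table` with class `gene_table` and a `coding` list column.
#' @export
gene_table <- function(gene_symbol, chrom, start, end, strand = "+",
                       coding = NULL) {
  gt <- data.table(gene = as.character(gene_symbol),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(gene_symbol)))
  if (any(gt$start > gt$end)) stop("gene start must be <= end")
  if (!all(gt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(coding)) coding <- rep(list(NULL), nrow(gt))
  if (length(coding) != nrow(gt)) stop("coding list length mismatch")
  none <- matrix(numeric(0), 0, 2)
  coding <- lapply(coding, function(cd) if (is.null(cd)) none else cd)
  for (i in seq_len(nrow(gt))) {
    cd <- coding[[i]]
    if (!is.null(cd) && nrow(cd) &&
        (any(cd[, 1] < gt$start[i]) || any(cd[, 2] > gt$end[i])))
      stop("coding subintervals must be nested within the gene body (",
           gt$gene[i], ")")
  }
  gt[, coding := coding]
  setattr(gt, "class", c("gene_table", class(gt)))
  gt[]
}

#' Construct association records
#'
#' One row per tested (variant, phenotype) pair, carrying the dosage effect
#' (beta or log-odds), its standard error, the Wald p-value and the analysed
#' sample size.
#'
#' @param variant_id,phenotype,effect,se,p,n,model per-record fields;
#'   `model` is `"linear"` or `"logistic"`.
#' @param check_wald if `TRUE`, verify that `p` is consistent with
#'   `effect/se` under the Wald construction (normal reference) to within a
#'   loose floating tolerance.
#' @return A `data.table` with class `association_records`.
#' @export
association_records <- function(variant_id, phenotype, effect, se, p, n,
                                model, check_wald = FALSE) {
  ar <- data.table(variant_id = as.character(variant_id),
                   phenotype = as.character(phenotype),
                   effect = as.numeric(effect), se = as.numeric(se),
                   p = as.numeric(p), n = as.integer(n),
                   model = as.character(model))
  ok <- !is.na(ar$p)
  if (any(ar$se[!is.na(ar$se)] <= 0)) stop("standard errors must be > 0")
  if (any(ar$p[ok] <= 0 | ar$p[ok] > 1)) stop("p-values must lie in (0, 1]")
  if (!all(ar$model %in% c("linear", "logistic")))
    stop("model must be 'linear' or 'logistic'")
  if (check_wald) {
    pw <- 2 * pnorm(-abs(ar$effect / ar$se))
    # normal vs t reference differ at small n; tolerate a generous band
    bad <- ok & abs(log(pmax(pw, 1e-300)) - log(pmax(ar$p, 1e-300))) > 0.5
    if (any(bad))
      stop("p-values inconsistent with Wald effect/se for ",
           sum(bad), " records")
  }
  setattr(ar, "class", c("association_records", class(ar)))
  ar[]
}
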