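#' Read genotypes from VCF, PLINK binary or dosage TSV
#'
#' Dosages are ALT-allele counts under the additive model.  For VCF the GT
#' field is parsed (phased or unphased); multi-allelic sites are handled per
#' `multiallelic`: `"split"` (default) emits one bi-allelic record per ALT
#' allele (id suffixed `_alt<k>`), `"reject"` raises an error naming the
#' site.  Sample order is preserved as stored in the file.
#'
#' @param path input file.
#' @param format one of `"vcf"`, `"plink"` (`path` is the `.bed` file or the
#'   triplet prefix), `"dosage"` (TSV: variant metadata columns then one
#'   column per sample).
#' @param multiallelic `"split"` or `"reject"` (VCF only).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink", "dosage"),
                           multiallelic = c("split", "reject")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  switch(format,
         vcf = read_genotypes_vcf(path, multiallelic),
         plink = read_genotypes_plink(path),
         dosage = read_genotypes_dosage(path))
}

read_genotypes_vcf <- function(path, multiallelic) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alts)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("var", seq_along(rr))
  if (multiallelic == "reject" && any(n_alt > 1))
    stop("multi-allelic site(s) under policy 'reject': ",
         paste(ids[n_alt > 1], collapse = ", "))
  samples <- colnames(gt)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  out_dos <- list(); out_meta <- list()
  for (i in seq_along(ids)) {
    alleles <- as.character(alts[[i]])
    toks <- strsplit(gt[i, ], "[/|]")
    for (k in seq_along(alleles)) {
      dos <- vapply(toks, function(tk) {
        if (any(tk == ".")) return(NA_real_)
        sum(tk == as.character(k))
      }, numeric(1))
      id_k <- if (length(alleles) > 1) paste0(ids[i], "_alt", k) else ids[i]
      out_dos[[length(out_dos) + 1L]] <- dos
      out_meta[[length(out_meta) + 1L]] <-
        data.table(id = id_k, chrom = chrom[i], pos = pos[i],
                   ref = ref[i], alt = alleles[k])
    }
  }
  dosages <- do.call(cbind, out_dos)
  meta <- rbindlist(out_meta)
  meta[, maf := NA_real_]
  genotype_matrix(dosages, meta, samples)
}

read_genotypes_dosage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", na.strings = c("NA", "."))
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt)))
    stop("dosage table must have columns ", paste(need, collapse = ", "))
  samples <- setdiff(names(dt), need)
  dosages <- t(as.matrix(dt[, samples, with = FALSE]))
  genotype_matrix(dosages, dt[, need, with = FALSE], samples)
}

#' Write genotypes to VCF, PLINK binary or dosage TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; for `"plink"` the triplet prefix (`.bed`,
#'   `.bim`, `.fam` are written).
#' @param format output format.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "plink", "dosage")) {
  format <- match.arg(format)
  switch(format,
         vcf = write_genotypes_vcf(gm, path),
         plink = write_genotypes_plink(gm, path),
         dosage = write_genotypes_dosage(gm, path))
  invisible(path)
}

write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  v <- gm$variants
  for (j in seq_len(nrow(v))) {
    d <- gm$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
}

write_genotypes_dosage <- function(gm, path) {
  dt <- as.data.table(gm$variants[, c("id", "chrom", "pos", "ref", "alt")])
  dos <- as.data.table(t(gm$dosages))
  setnames(dos, gm$individuals)
  fwrite(cbind(dt, dos), path, sep = "\t", na = "NA", quote = FALSE)
}

# PLINK .bed: magic 0x6c 0x1b, mode 0x01 (SNP-major); per variant,
# ceil(n/4) bytes, 2 bits per sample LSB-first:
# 00 = hom A1, 10 = het, 11 = hom A2, 01 = missing.
# We write A1 = ALT so that hom A1 <-> dosage 2.
write_genotypes_plink <- function(gm, prefix) {
  v <- gm$variants
  n <- length(gm$individuals)
  fam <- data.table(fid = gm$individuals, iid = gm$individuals,
                    pat = 0L, mat = 0L, sex = 0L, phe = -9L)
  fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE,
         quote = FALSE)
  cm <- rep(0, nrow(v))
  bim <- data.table(chrom = v$chrom, id = v$id, cm = cm, pos = v$pos,
                    a1 = v$alt, a2 = v$ref)
  fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE,
         quote = FALSE)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage -> 2-bit code; NA -> 1
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nbytes <- ceiling(n / 4)
  for (j in seq_len(nrow(v))) {
    d <- gm$dosages[, j]
    bits <- ifelse(is.na(d), 1L, code[as.character(d)])
    bits <- c(bits, rep(0L, nbytes * 4 - n))
    m <- matrix(bits, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("no such file: ", f)
  fam <- fread(paste0(prefix, ".fam"), header = FALSE)
  bim <- fread(paste0(prefix, ".bim"), header = FALSE)
  setnames(bim, c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed supported: ", bed)
  nbytes <- ceiling(n / 4)
  if (length(raw) != 3 + nbytes * m)
    stop("inconsistent .bed size: expected ", 3 + nbytes * m, " bytes, got ",
         length(raw))
  body <- as.integer(raw[-(1:3)])
  # expand each byte to its four 2-bit codes, LSB-first
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  lookup <- c(2, NA, 1, 0)  # code 0..3 -> A1 dosage
  dosages <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    cj <- codes[, ((j - 1) * nbytes + 1):(j * nbytes)]
    dosages[, j] <- lookup[cj[seq_len(n)] + 1L]
  }
  meta <- data.table(id = as.character(bim$id), chrom = as.character(bim$chrom),
                     pos = bim$pos, ref = as.character(bim$a2),
                     alt = as.character(bim$a1), maf = NA_real_)
  genotype_matrix(dosages, meta, as.character(fam$V2))
}

#' Read a phenotype table from TSV
#'
#' @param path tab-separated file with a header row and one row per
#'   individual; must contain an `individual` id column, the covariates and
#'   every phenotype named in `type_map`.
#' @param type_map named character vector phenotype -> `"continuous"` /
#'   `"binary"`.
#' @param category_map named character vector phenotype -> category code.
#' @param covariates covariate column names (default `c("age","sex")`).
#' @param na_strings markers normalized to missing.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, type_map, category_map,
                            covariates = c("age", "sex"),
                            na_strings = c("NA", ".", "-9")) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", na.strings = na_strings)
  if (!"individual" %in% names(dt))
    stop("phenotype file needs an 'individual' column")
  missing_cols <- setdiff(names(type_map), names(dt))
  if (length(missing_cols))
    stop("mapped phenotype column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  phenotype_table(as.data.frame(dt), dt$individual, type_map, category_map,
                  covariates)
}

#' Write a phenotype table to TSV
#' @param pt a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(pt, path) {
  out <- cbind(data.table(individual = pt$individuals),
               as.data.table(pt$data[, c(pt$covariates, names(pt$types))]))
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

summary_stats_header <- c("variant", "phenotype", "effect", "se", "p", "n",
                          "model")

#' Write association records as a summary-statistics TSV
#'
#' Fixed header `variant phenotype effect se p n model`, mirroring the shape
#' of downloadable biobank summary-statistics files.
#'
#' @param records an [association_records()] table (non-empty).
#' @param path output path.
#' @export
write_summary_stats <- function(records, path) {
  if (!nrow(records)) stop("records must be non-empty")
  ok <- !is.na(records$p)
  if (any(records$p[ok] <= 0 | records$p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  out <- data.table(variant = records$variant_id,
                    phenotype = records$phenotype,
                    effect = records$effect, se = records$se, p = records$p,
                    n = records$n, model = records$model)
  ok <- tryCatch({fwrite(out, path, sep = "\t", na = "NA", quote = FALSE); TRUE},
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a summary-statistics TSV
#' @param path file written by [write_summary_stats()] (or any TSV with the
#'   same header).
#' @return An [association_records()] table.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", na.strings = "NA")
  if (!all(summary_stats_header %in% names(dt)))
    stop("summary-statistics file must have header: ",
         paste(summary_stats_header, collapse = " "))
  association_records(dt$variant, dt$phenotype, dt$effect, dt$se, dt$p,
                      dt$n, dt$model)
}

#' Read gene annotations from BED or GFF3
#'
#' Coordinates are converted to the package's internal 1-based inclusive
#' convention (`rtracklayer` already performs the BED 0-based half-open
#' conversion).  For GFF3, `gene` features define gene bodies (symbol from
#' `Name`, falling back to `ID`) and `CDS` features define coding
#' subintervals, attached to their parent gene.
#'
#' @param path `.bed` or `.gff3`/`.gff` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A [gene_table()].
#' @export
read_gene_annotations <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  df <- as.data.frame(gr)
  if (format == "bed") {
    nm <- if ("name" %in% names(df)) df$name else paste0("gene", seq_len(nrow(df)))
    # BED12 thickStart/thickEnd, when present, delimit the coding span
    coding <- rep(list(NULL), nrow(df))
    if (all(c("thick.start", "thick.end") %in% names(df))) {
      for (i in seq_len(nrow(df)))
        if (!is.na(df$thick.start[i]) && df$thick.end[i] >= df$thick.start[i])
          coding[[i]] <- cbind(df$thick.start[i], df$thick.end[i])
    }
    return(gene_table(nm, df$seqnames, df$start, df$end,
                      ifelse(df$strand == "-", "-", "+"), coding))
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no 'gene' features in ", path)
  sym <- if ("Name" %in% names(genes) && !all(is.na(genes$Name)))
    ifelse(is.na(genes$Name), genes$ID, genes$Name) else genes$ID
  cds <- df[df$type == "CDS", , drop = FALSE]
  coding <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- cds[vapply(cds$Parent, function(p) genes$ID[i] %in% unlist(p),
                      logical(1)), , drop = FALSE]
    if (!nrow(hit)) NULL else cbind(hit$start, hit$end)
  })
  gene_table(sym, genes$seqnames, genes$start, genes$end,
             ifelse(genes$strand == "-", "-", "+"), coding)
}

#' Validate a genotype/phenotype pair for analysis
#'
#' Checks that the two containers parse, that sample identifier sets
#' intersect, and reports basic dimensions.  Backs the
#' `phewasnet validate` command-line entry point.
#'
#' @param genotypes path to a genotype file.
#' @param phenotypes path to a phenotype TSV.
#' @param format genotype format passed to [read_genotypes()].
#' @param type_map,category_map phenotype typing maps.
#' @return A list with the parsed objects and the shared sample ids.
#' @export
validate_inputs <- function(genotypes, phenotypes, format = "vcf",
                            type_map, category_map) {
  gm <- read_genotypes(genotypes, format)
  pt <- read_phenotypes(phenotypes, type_map, category_map)
  shared <- intersect(gm$individuals, pt$individuals)
  if (!length(shared))
    stop("no shared sample identifiers between genotypes and phenotypes")
  message(length(shared), " shared individuals, ", nrow(gm$variants),
          " variants, ", length(pt$types), " phenotypes")
  invisible(list(genotypes = gm, phenotypes = pt, shared = shared))
}
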