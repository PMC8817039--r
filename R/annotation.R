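#' Map variants to genes by coordinates
#'
#' A variant is assigned to every gene whose body extended by `flank` bases
#' on both sides (strand-symmetric) contains its position; with
#' `mode = "nearest"` only the closest such gene is kept (ties broken by
#' smaller distance, then lexicographic symbol).  Variants farther than
#' `flank` from every interval are left unassigned; unknown chromosomes are
#' unassigned with a warning.  A variant is classified `coding` iff its
#' position falls inside a coding subinterval of an assigned gene, and the
#' impact group is the two-level surrogate `moderate-high` iff coding, else
#' `modifier-low`; externally computed impact labels can be supplied
#' through `impact_override` when real consequence annotations exist.
#'
#' @param variants a [variant_table()] (or the `variants` table of a
#'   genotype matrix).
#' @param genes a [gene_table()].
#' @param flank window in bp added upstream and downstream (default 5000).
#' @param mode `"all-overlapping"` (default) or `"nearest"`.
#' @param impact_override optional named vector variant id ->
#'   `"modifier-low"` / `"moderate-high"` taking precedence over the
#'   surrogate.
#' @return A `data.table` (class `variant_annotation`) with columns
#'   `variant_id`, `genes` (list column, possibly empty), `region_class`,
#'   `impact_group`.
#' @export
map_variants_to_genes <- function(variants, genes, flank = 5000,
                                  mode = c("all-overlapping", "nearest"),
                                  impact_override = NULL) {
  mode <- match.arg(mode)
  variants <- as.data.table(variants)
  genes <- as.data.table(genes)
  nv <- nrow(variants)
  gene_hits <- vector("list", nv)
  coding <- logical(nv)
  unknown <- setdiff(unique(variants$chrom), unique(genes$chrom))
  if (length(unknown))
    warning("variants on chromosome(s) without gene annotation left ",
            "unassigned: ", paste(unknown, collapse = ", "))
  for (ch in intersect(unique(variants$chrom), unique(genes$chrom))) {
    vi <- which(variants$chrom == ch)
    gi <- which(genes$chrom == ch)
    vr <- IRanges::IRanges(start = variants$pos[vi], width = 1)
    gr <- IRanges::IRanges(start = pmax(genes$start[gi] - flank, 1L),
                           end = genes$end[gi] + flank)
    ov <- IRanges::findOverlaps(vr, gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh)) {
      i <- vi[qh[k]]; g <- gi[sh[k]]
      gene_hits[[i]] <- c(gene_hits[[i]], g)
      cd <- genes$coding[[g]]
      if (!is.null(cd) && nrow(cd) &&
          any(variants$pos[i] >= cd[, 1] & variants$pos[i] <= cd[, 2]))
        coding[i] <- TRUE
    }
  }
  if (mode == "nearest") {
    for (i in which(lengths(gene_hits) > 1)) {
      g <- gene_hits[[i]]
      d <- pmax(genes$start[g] - variants$pos[i],
                variants$pos[i] - genes$end[g], 0L)
      best <- g[order(d, genes$gene[g])][1]
      gene_hits[[i]] <- best
      cd <- genes$coding[[best]]
      coding[i] <- !is.null(cd) && nrow(cd) &&
        any(variants$pos[i] >= cd[, 1] & variants$pos[i] <= cd[, 2])
    }
  }
  syms <- lapply(gene_hits, function(g)
    if (is.null(g)) character(0) else sort(unique(genes$gene[g])))
  ann <- data.table(variant_id = variants$id, genes = syms,
                    region_class = ifelse(coding, "coding", "non-coding"),
                    impact_group = ifelse(coding, "moderate-high",
                                          "modifier-low"))
  if (!is.null(impact_override)) {
    hit <- match(names(impact_override), ann$variant_id)
    ann$impact_group[hit[!is.na(hit)]] <-
      impact_override[!is.na(hit)]
  }
  setattr(ann, "class", c("variant_annotation", class(ann)))
  ann[]
}

#' Fraction of annotated variants in coding regions
#' @param annotations a [map_variants_to_genes()] table (non-empty).
#' @return numeric in `[0, 1]`.
#' @export
coding_fraction <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation set")
  mean(annotations$region_class == "coding")
}

#' Export a variant annotation table as TSV
#' @param annotations annotation table.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.table(variant_id = annotations$variant_id,
                    genes = vapply(annotations$genes, paste,
                                   character(1), collapse = ","),
                    region_class = annotations$region_class,
                    impact_group = annotations$impact_group)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
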