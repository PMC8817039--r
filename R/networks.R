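#' Extract cross-phenotype associations
#'
#' A cross-phenotype association is a variant associated with two or more
#' phenotypes below the exploratory threshold; each carries its gene
#' mapping when annotations are supplied.
#'
#' @param run a `phewas_run`.
#' @param annotations optional [map_variants_to_genes()] table covering the
#'   run's variants.
#' @param p_threshold filter (default: the run's exploratory threshold,
#'   1e-4).
#' @return A `data.table` (class `cpa_table`) with columns `variant_id`,
#'   `phenotypes` (list, `|set| >= 2`), `genes` (list).
#' @export
extract_cpa <- function(run, annotations = NULL,
                        p_threshold = run$thresholds$exploratory) {
  rec <- run$records
  hits <- rec[!is.na(p) & p < p_threshold]
  empty <- data.table(variant_id = character(),
                      phenotypes = list(), genes = list())
  if (!nrow(hits)) return(as_cpa(empty))
  sets <- hits[, .(phenotypes = list(sort(unique(phenotype)))),
               by = variant_id]
  sets <- sets[lengths(phenotypes) >= 2]
  if (!nrow(sets)) return(as_cpa(empty))
  if (!is.null(annotations)) {
    gi <- match(sets$variant_id, annotations$variant_id)
    sets[, genes := lapply(gi, function(i)
      if (is.na(i)) character(0) else annotations$genes[[i]])]
  } else sets[, genes := rep(list(character(0)), .N)]
  as_cpa(sets)
}

as_cpa <- function(dt) {
  setattr(dt, "class", unique(c("cpa_table", class(dt))))
  dt[]
}

#' Build the bipartite phenotype network
#'
#' Projection graph connecting two phenotypes whenever they co-occur in at
#' least one cross-phenotype association (share at least one locus).  Edges
#' carry the deduplicated shared-locus and shared-gene lists; nodes carry
#' the category code and their phenotype degree.
#'
#' @param cpas a [extract_cpa()] table.
#' @param categories optional named vector phenotype -> category code.
#' @return An `igraph` graph (class also `phenotype_network`) with vertex
#'   attributes `category`, `degree` and edge attributes `shared_loci`,
#'   `shared_genes`, `weight` (= number of shared loci).
#' @export
build_phenotype_network <- function(cpas, categories = NULL) {
  edges <- new.env(parent = emptyenv())
  nodes <- character(0)
  for (i in seq_len(nrow(cpas))) {
    phs <- cpas$phenotypes[[i]]
    nodes <- union(nodes, phs)
    if (length(phs) < 2) next
    prs <- utils::combn(sort(phs), 2)
    for (k in seq_len(ncol(prs))) {
      key <- paste(prs[1, k], prs[2, k], sep = "\r")
      cur <- edges[[key]]
      if (is.null(cur))
        cur <- list(loci = character(0), genes = character(0))
      cur$loci <- union(cur$loci, cpas$variant_id[i])
      cur$genes <- union(cur$genes, cpas$genes[[i]])
      edges[[key]] <- cur
    }
  }
  keys <- sort(ls(edges))
  if (length(keys)) {
    em <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
      directed = FALSE, vertices = data.frame(name = sort(nodes)))
    igraph::E(g)$shared_loci <- lapply(keys, function(k)
      sort(edges[[k]]$loci))
    igraph::E(g)$shared_genes <- lapply(keys, function(k)
      sort(edges[[k]]$genes))
    igraph::E(g)$weight <- vapply(keys, function(k)
      length(edges[[k]]$loci), numeric(1))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(sort(nodes))
  }
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$category <- if (is.null(categories)) NA_character_
  else unname(categories[igraph::V(g)$name])
  class(g) <- unique(c("phenotype_network", class(g)))
  g
}

#' Build the bipartite gene network
#'
#' Genes carrying at least one sub-threshold variant become nodes; two
#' genes are connected when they share at least one associated phenotype.
#' Each node carries its `phenotype_degree` (number of phenotypes with a
#' sub-threshold variant mapped to the gene) and `gene_degree` (incident
#' edges in this projection).
#'
#' @param run a `phewas_run`.
#' @param annotations [map_variants_to_genes()] table.
#' @param p_threshold association filter (default exploratory, 1e-4).
#' @return An `igraph` graph (class also `gene_network`).
#' @export
build_gene_network <- function(run, annotations,
                               p_threshold = run$thresholds$exploratory) {
  rec <- run$records[!is.na(p) & p < p_threshold]
  gi <- match(rec$variant_id, annotations$variant_id)
  genes_per_rec <- lapply(gi, function(i)
    if (is.na(i)) character(0) else annotations$genes[[i]])
  n_unmapped <- sum(lengths(genes_per_rec) == 0)
  if (n_unmapped)
    message(n_unmapped, " sub-threshold association(s) on variants with ",
            "no mapped gene contribute no node")
  long <- data.table(
    gene = unlist(genes_per_rec),
    phenotype = rep(rec$phenotype, lengths(genes_per_rec)))
  long <- unique(long)
  if (!nrow(long)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    class(g) <- unique(c("gene_network", class(g)))
    return(g)
  }
  pheno_sets <- split(long$phenotype, long$gene)
  genes <- sort(names(pheno_sets))
  by_pheno <- split(long$gene, long$phenotype)
  ekeys <- unique(unlist(lapply(by_pheno, function(gs) {
    gs <- sort(unique(gs))
    if (length(gs) < 2) return(character(0))
    prs <- utils::combn(gs, 2)
    paste(prs[1, ], prs[2, ], sep = "\r")
  })))
  if (length(ekeys)) {
    em <- do.call(rbind, strsplit(sort(ekeys), "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = em[, 1], to = em[, 2]), directed = FALSE,
      vertices = data.frame(name = genes))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(genes)
  }
  igraph::V(g)$phenotype_degree <-
    lengths(pheno_sets[igraph::V(g)$name])
  igraph::V(g)$gene_degree <- igraph::degree(g)
  class(g) <- unique(c("gene_network", class(g)))
  g
}

#' Partition network neighbors by focus-set membership
#'
#' Every node connected to at least one of the focus phenotypes is assigned
#' to exactly one of the `2^|focus| - 1` non-empty membership classes — the
#' Venn-diagram partition used to compare, e.g., the obesity indices BMI,
#' waist circumference, total and visceral adipose tissue.
#'
#' @param network a [build_phenotype_network()] (or gene network) graph.
#' @param focus character vector of focus node names (at most 6).
#' @return Named list, one element per non-empty membership class (names
#'   like `"A&B"`), each a character vector of nodes connected to exactly
#'   that subset of foci.  Empty list when nothing is connected.
#' @export
phenotype_intersection_sets <- function(network, focus) {
  if (length(focus) > 6)
    stop("more than 6 focus phenotypes refused (combinatorial blowup)")
  miss <- setdiff(focus, igraph::V(network)$name)
  if (length(miss)) stop("focus not in network: ", paste(miss, collapse = ", "))
  nbrs <- lapply(focus, function(f)
    igraph::V(network)$name[igraph::neighbors(network, f)])
  names(nbrs) <- focus
  members <- setdiff(unique(unlist(nbrs)), focus)
  out <- list()
  for (node in members) {
    cls <- focus[vapply(nbrs, function(x) node %in% x, logical(1))]
    key <- paste(cls, collapse = "&")
    out[[key]] <- c(out[[key]], node)
  }
  lapply(out, sort)
}

#' Cross-phenotype map around a core phenotype
#'
#' The star subgraph of a core phenotype and its network neighbors, with
#' shared-locus annotations, grouped by the 13 biological category codes.
#'
#' @param network a [build_phenotype_network()] graph.
#' @param core core phenotype name (must be in the network).
#' @return List with `core`, `branches` (data.table: `phenotype`,
#'   `category`, `shared_loci` list, `n_shared_loci`) and `by_category`
#'   (split of branch phenotypes by category; a partition of the
#'   neighbors).
#' @export
cross_phenotype_map <- function(network, core) {
  if (!core %in% igraph::V(network)$name)
    stop("unknown core phenotype: ", core)
  eids <- igraph::incident(network, core)
  if (!length(eids)) {
    br <- data.table(phenotype = character(), category = character(),
                     shared_loci = list(), n_shared_loci = integer())
    return(list(core = core, branches = br,
                by_category = split(character(0), character(0))))
  }
  ends <- igraph::ends(network, eids)
  nbr <- ifelse(ends[, 1] == core, ends[, 2], ends[, 1])
  loci <- igraph::E(network)$shared_loci[as.integer(eids)]
  cat_ <- igraph::V(network)$category[match(nbr, igraph::V(network)$name)]
  ord <- order(nbr)
  br <- data.table(phenotype = nbr[ord], category = cat_[ord],
                   shared_loci = loci[ord],
                   n_shared_loci = lengths(loci)[ord])
  list(core = core, branches = br,
       by_category = split(br$phenotype, br$category))
}

#' Export a network as GraphML and a TSV edge list
#'
#' List-valued edge attributes (shared loci/genes) are flattened to
#' comma-separated strings for both formats.
#'
#' @param network an igraph network from this package.
#' @param graphml_path,edgelist_path output paths (either may be `NULL`).
#' @export
export_network <- function(network, graphml_path = NULL,
                           edgelist_path = NULL) {
  g <- network
  class(g) <- "igraph"
  for (attr in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, attr)
    if (is.list(v))
      g <- igraph::set_edge_attr(g, attr, value = vapply(
        v, paste, character(1), collapse = ","))
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    if (igraph::ecount(g)) {
      ends <- igraph::as_edgelist(g)
      dt <- data.table(from = ends[, 1], to = ends[, 2])
      for (attr in igraph::edge_attr_names(g))
        dt[[attr]] <- igraph::edge_attr(g, attr)
    } else dt <- data.table(from = character(), to = character())
    fwrite(dt, edgelist_path, sep = "\t", quote = FALSE)
  }
  invisible(network)
}
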