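random_cpa_run <- function(seed, n_variants = 30, n_phen = 8) {
  set.seed(seed)
  phs <- paste0("P", seq_len(n_phen))
  rows <- do.call(rbind, lapply(seq_len(n_variants), function(v) {
    k <- sample(0:4, 1)
    if (!k) return(NULL)
    data.frame(variant_id = sprintf("v%03d", v),
               phenotype = sample(phs, k))
  }))
  run_fixture(rows$variant_id, rows$phenotype,
              p = rep(1e-6, nrow(rows)))
}

test_that("cross-phenotype extraction keeps exactly multi-phenotype variants", {
  run <- run_fixture(c("v1", "v1", "v2", "v3", "v3", "v3"),
                     c("A", "B", "A", "A", "B", "C"),
                     p = c(1e-6, 1e-5, 1e-9, 1e-5, 1e-5, 2e-4))
  cpa <- extract_cpa(run)
  expect_setequal(cpa$variant_id, c("v1", "v3"))
  expect_equal(cpa$phenotypes[[which(cpa$variant_id == "v3")]], c("A", "B"))
  # threshold 0 is a vacuous filter
  expect_equal(nrow(extract_cpa(run, p_threshold = 0)), 0L)
  # gene mappings carried through
  ann <- data.table::data.table(variant_id = c("v1", "v3"),
                                genes = list("GENE1", character(0)),
                                region_class = "non-coding",
                                impact_group = "modifier-low")
  cpa2 <- extract_cpa(run, ann)
  expect_equal(cpa2$genes[[which(cpa2$variant_id == "v1")]], "GENE1")
})

test_that("one cpa over three phenotypes yields a triangle", {
  run <- run_fixture(rep("v1", 3), c("A", "B", "C"), p = rep(1e-6, 3))
  net <- build_phenotype_network(extract_cpa(run))
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 3L)
  expect_equal(unname(igraph::V(net)$degree), rep(2, 3))
  expect_equal(igraph::E(net)$shared_loci[[1]], "v1")
})

test_that("disjoint cpas give disconnected components", {
  run <- run_fixture(c("v1", "v1", "v2", "v2"), c("A", "B", "C", "D"),
                     p = rep(1e-6, 4))
  net <- build_phenotype_network(extract_cpa(run))
  expect_equal(igraph::count_components(net), 2L)
})

test_that("handshake lemma and shuffle-invariance on random fixtures", {
  for (seed in 1:100) {
    run <- random_cpa_run(seed)
    cpa <- extract_cpa(run)
    net <- build_phenotype_network(cpa)
    expect_equal(sum(igraph::V(net)$degree), 2 * igraph::ecount(net))
    shuffled <- cpa[sample(nrow(cpa))]
    net2 <- build_phenotype_network(shuffled)
    e1 <- igraph::as_edgelist(net)
    e2 <- igraph::as_edgelist(net2)
    key <- function(e) sort(paste(pmin(e[, 1], e[, 2]),
                                  pmax(e[, 1], e[, 2])))
    expect_identical(key(e1), key(e2))
  }
})

test_that("recovered phenotype pairs equal planted pleiotropy pairs", {
  recovered <- vapply(1:20, function(seed) {
    coh <- pleiotropy_cohort(n = 2500, seed = seed, effect = 2)
    run <- run_phewas(coh$genotypes, coh$phenotypes)
    net <- build_phenotype_network(extract_cpa(run))
    em <- igraph::as_edgelist(net)
    pairs <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    identical(pairs, "traitA traitB")
  }, logical(1))
  expect_gte(sum(recovered), 18L)
})

test_that("gene network connects genes sharing phenotypes with degrees", {
  run <- run_fixture(c("v1", "v2", "v3", "v3", "v3"),
                     c("A", "A", "A", "B", "C"),
                     p = rep(1e-6, 5))
  ann <- data.table::data.table(
    variant_id = c("v1", "v2", "v3"),
    genes = list("G1", "G2", "G3"),
    region_class = "non-coding", impact_group = "modifier-low")
  gnet <- build_gene_network(run, ann)
  expect_setequal(igraph::V(gnet)$name, c("G1", "G2", "G3"))
  # all three genes share phenotype A -> triangle
  expect_equal(igraph::ecount(gnet), 3L)
  pd <- setNames(igraph::V(gnet)$phenotype_degree, igraph::V(gnet)$name)
  expect_equal(unname(pd["G3"]), 3)
  expect_equal(unname(pd["G1"]), 1)
  expect_equal(sum(igraph::V(gnet)$gene_degree), 2 * igraph::ecount(gnet))
})

test_that("planted hub gene tops the phenotype degree", {
  coh <- pleiotropy_cohort(n = 3000, seed = 3, effect = 2)
  run <- run_phewas(coh$genotypes, coh$phenotypes)
  genes <- genes_fixture(c("HUB", "OTHER"),
                         start = c(24000L, 40000L), end = c(26000L, 42000L))
  ann <- map_variants_to_genes(coh$genotypes$variants, genes)
  gnet <- build_gene_network(run, ann)
  pd <- setNames(igraph::V(gnet)$phenotype_degree, igraph::V(gnet)$name)
  expect_equal(names(which.max(pd)), "HUB")
})

test_that("intersection classes partition connected phenotypes", {
  run <- run_fixture(
    c("v1", "v1", "v2", "v2", "v3", "v3", "v3", "v4", "v4"),
    c("BMI", "X1", "WC", "X2", "VAT", "WC", "X2", "TAT", "X3"),
    p = rep(1e-6, 9))
  net <- build_phenotype_network(extract_cpa(run))
  part <- phenotype_intersection_sets(net, c("BMI", "WC", "VAT", "TAT"))
  expect_equal(part[["BMI"]], "X1")
  expect_setequal(part[["WC&VAT"]], "X2")  # linked to exactly WC and VAT
  expect_equal(part[["TAT"]], "X3")
  # each member appears in exactly one class
  expect_false(anyDuplicated(unlist(part)) > 0)
  expect_error(phenotype_intersection_sets(net, paste0("F", 1:7)), "6")
  # no connections -> empty partition
  iso <- build_phenotype_network(extract_cpa(run_fixture("v9", "Z", 0.5)))
  expect_length(phenotype_intersection_sets(iso, character(0)), 0L)
})

test_that("cross-phenotype map: 27 branches, categories partition them", {
  set.seed(13)
  nbrs <- sprintf("N%02d", 1:27)
  cats <- setNames(c("LS", sample(c("AM", "CV", "DS", "EM"), 27, TRUE)),
                   c("coffee", nbrs))
  run <- run_fixture(rep(sprintf("v%02d", 1:27), each = 2),
                     as.vector(rbind(rep("coffee", 27), nbrs)),
                     p = rep(1e-6, 54))
  net <- build_phenotype_network(extract_cpa(run), categories = cats)
  cmap <- cross_phenotype_map(net, "coffee")
  expect_equal(nrow(cmap$branches), 27L)
  expect_setequal(unlist(cmap$by_category), nbrs)
  expect_false(anyDuplicated(unlist(cmap$by_category)) > 0)
  expect_error(cross_phenotype_map(net, "tea"), "unknown core")
  # isolated phenotype -> empty star
  iso_run <- run_fixture(c("v1", "v1"), c("A", "B"), p = c(1e-6, 1e-6))
  iso_net <- build_phenotype_network(extract_cpa(iso_run))
  iso_net2 <- iso_net + igraph::vertices("lonely")
  class(iso_net2) <- class(iso_net)
  expect_equal(nrow(cross_phenotype_map(iso_net2, "lonely")$branches), 0L)
})

test_that("network export writes GraphML and edge list", {
  run <- run_fixture(c("v1", "v1", "v1"), c("A", "B", "C"), rep(1e-6, 3))
  net <- build_phenotype_network(extract_cpa(run))
  gml <- file.path(tempdir(), "net.graphml")
  tsv <- file.path(tempdir(), "net.tsv")
  export_network(net, gml, tsv)
  expect_true(file.size(gml) > 0)
  el <- data.table::fread(tsv)
  expect_equal(nrow(el), 3L)
  expect_true(all(c("from", "to", "shared_loci", "weight") %in% names(el)))
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(reread), 3)
})
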