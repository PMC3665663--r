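test_that("hypergeometric tails equal exhaustive enumeration for N <= 12", {
  expect_identical(hypergeom_tail(0, 5, 4, 10, "GE"), 1)
  expect_equal(hypergeom_tail(4, 5, 4, 10, "GE"), 5 / 210)
  set.seed(13)
  for (i in 1:40) {
    N <- sample(2:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:n, 1)
    for (tail in c("GE", "LE")) {
      expect_equal(hypergeom_tail(k, K, n, N, tail),
                   oracle_hypergeom_tail(k, K, n, N, tail),
                   info = sprintf("k=%d K=%d n=%d N=%d %s", k, K, n, N, tail))
    }
    ## complementary tails: P(X >= k) + P(X <= k - 1) = 1
    if (k >= 1) {
      expect_equal(hypergeom_tail(k, K, n, N, "GE") +
                     hypergeom_tail(k - 1, K, n, N, "LE"), 1)
    }
  }
  expect_error(hypergeom_tail(5, 3, 4, 2, "GE"), "inconsistent")
})

test_that("class reaction sets union transitively over the ontology", {
  comps <- lapply(c("A", "B"), compound_record)
  rxn <- function(id) reaction_record(id, reaction_participants(
    c("A", "B"), 1L, c("LEFT", "RIGHT")))
  db <- pathway_db("cls",
    compounds = comps,
    reactions = lapply(c("R1", "R2", "R3"), rxn),
    pathways = list(
      pathway_record("P1", "BASE", reaction_ids = c("R1", "R2"), class_ids = "C-LEFT"),
      pathway_record("P2", "BASE", reaction_ids = c("R2", "R3"), class_ids = "C-RIGHT")),
    classes = list(class_node("C-ROOT"),
                   class_node("C-LEFT", parent_ids = "C-ROOT"),
                   class_node("C-RIGHT", parent_ids = "C-ROOT")))
  sets <- class_reaction_sets(db)
  expect_setequal(sets[["C-LEFT"]], c("R1", "R2"))
  expect_setequal(sets[["C-RIGHT"]], c("R2", "R3"))
  ## parent is the union of its children; the shared reaction counts once
  expect_setequal(sets[["C-ROOT"]], c("R1", "R2", "R3"))
  expect_identical(length(sets[["C-ROOT"]]), 3L)
})

enrich_fixture <- function() {
  ## 20 pathway reactions, 10 linked; class ENR holds 6 linked reactions,
  ## class OTH the remaining 14 (4 linked); 2 classes tested
  comps <- lapply(c("A", "B"), compound_record)
  rxn <- function(id) reaction_record(id, reaction_participants(
    c("A", "B"), 1L, c("LEFT", "RIGHT")))
  rids <- sprintf("R%02d", 1:20)
  db <- pathway_db("en",
    compounds = comps,
    reactions = lapply(rids, rxn),
    pathways = list(
      pathway_record("P-ENR", "BASE", reaction_ids = rids[1:6], class_ids = "ENR"),
      pathway_record("P-OTH", "BASE", reaction_ids = rids[7:20], class_ids = "OTH")),
    classes = list(class_node("ENR"), class_node("OTH")))
  links <- data.frame(a_id = rids[1:10], b_id = sprintf("X%02d", 1:10))
  list(db = db, links = links)
}

test_that("enrichment and depletion calls match the enumeration oracle", {
  fx <- enrich_fixture()
  res <- enrichment_depletion(fx$db, fx$links)
  enr <- res[res$class_id == "ENR", ]
  expect_equal(enr$p_enrich, 210 / 38760, tolerance = 1e-12)
  expect_equal(enr$p_enrich, oracle_hypergeom_tail(6, 10, 6, 20, "GE"))
  expect_equal(enr$p_adjusted, 2 * 210 / 38760, tolerance = 1e-12)
  expect_identical(enr$status, "ENRICHED")
  oth <- res[res$class_id == "OTH", ]
  expect_equal(oth$p_deplete, oracle_hypergeom_tail(4, 10, 14, 20, "LE"))
  expect_identical(oth$status, if (min(1, 2 * oth$p_deplete) <= 0.025) "DEPLETED" else "NS")
})

test_that("uniform links yield no significant classes; never both directions", {
  fx <- enrich_fixture()
  ## links spread evenly: each class matches the background rate closely
  even <- data.frame(a_id = sprintf("R%02d", c(1:3, 7:13)),
                     b_id = sprintf("Y%02d", 1:10))
  res <- enrichment_depletion(fx$db, even)
  expect_true(all(res$status == "NS"))
  ## a class can never be simultaneously enriched and depleted: the two
  ## adjusted one-sided tails cannot both fall under alpha < 0.5
  res2 <- enrichment_depletion(fx$db, fx$links, enrichment_config(alpha = 0.4))
  for (i in seq_len(nrow(res2))) {
    expect_false(min(1, 2 * res2$p_enrich[[i]]) <= 0.4 &&
                   min(1, 2 * res2$p_deplete[[i]]) <= 0.4)
  }
})

unique_fixture <- function(n_rxn, covered) {
  comps <- lapply(c("A", "B"), compound_record)
  rxn <- function(id) reaction_record(id, reaction_participants(
    c("A", "B"), 1L, c("LEFT", "RIGHT")))
  rids <- sprintf("R%d", seq_len(n_rxn))
  db <- pathway_db("u", compounds = comps, reactions = lapply(rids, rxn),
                   pathways = list(pathway_record("P", "BASE", reaction_ids = rids)))
  other_ids <- sprintf("Q%d", seq_len(n_rxn))
  other <- pathway_db("o", compounds = comps,
                      reactions = lapply(other_ids, rxn),
                      pathways = list(pathway_record("QP", "BASE",
                                                     reaction_ids = other_ids)))
  links <- if (covered > 0) {
    data.frame(a_id = rids[seq_len(covered)], b_id = other_ids[seq_len(covered)])
  } else {
    NULL
  }
  list(db = db, other = other, links = links)
}

test_that("pathway uniqueness uses the inclusive one-third rule", {
  fx1 <- unique_fixture(4L, 1L) # best other pathway covers 1/4
  expect_true(pathway_unique(fx1$db, "P", fx1$links, fx1$other))
  fx2 <- unique_fixture(4L, 2L) # covers 1/2 > 1/3
  expect_false(pathway_unique(fx2$db, "P", fx2$links, fx2$other))
  fx3 <- unique_fixture(3L, 1L) # exactly 1/3: inclusive boundary
  expect_true(pathway_unique(fx3$db, "P", fx3$links, fx3$other))
  ## monotone: adding links never flips not-unique back to unique
  fx4 <- unique_fixture(4L, 3L)
  expect_false(pathway_unique(fx4$db, "P", fx4$links, fx4$other))
})

test_that("taxon table rolls pathways up the tree and applies the threshold", {
  comps <- lapply(c("A", "B"), compound_record)
  rxn <- function(id) reaction_record(id, reaction_participants(
    c("A", "B"), 1L, c("LEFT", "RIGHT")))
  taxa <- list(taxon_node("1", "root"),
               taxon_node("2", "bacteria", parent_id = "1"),
               taxon_node("3", "proteobacteria", parent_id = "2"))
  pws <- lapply(1:4, function(i) {
    pathway_record(sprintf("P%d", i), "BASE", reaction_ids = sprintf("R%d", i),
                   taxonomic_range = if (i <= 3) "3" else "2")
  })
  db <- pathway_db("tax", compounds = comps,
                   reactions = lapply(sprintf("R%d", 1:4), rxn),
                   pathways = pws, taxa = taxa)
  other <- pathway_db("o2", compounds = comps, reactions = list(rxn("QR")),
                      pathways = list(pathway_record("QP", "BASE", reaction_ids = "QR")))
  cfg <- uniqueness_config(min_taxon_pathways = 1L)
  tab <- taxon_uniqueness_table(db, NULL, other, cfg)
  ## child pathways roll up to every ancestor row
  expect_identical(tab$pathways[tab$taxon_id == "1"], 4L)
  expect_identical(tab$pathways[tab$taxon_id == "2"], 4L)
  expect_identical(tab$pathways[tab$taxon_id == "3"], 3L)
  ## unlinked pathways are all unique; percentage printed to one decimal
  expect_identical(tab$pct_unique[tab$taxon_id == "1"], 100)
  ## taxa under the pathway-count threshold are excluded
  cfg50 <- uniqueness_config(min_taxon_pathways = 5L)
  expect_identical(nrow(taxon_uniqueness_table(db, NULL, other, cfg50)), 0L)
})
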