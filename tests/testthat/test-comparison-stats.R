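test_that("jaccard matches its definition and brute-force set arithmetic", {
  expect_identical(jaccard(10, 10, 10), 1)
  expect_identical(jaccard(5, 7, 0), 0)
  expect_error(jaccard(0, 0, 0), "undefined")
  expect_error(jaccard(3, 3, 4), "common exceeds")
  set.seed(11)
  for (i in 1:30) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    expect_equal(jaccard(length(a), length(b), length(intersect(a, b))),
                 oracle_jaccard_sets(a, b))
  }
})

overlap_fixture <- function() {
  mk <- function(prefix, n) {
    ids <- paste0(prefix, seq_len(n))
    pathway_db(paste0("db", prefix),
               compounds = lapply(ids, compound_record),
               reactions = list(reaction_record(paste0(prefix, "R"),
                 reaction_participants(ids[1:2], 1L, c("LEFT", "RIGHT")))))
  }
  list(a = mk("A", 5L), b = mk("B", 4L))
}

test_that("overlap rows equal hand enumeration on a small fixture", {
  fx <- overlap_fixture()
  cl <- data.frame(a_id = c("A1", "A3"), b_id = c("B1", "B3"))
  rl <- data.frame(a_id = "AR", b_id = "BR")
  tab <- overlap_table(fx$a, fx$b, cl, rl)
  all_cpd <- tab[tab$category == "ALL_COMPOUNDS", ]
  expect_identical(all_cpd$n_a, 5L)
  expect_identical(all_cpd$n_b, 4L)
  expect_identical(all_cpd$common, 2L)
  expect_equal(all_cpd$jaccard, 2 / 7)
  ## substrates: A1, A2 vs B1, B2; only the A1-B1 link lands inside both
  subs <- tab[tab$category == "REACTION_SUBSTRATES", ]
  expect_identical(subs$common, 1L)
  expect_equal(subs$jaccard, 1 / 3)
  rxns <- tab[tab$category == "ALL_REACTIONS", ]
  expect_identical(rxns$common, 1L)
  ## no pathways: empty pathway scopes, zero common
  expect_identical(tab[tab$category == "PATHWAY_REACTIONS", ]$common, 0L)
})

test_that("full-overlap zero-noise twins give jaccard 1 everywhere", {
  twin <- generate_twin_databases(zero_noise_config(seed = 10, n_compounds = 60,
                                                    n_reactions = 22))
  cc <- concordance(twin$db_a, twin$db_b)
  tab <- overlap_table(twin$db_a, twin$db_b,
                       links_of_type(cc$links, "compound"),
                       links_of_type(cc$links, "reaction"))
  for (i in seq_len(nrow(tab))) {
    if (tab$n_a[[i]] > 0L) expect_equal(tab$jaccard[[i]], 1, info = tab$category[[i]])
  }
  ## common never exceeds the number of links
  expect_true(all(tab$common[tab$category %in%
    c("ALL_COMPOUNDS", "REACTION_SUBSTRATES", "PATHWAY_REACTION_SUBSTRATES")] <=
      sum(cc$links$entity_type == "compound")))
})

test_that("attribute coverage applies the minimum-objects threshold", {
  comps <- c(
    lapply(1:99, function(i) compound_record(sprintf("W%03d", i),
      attributes = list(`MONOISOTOPIC-MW` = "1.0"))),
    lapply(1:101, function(i) compound_record(sprintf("X%03d", i),
      attributes = list(`CREATION-DATE` = "2012"))))
  db <- pathway_db("cov", compounds = comps)
  cov100 <- attribute_coverage(db, "compound", min_objects = 100L)
  expect_identical(cov100$attribute, "CREATION-DATE")
  expect_identical(cov100$count, 101L)
  cov1 <- attribute_coverage(db, "compound", min_objects = 1L)
  expect_setequal(cov1$attribute, c("CREATION-DATE", "MONOISOTOPIC-MW"))
  expect_identical(cov1$count[cov1$attribute == "MONOISOTOPIC-MW"], 99L)
})

test_that("summary statistics use the stated denominators", {
  db <- pathway_db("st", compounds = list(
    compound_record("A", synonyms = character()),
    compound_record("B", synonyms = c("b1", "b2"), comment = "abcde")))
  st <- summary_stats(db)
  expect_equal(st$compounds$mean_names, 2)       # (1 + 3) / 2
  expect_equal(st$compounds$mean_comment_length, 5) # commented objects only
  expect_identical(st$compounds$with_comments, 1L)
  ## empty database: means reported as absent
  st0 <- summary_stats(pathway_db("empty"))
  expect_true(is.na(st0$compounds$mean_names))
  expect_true(is.na(st0$pathways$base$reactions_per_pathway))
})

test_that("pathway size histograms bin sizes and honour exclusions", {
  db <- tiny_db()
  comps <- db$compounds
  rxns <- db$reactions
  pws <- list(
    pathway_record("P1", "BASE", reaction_ids = "R-GLYC"),
    pathway_record("P2", "BASE", reaction_ids = "R-PYR"),
    pathway_record("P3", "BASE", reaction_ids = c("R-GLYC", "R-WATER")))
  db2 <- pathway_db("h", compounds = comps, reactions = rxns, pathways = pws)
  h <- pathway_size_histogram(db2, "BASE")
  expect_identical(h$count[h$bin_start == 1L], 2L)
  expect_identical(h$count[h$bin_start == 2L], 1L)
  h2 <- pathway_size_histogram(db2, "BASE", exclude = "P3")
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$count, 2L)
  expect_warning(pathway_size_histogram(db2, "BASE", exclude = "NOPE"),
                 "not found")
  ## fraction of single-reaction pathways from the bins equals the hand count
  expect_equal(h$count[h$bin_start == 1L] / sum(h$count), 2 / 3)
})

test_that("link coverage partitions pathways into all/some/none", {
  db <- tiny_db()
  pws <- list(
    pathway_record("P1", "BASE", reaction_ids = "R-GLYC"),
    pathway_record("P2", "BASE", reaction_ids = c("R-GLYC", "R-PYR", "R-WATER")),
    pathway_record("P3", "BASE", reaction_ids = "R-WATER"))
  db2 <- pathway_db("c", compounds = db$compounds, reactions = db$reactions,
                    pathways = pws)
  links <- data.frame(a_id = "R-GLYC", b_id = "OTHER-R")
  cov <- pathway_link_coverage(db2, links, "BASE", side = "a")
  expect_identical(cov$classification[["P1"]], "ALL")
  expect_identical(cov$classification[["P2"]], "SOME")
  expect_identical(cov$classification[["P3"]], "NONE")
  expect_identical(sum(cov$counts), 3L)
  expect_identical(cov$unlinked_reaction_count, 2L) # R-PYR, R-WATER
  ## no links at all: everything NONE
  cov0 <- pathway_link_coverage(db2, NULL, "BASE", side = "a")
  expect_identical(unname(cov0$counts), c(0L, 0L, 3L))
})

test_that("reports are complete and byte-deterministic", {
  twin <- generate_twin_databases(generator_config(seed = 33, n_compounds = 70,
                                                   n_reactions = 26))
  cc <- concordance(twin$db_a, twin$db_b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_report(twin$db_a, twin$db_b, cc$links, d1, min_objects = 10L)
  generate_report(twin$db_a, twin$db_b, cc$links, d2, min_objects = 10L)
  expect_setequal(list.files(d1),
                  c("overlap.tsv", "attributes_a.tsv", "attributes_b.tsv",
                    "quality.tsv", "pathway_sizes_a.tsv", "pathway_sizes_b.tsv",
                    "coverage.tsv", "summary.md"))
  expect_true(dirs_identical(d1, d2))
})

test_that("report ratio lines follow the pathway counts", {
  mkpwys <- function(n, prefix) lapply(seq_len(n), function(i) {
    pathway_record(sprintf("%s-%02d", prefix, i), "BASE", reaction_ids = "R")
  })
  mk <- function(name, n_pwy) {
    pathway_db(name,
               compounds = list(compound_record("A"), compound_record("B")),
               reactions = list(reaction_record("R", reaction_participants(
                 c("A", "B"), 1L, c("LEFT", "RIGHT")))),
               pathways = mkpwys(n_pwy, toupper(name)))
  }
  d <- withr::local_tempdir()
  generate_report(mk("a", 20L), mk("b", 2L), correspondence_set(), d)
  md <- readLines(file.path(d, "summary.md"))
  expect_true(any(grepl("Base pathways: 20 vs 2 \\(ratio 10\\.0\\)", md)))
})
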