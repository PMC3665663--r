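stoich_fixture <- function() {
  mk <- function(prefix) {
    ids <- paste0(prefix, c("A", "B", "C"))
    pathway_db(paste0("db", prefix),
               compounds = lapply(ids, function(id) cpd(id, name = tolower(id))),
               reactions = list(
                 reaction_record(paste0(prefix, "R1"), reaction_participants(
                   ids, 1L, c("LEFT", "LEFT", "RIGHT")),
                   ec_numbers = "1.2.3.4", uniprot_accessions = "P00001",
                   activity_names = "Alcohol dehydrogenase."),
                 reaction_record(paste0(prefix, "R2"), reaction_participants(
                   c(ids[[1L]], ids[[3L]]), 1L, c("LEFT", "RIGHT")))))
  }
  list(a = mk("M"), b = mk("K"),
       links = data.frame(a_id = c("MA", "MB", "MC"), b_id = c("KA", "KB", "KC")))
}

test_that("stoichiometric columns follow the sign and coefficient conventions", {
  db <- pathway_db("s", compounds = lapply(c("A", "B"), compound_record),
                   reactions = list(reaction_record("R", reaction_participants(
                     c("A", "B"), c(2L, 1L), c("LEFT", "RIGHT")))))
  empty <- pathway_db("e")
  S <- build_stoich_matrix(db, empty, NULL)
  col <- S$matrix[, "a:R"]
  expect_identical(col[["a:A"]], -2)
  expect_identical(col[["a:B"]], 1)
})

test_that("linked compounds share rows; unlinked databases have zero cosines", {
  fx <- stoich_fixture()
  S <- build_stoich_matrix(fx$a, fx$b, fx$links)
  u <- S$matrix[, "a:MR1"]; v <- S$matrix[, "b:KR1"]
  expect_equal(cosine_similarity(as.numeric(u), as.numeric(v)), 1)
  ## with no links, supports are disjoint
  S0 <- build_stoich_matrix(fx$a, fx$b, NULL)
  expect_identical(cosine_similarity(as.numeric(S0$matrix[, "a:MR1"]),
                                     as.numeric(S0$matrix[, "b:KR1"])), 0)
  expect_error(build_stoich_matrix(fx$a, fx$b,
                                   data.frame(a_id = "NOPE", b_id = "KA")),
               "unknown")
})

test_that("cosine similarity matches hand arithmetic", {
  expect_equal(cosine_similarity(c(-1, -1, 1), c(-1, -1, 1)), 1)
  expect_equal(cosine_similarity(c(-1, -1, 1), c(1, 1, -1)), -1)
  expect_equal(cosine_similarity(c(-1, -1, 1), c(-1, 0, 1)), 2 / sqrt(6))
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 1))))
  set.seed(5)
  for (i in 1:20) {
    u <- stats::rnorm(6)
    expect_equal(cosine_similarity(u, u), 1)
    expect_equal(cosine_similarity(u, -u), -1)
  }
})

test_that("annotation features fire on shared accessions, exact EC, canonical names", {
  ra <- reaction_record("RA", reaction_participants("X", 1L, "LEFT"),
                        ec_numbers = c("1.1.1.1", "2.7.-.-"),
                        uniprot_accessions = c("P00001", "Q12345"),
                        activity_names = "Alcohol dehydrogenase.")
  rb_shared <- reaction_record("RB", reaction_participants("X", 1L, "LEFT"),
                               ec_numbers = "1.1.1.2",
                               uniprot_accessions = "P00001",
                               activity_names = "alcohol-dehydrogenase")
  expect_true(uniprot_feature(ra, rb_shared))
  expect_false(ec_feature(ra, rb_shared)) # 1.1.1.1 vs 1.1.1.2
  expect_true(activity_name_feature(ra, rb_shared))
  ## partial EC matches only the identical partial string
  rb_partial <- reaction_record("RC", reaction_participants("X", 1L, "LEFT"),
                                ec_numbers = "2.7.-.-")
  expect_true(ec_feature(ra, rb_partial))
  rb_prefix <- reaction_record("RD", reaction_participants("X", 1L, "LEFT"),
                               ec_numbers = "2.7.1.1")
  expect_false(ec_feature(ra, rb_prefix))
  expect_false(uniprot_feature(ra, rb_partial))
})

test_that("the main rule needs both cosine and a feature; fallback needs 1:1 EC", {
  fx <- stoich_fixture()
  ## KR2/MR2 have cosine 1 but no annotations: unmatched by the main rule,
  ## and no EC at all, so no fallback either
  res <- infer_reaction_matches(fx$a, fx$b, fx$links)
  expect_identical(res$matches$a_id, "MR1")
  expect_identical(res$matches$b_id, "KR1")
  expect_false(grepl("EC_FALLBACK", res$matches$features))

  ## low cosine + unique EC: only reachable through the fallback
  mk <- function(prefix, right_id) {
    ids <- paste0(prefix, c("A", "B", "C", "D"))
    pathway_db(paste0("db", prefix),
               compounds = lapply(ids, function(id) cpd(id, tolower(id))),
               reactions = list(reaction_record(paste0(prefix, "R"),
                 reaction_participants(c(ids[[1L]], ids[[2L]], right_id), 1L,
                                       c("LEFT", "LEFT", "RIGHT")),
                 ec_numbers = "9.9.9.9")))
  }
  a <- mk("M", "MC")
  b <- mk("K", "KD")
  links <- data.frame(a_id = c("MA"), b_id = c("KA")) # cosine 1/3 < 0.6
  res2 <- infer_reaction_matches(a, b, links)
  expect_identical(res2$matches$features, "EC_FALLBACK")
  res3 <- infer_reaction_matches(a, b, links,
                                 cfg = reaction_match_config(ec_fallback = FALSE))
  expect_identical(nrow(res3$matches), 0L)
})

test_that("reversed reactions still clear the absolute-cosine gate", {
  mk <- function(prefix, flip) {
    ids <- paste0(prefix, c("A", "B"))
    sides <- if (flip) c("RIGHT", "LEFT") else c("LEFT", "RIGHT")
    pathway_db(paste0("db", prefix),
               compounds = lapply(ids, function(id) cpd(id, tolower(id))),
               reactions = list(reaction_record(paste0(prefix, "R"),
                 reaction_participants(ids, 1L, sides),
                 uniprot_accessions = "P1")))
  }
  res <- infer_reaction_matches(mk("M", FALSE), mk("K", TRUE),
                                data.frame(a_id = c("MA", "MB"),
                                           b_id = c("KA", "KB")))
  expect_identical(nrow(res$matches), 1L)
  expect_equal(unname(res$cosines), -1)
})

test_that("duplicate reactions cluster directly or after reversal", {
  mkdb <- function(reactions) {
    pathway_db("d", compounds = lapply(c("A", "B", "C"), compound_record),
               reactions = reactions)
  }
  rxn <- function(id, left, right, cl = 1L, cr = 1L) {
    reaction_record(id, reaction_participants(
      c(left, right), c(rep(cl, length(left)), rep(cr, length(right))),
      c(rep("LEFT", length(left)), rep("RIGHT", length(right)))))
  }
  ## forward and reversed forms are duplicates
  db <- mkdb(list(rxn("R1", c("A", "B"), "C"), rxn("R2", "C", c("A", "B"))))
  expect_identical(duplicate_reaction_count(db), 1L)
  ## differing coefficients are not duplicates
  db2 <- mkdb(list(rxn("R1", "A", "B", cl = 2L), rxn("R2", "A", "B")))
  expect_identical(duplicate_reaction_count(db2), 0L)
  ## three copies count twice
  db3 <- mkdb(list(rxn("R1", "A", "B"), rxn("R2", "A", "B"), rxn("R3", "A", "B")))
  clusters <- detect_duplicate_reactions(db3)
  expect_identical(length(clusters), 1L)
  expect_setequal(clusters[[1L]], c("R1", "R2", "R3"))
  expect_identical(duplicate_reaction_count(db3), 2L)
})

test_that("accepted reaction matches are one-to-one on generator output", {
  twin <- generate_twin_databases(generator_config(seed = 41, n_compounds = 90,
                                                   n_reactions = 35))
  cc <- concordance(twin$db_a, twin$db_b)
  m <- cc$reaction_matches
  expect_identical(anyDuplicated(m$a_id), 0L)
  expect_identical(anyDuplicated(m$b_id), 0L)
})
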