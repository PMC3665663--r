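test_that("name canonicalization strips case and punctuation", {
  expect_identical(canonicalize_name("D-Glucose"), canonicalize_name("d glucose"))
  expect_identical(canonicalize_name("A.T.P."), canonicalize_name("ATP"))
  expect_identical(canonicalize_name("L-alanine!"), "lalanine")
  expect_identical(canonicalize_name(""), "")
})

test_that("tanimoto matches brute-force set arithmetic", {
  expect_identical(tanimoto(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_identical(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_true(is.na(tanimoto(integer(), integer())))
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:40, sample(1:15, 1))
    b <- sample(0:40, sample(1:15, 1))
    expect_equal(tanimoto(a, b), oracle_tanimoto_sets(a, b))
  }
})

test_that("fingerprint+structure feature needs strict Tanimoto and key equality", {
  base <- cpd("X", "x", inchi = "I1", pik = "K1", fp = 1:8)
  expect_true(fingerprint_structure_feature(base, cpd("Y", "x", "I1", "K1", 1:8)))
  ## Tanimoto exactly at the threshold does not fire (strict inequality)
  a <- cpd("A", "x", "I1", "K1", fp = c(1, 2, 3))
  b <- cpd("B", "x", "I1", "K1", fp = c(1, 2, 3, 4)) # 3/4 = 0.75
  expect_false(fingerprint_structure_feature(a, b))
  ## identical fingerprints but different protonation-invariant keys
  expect_false(fingerprint_structure_feature(base, cpd("Z", "x", "I1", "K2", 1:8)))
  ## missing fingerprint is false, not an error
  expect_false(fingerprint_structure_feature(base, cpd("W", "x", "I1", "K1")))
})

test_that("exact stereo feature requires byte-identical structure strings", {
  expect_true(exact_stereo_feature(cpd("A", "x", "InChI=1S/c1/t1"),
                                   cpd("B", "x", "InChI=1S/c1/t1")))
  expect_false(exact_stereo_feature(cpd("A", "x", "InChI=1S/c1/t1"),
                                    cpd("B", "x", "InChI=1S/c1/t2")))
  expect_false(exact_stereo_feature(cpd("A", "x", "InChI=1S/c1"), cpd("B", "x")))
})

abo_fixture <- function() {
  mk_db <- function(prefix) {
    ids <- paste0(prefix, c("A", "B", "C"))
    pathway_db(paste0("db", prefix),
               compounds = lapply(seq_along(ids), function(i) {
                 cpd(ids[[i]], name = paste("cpd", c("a", "b", "c")[[i]]))
               }),
               reactions = list(reaction_record(paste0(prefix, "R"),
                 reaction_participants(ids, 1L, c("LEFT", "LEFT", "RIGHT")))))
  }
  list(a = mk_db("M"), b = mk_db("K"))
}

test_that("all-but-one emits exactly the single residual pair", {
  fx <- abo_fixture()
  rlinks <- data.frame(a_id = "MR", b_id = "KR")
  two_known <- data.frame(a_id = c("MA", "MB"), b_id = c("KA", "KB"))
  cands <- all_but_one_candidates(rlinks, two_known, fx$a, fx$b)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$c_m, "MC")
  expect_identical(cands$c_k, "KC")
  ## two unmatched pairs remain: no candidate
  one_known <- data.frame(a_id = "MA", b_id = "KA")
  expect_identical(nrow(all_but_one_candidates(rlinks, one_known, fx$a, fx$b)), 0L)
  ## residual compound already linked elsewhere: no candidate
  taken <- data.frame(a_id = c("MA", "MB", "MX"), b_id = c("KA", "KB", "KC"))
  expect_identical(nrow(all_but_one_candidates(rlinks, taken, fx$a, fx$b)), 0L)
})

test_that("inference applies the feature + name gate and finds all-but-one at fixpoint", {
  fx <- abo_fixture()
  links <- correspondence_set(
    entity_type = c("compound", "compound", "reaction"),
    a_id = c("MA", "MB", "MR"), b_id = c("KA", "KB", "KR"),
    source = "curated")
  res <- infer_compound_matches(fx$a, fx$b, existing = links)
  expect_identical(res$matches$a_id, "MC")
  expect_identical(res$matches$b_id, "KC")
  expect_identical(res$matches$features, "ALL_BUT_ONE")
})

test_that("name gate blocks structure-identical compounds with different names", {
  a <- pathway_db("a", compounds = list(cpd("A1", "alpha", "I1", "K1", 1:6)),
                  reactions = list())
  b <- pathway_db("b", compounds = list(cpd("B1", "beta", "I1", "K1", 1:6)),
                  reactions = list())
  res <- infer_compound_matches(a, b)
  expect_identical(nrow(res$matches), 0L)
})

test_that("ambiguous partners are contradictions and void all implicated pairs", {
  a <- pathway_db("a", compounds = list(cpd("A1", "same", "I1", "K1", 1:6)))
  b <- pathway_db("b", compounds = list(cpd("B1", "same", "I1", "K1", 1:6),
                                        cpd("B2", "same", "I1", "K1", 1:6)))
  res <- infer_compound_matches(a, b)
  expect_identical(nrow(res$matches), 0L)
  expect_identical(nrow(res$contradictions), 2L)
})

test_that("accepted matches are one-to-one and symmetric under view swap", {
  twin <- generate_twin_databases(generator_config(seed = 37, n_compounds = 90,
                                                   n_reactions = 35))
  fwd <- infer_compound_matches(twin$db_a, twin$db_b)
  expect_identical(anyDuplicated(fwd$matches$a_id), 0L)
  expect_identical(anyDuplicated(fwd$matches$b_id), 0L)
  rev <- infer_compound_matches(twin$db_b, twin$db_a)
  expect_setequal(paste(fwd$matches$a_id, fwd$matches$b_id),
                  paste(rev$matches$b_id, rev$matches$a_id))
})

test_that("lowering the Tanimoto threshold never removes a match", {
  ## contradiction-free fixture: distinct names, noisy fingerprints
  mk <- function(prefix, extra_bit) {
    pathway_db(prefix, compounds = lapply(1:6, function(i) {
      cpd(paste0(prefix, i), name = paste("compound", i),
          inchi = paste0("I", i), pik = paste0("K", i),
          fp = c(seq_len(4 + i), 50 + i + extra_bit))
    }))
  }
  a <- mk("a", 0L)
  b <- mk("b", 100L)
  got <- function(thr) {
    m <- infer_compound_matches(a, b, cfg = compound_match_config(
      tanimoto_threshold = thr))$matches
    paste(m$a_id, m$b_id)
  }
  sets <- lapply(c(0.9, 0.75, 0.5, 0.2), got)
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
})

test_that("duplicate compound detection clusters identical structure strings", {
  db <- pathway_db("d", compounds = list(
    cpd("C1", "one", "I-SAME"), cpd("C2", "two", "I-SAME"),
    cpd("C3", "three", "I-SAME"), cpd("C4", "four", "I-OTHER"),
    cpd("C5", "five"), cpd("C6", "six")))
  clusters <- detect_duplicate_compounds(db)
  expect_identical(length(clusters), 1L)
  expect_setequal(clusters[[1L]], c("C1", "C2", "C3"))
  expect_identical(duplicate_compound_count(db), 2L)
  ## two records, same structure: one cluster, count 1
  db2 <- pathway_db("d2", compounds = list(cpd("X", "x", "I"), cpd("Y", "y", "I")))
  expect_identical(duplicate_compound_count(db2), 1L)
})
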