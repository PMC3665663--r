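## Shared fixtures and independent oracles for the test suite.

## A small hand-built database: glucose glycolysis-flavoured fixture with
## one balanced and one hydrogen-unbalanced reaction.
tiny_db <- function() {
  pathway_db(
    name = "tiny",
    compounds = list(
      compound_record("GLC", "D-Glucose", synonyms = c("glucose", "dextrose"),
                      formula = "C6H12O6",
                      inchi = "InChI=1S/C6H12O6/c1/t1",
                      structure_key = "GLC-CORE/t1",
                      protonation_invariant_key = "GLC-CORE",
                      fingerprint = c(1L, 5L, 9L)),
      compound_record("LAC", "Lactate", formula = "C3H6O3",
                      inchi = "InChI=1S/C3H6O3/c2/t1",
                      structure_key = "LAC-CORE/t1",
                      protonation_invariant_key = "LAC-CORE",
                      fingerprint = c(2L, 5L, 7L)),
      compound_record("PYR", "Pyruvate", formula = "C3H4O3"),
      compound_record("WAT", "Water", formula = "H2O"),
      compound_record("OXY", "Oxygen", formula = "O2"),
      compound_record("HYD", "Hydrogen", formula = "H2")
    ),
    reactions = list(
      reaction_record("R-GLYC", reaction_participants(
        c("GLC", "LAC"), c(1L, 2L), c("LEFT", "RIGHT")),
        ec_numbers = "1.1.1.27"),
      reaction_record("R-PYR", reaction_participants(
        c("GLC", "PYR"), c(1L, 2L), c("LEFT", "RIGHT"))),
      reaction_record("R-WATER", reaction_participants(
        c("HYD", "OXY", "WAT"), c(2L, 1L, 2L), c("LEFT", "LEFT", "RIGHT")))
    ),
    pathways = list(
      pathway_record("PWY-1", "BASE", reaction_ids = "R-GLYC"),
      pathway_record("SPWY-1", "SUPER", reaction_ids = "R-PYR",
                     subpathway_ids = "PWY-1")
    )
  )
}

## minimal compound constructor for matching tests
cpd <- function(id, name, inchi = NA, pik = NA, fp = NULL, synonyms = character()) {
  compound_record(id, common_name = name, synonyms = synonyms, inchi = inchi,
                  structure_key = if (is.na(inchi)) NA else paste0(inchi, "#sk"),
                  protonation_invariant_key = pik, fingerprint = fp)
}

## small zero-noise generator configuration (views identical up to renaming)
zero_noise_config <- function(seed = 1L, ...) {
  generator_config(seed = seed,
                   shared_compound_fraction = 1, shared_reaction_fraction = 1,
                   name_mangle_prob = 0, protonation_variant_prob = 0,
                   stereo_loss_prob = 0, duplicate_compound_rate = 0,
                   duplicate_reaction_rate = 0, imbalance_rate = 0,
                   ec_annotation_prob = 1, ec_collision_rate = 0,
                   uniprot_share_prob = 1, activity_name_share_prob = 1,
                   fingerprint_noise_bits = 0, ...)
}

## --- independent oracles -------------------------------------------------

## brute-force set statistics over explicit sets
oracle_jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))
oracle_tanimoto_sets <- oracle_jaccard_sets

## hypergeometric tail by exhaustive enumeration of all C(N, n) draws:
## population 1..N, marked elements 1..K
oracle_hypergeom_tail <- function(k, K, n, N, tail) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  if (tail == "GE") mean(marked >= k) else mean(marked <= k)
}

## Clopper-Pearson endpoints by direct root search on the binomial tails
oracle_clopper_pearson <- function(x, n, confidence) {
  alpha <- 1 - confidence
  lo <- if (x == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

## random formula string with known atom counts, built token by token
## (optionally wrapping a parenthesised group); the expected counts are
## accumulated independently of the parser under test
random_formula_case <- function(max_groups = 4) {
  elements <- c("C", "H", "O", "N", "Na", "Cl", "Fe", "Ca", "Mg")
  expected <- integer()
  add <- function(sym, k) {
    expected[sym] <<- (if (sym %in% names(expected)) expected[[sym]] else 0L) + k
  }
  str <- ""
  for (g in seq_len(sample(1:max_groups, 1))) {
    if (stats::runif(1) < 0.4) {
      mult <- sample(1:3, 1)
      inner <- ""
      for (t in seq_len(sample(1:3, 1))) {
        sym <- sample(elements, 1)
        k <- sample(1:9, 1)
        inner <- paste0(inner, sym, if (k > 1) k else "")
        add(sym, k * mult)
      }
      str <- paste0(str, "(", inner, ")", if (mult > 1) mult else "")
    } else {
      sym <- sample(elements, 1)
      k <- sample(1:12, 1)
      str <- paste0(str, sym, if (k > 1) k else "")
      add(sym, k)
    }
  }
  list(formula = str, expected = element_bag(expected))
}

## byte-compare two directories written by the package
dirs_identical <- function(d1, d2) {
  f1 <- sort(list.files(d1))
  f2 <- sort(list.files(d2))
  if (!identical(f1, f2)) return(FALSE)
  all(vapply(f1, function(f) {
    identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }, logical(1)))
}
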