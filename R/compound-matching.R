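#' Canonicalize an entity name
#'
#' Lowercases the string and removes every character outside `[a-z0-9]`, so
#' that punctuation and capitalization differences do not block exact name
#' matching (e.g. `"D-Glucose"` and `"d glucose"` share one key).
#'
#' @param name character vector of names.
#' @return canonical key strings (empty input gives an empty key).
#' @export
canonicalize_name <- function(name) {
  gsub("[^a-z0-9]", "", tolower(as.character(name)))
}

#' Tanimoto coefficient of two fingerprint bit sets
#'
#' @param a,b integer vectors of set bit positions.
#' @return `|a & b| / |a | b|`; `NA` if both sets are empty (undefined --
#'   never treated as a match).
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Compound match configuration
#'
#' @param tanimoto_threshold fingerprint similarity threshold; the feature
#'   requires Tanimoto strictly greater than this value (default 0.75).
#' @param require_name_match require canonical-name equality (common name or
#'   any synonym) for every accepted match.
#' @param features_enabled subset of
#'   `c("FINGERPRINT_STRUCT", "EXACT_STEREO", "ALL_BUT_ONE")`.
#' @return an object of class `compound_match_config`.
#' @export
compound_match_config <- function(tanimoto_threshold = 0.75,
                                  require_name_match = TRUE,
                                  features_enabled = c("FINGERPRINT_STRUCT",
                                                       "EXACT_STEREO",
                                                       "ALL_BUT_ONE")) {
  stopifnot(tanimoto_threshold >= 0, tanimoto_threshold <= 1)
  features_enabled <- match.arg(features_enabled,
                                c("FINGERPRINT_STRUCT", "EXACT_STEREO", "ALL_BUT_ONE"),
                                several.ok = TRUE)
  structure(list(tanimoto_threshold = tanimoto_threshold,
                 require_name_match = isTRUE(require_name_match),
                 features_enabled = features_enabled),
            class = "compound_match_config")
}

#' Fingerprint-plus-structure compound match feature
#'
#' Fires iff the fingerprint Tanimoto coefficient exceeds the configured
#' threshold (strict) AND the protonation-invariant structure keys are equal,
#' so compounds differing only in protonation state can still match. A
#' missing fingerprint or key makes the feature false, not an error.
#'
#' @param ca,cb `compound_record`s from databases A and B.
#' @param cfg a [compound_match_config()].
#' @return logical.
#' @export
fingerprint_structure_feature <- function(ca, cb, cfg = compound_match_config()) {
  if (is.null(ca$fingerprint) || is.null(cb$fingerprint)) return(FALSE)
  if (is.na(ca$protonation_invariant_key) || is.na(cb$protonation_invariant_key)) return(FALSE)
  if (ca$protonation_invariant_key != cb$protonation_invariant_key) return(FALSE)
  tc <- tanimoto(ca$fingerprint, cb$fingerprint)
  !is.na(tc) && tc > cfg$tanimoto_threshold
}

#' Exact stereo-structure compound match feature
#'
#' Fires iff both compounds carry a full structure string (InChI-style,
#' including stereo and proton layers) and the strings are byte-identical.
#'
#' @param ca,cb `compound_record`s.
#' @return logical.
#' @export
exact_stereo_feature <- function(ca, cb) {
  !is.na(ca$inchi) && !is.na(cb$inchi) && identical(ca$inchi, cb$inchi)
}

## all canonical name keys of a compound (common name + synonyms), non-empty
compound_name_keys <- function(c) {
  keys <- unique(canonicalize_name(c(c$common_name, c$synonyms)))
  keys[nzchar(keys)]
}

names_match <- function(ca, cb) {
  length(intersect(compound_name_keys(ca), compound_name_keys(cb))) > 0L
}

#' All-but-one compound match candidates
#'
#' For each accepted reaction correspondence whose substrate sets are fully
#' matched except for exactly one compound on each side, and where neither
#' residual compound is already linked to anything, propose the residual pair
#' as a candidate match.
#'
#' @param reaction_links data frame with columns `a_id`, `b_id` of accepted
#'   reaction correspondences.
#' @param compound_links data frame with columns `a_id`, `b_id` of current
#'   compound correspondences.
#' @param db_a,db_b the two databases.
#' @return data frame with columns `a_rxn`, `b_rxn`, `c_m` (A-side residual
#'   compound) and `c_k` (B-side residual compound).
#' @export
all_but_one_candidates <- function(reaction_links, compound_links, db_a, db_b) {
  out <- list()
  a2b <- stats::setNames(compound_links$b_id, compound_links$a_id)
  linked_a <- compound_links$a_id
  linked_b <- compound_links$b_id
  for (i in seq_len(NROW(reaction_links))) {
    ra <- db_a$reactions[[reaction_links$a_id[[i]]]]
    rb <- db_b$reactions[[reaction_links$b_id[[i]]]]
    if (is.null(ra) || is.null(rb)) next
    subs_a <- unique(ra$participants$compound_id)
    subs_b <- unique(rb$participants$compound_id)
    partners <- unname(a2b[subs_a])
    covered_a <- !is.na(partners) & partners %in% subs_b
    covered_b <- subs_b %in% partners[covered_a]
    res_a <- subs_a[!covered_a]
    res_b <- subs_b[!covered_b]
    if (length(res_a) == 1L && length(res_b) == 1L &&
        !(res_a %in% linked_a) && !(res_b %in% linked_b)) {
      out[[length(out) + 1L]] <- data.frame(
        a_rxn = ra$id, b_rxn = rb$id, c_m = res_a, c_k = res_b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    data.frame(a_rxn = character(), b_rxn = character(),
               c_m = character(), c_k = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

## drop every proposal implicated in a contradiction (an id proposed with
## two or more distinct partners); returns list(accepted, contradictions)
resolve_contradictions <- function(props) {
  if (nrow(props) == 0L) return(list(accepted = props, contradictions = props[0, , drop = FALSE]))
  pair_key <- paste(props$a_id, props$b_id, sep = "\r")
  props <- props[!duplicated(pair_key), , drop = FALSE]
  bad_a <- names(which(table(props$a_id) > 1L))
  bad_b <- names(which(table(props$b_id) > 1L))
  bad <- props$a_id %in% bad_a | props$b_id %in% bad_b
  list(accepted = props[!bad, , drop = FALSE],
       contradictions = props[bad, , drop = FALSE])
}

#' Infer compound correspondences between two databases
#'
#' Implements the rule system: a candidate pair is accepted iff at least one
#' enabled feature fires (`FINGERPRINT_STRUCT`, `EXACT_STEREO` or, in later
#' passes, `ALL_BUT_ONE`), the canonical name keys intersect (common name or
#' any synonym, unless disabled), and the pair participates in no
#' contradiction (a compound proposed with two or more distinct partners
#' voids all of its pairs). All-but-one inference runs after the direct pass,
#' using accepted reaction links, and iterates to a fixpoint since each new
#' compound match can complete another reaction pair. Existing curated or
#' imported links are kept and never overridden; inference never relinks an
#' already-linked compound.
#'
#' @param db_a,db_b the two `pathway_db`s.
#' @param existing optional [correspondence_set()] of pre-existing compound
#'   links and accepted reaction links (consumed by all-but-one inference).
#' @param cfg a [compound_match_config()].
#' @return list with elements `matches` (a `correspondence_set` of inferred
#'   compound matches) and `contradictions` (data frame of voided pairs).
#' @export
infer_compound_matches <- function(db_a, db_b, existing = NULL,
                                   cfg = compound_match_config()) {
  existing_cpd <- links_of_type(existing, "compound")
  reaction_links <- links_of_type(existing, "reaction")
  taken_a <- existing_cpd$a_id
  taken_b <- existing_cpd$b_id

  ## candidate generation: pairs sharing at least one canonical name key
  key_table <- function(db) {
    ids <- names(db$compounds)
    keys <- lapply(db$compounds, compound_name_keys)
    data.frame(id = rep(ids, lengths(keys)),
               key = unlist(keys, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  ka <- key_table(db_a)
  kb <- key_table(db_b)
  cand <- merge(ka, kb, by = "key", suffixes = c("_a", "_b"))
  cand <- unique(cand[, c("id_a", "id_b")])
  cand <- cand[!(cand$id_a %in% taken_a) & !(cand$id_b %in% taken_b), , drop = FALSE]

  direct <- list()
  for (i in seq_len(nrow(cand))) {
    ca <- db_a$compounds[[cand$id_a[[i]]]]
    cb <- db_b$compounds[[cand$id_b[[i]]]]
    feats <- character()
    if ("FINGERPRINT_STRUCT" %in% cfg$features_enabled &&
        fingerprint_structure_feature(ca, cb, cfg)) {
      feats <- c(feats, "FINGERPRINT_STRUCT")
    }
    if ("EXACT_STEREO" %in% cfg$features_enabled && exact_stereo_feature(ca, cb)) {
      feats <- c(feats, "EXACT_STEREO")
    }
    if (length(feats) > 0L) {
      direct[[length(direct) + 1L]] <- data.frame(
        a_id = ca$id, b_id = cb$id, features = paste(feats, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  proposals <- if (length(direct) == 0L) {
    data.frame(a_id = character(), b_id = character(), features = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, direct)
  }

  res <- resolve_contradictions(proposals)

  ## all-but-one: iterate to fixpoint (proposals only ever grow)
  if ("ALL_BUT_ONE" %in% cfg$features_enabled && nrow(reaction_links) > 0L) {
    repeat {
      current <- data.frame(
        a_id = c(existing_cpd$a_id, res$accepted$a_id),
        b_id = c(existing_cpd$b_id, res$accepted$b_id),
        stringsAsFactors = FALSE)
      abo <- all_but_one_candidates(reaction_links, current, db_a, db_b)
      if (nrow(abo) > 0L) {
        keep <- vapply(seq_len(nrow(abo)), function(i) {
          ca <- db_a$compounds[[abo$c_m[[i]]]]
          cb <- db_b$compounds[[abo$c_k[[i]]]]
          !cfg$require_name_match || names_match(ca, cb)
        }, logical(1))
        abo <- abo[keep, , drop = FALSE]
      }
      if (nrow(abo) == 0L) break
      new <- data.frame(a_id = abo$c_m, b_id = abo$c_k,
                        features = "ALL_BUT_ONE", stringsAsFactors = FALSE)
      pair_key <- paste(proposals$a_id, proposals$b_id, sep = "\r")
      new_key <- paste(new$a_id, new$b_id, sep = "\r")
      new <- new[!(new_key %in% pair_key), , drop = FALSE]
      if (nrow(new) == 0L) break
      proposals <- rbind(proposals, new)
      res <- resolve_contradictions(merge_features(proposals))
    }
  }

  accepted <- res$accepted
  matches <- correspondence_set(
    entity_type = rep("compound", nrow(accepted)),
    a_id = accepted$a_id, b_id = accepted$b_id,
    source = rep("inferred", nrow(accepted)),
    features = accepted$features)
  list(matches = matches, contradictions = res$contradictions)
}

## combine feature strings for duplicate (a_id, b_id) proposals
merge_features <- function(props) {
  key <- paste(props$a_id, props$b_id, sep = "\r")
  if (!anyDuplicated(key)) return(props)
  feats <- vapply(split(props$features, key), function(f) {
    paste(sort(unique(unlist(strsplit(f, ",", fixed = TRUE)))), collapse = ",")
  }, character(1))
  out <- props[!duplicated(key), , drop = FALSE]
  out$features <- unname(feats[paste(out$a_id, out$b_id, sep = "\r")])
  out
}

#' Detect duplicate compounds within one database
#'
#' Compounds with identical non-empty structure strings (InChI) form a
#' duplicate cluster. The duplicate count follows the cluster-size
#' convention: each cluster of size k contributes k - 1 duplicates.
#'
#' @param db a `pathway_db`.
#' @return `detect_duplicate_compounds`: list of character vectors (clusters
#'   of compound ids, each of size >= 2). `duplicate_compound_count`: integer.
#' @export
detect_duplicate_compounds <- function(db) {
  inchis <- vapply(db$compounds, function(c) c$inchi, character(1))
  ok <- !is.na(inchis) & nzchar(inchis)
  groups <- split(names(db$compounds)[ok], inchis[ok])
  clusters <- Filter(function(g) length(g) >= 2L, groups)
  unname(lapply(clusters[order(names(clusters))], sort))
}

#' @rdname detect_duplicate_compounds
#' @export
duplicate_compound_count <- function(db) {
  sum(vapply(detect_duplicate_compounds(db), function(g) length(g) - 1L, integer(1)))
}
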