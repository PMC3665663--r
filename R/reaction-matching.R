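#' Reaction match configuration
#'
#' @param cosine_threshold similarity threshold on the absolute cosine of
#'   the two stoichiometry column vectors; strict (default 0.6).
#' @param features_enabled subset of `c("UNIPROT", "EC", "ACTIVITY_NAME")`.
#' @param ec_fallback after the main rule, accept remaining unmatched pairs
#'   sharing an EC number when that EC maps exactly one unmatched A-reaction
#'   to exactly one unmatched B-reaction.
#' @return an object of class `reaction_match_config`.
#' @export
reaction_match_config <- function(cosine_threshold = 0.6,
                                  features_enabled = c("UNIPROT", "EC", "ACTIVITY_NAME"),
                                  ec_fallback = TRUE) {
  stopifnot(cosine_threshold >= 0, cosine_threshold <= 1)
  features_enabled <- match.arg(features_enabled,
                                c("UNIPROT", "EC", "ACTIVITY_NAME"),
                                several.ok = TRUE)
  structure(list(cosine_threshold = cosine_threshold,
                 features_enabled = features_enabled,
                 ec_fallback = isTRUE(ec_fallback)),
            class = "reaction_match_config")
}

#' Build the joint stoichiometric matrix of two databases
#'
#' Reactions are columns; each distinct compound identity is a row. Linked
#' compound pairs share one row (identity key = the pair); unlinked
#' compounds get database-private rows. Reactant coefficients are entered as
#' negative values, product coefficients as positive; a compound appearing
#' on both sides contributes its net coefficient.
#'
#' @param db_a,db_b the two databases.
#' @param compound_links data frame (`a_id`, `b_id`) of one-to-one compound
#'   correspondences.
#' @return list with the sparse `matrix` (rows = compound identities,
#'   columns = db-qualified reaction ids), and the column name vectors
#'   `a_cols`, `b_cols`.
#' @export
build_stoich_matrix <- function(db_a, db_b, compound_links) {
  if (NROW(compound_links) > 0L) {
    bad_a <- setdiff(compound_links$a_id, names(db_a$compounds))
    bad_b <- setdiff(compound_links$b_id, names(db_b$compounds))
    if (length(bad_a) + length(bad_b) > 0L) {
      stop("compound links reference unknown compounds: ",
           paste(c(bad_a, bad_b), collapse = ", "))
    }
    if (anyDuplicated(compound_links$a_id) || anyDuplicated(compound_links$b_id)) {
      stop("compound links must be one-to-one")
    }
  }
  a2row <- stats::setNames(paste0("a:", names(db_a$compounds)), names(db_a$compounds))
  b2row <- stats::setNames(paste0("b:", names(db_b$compounds)), names(db_b$compounds))
  if (NROW(compound_links) > 0L) {
    pair_row <- paste0("pair:", compound_links$a_id)
    a2row[compound_links$a_id] <- pair_row
    b2row[compound_links$b_id] <- pair_row
  }
  triplets <- function(db, row_map, prefix) {
    rows <- character(); cols <- character(); vals <- integer()
    for (r in db$reactions) {
      p <- r$participants
      if (nrow(p) == 0L) next
      rows <- c(rows, unname(row_map[p$compound_id]))
      cols <- c(cols, rep(paste0(prefix, r$id), nrow(p)))
      vals <- c(vals, ifelse(p$side == "LEFT", -p$coefficient, p$coefficient))
    }
    list(rows = rows, cols = cols, vals = vals)
  }
  ta <- triplets(db_a, a2row, "a:")
  tb <- triplets(db_b, b2row, "b:")
  row_names <- sort(unique(c(ta$rows, tb$rows)))
  col_names <- c(paste0("a:", names(db_a$reactions)), paste0("b:", names(db_b$reactions)))
  m <- Matrix::sparseMatrix(
    i = match(c(ta$rows, tb$rows), row_names),
    j = match(c(ta$cols, tb$cols), col_names),
    x = c(ta$vals, tb$vals),
    dims = c(length(row_names), length(col_names)),
    dimnames = list(row_names, col_names))
  m <- Matrix::drop0(m)
  list(matrix = m,
       a_cols = paste0("a:", names(db_a$reactions)),
       b_cols = paste0("b:", names(db_b$reactions)))
}

#' Cosine similarity of two stoichiometry vectors
#'
#' @param u,v numeric vectors of equal length (or named sparse vectors over
#'   the same row space).
#' @return `dot(u, v) / (|u| |v|)` in `[-1, 1]`; `NA` for a zero vector
#'   (undefined -- never treated as a match).
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

canonical_activity_keys <- function(r) {
  k <- unique(canonicalize_name(r$activity_names))
  k[nzchar(k)]
}

#' Reaction annotation match features
#'
#' `uniprot_feature`: at least one UniProt accession in common.
#' `ec_feature`: exact full-string equality of any EC number pair (partial
#' EC forms such as `"1.1.1.-"` match only identical partial strings).
#' `activity_name_feature`: canonical-key equality of any enzymatic activity
#' name pair (see [canonicalize_name()]). Missing annotations make a feature
#' false, never an error.
#'
#' @param ra,rb `reaction_record`s from databases A and B.
#' @return logical.
#' @export
uniprot_feature <- function(ra, rb) {
  length(intersect(ra$uniprot_accessions, rb$uniprot_accessions)) > 0L
}

#' @rdname uniprot_feature
#' @export
ec_feature <- function(ra, rb) {
  length(intersect(ra$ec_numbers, rb$ec_numbers)) > 0L
}

#' @rdname uniprot_feature
#' @export
activity_name_feature <- function(ra, rb) {
  length(intersect(canonical_activity_keys(ra), canonical_activity_keys(rb))) > 0L
}

reaction_features <- function(ra, rb, cfg) {
  feats <- character()
  if ("UNIPROT" %in% cfg$features_enabled && uniprot_feature(ra, rb)) {
    feats <- c(feats, "UNIPROT")
  }
  if ("EC" %in% cfg$features_enabled && ec_feature(ra, rb)) {
    feats <- c(feats, "EC")
  }
  if ("ACTIVITY_NAME" %in% cfg$features_enabled && activity_name_feature(ra, rb)) {
    feats <- c(feats, "ACTIVITY_NAME")
  }
  feats
}

#' Infer reaction correspondences between two databases
#'
#' Main rule: a pair is accepted iff the absolute cosine similarity of its
#' stoichiometry column vectors (sharing rows through `compound_links`)
#' strictly exceeds the threshold, at least one annotation feature fires,
#' and the pair participates in no contradiction (a reaction proposed with
#' two or more distinct partners voids all of its pairs). EC fallback: among
#' reactions still unmatched afterwards, pairs sharing an EC number whose
#' mapping is one-to-one are accepted; the fallback never overrides a
#' main-rule match or resurrects a contradiction-voided pair. Existing links
#' are kept and never overridden.
#'
#' @param db_a,db_b the two databases.
#' @param compound_links data frame (`a_id`, `b_id`) of compound
#'   correspondences (possibly empty).
#' @param existing optional `correspondence_set` of pre-existing reaction
#'   links.
#' @param cfg a [reaction_match_config()].
#' @return list with `matches` (a `correspondence_set`; its `features`
#'   column carries the fired features, with `EC_FALLBACK` marking fallback
#'   matches), `contradictions`, and `cosines` (named numeric of accepted
#'   pair cosines).
#' @export
infer_reaction_matches <- function(db_a, db_b, compound_links = NULL,
                                   existing = NULL,
                                   cfg = reaction_match_config()) {
  existing_rxn <- links_of_type(existing, "reaction")
  taken_a <- existing_rxn$a_id
  taken_b <- existing_rxn$b_id
  if (is.null(compound_links)) {
    compound_links <- data.frame(a_id = character(), b_id = character(),
                                 stringsAsFactors = FALSE)
  }

  S <- build_stoich_matrix(db_a, db_b, compound_links)
  A <- S$matrix[, S$a_cols, drop = FALSE]
  B <- S$matrix[, S$b_cols, drop = FALSE]
  dots <- Matrix::crossprod(A, B)
  na_norm <- sqrt(Matrix::colSums(A^2))
  nb_norm <- sqrt(Matrix::colSums(B^2))

  ## only nonzero dot products can clear a positive threshold
  tri <- Matrix::summary(dots)
  cand <- data.frame(ai = tri$i, bi = tri$j, dot = tri$x)
  denom <- na_norm[cand$ai] * nb_norm[cand$bi]
  cand$cos <- ifelse(denom > 0, cand$dot / denom, NA_real_)
  cand <- cand[!is.na(cand$cos) & abs(cand$cos) > cfg$cosine_threshold, , drop = FALSE]

  a_ids <- names(db_a$reactions)
  b_ids <- names(db_b$reactions)
  props <- list()
  for (i in seq_len(nrow(cand))) {
    aid <- a_ids[[cand$ai[[i]]]]
    bid <- b_ids[[cand$bi[[i]]]]
    if (aid %in% taken_a || bid %in% taken_b) next
    feats <- reaction_features(db_a$reactions[[aid]], db_b$reactions[[bid]], cfg)
    if (length(feats) > 0L) {
      props[[length(props) + 1L]] <- data.frame(
        a_id = aid, b_id = bid, features = paste(feats, collapse = ","),
        cosine = cand$cos[[i]], stringsAsFactors = FALSE)
    }
  }
  proposals <- if (length(props) == 0L) {
    data.frame(a_id = character(), b_id = character(), features = character(),
               cosine = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, props)
  }
  res <- resolve_contradictions(proposals)
  accepted <- res$accepted
  voided <- res$contradictions

  ## EC fallback among remaining unmatched reactions
  fallback <- NULL
  if (cfg$ec_fallback) {
    matched_a <- c(taken_a, accepted$a_id)
    matched_b <- c(taken_b, accepted$b_id)
    free_a <- setdiff(a_ids, matched_a)
    free_b <- setdiff(b_ids, matched_b)
    ec_map <- function(ids, db) {
      ecs <- lapply(db$reactions[ids], function(r) unique(r$ec_numbers))
      data.frame(id = rep(ids, lengths(ecs)),
                 ec = unlist(ecs, use.names = FALSE),
                 stringsAsFactors = FALSE)
    }
    ea <- ec_map(free_a, db_a)
    eb <- ec_map(free_b, db_b)
    shared <- intersect(ea$ec, eb$ec)
    one_to_one <- shared[vapply(shared, function(e) {
      sum(ea$ec == e) == 1L && sum(eb$ec == e) == 1L
    }, logical(1))]
    if (length(one_to_one) > 0L) {
      fb <- data.frame(
        a_id = vapply(one_to_one, function(e) ea$id[ea$ec == e], character(1)),
        b_id = vapply(one_to_one, function(e) eb$id[eb$ec == e], character(1)),
        stringsAsFactors = FALSE)
      ## never resurrect a contradiction-voided pair; keep the mapping 1:1
      if (nrow(voided) > 0L) {
        voided_key <- paste(voided$a_id, voided$b_id, sep = "\r")
        fb <- fb[!(paste(fb$a_id, fb$b_id, sep = "\r") %in% voided_key), , drop = FALSE]
      }
      fb <- fb[!duplicated(fb$a_id) & !duplicated(fb$b_id), , drop = FALSE]
      fb <- fb[!(fb$a_id %in% names(which(table(fb$a_id) > 1L))) &
                 !(fb$b_id %in% names(which(table(fb$b_id) > 1L))), , drop = FALSE]
      if (nrow(fb) > 0L) {
        cosv <- vapply(seq_len(nrow(fb)), function(i) {
          ca <- match(paste0("a:", fb$a_id[[i]]), colnames(S$matrix))
          cb <- match(paste0("b:", fb$b_id[[i]]), colnames(S$matrix))
          cosine_similarity(as.numeric(S$matrix[, ca]), as.numeric(S$matrix[, cb]))
        }, numeric(1))
        fallback <- data.frame(a_id = fb$a_id, b_id = fb$b_id,
                               features = "EC_FALLBACK", cosine = cosv,
                               stringsAsFactors = FALSE)
      }
    }
  }

  all_acc <- rbind(accepted, fallback)
  if (is.null(all_acc)) {
    all_acc <- data.frame(a_id = character(), b_id = character(),
                          features = character(), cosine = numeric(),
                          stringsAsFactors = FALSE)
  }
  matches <- correspondence_set(
    entity_type = rep("reaction", nrow(all_acc)),
    a_id = all_acc$a_id, b_id = all_acc$b_id,
    source = rep("inferred", nrow(all_acc)),
    features = all_acc$features)
  list(matches = matches,
       contradictions = voided,
       cosines = stats::setNames(all_acc$cosine,
                                 paste(all_acc$a_id, all_acc$b_id, sep = "|")))
}

## canonical duplicate signature: the unordered pair of side multisets
reaction_signature <- function(r) {
  p <- r$participants
  side_str <- function(side) {
    q <- p[p$side == side, , drop = FALSE]
    paste(sort(paste0(q$coefficient, "*", q$compound_id)), collapse = "+")
  }
  s <- sort(c(side_str("LEFT"), side_str("RIGHT")))
  paste(s[[1L]], s[[2L]], sep = " <=> ")
}

#' Detect duplicate reactions within one database
#'
#' Two reactions are duplicates if their reactant and product coefficient
#' multisets are equal, directly or after reversing one of them. The
#' duplicate count is the sum over clusters of (cluster size - 1).
#'
#' @param db a `pathway_db`.
#' @return `detect_duplicate_reactions`: list of id clusters (size >= 2).
#'   `duplicate_reaction_count`: integer.
#' @export
detect_duplicate_reactions <- function(db) {
  sigs <- vapply(db$reactions, reaction_signature, character(1))
  groups <- split(names(db$reactions), sigs)
  clusters <- Filter(function(g) length(g) >= 2L, groups)
  unname(lapply(clusters[order(names(clusters))], sort))
}

#' @rdname detect_duplicate_reactions
#' @export
duplicate_reaction_count <- function(db) {
  sum(vapply(detect_duplicate_reactions(db), function(g) length(g) - 1L, integer(1)))
}
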