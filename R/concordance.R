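#' Infer a full concordance between two pathway databases
#'
#' The package's central computation: alternates compound and reaction
#' correspondence inference until a fixpoint. Compound matching supplies
#' shared rows for the stoichiometric matrix; accepted reaction matches in
#' turn enable all-but-one compound inference; the loop repeats until no
#' new links appear (usually two or three rounds).
#'
#' @param db_a,db_b the two `pathway_db`s.
#' @param existing optional [correspondence_set()] of curated or imported
#'   links; these are kept and never overridden.
#' @param compound_cfg a [compound_match_config()].
#' @param reaction_cfg a [reaction_match_config()].
#' @param max_rounds safety cap on alternation rounds.
#' @return an object of class `concordance` with components `links` (the
#'   combined `correspondence_set`, existing plus inferred),
#'   `compound_matches`, `reaction_matches`, `contradictions` (list with
#'   `compound` and `reaction` elements), `rounds`, and the database names.
#' @examples
#' twin <- generate_twin_databases(generator_config(seed = 42, n_compounds = 60,
#'                                                  n_reactions = 25))
#' cc <- concordance(twin$db_a, twin$db_b)
#' summary(cc)
#' @export
concordance <- function(db_a, db_b, existing = NULL,
                        compound_cfg = compound_match_config(),
                        reaction_cfg = reaction_match_config(),
                        max_rounds = 10L) {
  stopifnot(inherits(db_a, "pathway_db"), inherits(db_b, "pathway_db"))
  base_links <- if (is.null(existing)) correspondence_set() else existing
  cpd_matches <- correspondence_set()
  rxn_matches <- correspondence_set()
  contr_cpd <- NULL
  contr_rxn <- NULL
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    current <- bind_links(base_links, rxn_matches)
    cm <- infer_compound_matches(db_a, db_b, current, compound_cfg)
    cpd_matches <- cm$matches
    contr_cpd <- cm$contradictions
    cpd_links <- bind_links(links_of_type(base_links, "compound"), cpd_matches)
    rm <- infer_reaction_matches(db_a, db_b,
                                 compound_links = cpd_links,
                                 existing = base_links,
                                 cfg = reaction_cfg)
    new_rxn <- rm$matches
    contr_rxn <- rm$contradictions
    stable <- nrow(new_rxn) == nrow(rxn_matches) &&
      setequal(paste(new_rxn$a_id, new_rxn$b_id),
               paste(rxn_matches$a_id, rxn_matches$b_id))
    rxn_matches <- new_rxn
    if (stable || rounds >= max_rounds) break
  }
  structure(list(
    db_a_name = db_a$name, db_b_name = db_b$name,
    links = bind_links(base_links, cpd_matches, rxn_matches),
    compound_matches = cpd_matches,
    reaction_matches = rxn_matches,
    contradictions = list(compound = contr_cpd, reaction = contr_rxn),
    rounds = rounds
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance %s ~ %s: %d compound links, %d reaction links (%d rounds)>\n",
              x$db_a_name, x$db_b_name,
              sum(x$links$entity_type == "compound"),
              sum(x$links$entity_type == "reaction"),
              x$rounds))
  invisible(x)
}

#' @export
summary.concordance <- function(object, ...) {
  feat_count <- function(m) {
    if (nrow(m) == 0L) return(stats::setNames(integer(), character()))
    feats <- unlist(strsplit(m$features, ",", fixed = TRUE), use.names = FALSE)
    tab <- table(feats)
    stats::setNames(as.integer(tab), names(tab))
  }
  out <- list(
    db_a = object$db_a_name, db_b = object$db_b_name,
    n_compound_links = sum(object$links$entity_type == "compound"),
    n_reaction_links = sum(object$links$entity_type == "reaction"),
    n_inferred_compound = nrow(object$compound_matches),
    n_inferred_reaction = nrow(object$reaction_matches),
    compound_features = feat_count(object$compound_matches),
    reaction_features = feat_count(object$reaction_matches),
    n_compound_contradictions = NROW(object$contradictions$compound),
    n_reaction_contradictions = NROW(object$contradictions$reaction),
    rounds = object$rounds)
  class(out) <- "summary.concordance"
  out
}

#' @export
print.summary.concordance <- function(x, ...) {
  cat(sprintf("Concordance of %s and %s (%d rounds)\n", x$db_a, x$db_b, x$rounds))
  cat(sprintf("  compound links: %d (%d inferred; contradictions voided %d pairs)\n",
              x$n_compound_links, x$n_inferred_compound, x$n_compound_contradictions))
  if (length(x$compound_features) > 0L) {
    cat("    features:", paste(names(x$compound_features), x$compound_features,
                               sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  reaction links: %d (%d inferred; contradictions voided %d pairs)\n",
              x$n_reaction_links, x$n_inferred_reaction, x$n_reaction_contradictions))
  if (length(x$reaction_features) > 0L) {
    cat("    features:", paste(names(x$reaction_features), x$reaction_features,
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
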