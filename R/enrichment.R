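#' Hypergeometric tail probability
#'
#' One-sided Fisher-exact tail for a 2x2 margin: the probability that a
#' hypergeometric draw (population `N`, `K` marked, `n` drawn) yields at
#' least (`GE`) or at most (`LE`) `k` marked elements.
#'
#' @param k observed marked count in the draw.
#' @param K marked population size.
#' @param n draw size.
#' @param N population size.
#' @param tail `"GE"` for enrichment, `"LE"` for depletion.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N, tail = c("GE", "LE")) {
  tail <- match.arg(tail)
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N)) {
    stop("hypergeom_tail: inconsistent margins")
  }
  if (k > K) {
    if (tail == "GE") return(0) else return(1)
  }
  if (tail == "GE") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' Transitive reaction sets of pathway classes
#'
#' A class's reaction set is the union over the pathways assigned to it or
#' to any descendant class (the class ontology is a DAG via `parent_ids`),
#' with pathway reaction lists taken transitively through subpathways.
#'
#' @param db a `pathway_db`.
#' @return named list: class id to character vector of reaction ids.
#' @export
class_reaction_sets <- function(db) {
  cls_ids <- names(db$classes)
  parents <- lapply(db$classes, function(cl) cl$parent_ids)
  if (has_cycle(parents)) stop("class ontology contains a cycle")
  ## ancestors of each class (including itself): pathway in class C counts
  ## for C and for every ancestor of C
  ancestors <- stats::setNames(vector("list", length(cls_ids)), cls_ids)
  anc <- function(cid) {
    if (!is.null(ancestors[[cid]])) return(ancestors[[cid]])
    out <- cid
    for (p in parents[[cid]]) {
      if (p %in% cls_ids) out <- union(out, anc(p))
    }
    ancestors[[cid]] <<- out
    out
  }
  for (cid in cls_ids) anc(cid)
  sets <- stats::setNames(replicate(length(cls_ids), character(), simplify = FALSE),
                          cls_ids)
  for (pid in names(db$pathways)) {
    pw <- db$pathways[[pid]]
    if (length(pw$class_ids) == 0L) next
    rxns <- pathway_reactions_transitive(db, pid)
    touched <- unique(unlist(ancestors[intersect(pw$class_ids, cls_ids)],
                             use.names = FALSE))
    for (cid in touched) sets[[cid]] <- union(sets[[cid]], rxns)
  }
  lapply(sets, sort)
}

#' Enrichment configuration
#'
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.025).
#' @param correction `"BONFERRONI"` (multiply by the number of classes
#'   tested, cap at 1) or `"NONE"`.
#' @return an object of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.025, correction = c("BONFERRONI", "NONE")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, correction = match.arg(correction)),
            class = "enrichment_config")
}

#' Pathway-class enrichment/depletion for cross-database reaction links
#'
#' For each pathway class with a non-empty reaction set, tests whether the
#' class contains significantly more (enriched) or fewer (depleted) linked
#' reactions than expected under the hypergeometric null. The background
#' population is the database's pathway reactions; the marked set is those
#' with a link to the other database.
#'
#' @param db database whose ontology is analysed.
#' @param reaction_links correspondence data frame (`a_id`, `b_id`).
#' @param cfg an [enrichment_config()].
#' @param side which side of the link table `db` occupies.
#' @return data frame with columns `class_id`, `class_size_pathways`,
#'   `n_reactions`, `n_linked`, `p_enrich`, `p_deplete`, `p_adjusted`,
#'   `status` (`ENRICHED`, `DEPLETED` or `NS`).
#' @export
enrichment_depletion <- function(db, reaction_links, cfg = enrichment_config(),
                                 side = c("a", "b")) {
  side <- match.arg(side)
  linked_ids <- if (NROW(reaction_links) == 0L) character()
                else if (side == "a") reaction_links$a_id else reaction_links$b_id
  background <- pathway_reaction_set(db)
  N <- length(background)
  K <- sum(background %in% linked_ids)
  sets <- class_reaction_sets(db)
  sets <- Filter(function(s) length(s) > 0L, sets)
  m <- length(sets)
  if (m == 0L || N == 0L) {
    return(data.frame(class_id = character(), class_size_pathways = integer(),
                      n_reactions = integer(), n_linked = integer(),
                      p_enrich = numeric(), p_deplete = numeric(),
                      p_adjusted = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  ## pathway membership per class (transitive over the ontology)
  pwy_count <- vapply(names(sets), function(cid) {
    desc_count_for_class(db, cid)
  }, integer(1))
  rows <- lapply(names(sets), function(cid) {
    s <- intersect(sets[[cid]], background)
    n <- length(s)
    k <- sum(s %in% linked_ids)
    pe <- hypergeom_tail(k, K, n, N, "GE")
    pd <- hypergeom_tail(k, K, n, N, "LE")
    mult <- if (cfg$correction == "BONFERRONI") m else 1L
    pe_adj <- min(1, pe * mult)
    pd_adj <- min(1, pd * mult)
    status <- if (pe_adj <= cfg$alpha) "ENRICHED"
              else if (pd_adj <= cfg$alpha) "DEPLETED"
              else "NS"
    data.frame(class_id = cid, class_size_pathways = pwy_count[[cid]],
               n_reactions = n, n_linked = k,
               p_enrich = pe, p_deplete = pd,
               p_adjusted = min(pe_adj, pd_adj), status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$class_id), , drop = FALSE]
}

## number of pathways assigned to a class or any of its descendants
desc_count_for_class <- function(db, class_id) {
  cls_ids <- names(db$classes)
  children <- stats::setNames(replicate(length(cls_ids), character(), simplify = FALSE),
                              cls_ids)
  for (cid in cls_ids) {
    for (p in db$classes[[cid]]$parent_ids) {
      if (p %in% cls_ids) children[[p]] <- c(children[[p]], cid)
    }
  }
  desc <- class_id
  stack <- children[[class_id]]
  while (length(stack) > 0L) {
    x <- stack[[1L]]; stack <- stack[-1L]
    if (!(x %in% desc)) { desc <- c(desc, x); stack <- c(stack, children[[x]]) }
  }
  sum(vapply(db$pathways, function(pw) any(pw$class_ids %in% desc), logical(1)))
}

#' Uniqueness configuration
#'
#' @param max_linked_fraction a pathway is unique if at most this fraction
#'   of its reactions has links landing inside a single other-database
#'   pathway (inclusive; default 1/3).
#' @param min_taxon_pathways taxa with fewer associated pathways are
#'   excluded from the taxon table (default 50).
#' @return an object of class `uniqueness_config`.
#' @export
uniqueness_config <- function(max_linked_fraction = 1 / 3,
                              min_taxon_pathways = 50L) {
  stopifnot(max_linked_fraction >= 0, max_linked_fraction <= 1,
            min_taxon_pathways >= 0)
  structure(list(max_linked_fraction = max_linked_fraction,
                 min_taxon_pathways = as.integer(min_taxon_pathways)),
            class = "uniqueness_config")
}

#' Is a pathway unique to its database?
#'
#' For each other-database pathway Q, the coverage of Q is the fraction of
#' this pathway's reactions whose linked counterpart is a member of Q
#' (transitively). The pathway is unique iff the best-covering Q still
#' covers at most `max_linked_fraction` of its reactions (inclusive
#' boundary: exactly one third counts as unique).
#'
#' @param db database owning the pathway.
#' @param pathway_id id of a pathway with at least one reaction.
#' @param reaction_links correspondence data frame (`a_id`, `b_id`);
#'   `db` is assumed to be on side `side`.
#' @param other_db the other database.
#' @param cfg a [uniqueness_config()].
#' @param side which link side `db` occupies.
#' @return logical.
#' @export
pathway_unique <- function(db, pathway_id, reaction_links, other_db,
                           cfg = uniqueness_config(), side = c("a", "b")) {
  side <- match.arg(side)
  rxns <- pathway_reactions_transitive(db, pathway_id)
  if (length(rxns) == 0L) stop("pathway ", sQuote(pathway_id), " has no reactions")
  if (NROW(reaction_links) == 0L) return(TRUE)
  own <- if (side == "a") reaction_links$a_id else reaction_links$b_id
  other <- if (side == "a") reaction_links$b_id else reaction_links$a_id
  partner <- stats::setNames(other, own)
  linked_partners <- partner[intersect(rxns, names(partner))]
  if (length(linked_partners) == 0L) return(TRUE)
  best <- 0
  for (qid in names(other_db$pathways)) {
    q_rxns <- pathway_reactions_transitive(other_db, qid)
    cov <- sum(linked_partners %in% q_rxns) / length(rxns)
    if (cov > best) best <- cov
  }
  best <= cfg$max_linked_fraction
}

#' Taxon-level pathway uniqueness table
#'
#' A base pathway counts under taxon `t` if any taxon in its taxonomic
#' range equals `t` or descends from `t`. Rows are restricted to taxa with
#' at least `min_taxon_pathways` associated pathways; the percent-unique
#' column is reported to one decimal.
#'
#' @param db database with taxonomy and base pathways.
#' @param reaction_links correspondence data frame.
#' @param other_db the other database.
#' @param cfg a [uniqueness_config()].
#' @param side which link side `db` occupies.
#' @return data frame (`taxon_id`, `name`, `pathways`, `unique_pathways`,
#'   `pct_unique`) sorted by decreasing pathway count.
#' @export
taxon_uniqueness_table <- function(db, reaction_links, other_db,
                                   cfg = uniqueness_config(), side = c("a", "b")) {
  side <- match.arg(side)
  tax_ids <- names(db$taxa)
  children <- stats::setNames(replicate(length(tax_ids), character(), simplify = FALSE),
                              tax_ids)
  for (tid in tax_ids) {
    p <- db$taxa[[tid]]$parent_id
    if (!is.na(p) && p %in% tax_ids) children[[p]] <- c(children[[p]], tid)
  }
  descendants <- function(tid) {
    out <- tid
    stack <- children[[tid]]
    while (length(stack) > 0L) {
      x <- stack[[1L]]; stack <- stack[-1L]
      out <- c(out, x); stack <- c(stack, children[[x]])
    }
    out
  }
  base_ids <- names(Filter(function(p) p$kind == "BASE", db$pathways))
  uniq <- stats::setNames(vapply(base_ids, function(pid) {
    pathway_unique(db, pid, reaction_links, other_db, cfg, side)
  }, logical(1)), base_ids)
  rows <- lapply(tax_ids, function(tid) {
    desc <- descendants(tid)
    pids <- base_ids[vapply(db$pathways[base_ids], function(pw) {
      any(pw$taxonomic_range %in% desc)
    }, logical(1))]
    n <- length(pids)
    u <- sum(uniq[pids])
    data.frame(taxon_id = tid, name = db$taxa[[tid]]$name,
               pathways = n, unique_pathways = u,
               pct_unique = if (n > 0L) round(100 * u / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$pathways >= cfg$min_taxon_pathways, , drop = FALSE]
  out <- out[order(-out$pathways, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
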