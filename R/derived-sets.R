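## Derived entity sets: pathway reaction sets (transitive through
## subpathways) and substrate sets over reaction scopes.

## reaction ids of one pathway, transitively including subpathways
pathway_reactions_transitive <- function(db, pathway_id) {
  seen <- character()
  out <- character()
  stack <- pathway_id
  while (length(stack) > 0L) {
    pid <- stack[[1L]]
    stack <- stack[-1L]
    if (pid %in% seen) next
    seen <- c(seen, pid)
    pw <- db$pathways[[pid]]
    if (is.null(pw)) stop("unknown pathway id ", sQuote(pid))
    out <- c(out, pw$reaction_ids)
    stack <- c(stack, pw$subpathway_ids)
  }
  unique(out)
}

#' Reactions belonging to pathways of a database
#'
#' Super pathways contribute their directly listed reactions plus,
#' transitively, the reactions of their subpathways.
#'
#' @param db a `pathway_db`.
#' @param kind restrict to pathways of one kind (`"BASE"` or `"SUPER"`);
#'   `NULL` means pathways of any kind.
#' @return a character vector (set) of reaction ids.
#' @export
pathway_reaction_set <- function(db, kind = NULL) {
  pws <- db$pathways
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("BASE", "SUPER"))
    pws <- Filter(function(p) p$kind == kind, pws)
  }
  if (length(pws) == 0L) return(character())
  sort(unique(unlist(lapply(names(pws), function(pid) {
    pathway_reactions_transitive(db, pid)
  }), use.names = FALSE)))
}

#' Substrate sets of a database
#'
#' The union of participant compound ids over a reaction scope: either every
#' reaction in the database, or only reactions belonging to at least one
#' pathway (optionally of a single kind).
#'
#' @param db a `pathway_db`.
#' @param scope `"ALL_REACTIONS"` or `"PATHWAY_REACTIONS"`.
#' @param pathway_kind for the pathway scope, restrict to `"BASE"` or
#'   `"SUPER"` pathways; `NULL` means any kind.
#' @return a character vector (set) of compound ids.
#' @export
substrate_set <- function(db, scope = c("ALL_REACTIONS", "PATHWAY_REACTIONS"),
                          pathway_kind = NULL) {
  scope <- match.arg(scope)
  rids <- if (scope == "ALL_REACTIONS") {
    names(db$reactions)
  } else {
    pathway_reaction_set(db, kind = pathway_kind)
  }
  if (length(rids) == 0L) return(character())
  sort(unique(unlist(lapply(db$reactions[rids], function(r) r$participants$compound_id),
                     use.names = FALSE)))
}
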