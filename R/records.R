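## Record constructors for the pathway-database data model. All records are
## plain lists with a class attribute; collections inside a pathway_db are
## named lists sorted by id so that equality is field-for-field identical().

normalize_links <- function(links) {
  if (is.null(links) || length(links) == 0L) {
    return(stats::setNames(character(), character()))
  }
  if (is.null(names(links)) || any(!nzchar(names(links)))) {
    stop("links must be a named character vector (database name -> foreign id)")
  }
  out <- as.character(links)
  names(out) <- names(links)
  out[order(names(out))]
}

normalize_attributes <- function(attributes) {
  if (is.null(attributes) || length(attributes) == 0L) {
    return(stats::setNames(list(), character()))
  }
  if (is.null(names(attributes)) || any(!nzchar(names(attributes)))) {
    stop("attributes must be a named list (attribute name -> character values)")
  }
  out <- lapply(attributes, as.character)
  out[order(names(out))]
}

chr_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[[1L]])) NA_character_ else as.character(x[[1L]])
}

#' Construct a compound record
#'
#' @param id unique compound identifier within its database.
#' @param common_name primary display name.
#' @param synonyms additional names.
#' @param formula raw molecular formula string, or `NA`.
#' @param inchi full structure string including stereo and proton layers, or `NA`.
#' @param structure_key canonical connectivity+stereo key, or `NA`.
#' @param protonation_invariant_key structure key with proton/charge
#'   information removed, or `NA`.
#' @param fingerprint integer vector of set bit positions, or `NULL`.
#' @param links named character vector of cross-database links.
#' @param comment free-text comment or `NA`.
#' @param is_class `TRUE` for generic substrate classes.
#' @param attributes named list of free-form attribute values (used by
#'   coverage statistics).
#' @return an object of class `compound_record`.
#' @export
compound_record <- function(id, common_name = id, synonyms = character(),
                            formula = NA_character_, inchi = NA_character_,
                            structure_key = NA_character_,
                            protonation_invariant_key = NA_character_,
                            fingerprint = NULL, links = NULL,
                            comment = NA_character_, is_class = FALSE,
                            attributes = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("compound_record: id must be a non-empty string")
  }
  fp <- if (is.null(fingerprint) || length(fingerprint) == 0L) {
    NULL
  } else {
    fp <- sort(unique(as.integer(fingerprint)))
    if (any(fp < 0L)) stop("compound_record: fingerprint bits must be non-negative")
    fp
  }
  structure(list(
    id = id,
    common_name = as.character(common_name),
    synonyms = as.character(synonyms),
    formula = chr_or_na(formula),
    inchi = chr_or_na(inchi),
    structure_key = chr_or_na(structure_key),
    protonation_invariant_key = chr_or_na(protonation_invariant_key),
    fingerprint = fp,
    links = normalize_links(links),
    comment = chr_or_na(comment),
    is_class = isTRUE(is_class),
    attributes = normalize_attributes(attributes)
  ), class = "compound_record")
}

#' Construct a reaction participant table
#'
#' Participants are held as a data frame with columns `compound_id`,
#' `coefficient` and `side` (`"LEFT"` or `"RIGHT"`). Duplicate participant
#' rows on the same side are merged by summing coefficients.
#'
#' @param compound_id character vector of compound ids.
#' @param coefficient positive integer coefficients (recycled).
#' @param side `"LEFT"` or `"RIGHT"` per participant.
#' @return a normalized participant data frame.
#' @export
reaction_participants <- function(compound_id, coefficient = 1L, side) {
  df <- data.frame(compound_id = as.character(compound_id),
                   coefficient = as.integer(coefficient),
                   side = as.character(side),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (!all(df$side %in% c("LEFT", "RIGHT"))) {
      stop("participant side must be LEFT or RIGHT")
    }
    if (any(is.na(df$coefficient)) || any(df$coefficient < 1L)) {
      stop("participant coefficients must be integers >= 1")
    }
    key <- paste(df$side, df$compound_id, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- vapply(split(df$coefficient, key), sum, integer(1))
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$coefficient <- as.integer(agg[paste(df$side, df$compound_id, sep = "\r")])
    }
    df <- df[order(df$side != "LEFT", df$compound_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Construct a reaction record
#'
#' @param id unique reaction identifier.
#' @param participants participant data frame from [reaction_participants()].
#' @param ec_numbers dotted EC number strings (partial forms allowed).
#' @param uniprot_accessions UniProt accession strings.
#' @param activity_names enzymatic activity names.
#' @param direction one of `LEFT-TO-RIGHT`, `RIGHT-TO-LEFT`, `REVERSIBLE`,
#'   `UNKNOWN`.
#' @param spontaneous logical flag or `NA`.
#' @param links,comment,attributes as for [compound_record()].
#' @return an object of class `reaction_record`. The `is_generic` flag is
#'   filled in during database validation (it depends on the compound table).
#' @export
reaction_record <- function(id, participants, ec_numbers = character(),
                            uniprot_accessions = character(),
                            activity_names = character(),
                            direction = "UNKNOWN", spontaneous = NA,
                            links = NULL, comment = NA_character_,
                            attributes = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction_record: id must be a non-empty string")
  }
  if (missing(participants) || !is.data.frame(participants)) {
    stop("reaction_record: participants must be a data frame")
  }
  participants <- reaction_participants(participants$compound_id,
                                        participants$coefficient,
                                        participants$side)
  direction <- match.arg(direction,
                         c("LEFT-TO-RIGHT", "RIGHT-TO-LEFT", "REVERSIBLE", "UNKNOWN"))
  structure(list(
    id = id,
    participants = participants,
    ec_numbers = as.character(ec_numbers),
    uniprot_accessions = as.character(uniprot_accessions),
    activity_names = as.character(activity_names),
    direction = direction,
    spontaneous = as.logical(spontaneous),
    links = normalize_links(links),
    comment = chr_or_na(comment),
    attributes = normalize_attributes(attributes),
    is_generic = NA
  ), class = "reaction_record")
}

#' Construct a pathway record
#'
#' @param id unique pathway identifier.
#' @param kind `"BASE"` (an individual pathway; rendered as a KEGG-style
#'   module) or `"SUPER"` (a composite of base pathways plus extra
#'   reactions; a KEGG-style map).
#' @param reaction_ids reactions directly listed in the pathway.
#' @param subpathway_ids component pathways (`SUPER` only).
#' @param class_ids pathway-class ontology nodes this pathway belongs to.
#' @param taxonomic_range taxon ids in which the pathway is expected.
#' @param links,comment,attributes as for [compound_record()].
#' @return an object of class `pathway_record`.
#' @export
pathway_record <- function(id, kind = c("BASE", "SUPER"),
                           reaction_ids = character(),
                           subpathway_ids = character(),
                           class_ids = character(),
                           taxonomic_range = character(),
                           links = NULL, comment = NA_character_,
                           attributes = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("pathway_record: id must be a non-empty string")
  }
  kind <- match.arg(kind)
  structure(list(
    id = id,
    kind = kind,
    reaction_ids = as.character(reaction_ids),
    subpathway_ids = as.character(subpathway_ids),
    class_ids = as.character(class_ids),
    taxonomic_range = as.character(taxonomic_range),
    links = normalize_links(links),
    comment = chr_or_na(comment),
    attributes = normalize_attributes(attributes)
  ), class = "pathway_record")
}

#' Construct a pathway-class ontology node
#'
#' @param id class identifier.
#' @param name display name.
#' @param parent_ids parent class ids (empty for roots). The class graph must
#'   be acyclic.
#' @return an object of class `class_node`.
#' @export
class_node <- function(id, name = id, parent_ids = character()) {
  structure(list(id = as.character(id), name = as.character(name),
                 parent_ids = as.character(parent_ids)),
            class = "class_node")
}

#' Construct a taxonomy node
#'
#' @param id taxon id (numeric NCBI-style id as a string).
#' @param name taxon name.
#' @param parent_id parent taxon id, or `NA` for the root.
#' @return an object of class `taxon_node`.
#' @export
taxon_node <- function(id, name = id, parent_id = NA_character_) {
  structure(list(id = as.character(id), name = as.character(name),
                 parent_id = chr_or_na(parent_id)),
            class = "taxon_node")
}

as_keyed_collection <- function(records, what) {
  if (length(records) == 0L) {
    return(stats::setNames(list(), character()))
  }
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(records) <- ids
  records[order(ids)]
}

#' Assemble and validate a pathway database
#'
#' Checks referential integrity across all collections (reaction participants
#' resolve to compounds, pathway reaction/subpathway/class/taxon references
#' resolve, the class graph is acyclic, the taxonomy is a rooted tree) and
#' derives each reaction's `is_generic` flag (`TRUE` iff any participant is a
#' compound class).
#'
#' @param name database name.
#' @param compounds,reactions,pathways,classes,taxa lists of the respective
#'   record objects.
#' @return an object of class `pathway_db`.
#' @export
pathway_db <- function(name, compounds = list(), reactions = list(),
                       pathways = list(), classes = list(), taxa = list()) {
  db <- structure(list(
    name = as.character(name),
    compounds = as_keyed_collection(compounds, "compound"),
    reactions = as_keyed_collection(reactions, "reaction"),
    pathways = as_keyed_collection(pathways, "pathway"),
    classes = as_keyed_collection(classes, "class"),
    taxa = as_keyed_collection(taxa, "taxon")
  ), class = "pathway_db")
  validate_pathway_db(db)
}

#' Validate a pathway database
#'
#' @param db a `pathway_db`.
#' @return the database, with derived flags filled in; errors list every
#'   offending id on failure.
#' @export
validate_pathway_db <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  problems <- character()
  cpd_ids <- names(db$compounds)
  rxn_ids <- names(db$reactions)
  pwy_ids <- names(db$pathways)
  cls_ids <- names(db$classes)
  tax_ids <- names(db$taxa)

  is_class_cpd <- vapply(db$compounds, function(c) isTRUE(c$is_class), logical(1))

  for (rid in rxn_ids) {
    r <- db$reactions[[rid]]
    p <- r$participants
    missing <- setdiff(unique(p$compound_id), cpd_ids)
    if (length(missing) > 0L) {
      problems <- c(problems, sprintf(
        "reaction %s references unknown compound(s): %s",
        rid, paste(missing, collapse = ", ")))
    }
    if (!any(p$side == "LEFT") || !any(p$side == "RIGHT")) {
      ## degenerate reaction: tolerated but flagged via attribute
      a <- db$reactions[[rid]]$attributes
      if (!("DEGENERATE" %in% names(a))) {
        a[["DEGENERATE"]] <- "T"
        db$reactions[[rid]]$attributes <- a[order(names(a))]
      }
    }
    known <- intersect(unique(p$compound_id), cpd_ids)
    db$reactions[[rid]]$is_generic <-
      length(known) > 0L && any(is_class_cpd[known])
  }

  for (pid in pwy_ids) {
    pw <- db$pathways[[pid]]
    bad_r <- setdiff(pw$reaction_ids, rxn_ids)
    if (length(bad_r) > 0L) {
      problems <- c(problems, sprintf("pathway %s references unknown reaction(s): %s",
                                      pid, paste(bad_r, collapse = ", ")))
    }
    bad_s <- setdiff(pw$subpathway_ids, pwy_ids)
    if (length(bad_s) > 0L) {
      problems <- c(problems, sprintf("pathway %s references unknown subpathway(s): %s",
                                      pid, paste(bad_s, collapse = ", ")))
    }
    bad_c <- setdiff(pw$class_ids, cls_ids)
    if (length(bad_c) > 0L) {
      problems <- c(problems, sprintf("pathway %s references unknown class(es): %s",
                                      pid, paste(bad_c, collapse = ", ")))
    }
    bad_t <- setdiff(pw$taxonomic_range, tax_ids)
    if (length(bad_t) > 0L) {
      problems <- c(problems, sprintf("pathway %s references unknown taxon(s): %s",
                                      pid, paste(bad_t, collapse = ", ")))
    }
    if (pw$kind == "BASE") {
      if (length(pw$subpathway_ids) > 0L) {
        problems <- c(problems, sprintf("base pathway %s lists subpathways", pid))
      }
      if (length(pw$reaction_ids) == 0L) {
        problems <- c(problems, sprintf("base pathway %s has no reactions", pid))
      }
    }
  }

  for (cid in cls_ids) {
    bad <- setdiff(db$classes[[cid]]$parent_ids, cls_ids)
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf("class %s references unknown parent(s): %s",
                                      cid, paste(bad, collapse = ", ")))
    }
  }
  if (length(cls_ids) > 0L && length(problems) == 0L) {
    parents <- lapply(db$classes, function(cl) cl$parent_ids)
    if (has_cycle(parents)) problems <- c(problems, "class ontology contains a cycle")
  }

  for (tid in tax_ids) {
    par <- db$taxa[[tid]]$parent_id
    if (!is.na(par) && !(par %in% tax_ids)) {
      problems <- c(problems, sprintf("taxon %s references unknown parent %s", tid, par))
    }
  }
  if (length(tax_ids) > 0L && length(problems) == 0L) {
    parents <- lapply(db$taxa, function(t) if (is.na(t$parent_id)) character() else t$parent_id)
    if (has_cycle(parents)) problems <- c(problems, "taxonomy contains a cycle")
  }

  if (length(problems) > 0L) {
    stop("invalid pathway database ", sQuote(db$name), ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  db
}

## detect a cycle in a parent-edge map (named list: node -> parent ids)
has_cycle <- function(parents) {
  state <- stats::setNames(integer(length(parents)), names(parents)) # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) return(TRUE)
    if (state[[id]] == 2L) return(FALSE)
    state[[id]] <<- 1L
    for (p in parents[[id]]) {
      if (p %in% names(parents) && visit(p)) return(TRUE)
    }
    state[[id]] <<- 2L
    FALSE
  }
  for (id in names(parents)) if (visit(id)) return(TRUE)
  FALSE
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db %s: %d compounds, %d reactions, %d pathways, %d classes, %d taxa>\n",
              sQuote(x$name), length(x$compounds), length(x$reactions),
              length(x$pathways), length(x$classes), length(x$taxa)))
  invisible(x)
}
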