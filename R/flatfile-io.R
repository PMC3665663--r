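## Attribute-value flat-file dialect, modeled on BioCyc-style .dat files.
##
## Record grammar: lines "ATTRIBUTE - VALUE"; record terminator "//";
## comment lines start with "#"; UTF-8. Reaction participants are encoded as
## "LEFT - <compound-id>" / "RIGHT - <compound-id>" with an optional
## continuation line "COEFFICIENT - <int>" applying to the preceding
## participant (default 1). Fingerprints are sorted comma-separated bit
## indices. DBLINKS values are "<db-name>:<foreign-id>".

DB_FILES <- c(compounds = "compounds.dat", reactions = "reactions.dat",
              pathways = "pathways.dat", classes = "classes.dat",
              taxonomy = "taxonomy.dat")

## parse one .dat file into a list of records; each record is a data frame
## (attr, value, line) preserving line order for continuation semantics.
read_attr_value_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list()
  cur_attr <- character()
  cur_val <- character()
  cur_line <- integer()
  flush <- function() {
    if (length(cur_attr) > 0L) {
      records[[length(records) + 1L]] <<- data.frame(
        attr = cur_attr, value = cur_val, line = cur_line,
        stringsAsFactors = FALSE)
    }
    cur_attr <<- character(); cur_val <<- character(); cur_line <<- integer()
  }
  for (i in seq_along(lines)) {
    line <- sub("[ \t\r]+$", "", lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "//") { flush(); next }
    m <- regexpr(" - ", line, fixed = TRUE)
    if (m == -1L) {
      stop(sprintf("%s:%d: malformed line (expected 'ATTRIBUTE - VALUE' or '//'): %s",
                   basename(path), i, sQuote(line)), call. = FALSE)
    }
    cur_attr <- c(cur_attr, substr(line, 1L, m - 1L))
    cur_val <- c(cur_val, substr(line, m + 3L, nchar(line)))
    cur_line <- c(cur_line, i)
  }
  flush()
  records
}

## pull values for one attribute, in file order
rec_values <- function(rec, attr) rec$value[rec$attr == attr]

rec_value1 <- function(rec, attr) {
  v <- rec_values(rec, attr)
  if (length(v) == 0L) NA_character_ else v[[1L]]
}

rec_unique_id <- function(rec, path) {
  id <- rec_value1(rec, "UNIQUE-ID")
  if (is.na(id)) {
    stop(sprintf("%s:%d: record is missing UNIQUE-ID", basename(path), rec$line[[1L]]),
         call. = FALSE)
  }
  id
}

parse_dblinks <- function(values, path, line) {
  if (length(values) == 0L) return(NULL)
  parts <- regmatches(values, regexpr(":", values, fixed = TRUE), invert = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop(sprintf("%s:%d: malformed DBLINKS value %s (expected '<db>:<id>')",
                 basename(path), line, sQuote(values[bad][[1L]])), call. = FALSE)
  }
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}

## attributes handled structurally per record kind; everything else is
## preserved in the free-form `attributes` map
KNOWN_ATTRS <- list(
  compound = c("UNIQUE-ID", "COMMON-NAME", "SYNONYMS", "CHEMICAL-FORMULA",
               "INCHI", "STRUCTURE-KEY", "PROTONATION-INVARIANT-KEY",
               "FINGERPRINT", "IS-CLASS", "DBLINKS", "COMMENT"),
  reaction = c("UNIQUE-ID", "LEFT", "RIGHT", "COEFFICIENT", "EC-NUMBER",
               "UNIPROT", "ACTIVITY-NAME", "DIRECTION", "SPONTANEOUS",
               "DBLINKS", "COMMENT"),
  pathway = c("UNIQUE-ID", "KIND", "REACTION-LIST", "SUBPATHWAYS",
              "CLASS-LIST", "TAXONOMIC-RANGE", "DBLINKS", "COMMENT"),
  class = c("UNIQUE-ID", "COMMON-NAME", "PARENT"),
  taxon = c("UNIQUE-ID", "COMMON-NAME", "PARENT")
)

extra_attributes <- function(rec, kind) {
  extra <- rec[!(rec$attr %in% KNOWN_ATTRS[[kind]]), , drop = FALSE]
  if (nrow(extra) == 0L) return(NULL)
  split(extra$value, extra$attr)
}

parse_compound_record <- function(rec, path) {
  fp_raw <- rec_value1(rec, "FINGERPRINT")
  fp <- if (is.na(fp_raw) || !nzchar(fp_raw)) NULL else as.integer(strsplit(fp_raw, ",", fixed = TRUE)[[1L]])
  compound_record(
    id = rec_unique_id(rec, path),
    common_name = { cn <- rec_value1(rec, "COMMON-NAME"); if (is.na(cn)) rec_unique_id(rec, path) else cn },
    synonyms = rec_values(rec, "SYNONYMS"),
    formula = rec_value1(rec, "CHEMICAL-FORMULA"),
    inchi = rec_value1(rec, "INCHI"),
    structure_key = rec_value1(rec, "STRUCTURE-KEY"),
    protonation_invariant_key = rec_value1(rec, "PROTONATION-INVARIANT-KEY"),
    fingerprint = fp,
    links = parse_dblinks(rec_values(rec, "DBLINKS"), path, rec$line[[1L]]),
    comment = rec_value1(rec, "COMMENT"),
    is_class = identical(rec_value1(rec, "IS-CLASS"), "T"),
    attributes = extra_attributes(rec, "compound")
  )
}

parse_reaction_record <- function(rec, path) {
  id <- rec_unique_id(rec, path)
  sides <- character(); cpds <- character(); coefs <- integer()
  for (i in seq_len(nrow(rec))) {
    a <- rec$attr[[i]]
    if (a %in% c("LEFT", "RIGHT")) {
      sides <- c(sides, a); cpds <- c(cpds, rec$value[[i]]); coefs <- c(coefs, 1L)
    } else if (a == "COEFFICIENT") {
      if (length(coefs) == 0L) {
        stop(sprintf("%s:%d: COEFFICIENT with no preceding LEFT/RIGHT line",
                     basename(path), rec$line[[i]]), call. = FALSE)
      }
      k <- suppressWarnings(as.integer(rec$value[[i]]))
      if (is.na(k) || k < 1L) {
        stop(sprintf("%s:%d: invalid COEFFICIENT %s", basename(path),
                     rec$line[[i]], sQuote(rec$value[[i]])), call. = FALSE)
      }
      coefs[[length(coefs)]] <- k
    }
  }
  spont_raw <- rec_value1(rec, "SPONTANEOUS")
  reaction_record(
    id = id,
    participants = reaction_participants(cpds, coefs, sides),
    ec_numbers = rec_values(rec, "EC-NUMBER"),
    uniprot_accessions = rec_values(rec, "UNIPROT"),
    activity_names = rec_values(rec, "ACTIVITY-NAME"),
    direction = { d <- rec_value1(rec, "DIRECTION"); if (is.na(d)) "UNKNOWN" else d },
    spontaneous = if (is.na(spont_raw)) NA else identical(spont_raw, "T"),
    links = parse_dblinks(rec_values(rec, "DBLINKS"), path, rec$line[[1L]]),
    comment = rec_value1(rec, "COMMENT"),
    attributes = extra_attributes(rec, "reaction")
  )
}

parse_pathway_record <- function(rec, path) {
  pathway_record(
    id = rec_unique_id(rec, path),
    kind = { k <- rec_value1(rec, "KIND"); if (is.na(k)) "BASE" else k },
    reaction_ids = rec_values(rec, "REACTION-LIST"),
    subpathway_ids = rec_values(rec, "SUBPATHWAYS"),
    class_ids = rec_values(rec, "CLASS-LIST"),
    taxonomic_range = rec_values(rec, "TAXONOMIC-RANGE"),
    links = parse_dblinks(rec_values(rec, "DBLINKS"), path, rec$line[[1L]]),
    comment = rec_value1(rec, "COMMENT"),
    attributes = extra_attributes(rec, "pathway")
  )
}

parse_class_record <- function(rec, path) {
  id <- rec_unique_id(rec, path)
  nm <- rec_value1(rec, "COMMON-NAME")
  class_node(id, name = if (is.na(nm)) id else nm,
             parent_ids = rec_values(rec, "PARENT"))
}

parse_taxon_record <- function(rec, path) {
  id <- rec_unique_id(rec, path)
  nm <- rec_value1(rec, "COMMON-NAME")
  taxon_node(id, name = if (is.na(nm)) id else nm,
             parent_id = rec_value1(rec, "PARENT"))
}

#' Read a pathway database from a flat-file directory
#'
#' The directory must contain `compounds.dat`, `reactions.dat` and
#' `pathways.dat`; `classes.dat` and `taxonomy.dat` are optional. The loaded
#' database is validated (see [validate_pathway_db()]).
#'
#' @param dir directory path.
#' @param name database name; defaults to the directory basename.
#' @return a validated [pathway_db()].
#' @export
read_pathway_db <- function(dir, name = basename(normalizePath(dir, mustWork = FALSE))) {
  mandatory <- DB_FILES[c("compounds", "reactions", "pathways")]
  for (f in mandatory) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("cannot load pathway database from %s: missing mandatory file %s",
                   dir, sQuote(f)), call. = FALSE)
    }
  }
  read_kind <- function(file, parser) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(list())
    lapply(read_attr_value_file(path), parser, path = path)
  }
  pathway_db(
    name = name,
    compounds = read_kind(DB_FILES[["compounds"]], parse_compound_record),
    reactions = read_kind(DB_FILES[["reactions"]], parse_reaction_record),
    pathways = read_kind(DB_FILES[["pathways"]], parse_pathway_record),
    classes = read_kind(DB_FILES[["classes"]], parse_class_record),
    taxa = read_kind(DB_FILES[["taxonomy"]], parse_taxon_record)
  )
}

emit_attr <- function(attr, values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(character())
  paste(attr, "-", values)
}

emit_links <- function(links) {
  if (length(links) == 0L) return(character())
  emit_attr("DBLINKS", paste0(names(links), ":", links))
}

emit_extra <- function(attributes) {
  if (length(attributes) == 0L) return(character())
  unlist(lapply(sort(names(attributes)), function(a) emit_attr(a, attributes[[a]])),
         use.names = FALSE)
}

serialize_compound <- function(c) {
  c(emit_attr("UNIQUE-ID", c$id),
    emit_attr("COMMON-NAME", c$common_name),
    emit_attr("SYNONYMS", c$synonyms),
    emit_attr("CHEMICAL-FORMULA", c$formula),
    emit_attr("INCHI", c$inchi),
    emit_attr("STRUCTURE-KEY", c$structure_key),
    emit_attr("PROTONATION-INVARIANT-KEY", c$protonation_invariant_key),
    if (!is.null(c$fingerprint)) emit_attr("FINGERPRINT", paste(c$fingerprint, collapse = ",")),
    if (isTRUE(c$is_class)) emit_attr("IS-CLASS", "T"),
    emit_links(c$links),
    emit_attr("COMMENT", c$comment),
    emit_extra(c$attributes),
    "//")
}

serialize_reaction <- function(r) {
  p <- r$participants
  part_lines <- character()
  for (i in seq_len(nrow(p))) {
    part_lines <- c(part_lines, paste(p$side[[i]], "-", p$compound_id[[i]]))
    if (p$coefficient[[i]] != 1L) {
      part_lines <- c(part_lines, paste("COEFFICIENT", "-", p$coefficient[[i]]))
    }
  }
  c(emit_attr("UNIQUE-ID", r$id),
    part_lines,
    emit_attr("EC-NUMBER", r$ec_numbers),
    emit_attr("UNIPROT", r$uniprot_accessions),
    emit_attr("ACTIVITY-NAME", r$activity_names),
    if (r$direction != "UNKNOWN") emit_attr("DIRECTION", r$direction),
    if (!is.na(r$spontaneous)) emit_attr("SPONTANEOUS", if (r$spontaneous) "T" else "F"),
    emit_links(r$links),
    emit_attr("COMMENT", r$comment),
    emit_extra(r$attributes),
    "//")
}

serialize_pathway <- function(pw) {
  c(emit_attr("UNIQUE-ID", pw$id),
    emit_attr("KIND", pw$kind),
    emit_attr("REACTION-LIST", pw$reaction_ids),
    emit_attr("SUBPATHWAYS", pw$subpathway_ids),
    emit_attr("CLASS-LIST", pw$class_ids),
    emit_attr("TAXONOMIC-RANGE", pw$taxonomic_range),
    emit_links(pw$links),
    emit_attr("COMMENT", pw$comment),
    emit_extra(pw$attributes),
    "//")
}

serialize_class <- function(cl) {
  c(emit_attr("UNIQUE-ID", cl$id),
    emit_attr("COMMON-NAME", cl$name),
    emit_attr("PARENT", cl$parent_ids),
    "//")
}

serialize_taxon <- function(t) {
  c(emit_attr("UNIQUE-ID", t$id),
    emit_attr("COMMON-NAME", t$name),
    emit_attr("PARENT", t$parent_id),
    "//")
}

#' Write a pathway database to a flat-file directory
#'
#' Emits the attribute-value dialect read by [read_pathway_db()], with
#' deterministic record ordering (sorted by id) so that two writes of the
#' same database are byte-identical.
#'
#' @param db a validated `pathway_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pathway_db <- function(db, dir) {
  stopifnot(inherits(db, "pathway_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_file <- function(records, serializer, file) {
    lines <- unlist(lapply(records, serializer), use.names = FALSE)
    if (is.null(lines)) lines <- character()
    con <- file(file.path(dir, file), open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  ## collections are already sorted by id
  write_file(db$compounds, serialize_compound, DB_FILES[["compounds"]])
  write_file(db$reactions, serialize_reaction, DB_FILES[["reactions"]])
  write_file(db$pathways, serialize_pathway, DB_FILES[["pathways"]])
  write_file(db$classes, serialize_class, DB_FILES[["classes"]])
  write_file(db$taxa, serialize_taxon, DB_FILES[["taxonomy"]])
  invisible(dir)
}
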