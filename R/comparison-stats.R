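#' Jaccard coefficient from set margins
#'
#' @param n_a,n_b sizes of the two sets.
#' @param common size of their intersection.
#' @return `common / (n_a + n_b - common)`.
#' @export
jaccard <- function(n_a, n_b, common) {
  if (common > min(n_a, n_b)) stop("jaccard: common exceeds a set size")
  if (n_a + n_b == 0) stop("jaccard: undefined for two empty sets")
  common / (n_a + n_b - common)
}

#' Entity overlap table for two databases
#'
#' One row per category (all compounds, reaction substrates, pathway
#' reaction substrates, all reactions, pathway reactions) with per-database
#' counts, per-pathway-kind sub-counts where applicable, the number of
#' correspondence pairs with both ends inside the category's sets
#' (`common`), and the Jaccard coefficient.
#'
#' @param db_a,db_b the two databases.
#' @param compound_links,reaction_links one-to-one correspondence data
#'   frames with columns `a_id`, `b_id`.
#' @return a data frame with columns `category`, `n_a`, `n_a_base`,
#'   `n_a_super`, `n_b`, `n_b_base`, `n_b_super`, `common`, `jaccard`.
#' @export
overlap_table <- function(db_a, db_b, compound_links, reaction_links) {
  common_in <- function(links, set_a, set_b) {
    if (NROW(links) == 0L) return(0L)
    sum(links$a_id %in% set_a & links$b_id %in% set_b)
  }
  row_for <- function(category, set_a, set_b, links,
                      sub_a_base = NA, sub_a_super = NA,
                      sub_b_base = NA, sub_b_super = NA) {
    common <- common_in(links, set_a, set_b)
    data.frame(category = category,
               n_a = length(set_a),
               n_a_base = sub_a_base, n_a_super = sub_a_super,
               n_b = length(set_b),
               n_b_base = sub_b_base, n_b_super = sub_b_super,
               common = common,
               jaccard = if (length(set_a) + length(set_b) == 0L) NA_real_
                         else jaccard(length(set_a), length(set_b), common),
               stringsAsFactors = FALSE)
  }
  cl <- compound_links
  rl <- reaction_links

  all_a <- names(db_a$compounds); all_b <- names(db_b$compounds)
  sub_a <- substrate_set(db_a, "ALL_REACTIONS")
  sub_b <- substrate_set(db_b, "ALL_REACTIONS")
  psub_a <- substrate_set(db_a, "PATHWAY_REACTIONS")
  psub_b <- substrate_set(db_b, "PATHWAY_REACTIONS")
  rxn_a <- names(db_a$reactions); rxn_b <- names(db_b$reactions)
  prxn_a <- pathway_reaction_set(db_a)
  prxn_b <- pathway_reaction_set(db_b)

  rbind(
    row_for("ALL_COMPOUNDS", all_a, all_b, cl),
    row_for("REACTION_SUBSTRATES", sub_a, sub_b, cl),
    row_for("PATHWAY_REACTION_SUBSTRATES", psub_a, psub_b, cl,
            sub_a_base = length(substrate_set(db_a, "PATHWAY_REACTIONS", "BASE")),
            sub_a_super = length(substrate_set(db_a, "PATHWAY_REACTIONS", "SUPER")),
            sub_b_base = length(substrate_set(db_b, "PATHWAY_REACTIONS", "BASE")),
            sub_b_super = length(substrate_set(db_b, "PATHWAY_REACTIONS", "SUPER"))),
    row_for("ALL_REACTIONS", rxn_a, rxn_b, rl),
    row_for("PATHWAY_REACTIONS", prxn_a, prxn_b, rl,
            sub_a_base = length(pathway_reaction_set(db_a, "BASE")),
            sub_a_super = length(pathway_reaction_set(db_a, "SUPER")),
            sub_b_base = length(pathway_reaction_set(db_b, "BASE")),
            sub_b_super = length(pathway_reaction_set(db_b, "SUPER")))
  )
}

#' Attribute coverage table
#'
#' Counts, per free-form attribute, how many objects of one entity kind
#' carry at least one value, keeping attributes reaching the threshold.
#'
#' @param db a `pathway_db`.
#' @param entity `"compound"`, `"reaction"` or `"pathway"`.
#' @param min_objects minimum number of carrying objects (default 100).
#' @return data frame (`attribute`, `count`), sorted by decreasing count
#'   then attribute name.
#' @export
attribute_coverage <- function(db, entity = c("compound", "reaction", "pathway"),
                               min_objects = 100L) {
  entity <- match.arg(entity)
  records <- switch(entity, compound = db$compounds,
                    reaction = db$reactions, pathway = db$pathways)
  counts <- new.env(parent = emptyenv())
  for (r in records) {
    for (a in names(r$attributes)) {
      if (length(r$attributes[[a]]) > 0L) {
        counts[[a]] <- (if (is.null(counts[[a]])) 0L else counts[[a]]) + 1L
      }
    }
  }
  attrs <- ls(counts)
  df <- data.frame(attribute = attrs,
                   count = vapply(attrs, function(a) counts[[a]], integer(1)),
                   stringsAsFactors = FALSE)
  df <- df[df$count >= min_objects, , drop = FALSE]
  df <- df[order(-df$count, df$attribute), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summary statistics of a database
#'
#' Arithmetic means over the conventional denominators: names per compound
#' over all compounds (common name plus synonyms); comment length in
#' characters over commented objects only; associated reactions per
#' compound over all compounds; reactions and compounds per pathway, per
#' pathway kind (transitive through subpathways). Undefined means (empty
#' denominators) are reported as `NA`.
#'
#' @param db a `pathway_db`.
#' @return a nested list of means and counts.
#' @export
summary_stats <- function(db) {
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  cpds <- db$compounds
  rxns <- db$reactions

  names_per_compound <- vapply(cpds, function(c) 1L + length(c$synonyms), integer(1))
  comment_lengths <- function(records) {
    cm <- vapply(records, function(r) r$comment, character(1))
    nchar(cm[!is.na(cm)])
  }
  rxn_per_cpd <- {
    tallies <- stats::setNames(integer(length(cpds)), names(cpds))
    for (r in rxns) {
      ids <- unique(r$participants$compound_id)
      tallies[ids] <- tallies[ids] + 1L
    }
    tallies
  }
  pwy_rxn_sets <- lapply(names(db$pathways), function(pid) {
    pathway_reactions_transitive(db, pid)
  })
  names(pwy_rxn_sets) <- names(db$pathways)
  pwy_per_rxn <- {
    tallies <- stats::setNames(integer(length(rxns)), names(rxns))
    for (s in pwy_rxn_sets) tallies[s] <- tallies[s] + 1L
    tallies
  }
  pwy_per_cpd <- {
    tallies <- stats::setNames(integer(length(cpds)), names(cpds))
    for (s in pwy_rxn_sets) {
      ids <- unique(unlist(lapply(db$reactions[s], function(r) r$participants$compound_id),
                           use.names = FALSE))
      tallies[ids] <- tallies[ids] + 1L
    }
    tallies
  }
  per_kind <- function(kind) {
    pids <- names(Filter(function(p) p$kind == kind, db$pathways))
    sizes <- vapply(pwy_rxn_sets[pids], length, integer(1))
    cpd_sizes <- vapply(pids, function(pid) {
      length(unique(unlist(lapply(db$reactions[pwy_rxn_sets[[pid]]],
                                  function(r) r$participants$compound_id),
                           use.names = FALSE)))
    }, integer(1))
    list(count = length(pids),
         reactions_per_pathway = mean_or_na(unname(sizes)),
         compounds_per_pathway = mean_or_na(unname(cpd_sizes)))
  }
  list(
    compounds = list(
      count = length(cpds),
      with_comments = length(comment_lengths(cpds)),
      mean_names = mean_or_na(unname(names_per_compound)),
      mean_comment_length = mean_or_na(comment_lengths(cpds)),
      mean_associated_reactions = mean_or_na(unname(rxn_per_cpd)),
      mean_associated_pathways = mean_or_na(unname(pwy_per_cpd))
    ),
    reactions = list(
      count = length(rxns),
      with_comments = length(comment_lengths(rxns)),
      mean_comment_length = mean_or_na(comment_lengths(rxns)),
      mean_associated_pathways = mean_or_na(unname(pwy_per_rxn))
    ),
    pathways = list(
      count = length(db$pathways),
      with_comments = length(comment_lengths(db$pathways)),
      mean_comment_length = mean_or_na(comment_lengths(db$pathways)),
      base = per_kind("BASE"),
      super = per_kind("SUPER")
    )
  )
}

#' Pathway size histogram
#'
#' Frequencies of pathway sizes (reaction counts, transitive through
#' subpathways) for pathways of one kind, with optional exclusion of
#' outlier pathways.
#'
#' @param db a `pathway_db`.
#' @param kind `"BASE"` or `"SUPER"`.
#' @param bin_width histogram bin width in reactions (default 1).
#' @param exclude pathway ids omitted from the histogram (reported in the
#'   `excluded` attribute; unknown ids raise a warning).
#' @return data frame (`bin_start`, `count`); bins are
#'   `[bin_start, bin_start + bin_width)`.
#' @export
pathway_size_histogram <- function(db, kind = c("BASE", "SUPER"),
                                   bin_width = 1L, exclude = character()) {
  kind <- match.arg(kind)
  pids <- names(Filter(function(p) p$kind == kind, db$pathways))
  unknown <- setdiff(exclude, pids)
  if (length(unknown) > 0L) {
    warning("excluded pathway id(s) not found: ", paste(unknown, collapse = ", "))
  }
  pids <- setdiff(pids, exclude)
  sizes <- vapply(pids, function(pid) length(pathway_reactions_transitive(db, pid)),
                  integer(1))
  if (length(sizes) == 0L) {
    out <- data.frame(bin_start = integer(), count = integer())
  } else {
    bins <- as.integer(floor((sizes - 1L) / bin_width) * bin_width + 1L)
    tab <- table(bins)
    out <- data.frame(bin_start = as.integer(names(tab)),
                      count = as.integer(tab))
  }
  attr(out, "excluded") <- intersect(exclude, names(db$pathways))
  out
}

#' Pathway link-coverage classification
#'
#' Classifies each pathway of one kind by whether all, some or none of its
#' reactions (transitive through subpathways) are linked to the other
#' database, and counts the distinct pathway reactions with no link.
#'
#' @param db database whose pathways are classified.
#' @param reaction_links correspondence data frame (`a_id`, `b_id`).
#' @param kind `"BASE"` or `"SUPER"`.
#' @param side which side of the link table `db` occupies (`"a"` or `"b"`).
#' @return list with `classification` (named character, values `ALL`,
#'   `SOME`, `NONE`), `counts` (named integer vector over the three
#'   classes) and `unlinked_reaction_count`.
#' @export
pathway_link_coverage <- function(db, reaction_links, kind = c("BASE", "SUPER"),
                                  side = c("a", "b")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  linked_ids <- if (NROW(reaction_links) == 0L) character()
                else if (side == "a") reaction_links$a_id else reaction_links$b_id
  pids <- names(Filter(function(p) p$kind == kind, db$pathways))
  cls <- stats::setNames(character(length(pids)), pids)
  unlinked <- character()
  for (pid in pids) {
    rxns <- pathway_reactions_transitive(db, pid)
    n_linked <- sum(rxns %in% linked_ids)
    cls[[pid]] <- if (length(rxns) == 0L || n_linked == 0L) "NONE"
                  else if (n_linked == length(rxns)) "ALL"
                  else "SOME"
    unlinked <- c(unlinked, rxns[!(rxns %in% linked_ids)])
  }
  counts <- c(ALL = sum(cls == "ALL"), SOME = sum(cls == "SOME"),
              NONE = sum(cls == "NONE"))
  list(classification = cls, counts = counts,
       unlinked_reaction_count = length(unique(unlinked)))
}

#' Generate a deterministic comparison report
#'
#' Writes the comparison bundle for two databases and their correspondence
#' tables: `overlap.tsv`, `attributes_a.tsv`, `attributes_b.tsv`,
#' `quality.tsv`, `pathway_sizes_a.tsv`, `pathway_sizes_b.tsv`,
#' `coverage.tsv` and `summary.md` (including pathway-count,
#' reactions-per-pathway and reaction-count ratio lines). Two runs on the
#' same inputs are byte-identical.
#'
#' @param db_a,db_b the two databases.
#' @param links a `correspondence_set` holding compound and reaction links.
#' @param out_dir output directory (created if needed).
#' @param min_objects attribute-coverage threshold (default 100; lower it
#'   for small databases).
#' @return `out_dir`, invisibly.
#' @export
generate_report <- function(db_a, db_b, links, out_dir, min_objects = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- links_of_type(links, "compound")
  rl <- links_of_type(links, "reaction")

  write_tsv <- function(df, file) {
    con <- file(file.path(out_dir, file), open = "wb")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
    if (nrow(df) > 0L) {
      rows <- do.call(paste, c(lapply(df, function(col) {
        if (is.numeric(col)) formatC(col, format = "g", digits = 15) else as.character(col)
      }), sep = "\t"))
      writeLines(rows, con, useBytes = TRUE)
    }
  }

  ov <- overlap_table(db_a, db_b, cl, rl)
  ov$jaccard <- round(ov$jaccard, 2)
  write_tsv(ov, "overlap.tsv")
  write_tsv(attribute_coverage(db_a, "compound", min_objects), "attributes_a.tsv")
  write_tsv(attribute_coverage(db_b, "compound", min_objects), "attributes_b.tsv")

  qual <- data.frame(
    db = c(db_a$name, db_b$name),
    reactions = c(length(db_a$reactions), length(db_b$reactions)),
    duplicate_compounds = c(duplicate_compound_count(db_a), duplicate_compound_count(db_b)),
    duplicate_reactions = c(duplicate_reaction_count(db_a), duplicate_reaction_count(db_b)),
    unbalanced_no_h = c(unbalanced_counts(db_a)$count_no_h, unbalanced_counts(db_b)$count_no_h),
    unbalanced_with_h = c(unbalanced_counts(db_a)$count_with_h, unbalanced_counts(db_b)$count_with_h),
    high_quality_reactions = c(high_quality_reaction_count(db_a),
                               high_quality_reaction_count(db_b)),
    stringsAsFactors = FALSE)
  write_tsv(qual, "quality.tsv")

  write_tsv(pathway_size_histogram(db_a, "BASE"), "pathway_sizes_a.tsv")
  write_tsv(pathway_size_histogram(db_b, "BASE"), "pathway_sizes_b.tsv")

  cov_rows <- do.call(rbind, lapply(list(
    list(db = db_a, side = "a", label = db_a$name),
    list(db = db_b, side = "b", label = db_b$name)), function(spec) {
      do.call(rbind, lapply(c("BASE", "SUPER"), function(k) {
        cv <- pathway_link_coverage(spec$db, rl, k, spec$side)
        data.frame(db = spec$label, kind = k,
                   all_linked = cv$counts[["ALL"]],
                   some_linked = cv$counts[["SOME"]],
                   none_linked = cv$counts[["NONE"]],
                   unlinked_reactions = cv$unlinked_reaction_count,
                   stringsAsFactors = FALSE)
      }))
    }))
  write_tsv(cov_rows, "coverage.tsv")

  st_a <- summary_stats(db_a)
  st_b <- summary_stats(db_b)
  ratio <- function(x, y) if (isTRUE(y > 0)) round(x / y, 1) else NA_real_
  md <- c(
    sprintf("# Comparison of %s and %s", db_a$name, db_b$name),
    "",
    sprintf("- Compounds: %d vs %d", length(db_a$compounds), length(db_b$compounds)),
    sprintf("- Reactions: %d vs %d (ratio %.1f)", length(db_a$reactions),
            length(db_b$reactions),
            ratio(length(db_a$reactions), length(db_b$reactions))),
    sprintf("- Base pathways: %d vs %d (ratio %.1f)", st_a$pathways$base$count,
            st_b$pathways$base$count,
            ratio(st_a$pathways$base$count, st_b$pathways$base$count)),
    sprintf("- Reactions per base pathway: %.2f vs %.2f (ratio %.1f)",
            st_a$pathways$base$reactions_per_pathway,
            st_b$pathways$base$reactions_per_pathway,
            ratio(st_b$pathways$base$reactions_per_pathway,
                  st_a$pathways$base$reactions_per_pathway)),
    sprintf("- Compound links: %d; reaction links: %d", nrow(cl), nrow(rl)),
    "")
  con <- file(file.path(out_dir, "summary.md"), open = "wb")
  writeLines(md, con, useBytes = TRUE)
  close(con)
  invisible(out_dir)
}
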