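#' Derive two noisy database views from a ground-truth universe
#'
#' Every universe entity visible in a view reappears under a fresh
#' view-local id. Shared entities receive independent noise in view B: name
#' mangling (case/punctuation only, so canonical keys survive), protonation
#' variants (altered proton layer of the structure string; the
#' protonation-invariant key and the atom-count formula are unchanged),
#' stereo loss (stereo layer dropped from structure string and structure
#' key, which also changes the derived fingerprint), and per-view
#' fingerprint bit noise. Duplicate records and mass imbalance (a hidden
#' filler participant perturbing hydrogen or carbon on one side) are
#' injected at configured rates and logged in the ground truth. Reaction
#' annotations (EC, UniProt, activity names) are shared between the views
#' with configured probabilities.
#'
#' @param universe result of [generate_universe()] (the list carrying the
#'   universe database and its visibility metadata).
#' @param config the same [generator_config()].
#' @return list with `db_a`, `db_b` (validated `pathway_db`s), `truth` (a
#'   `ground_truth` object) and `perturbations` (data frame logging the
#'   structure perturbations applied to shared compounds).
#' @export
derive_views <- function(universe, config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(universe$universe)) {
    meta <- universe$metadata
    uni <- universe$universe
  } else {
    stop("derive_views expects the list returned by generate_universe()")
  }
  set.seed((config$seed %% 2000000000L) + 1L)

  cpd_ids <- names(uni$compounds)
  rxn_ids <- names(uni$reactions)
  cvis <- meta$compound_vis[cpd_ids]
  rvis <- meta$reaction_vis[rxn_ids]

  idx_of <- stats::setNames(seq_along(cpd_ids), cpd_ids)
  view_cpd_id <- function(view, uid) sprintf("%s-CPD-%05d", toupper(view), idx_of[[uid]])
  view_rxn_id <- function(view, uid) {
    sprintf("%s-RXN-%04d", toupper(view), match(uid, rxn_ids))
  }

  perturb <- data.frame(universe_id = character(), kind = character(),
                        stringsAsFactors = FALSE)
  log_perturb <- function(uid, kind) {
    perturb <<- rbind(perturb, data.frame(universe_id = uid, kind = kind,
                                          stringsAsFactors = FALSE))
  }

  make_view_compound <- function(uc, view, shared) {
    name <- uc$common_name
    synonyms <- uc$synonyms
    inchi <- uc$inchi
    skey <- uc$structure_key
    if (view == "b" && shared) {
      if (stats::runif(1) < config$name_mangle_prob) {
        name <- mangle_name(name)
        log_perturb(uc$id, "name_mangle")
      }
      if (stats::runif(1) < config$stereo_loss_prob) {
        inchi <- sub("/t[0-9]+$", "", inchi)
        skey <- sub("/t[0-9]+$", "", skey)
        log_perturb(uc$id, "stereo_loss")
      }
      if (stats::runif(1) < config$protonation_variant_prob) {
        inchi <- paste0(inchi, "/p+1")
        log_perturb(uc$id, "protonation_variant")
      }
    }
    fp <- fingerprint_bits_of(skey, config$fingerprint_bits)
    if (config$fingerprint_noise_bits > 0L) {
      fp <- sort(unique(c(fp, sample.int(config$fingerprint_bits,
                                         config$fingerprint_noise_bits) - 1L)))
    }
    attrs <- list(`CREATION-DATE` = "2012-02-17")
    if (stats::runif(1) < 0.8) {
      attrs[["MONOISOTOPIC-MW"]] <- sprintf("%.2f", 12 * bag_total_atoms(parse_formula(uc$formula)))
    }
    if (view == "a" && stats::runif(1) < 0.3) {
      attrs[["GIBBS-0"]] <- sprintf("%.1f", stats::runif(1, -50, 50))
    }
    compound_record(
      id = view_cpd_id(view, uc$id),
      common_name = name, synonyms = synonyms,
      formula = uc$formula, inchi = inchi, structure_key = skey,
      protonation_invariant_key = uc$protonation_invariant_key,
      fingerprint = fp,
      comment = if (stats::runif(1) < 0.2) sprintf("synthetic compound %s", uc$id) else NA_character_,
      attributes = attrs)
  }

  ## per-universe-reaction annotations (shared or view-private)
  ann <- lapply(seq_along(rxn_ids), function(r) {
    ec <- if (stats::runif(1) < config$ec_annotation_prob) {
      sprintf("%d.%d.%d.%d", sample(1:6, 1L), sample(1:20, 1L), sample(1:30, 1L), r)
    } else {
      NA_character_
    }
    share_up <- stats::runif(1) < config$uniprot_share_prob
    share_act <- stats::runif(1) < config$activity_name_share_prob
    list(ec = ec,
         uniprot_a = if (share_up) sprintf("P%05d", r) else sprintf("PA%05d", r),
         uniprot_b = if (share_up) sprintf("P%05d", r) else sprintf("PB%05d", r),
         activity_a = if (share_act) sprintf("activity %d", r) else sprintf("activity %d alpha", r),
         activity_b = if (share_act) sprintf("activity %d", r) else sprintf("activity %d beta", r))
  })
  ## EC collisions: give some distinct reaction pairs an identical EC
  with_ec <- which(vapply(ann, function(a) !is.na(a$ec), logical(1)))
  n_coll <- as.integer(round(config$ec_collision_rate * length(with_ec) / 2))
  if (n_coll > 0L && length(with_ec) >= 2L) {
    for (i in seq_len(n_coll)) {
      pair <- sample(with_ec, 2L)
      ann[[pair[[2L]]]]$ec <- ann[[pair[[1L]]]]$ec
    }
  }

  truth_unbalanced <- data.frame(db = character(), reaction_id = character(),
                                 stringsAsFactors = FALSE)
  truth_dups <- data.frame(db = character(), kept_id = character(),
                           dup_id = character(), stringsAsFactors = FALSE)

  build_view <- function(view) {
    vis_ok <- if (view == "a") cvis %in% c("both", "a") else cvis %in% c("both", "b")
    compounds <- list()
    for (uid in cpd_ids[vis_ok]) {
      compounds[[length(compounds) + 1L]] <-
        make_view_compound(uni$compounds[[uid]], view, cvis[[uid]] == "both")
    }
    rvis_ok <- if (view == "a") rvis %in% c("both", "a") else rvis %in% c("both", "b")
    vr_ids <- rxn_ids[rvis_ok]

    reactions <- list()
    fill_n <- 0L
    for (uid in vr_ids) {
      ur <- uni$reactions[[uid]]
      r_idx <- match(uid, rxn_ids)
      a <- ann[[r_idx]]
      p <- ur$participants
      rec <- reaction_record(
        id = view_rxn_id(view, uid),
        participants = reaction_participants(
          compound_id = vapply(p$compound_id, function(cid) view_cpd_id(view, cid), character(1)),
          coefficient = p$coefficient, side = p$side),
        ec_numbers = if (is.na(a$ec)) character() else a$ec,
        uniprot_accessions = if (view == "a") a$uniprot_a else a$uniprot_b,
        activity_names = if (view == "a") a$activity_a else a$activity_b,
        direction = ur$direction,
        comment = if (stats::runif(1) < 0.3) sprintf("synthetic reaction %s", uid) else NA_character_)
      reactions[[length(reactions) + 1L]] <- rec
    }
    names(reactions) <- vr_ids

    ## duplicate injections (clones stay untouched by imbalance)
    dup_targets <- vr_ids[stats::runif(length(vr_ids)) < config$duplicate_reaction_rate]
    ## imbalance injections on non-cloned reactions only, so the flagged
    ## set equals the injected set exactly
    imb_candidates <- setdiff(vr_ids, dup_targets)
    imb_targets <- imb_candidates[stats::runif(length(imb_candidates)) < config$imbalance_rate]
    for (uid in imb_targets) {
      fill_n <- fill_n + 1L
      fid <- sprintf("%s-FILL-%03d", toupper(view), fill_n)
      compounds[[length(compounds) + 1L]] <- compound_record(
        id = fid, common_name = sprintf("%s filler %d", view, fill_n),
        formula = if (stats::runif(1) < 0.5) "H" else "C")
      rec <- reactions[[uid]]
      side <- sample(c("LEFT", "RIGHT"), 1L)
      rec$participants <- reaction_participants(
        compound_id = c(rec$participants$compound_id, fid),
        coefficient = c(rec$participants$coefficient, 1L),
        side = c(rec$participants$side, side))
      reactions[[uid]] <- rec
      truth_unbalanced <<- rbind(truth_unbalanced, data.frame(
        db = view, reaction_id = rec$id, stringsAsFactors = FALSE))
    }
    for (uid in dup_targets) {
      rec <- reactions[[uid]]
      clone <- rec
      clone$id <- paste0(rec$id, "-DUP")
      if (stats::runif(1) < 0.5) { # reversed copy is still a duplicate
        pp <- clone$participants
        pp$side <- ifelse(pp$side == "LEFT", "RIGHT", "LEFT")
        clone$participants <- reaction_participants(pp$compound_id, pp$coefficient, pp$side)
      }
      reactions[[length(reactions) + 1L]] <- clone
      truth_dups <<- rbind(truth_dups, data.frame(
        db = view, kept_id = rec$id, dup_id = clone$id, stringsAsFactors = FALSE))
    }

    ## duplicate compounds: same structure string under a fresh id
    cpd_pool <- seq_along(compounds)
    dup_cpds <- cpd_pool[stats::runif(length(cpd_pool)) < config$duplicate_compound_rate]
    for (i in dup_cpds) {
      orig <- compounds[[i]]
      if (is.na(orig$inchi)) next
      clone <- orig
      clone$id <- paste0(orig$id, "-DUP")
      compounds[[length(compounds) + 1L]] <- clone
      truth_dups <<- rbind(truth_dups, data.frame(
        db = view, kept_id = orig$id, dup_id = clone$id, stringsAsFactors = FALSE))
    }

    ## pathways: BASE pathways (modules for view B) plus SUPER aggregates
    n_base <- if (view == "a") config$n_base_pathways else config$n_modules
    n_super <- if (view == "a") config$n_superpathways else config$n_maps
    size_mean <- if (view == "a") config$base_pathway_size_mean else config$module_pathway_size_mean
    all_rxn_view_ids <- vapply(reactions, function(r) r$id, character(1))
    pathways <- list()
    if (n_base > 0L && length(all_rxn_view_ids) > 0L) {
      for (i in seq_len(n_base)) {
        size <- min(length(all_rxn_view_ids),
                    1L + stats::rpois(1L, max(size_mean - 1, 0)))
        pathways[[length(pathways) + 1L]] <- pathway_record(
          id = sprintf("%s-PWY-%03d", toupper(view), i), kind = "BASE",
          reaction_ids = sample(all_rxn_view_ids, size),
          class_ids = if (config$n_classes > 0L)
            sprintf("CLS-%02d", sample(config$n_classes, 1L)) else character(),
          taxonomic_range = if (config$n_taxa > 0L)
            sprintf("%d", 1000L + sample(config$n_taxa,
                                         min(config$n_taxa, sample(1:2, 1L)))) else character(),
          comment = if (stats::runif(1) < 0.5) sprintf("synthetic pathway %d", i) else NA_character_)
      }
      if (n_super > 0L) {
        base_pids <- sprintf("%s-PWY-%03d", toupper(view), seq_len(n_base))
        n_sub <- if (view == "a") 2:3 else 3:5 # maps aggregate more modules
        for (i in seq_len(n_super)) {
          pathways[[length(pathways) + 1L]] <- pathway_record(
            id = sprintf("%s-SPWY-%03d", toupper(view), i), kind = "SUPER",
            reaction_ids = sample(all_rxn_view_ids, min(length(all_rxn_view_ids), 2L)),
            subpathway_ids = sample(base_pids, min(length(base_pids), sample(n_sub, 1L))),
            class_ids = if (config$n_classes > 0L)
              sprintf("CLS-%02d", sample(config$n_classes, 1L)) else character())
        }
      }
    }

    pathway_db(paste0("db_", view),
               compounds = compounds,
               reactions = unname(reactions),
               pathways = pathways,
               classes = uni$classes,
               taxa = uni$taxa)
  }

  db_a <- build_view("a")
  db_b <- build_view("b")

  shared_cpds <- cpd_ids[cvis == "both"]
  shared_rxns <- rxn_ids[rvis == "both"]
  truth <- structure(list(
    compound_pairs = data.frame(
      a_id = vapply(shared_cpds, function(u) view_cpd_id("a", u), character(1), USE.NAMES = FALSE),
      b_id = vapply(shared_cpds, function(u) view_cpd_id("b", u), character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE),
    reaction_pairs = data.frame(
      a_id = vapply(shared_rxns, function(u) view_rxn_id("a", u), character(1), USE.NAMES = FALSE),
      b_id = vapply(shared_rxns, function(u) view_rxn_id("b", u), character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE),
    injected_unbalanced = truth_unbalanced,
    injected_duplicates = truth_dups
  ), class = "ground_truth")

  list(db_a = db_a, db_b = db_b, truth = truth, perturbations = perturb)
}

#' Generate a full synthetic benchmark
#'
#' Convenience wrapper: [generate_universe()] followed by [derive_views()].
#'
#' @param config a [generator_config()].
#' @return the [derive_views()] result, plus the `universe`.
#' @export
generate_twin_databases <- function(config = generator_config()) {
  u <- generate_universe(config)
  out <- derive_views(u, config)
  out$universe <- u$universe
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth: %d compound pairs, %d reaction pairs, ",
                     "%d injected imbalances, %d injected duplicates>\n"),
              nrow(x$compound_pairs), nrow(x$reaction_pairs),
              nrow(x$injected_unbalanced), nrow(x$injected_duplicates)))
  invisible(x)
}

#' Write / read ground truth (TSV)
#'
#' One row per fact: columns `entity_type` (`compound_pair`,
#' `reaction_pair`, `unbalanced`, `duplicate`), `db`, `a_id`, `b_id`.
#' For pairs, `db` is empty; for imbalances, `a_id` holds the reaction id;
#' for duplicates, `a_id`/`b_id` hold kept/duplicate ids. Rows are emitted
#' in deterministic order.
#'
#' @param truth a `ground_truth`.
#' @param path TSV file path.
#' @return `path` invisibly (write); a `ground_truth` (read).
#' @export
write_truth <- function(truth, path) {
  rows <- rbind(
    if (nrow(truth$compound_pairs) > 0L)
      data.frame(entity_type = "compound_pair", db = "",
                 a_id = truth$compound_pairs$a_id, b_id = truth$compound_pairs$b_id,
                 stringsAsFactors = FALSE),
    if (nrow(truth$reaction_pairs) > 0L)
      data.frame(entity_type = "reaction_pair", db = "",
                 a_id = truth$reaction_pairs$a_id, b_id = truth$reaction_pairs$b_id,
                 stringsAsFactors = FALSE),
    if (nrow(truth$injected_unbalanced) > 0L)
      data.frame(entity_type = "unbalanced", db = truth$injected_unbalanced$db,
                 a_id = truth$injected_unbalanced$reaction_id, b_id = "",
                 stringsAsFactors = FALSE),
    if (nrow(truth$injected_duplicates) > 0L)
      data.frame(entity_type = "duplicate", db = truth$injected_duplicates$db,
                 a_id = truth$injected_duplicates$kept_id,
                 b_id = truth$injected_duplicates$dup_id,
                 stringsAsFactors = FALSE))
  if (is.null(rows)) {
    rows <- data.frame(entity_type = character(), db = character(),
                       a_id = character(), b_id = character(),
                       stringsAsFactors = FALSE)
  }
  rows <- rows[order(rows$entity_type, rows$db, rows$a_id, rows$b_id), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("entity_type", "db", "a_id", "b_id"), collapse = "\t"),
             con, useBytes = TRUE)
  if (nrow(rows) > 0L) {
    writeLines(paste(rows$entity_type, rows$db, rows$a_id, rows$b_id, sep = "\t"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("entity_type", "db", "a_id", "b_id")
  if (!all(need %in% names(df))) {
    stop("truth table ", sQuote(path), " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  known <- c("compound_pair", "reaction_pair", "unbalanced", "duplicate")
  bad <- which(!(df$entity_type %in% known))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: unknown entity_type %s", basename(path),
                 bad[[1L]] + 1L, sQuote(df$entity_type[bad[[1L]]])), call. = FALSE)
  }
  pick <- function(type) df[df$entity_type == type, , drop = FALSE]
  cp <- pick("compound_pair"); rp <- pick("reaction_pair")
  ub <- pick("unbalanced"); dp <- pick("duplicate")
  structure(list(
    compound_pairs = data.frame(a_id = cp$a_id, b_id = cp$b_id, stringsAsFactors = FALSE),
    reaction_pairs = data.frame(a_id = rp$a_id, b_id = rp$b_id, stringsAsFactors = FALSE),
    injected_unbalanced = data.frame(db = ub$db, reaction_id = ub$a_id, stringsAsFactors = FALSE),
    injected_duplicates = data.frame(db = dp$db, kept_id = dp$a_id, dup_id = dp$b_id,
                                     stringsAsFactors = FALSE)
  ), class = "ground_truth")
}
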