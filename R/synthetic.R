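#' Configuration for the synthetic twin-database generator
#'
#' The generator creates a ground-truth universe of compounds and
#' balanced-by-construction reactions, then derives two noisy database
#' views with known correspondences. Defaults emulate a small
#' MetaCyc/KEGG-like setting: a few hundred compounds and reactions, half
#' the content shared between the views, mild name/structure noise, and the
#' two databases' differing pathway size regimes (base pathways averaging
#' 4.37 reactions in view A, module pathways averaging 6.22 in view B).
#'
#' Sharedness model: each reaction is shared with probability
#' `shared_reaction_fraction`; a shared reaction draws its reactants from
#' shared compounds and its products are created shared, while seed
#' compounds are shared with probability `shared_compound_fraction` (keep
#' the two fractions equal for a binomially distributed realized compound
#' overlap).
#'
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param n_compounds,n_reactions universe sizes.
#' @param shared_compound_fraction,shared_reaction_fraction proportions of
#'   entities visible in both views.
#' @param name_mangle_prob probability that view B's copy of a name gets
#'   case/punctuation mangling (canonicalization-invariant).
#' @param synonym_count_range integer range of synonyms per compound.
#' @param protonation_variant_prob probability that view B's copy of a
#'   shared compound carries an altered proton layer in its structure
#'   string (the protonation-invariant key is unchanged).
#' @param stereo_loss_prob probability that view B's copy drops the stereo
#'   layer from its structure string and structure key.
#' @param duplicate_compound_rate,duplicate_reaction_rate per-view rates of
#'   injected duplicate records.
#' @param imbalance_rate per-view rate of injected mass imbalance (a hidden
#'   filler participant perturbing H, or C, counts on one side).
#' @param ec_annotation_prob probability a reaction carries an EC number
#'   (shared by both views).
#' @param ec_collision_rate rate at which distinct reaction pairs are given
#'   identical EC numbers.
#' @param uniprot_share_prob,activity_name_share_prob probabilities that
#'   the two views share a UniProt accession / enzymatic activity name for
#'   a reaction (otherwise each view gets private annotations).
#' @param fingerprint_bits fingerprint bit-space size (default 256).
#' @param fingerprint_noise_bits random bits added per view copy.
#' @param base_pathway_size_mean,module_pathway_size_mean mean reactions
#'   per BASE pathway in views A and B.
#' @param n_base_pathways,n_modules,n_superpathways,n_maps pathway counts
#'   (A base/super, B module/map).
#' @param n_classes,n_taxa ontology and taxonomy sizes.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_compounds = 500L,
                             n_reactions = 300L,
                             shared_compound_fraction = 0.5,
                             shared_reaction_fraction = 0.5,
                             name_mangle_prob = 0.1,
                             synonym_count_range = c(0L, 2L),
                             protonation_variant_prob = 0.1,
                             stereo_loss_prob = 0.1,
                             duplicate_compound_rate = 0.01,
                             duplicate_reaction_rate = 0.01,
                             imbalance_rate = 0.05,
                             ec_annotation_prob = 0.7,
                             ec_collision_rate = 0.02,
                             uniprot_share_prob = 0.5,
                             activity_name_share_prob = 0.5,
                             fingerprint_bits = 256L,
                             fingerprint_noise_bits = 2L,
                             base_pathway_size_mean = 4.37,
                             module_pathway_size_mean = 6.22,
                             n_base_pathways = 40L,
                             n_modules = 15L,
                             n_superpathways = 6L,
                             n_maps = 5L,
                             n_classes = 12L,
                             n_taxa = 10L) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              n_reactions = as.integer(n_reactions),
              shared_compound_fraction = shared_compound_fraction,
              shared_reaction_fraction = shared_reaction_fraction,
              name_mangle_prob = name_mangle_prob,
              synonym_count_range = as.integer(synonym_count_range),
              protonation_variant_prob = protonation_variant_prob,
              stereo_loss_prob = stereo_loss_prob,
              duplicate_compound_rate = duplicate_compound_rate,
              duplicate_reaction_rate = duplicate_reaction_rate,
              imbalance_rate = imbalance_rate,
              ec_annotation_prob = ec_annotation_prob,
              ec_collision_rate = ec_collision_rate,
              uniprot_share_prob = uniprot_share_prob,
              activity_name_share_prob = activity_name_share_prob,
              fingerprint_bits = as.integer(fingerprint_bits),
              fingerprint_noise_bits = as.integer(fingerprint_noise_bits),
              base_pathway_size_mean = base_pathway_size_mean,
              module_pathway_size_mean = module_pathway_size_mean,
              n_base_pathways = as.integer(n_base_pathways),
              n_modules = as.integer(n_modules),
              n_superpathways = as.integer(n_superpathways),
              n_maps = as.integer(n_maps),
              n_classes = as.integer(n_classes),
              n_taxa = as.integer(n_taxa))
  props <- c("shared_compound_fraction", "shared_reaction_fraction",
             "name_mangle_prob", "protonation_variant_prob", "stereo_loss_prob",
             "duplicate_compound_rate", "duplicate_reaction_rate",
             "imbalance_rate", "ec_annotation_prob", "ec_collision_rate",
             "uniprot_share_prob", "activity_name_share_prob")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("generator_config: ", p, " must be in [0, 1]")
  }
  if (cfg$n_compounds < 0 || cfg$n_reactions < 0) {
    stop("generator_config: sizes must be non-negative")
  }
  if (cfg$n_reactions > 0L && cfg$n_compounds < 2L) {
    stop("generator_config: reactions require at least 2 compounds")
  }
  if (length(cfg$synonym_count_range) != 2L ||
      cfg$synonym_count_range[[1L]] > cfg$synonym_count_range[[2L]]) {
    stop("generator_config: synonym_count_range must be (lo, hi) with lo <= hi")
  }
  if (cfg$base_pathway_size_mean <= 0 || cfg$module_pathway_size_mean <= 0) {
    stop("generator_config: pathway size means must be positive")
  }
  structure(cfg, class = "generator_config")
}

## deterministic fingerprint bits from a structure key: polynomial rolling
## hash seeding positions in the fingerprint bit space
fingerprint_bits_of <- function(key, nbits, nset = 32L) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  bits <- integer(nset)
  for (j in seq_len(nset)) {
    h <- (h * 48271) %% 2147483647
    bits[[j]] <- as.integer(h %% nbits)
  }
  sort(unique(bits))
}

random_formula <- function() {
  counts <- c(C = sample(1:10, 1L), H = sample(2:16, 1L),
              O = sample(0:6, 1L), N = sample(0:3, 1L),
              P = if (stats::runif(1) < 0.15) sample(1:2, 1L) else 0L,
              S = if (stats::runif(1) < 0.1) 1L else 0L)
  element_bag(counts)
}

## split an element bag into k non-empty bags (multinomial per element)
partition_bag <- function(bag, k) {
  if (k == 1L) return(list(bag))
  parts <- matrix(0L, nrow = k, ncol = length(bag),
                  dimnames = list(NULL, names(bag)))
  for (j in seq_along(bag)) {
    parts[, j] <- as.integer(stats::rmultinom(1L, unclass(bag)[[j]], rep(1, k)))
  }
  totals <- rowSums(parts)
  while (any(totals == 0L)) {
    empty <- which(totals == 0L)[[1L]]
    donor <- which.max(totals)
    elem <- which.max(parts[donor, ])
    parts[donor, elem] <- parts[donor, elem] - 1L
    parts[empty, elem] <- parts[empty, elem] + 1L
    totals <- rowSums(parts)
  }
  lapply(seq_len(k), function(i) {
    element_bag(stats::setNames(parts[i, ], colnames(parts)))
  })
}

random_word <- function(n_syllables = 2L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, TRUE), sample(vow, n_syllables, TRUE)),
         collapse = "")
}

## case/punctuation mangling that preserves the canonical name key
mangle_name <- function(name) {
  chars <- strsplit(name, "", fixed = TRUE)[[1L]]
  flip <- stats::runif(length(chars)) < 0.3
  chars[flip] <- toupper(chars[flip])
  out <- paste(chars, collapse = "")
  out <- gsub(" ", sample(c("-", ".", " "), 1L), out, fixed = TRUE)
  if (stats::runif(1) < 0.3) out <- paste0(out, ".")
  out
}

#' Generate a ground-truth universe
#'
#' Creates compounds with random formulas, structure keys (a connectivity
#' core plus stereo layer; the protonation-invariant key is the core) and
#' deterministic fingerprints, plus reactions that are mass-balanced by
#' construction: each reaction's product formulas are obtained by
#' re-partitioning the summed atom counts of its reactants. Pathways are
#' assembled over the reactions with Poisson-distributed sizes, and a small
#' class ontology and taxonomy are attached.
#'
#' @param config a [generator_config()].
#' @return list with `universe` (a `pathway_db`) and `metadata` (data frame
#'   of per-entity visibility assignments and product counts, consumed by
#'   [derive_views()]).
#' @export
generate_universe <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  n_seed <- max(2L, as.integer(ceiling(0.15 * config$n_compounds)))
  n_products <- config$n_compounds - n_seed
  if (config$n_reactions > 0L && n_products < config$n_reactions) {
    stop("generator_config: infeasible sizes (need at least one product ",
         "compound per reaction; increase n_compounds or decrease n_reactions)")
  }

  vis_levels <- c("both", "a", "b")
  draw_vis <- function(p_shared, n) {
    sample(vis_levels, n, replace = TRUE,
           prob = c(p_shared, (1 - p_shared) / 2, (1 - p_shared) / 2))
  }

  compounds <- vector("list", config$n_compounds)
  cpd_vis <- character(config$n_compounds)
  cpd_bag <- vector("list", config$n_compounds)
  n_cpd <- 0L

  new_compound <- function(bag, vis) {
    n_cpd <<- n_cpd + 1L
    i <- n_cpd
    id <- sprintf("U-CPD-%05d", i)
    name <- sprintf("%s %d", random_word(), i)
    syn_rng <- config$synonym_count_range
    n_syn <- if (syn_rng[[1L]] == syn_rng[[2L]]) syn_rng[[1L]]
             else sample(syn_rng[[1L]]:syn_rng[[2L]], 1L)
    synonyms <- if (n_syn > 0L) sprintf("%s syn%d", name, seq_len(n_syn)) else character()
    core <- sprintf("CORE-%05d", i)
    stereo <- sprintf("t%d", sample(1:4, 1L))
    skey <- paste0(core, "/", stereo)
    formula <- format_formula(bag)
    compounds[[i]] <<- compound_record(
      id = id, common_name = name, synonyms = synonyms,
      formula = formula,
      inchi = paste0("InChI=1S/", formula, "/c", core, "/", stereo),
      structure_key = skey,
      protonation_invariant_key = core,
      fingerprint = fingerprint_bits_of(skey, config$fingerprint_bits))
    cpd_vis[[i]] <<- vis
    cpd_bag[[i]] <<- bag
    id
  }

  for (i in seq_len(n_seed)) {
    new_compound(random_formula(), draw_vis(config$shared_compound_fraction, 1L))
  }

  ## products per reaction: at least one each, extras spread at random
  rxn_vis <- draw_vis(config$shared_reaction_fraction, config$n_reactions)
  prod_counts <- rep(1L, config$n_reactions)
  extra <- n_products - config$n_reactions
  if (config$n_reactions > 0L && extra > 0L) {
    add <- tabulate(sample.int(config$n_reactions, extra, replace = TRUE),
                    config$n_reactions)
    prod_counts <- prod_counts + as.integer(pmin(add, 2L))
    short <- n_products - sum(prod_counts)
    while (short > 0L) { # redistribute what the per-reaction cap clipped
      j <- sample.int(config$n_reactions, 1L)
      prod_counts[[j]] <- prod_counts[[j]] + 1L
      short <- short - 1L
    }
  }

  reactions <- vector("list", config$n_reactions)
  for (r in seq_len(config$n_reactions)) {
    vis <- rxn_vis[[r]]
    pool_ok <- if (vis == "both") cpd_vis[seq_len(n_cpd)] == "both"
               else cpd_vis[seq_len(n_cpd)] %in% c("both", vis)
    pool <- which(pool_ok)
    if (length(pool) < 2L) {
      stop("generator_config: infeasible sharing fractions (reactant pool ",
           "for visibility ", sQuote(vis), " has fewer than 2 compounds)")
    }
    n_react <- min(length(pool), sample(2:3, 1L))
    react_idx <- sample(pool, n_react)
    coefs <- sample(1:2, n_react, replace = TRUE, prob = c(0.8, 0.2))
    total <- element_bag()
    for (j in seq_len(n_react)) {
      total <- bag_combine(total, bag_scale(cpd_bag[[react_idx[[j]]]], coefs[[j]]))
    }
    k <- min(prod_counts[[r]], bag_total_atoms(total))
    prods <- partition_bag(total, k)
    prod_ids <- vapply(prods, function(b) new_compound(b, vis), character(1))
    reactions[[r]] <- reaction_record(
      id = sprintf("U-RXN-%04d", r),
      participants = reaction_participants(
        compound_id = c(sprintf("U-CPD-%05d", react_idx), prod_ids),
        coefficient = c(coefs, rep(1L, length(prod_ids))),
        side = c(rep("LEFT", n_react), rep("RIGHT", length(prod_ids)))),
      direction = sample(c("LEFT-TO-RIGHT", "REVERSIBLE"), 1L))
  }
  ## if caps left product budget unused, fill with standalone seed compounds
  while (n_cpd < config$n_compounds) {
    new_compound(random_formula(), draw_vis(config$shared_compound_fraction, 1L))
  }

  ## class ontology: a root plus children attached to earlier nodes
  classes <- vector("list", config$n_classes)
  for (i in seq_len(config$n_classes)) {
    parent <- if (i == 1L) character() else sprintf("CLS-%02d", sample(seq_len(i - 1L), 1L))
    classes[[i]] <- class_node(sprintf("CLS-%02d", i),
                               name = sprintf("pathway class %d", i),
                               parent_ids = parent)
  }
  ## taxonomy: rooted tree
  taxa <- vector("list", config$n_taxa)
  for (i in seq_len(config$n_taxa)) {
    parent <- if (i == 1L) NA_character_ else sprintf("%d", 1000L + sample(seq_len(i - 1L), 1L))
    taxa[[i]] <- taxon_node(sprintf("%d", 1000L + i),
                            name = sprintf("taxon %d", i),
                            parent_id = parent)
  }

  ## universe pathways: base pathways over reaction samples, super pathways
  ## aggregating base pathways plus extra reactions
  pathways <- list()
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (config$n_base_pathways > 0L && length(rxn_ids) > 0L) {
    for (i in seq_len(config$n_base_pathways)) {
      size <- min(length(rxn_ids),
                  1L + stats::rpois(1L, max(config$base_pathway_size_mean - 1, 0)))
      pathways[[length(pathways) + 1L]] <- pathway_record(
        id = sprintf("U-PWY-%03d", i), kind = "BASE",
        reaction_ids = sample(rxn_ids, size),
        class_ids = if (config$n_classes > 0L)
          sprintf("CLS-%02d", sample(config$n_classes, 1L)) else character(),
        taxonomic_range = if (config$n_taxa > 0L)
          sprintf("%d", 1000L + sample(config$n_taxa,
                                       min(config$n_taxa, sample(1:2, 1L)))) else character())
    }
    if (config$n_superpathways > 0L) {
      base_ids <- sprintf("U-PWY-%03d", seq_len(config$n_base_pathways))
      for (i in seq_len(config$n_superpathways)) {
        subs <- sample(base_ids, min(length(base_ids), sample(2:3, 1L)))
        pathways[[length(pathways) + 1L]] <- pathway_record(
          id = sprintf("U-SPWY-%03d", i), kind = "SUPER",
          reaction_ids = sample(rxn_ids, min(length(rxn_ids), 2L)),
          subpathway_ids = subs,
          class_ids = if (config$n_classes > 0L)
            sprintf("CLS-%02d", sample(config$n_classes, 1L)) else character())
      }
    }
  }

  universe <- pathway_db("universe",
                         compounds = compounds[seq_len(n_cpd)],
                         reactions = reactions,
                         pathways = pathways,
                         classes = classes,
                         taxa = taxa)
  metadata <- list(
    compound_vis = stats::setNames(cpd_vis[seq_len(n_cpd)],
                                   sprintf("U-CPD-%05d", seq_len(n_cpd))),
    reaction_vis = stats::setNames(rxn_vis, rxn_ids))
  list(universe = universe, metadata = metadata)
}
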