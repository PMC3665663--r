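#' Audit the atom balance of one reaction
#'
#' Sums coefficient-weighted atom counts per side from each participant's
#' molecular formula and reports the per-element delta (right minus left).
#' `balanced_no_h` ignores hydrogen, since hydrogen imbalance can stem from
#' inconsistent protonation states rather than a genuinely wrong equation.
#' A reaction in which any participant lacks a parseable formula is reported
#' as skipped, with neither balance flag asserted.
#'
#' @param db a `pathway_db`.
#' @param reaction_id reaction to audit.
#' @return an object of class `balance_report`: list with `reaction_id`,
#'   `balanced_all`, `balanced_no_h`, `per_element_delta` (signed
#'   [element_bag()]) and `skipped`.
#' @export
reaction_balance <- function(db, reaction_id) {
  r <- db$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction id ", sQuote(reaction_id))
  p <- r$participants
  delta <- element_bag()
  skipped <- FALSE
  for (i in seq_len(nrow(p))) {
    cpd <- db$compounds[[p$compound_id[[i]]]]
    f <- cpd$formula
    if (is.na(f) || !nzchar(f)) { skipped <- TRUE; break }
    bag <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(bag)) { skipped <- TRUE; break }
    sign <- if (p$side[[i]] == "LEFT") -1L else 1L
    delta <- bag_combine(delta, bag_scale(bag, p$coefficient[[i]]), sign = sign)
  }
  if (skipped) {
    rep <- list(reaction_id = reaction_id, balanced_all = NA,
                balanced_no_h = NA, per_element_delta = NULL, skipped = TRUE)
  } else {
    no_h <- delta[names(delta) != "H"]
    rep <- list(reaction_id = reaction_id,
                balanced_all = length(delta) == 0L,
                balanced_no_h = length(no_h) == 0L,
                per_element_delta = delta,
                skipped = FALSE)
  }
  class(rep) <- "balance_report"
  rep
}

#' @export
print.balance_report <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("<balance_report %s: skipped (unparseable formula)>\n", x$reaction_id))
  } else {
    cat(sprintf("<balance_report %s: balanced_all=%s balanced_no_h=%s>\n",
                x$reaction_id, x$balanced_all, x$balanced_no_h))
    if (!x$balanced_all) print(x$per_element_delta)
  }
  invisible(x)
}

#' Count unbalanced reactions in a database
#'
#' @param db a `pathway_db`.
#' @return list with `count_no_h` (unbalanced ignoring hydrogen),
#'   `count_with_h` (unbalanced counting hydrogen) and `skipped` (reactions
#'   with an unparseable or missing formula, excluded from both counts).
#'   `count_no_h <= count_with_h` always holds.
#' @export
unbalanced_counts <- function(db) {
  count_no_h <- 0L; count_with_h <- 0L; skipped <- 0L
  for (rid in names(db$reactions)) {
    rep <- reaction_balance(db, rid)
    if (rep$skipped) {
      skipped <- skipped + 1L
    } else {
      if (!rep$balanced_no_h) count_no_h <- count_no_h + 1L
      if (!rep$balanced_all) count_with_h <- count_with_h + 1L
    }
  }
  list(count_no_h = count_no_h, count_with_h = count_with_h, skipped = skipped)
}

#' Reactions flagged as unbalanced
#'
#' @param db a `pathway_db`.
#' @param counting_hydrogen flag reactions unbalanced when hydrogen counts
#'   (default) or only when some non-hydrogen element is off.
#' @return character vector of reaction ids (skipped reactions excluded).
#' @export
unbalanced_reactions <- function(db, counting_hydrogen = TRUE) {
  flagged <- character()
  for (rid in names(db$reactions)) {
    rep <- reaction_balance(db, rid)
    if (rep$skipped) next
    bad <- if (counting_hydrogen) !rep$balanced_all else !rep$balanced_no_h
    if (bad) flagged <- c(flagged, rid)
  }
  flagged
}

#' High-quality reaction count
#'
#' Total reaction instances minus within-database duplicates minus reactions
#' unbalanced when counting hydrogen (plain subtraction; a reaction that is
#' both duplicate and unbalanced is subtracted twice). Skipped
#' (formula-less) reactions count as balanced, since the count removes
#' demonstrated problems, not unverifiable records.
#'
#' @param db a `pathway_db`.
#' @return integer.
#' @export
high_quality_reaction_count <- function(db) {
  length(db$reactions) - duplicate_reaction_count(db) -
    unbalanced_counts(db)$count_with_h
}
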