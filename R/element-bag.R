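#' Element bags: multisets of atoms
#'
#' An element bag maps IUPAC element symbols to atom counts. Bags are stored
#' as named integer vectors sorted by symbol with zero counts dropped, so two
#' bags are equal element-wise iff they are `identical()`. Signed bags (used
#' for balance deltas) are permitted via `allow_negative`.
#'
#' @param counts named integer (or coercible) vector of atom counts.
#' @param allow_negative keep negative counts (balance deltas) instead of
#'   rejecting them.
#' @return an object of class `element_bag`.
#' @export
element_bag <- function(counts = integer(), allow_negative = FALSE) {
  if (length(counts) == 0L) {
    out <- structure(integer(), names = character())
    class(out) <- "element_bag"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element_bag: all counts must be named by element symbol")
  }
  counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  if (!allow_negative && any(counts < 0L)) {
    stop("element_bag: negative atom counts are not allowed")
  }
  counts <- counts[counts != 0L]
  counts <- counts[order(names(counts))]
  class(counts) <- "element_bag"
  counts
}

#' @export
print.element_bag <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<element bag: empty>\n")
  } else {
    cat("<element bag> ", paste0(names(x), ":", unclass(x), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

## signed sum of bags: a + sign * b
bag_combine <- function(a, b, sign = 1L) {
  syms <- union(names(a), names(b))
  av <- ifelse(syms %in% names(a), unclass(a)[syms], 0L)
  bv <- ifelse(syms %in% names(b), unclass(b)[syms], 0L)
  element_bag(stats::setNames(as.integer(av + sign * bv), syms), allow_negative = TRUE)
}

bag_scale <- function(a, k) {
  element_bag(stats::setNames(as.integer(unclass(a) * k), names(a)), allow_negative = TRUE)
}

bag_total_atoms <- function(a) sum(abs(unclass(a)))

#' Parse a molecular formula into atom counts
#'
#' Accepts element symbols with optional integer counts and parenthesised
#' groups with multipliers, e.g. `"C6H12O6"` or `"Ca(OH)2"`. Trailing charge
#' tokens such as `"+"`, `"-2"` are stripped before parsing: balance checking
#' is atom-based, so charge is ignored.
#'
#' @param formula a single formula string.
#' @return an [element_bag()] of exact atom counts.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("Ca(OH)2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("parse_formula: formula must be a single non-NA string")
  }
  stripped <- sub("([+-][0-9]*)+$", "", formula)
  if (!nzchar(stripped)) {
    stop("parse_formula: empty formula ", sQuote(formula))
  }
  chars <- strsplit(stripped, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[[pos]] else ""
  read_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[[pos]])) pos <<- pos + 1L
    if (pos == start) 1L else as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  read_group <- function() {
    bag <- element_bag()
    repeat {
      ch <- peek()
      if (ch == "" || ch == ")") break
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- read_group()
        if (peek() != ")") {
          stop(sprintf("parse_formula: unbalanced '(' in %s at position %d",
                       sQuote(formula), pos))
        }
        pos <<- pos + 1L
        bag <- bag_combine(bag, bag_scale(inner, read_int()))
      } else if (grepl("[A-Z]", ch)) {
        start <- pos
        pos <<- pos + 1L
        while (pos <= n && grepl("[a-z]", chars[[pos]])) pos <<- pos + 1L
        sym <- paste(chars[start:(pos - 1L)], collapse = "")
        bag <- bag_combine(bag, element_bag(stats::setNames(read_int(), sym)))
      } else {
        stop(sprintf("parse_formula: unexpected character %s at position %d in %s",
                     sQuote(ch), pos, sQuote(formula)))
      }
    }
    bag
  }

  bag <- read_group()
  if (pos <= n) {
    stop(sprintf("parse_formula: unexpected character %s at position %d in %s",
                 sQuote(peek()), pos, sQuote(formula)))
  }
  if (length(bag) == 0L) {
    stop("parse_formula: formula ", sQuote(formula), " contains no atoms")
  }
  bag
}

## deparse an element bag back to a formula string (canonical symbol order)
format_formula <- function(bag) {
  b <- unclass(bag)
  paste0(names(b), ifelse(b == 1L, "", as.character(b)), collapse = "")
}
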