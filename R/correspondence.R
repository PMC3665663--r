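#' Correspondence sets
#'
#' A correspondence set records directed A-to-B entity matches with their
#' provenance (`curated`, `imported` or `inferred`) and the match features
#' that fired. It is a data frame with columns `entity_type` (`"compound"` or
#' `"reaction"`), `a_id`, `b_id`, `source` and `features` (comma-separated).
#'
#' @param entity_type,a_id,b_id,source,features column vectors (recycled
#'   where length one).
#' @return an object of classes `correspondence_set` and `data.frame`.
#' @export
correspondence_set <- function(entity_type = character(), a_id = character(),
                               b_id = character(), source = "inferred",
                               features = "") {
  n <- length(a_id)
  df <- data.frame(entity_type = rep_len(as.character(entity_type), n),
                   a_id = as.character(a_id),
                   b_id = rep_len(as.character(b_id), n),
                   source = rep_len(as.character(source), n),
                   features = rep_len(as.character(features), n),
                   stringsAsFactors = FALSE)
  if (n > 0L) {
    if (!all(df$entity_type %in% c("compound", "reaction"))) {
      stop("entity_type must be 'compound' or 'reaction'")
    }
    if (!all(df$source %in% c("curated", "imported", "inferred"))) {
      stop("source must be curated, imported or inferred")
    }
  }
  class(df) <- c("correspondence_set", "data.frame")
  df
}

links_of_type <- function(links, type) {
  if (is.null(links) || nrow(links) == 0L) {
    return(correspondence_set())
  }
  out <- links[links$entity_type == type, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correspondence_set", "data.frame")
  out
}

bind_links <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(parts) == 0L) return(correspondence_set())
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("correspondence_set", "data.frame")
  out
}

#' Write / read a correspondence table (TSV)
#'
#' Columns: `entity_type  a_id  b_id  source  features`. Rows are emitted in
#' deterministic order (entity type, then `a_id`, then `b_id`).
#'
#' @param links a `correspondence_set`.
#' @param path TSV file path.
#' @return `path` invisibly (write); a `correspondence_set` (read).
#' @export
write_correspondences <- function(links, path) {
  df <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    df <- df[order(df$entity_type, df$a_id, df$b_id), , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("entity_type", "a_id", "b_id", "source", "features"),
                   collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df) > 0L) {
    writeLines(paste(df$entity_type, df$a_id, df$b_id, df$source, df$features,
                     sep = "\t"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("entity_type", "a_id", "b_id", "source", "features")
  if (!all(need %in% names(df))) {
    stop("correspondence table ", sQuote(path), " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!(df$entity_type %in% c("compound", "reaction")))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: unknown entity_type %s", basename(path),
                 bad[[1L]] + 1L, sQuote(df$entity_type[bad[[1L]]])), call. = FALSE)
  }
  correspondence_set(df$entity_type, df$a_id, df$b_id, df$source, df$features)
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("<correspondence_set: %d compound, %d reaction links>\n",
              sum(x$entity_type == "compound"), sum(x$entity_type == "reaction")))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
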