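#' Construct and validate a response matrix
#'
#' A `response_matrix` is the raw analysis input: an integer matrix of
#' `n` respondents by `k` items, with response codes `0..m_j` for item `j`.
#' Items are dichotomous (`m_j = 1`) unless a per-item category count is
#' supplied. Codes are taken as already 0-based consecutive integers; the
#' validator rejects out-of-range codes rather than silently recoding.
#'
#' @param x integer matrix (or data frame coercible to one), respondents in
#'   rows, items in columns.
#' @param item_labels character vector of unique item labels; defaults to
#'   the column names, or `i1..ik` when absent.
#' @param n_categories integer vector of per-item category counts
#'   (`m_j + 1`), each at least 2. A single value is recycled. `NULL`
#'   declares every item dichotomous.
#' @return an object of class `response_matrix`: the integer matrix with
#'   attributes `item_labels` and `n_categories`.
#' @examples
#' response_matrix(matrix(c(1, 1, 0, 1, 0, 0), nrow = 3, ncol = 2))
#' @export
response_matrix <- function(x, item_labels = NULL, n_categories = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame", call. = FALSE)
  if (is.double(x)) {
    if (any(!is.na(x) & x != round(x)))
      stop("response codes must be integers", call. = FALSE)
    storage.mode(x) <- "integer"
  }
  if (!is.integer(x)) stop("response codes must be integers", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("a scale needs at least 2 items", call. = FALSE)
  if (n < 1L) stop("at least one respondent is required", call. = FALSE)
  if (is.null(item_labels)) item_labels <- colnames(x)
  if (is.null(item_labels)) item_labels <- paste0("i", seq_len(k))
  item_labels <- as.character(item_labels)
  if (length(item_labels) != k || anyDuplicated(item_labels))
    stop("item labels must be unique and match the number of items",
         call. = FALSE)
  if (is.null(n_categories)) n_categories <- 2L
  n_categories <- as.integer(n_categories)
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, k)
  if (length(n_categories) != k || any(n_categories < 2L))
    stop("`n_categories` must give one count >= 2 per item", call. = FALSE)
  if (anyNA(x)) stop("missing responses must be removed before construction",
                     call. = FALSE)
  for (j in seq_len(k)) {
    bad <- which(x[, j] < 0L | x[, j] > n_categories[j] - 1L)
    if (length(bad))
      stop(sprintf(
        "item '%s' (row %d): code %d outside the declared range 0..%d",
        item_labels[j], bad[1L], x[bad[1L], j], n_categories[j] - 1L),
        call. = FALSE)
  }
  dimnames(x) <- list(NULL, item_labels)
  structure(x, item_labels = item_labels, n_categories = n_categories,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d respondents x %d items\n", nrow(x), ncol(x)))
  nc <- attr(x, "n_categories")
  cat("Items:", paste(sprintf("%s (0..%d)", attr(x, "item_labels"), nc - 1L),
                      collapse = ", "), "\n")
  print(head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

item_labels <- function(x) attr(x, "item_labels")

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(d) lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L)) stop("could not detect a delimiter in ", path,
                              call. = FALSE)
  names(counts)[which.max(counts)]
}

#' Read a respondent-by-item response table from a delimited file
#'
#' Reads a CSV/TSV file with a header row, extracts the named item columns
#' (and, optionally, a sample-weight column), drops rows with any missing
#' item response (listwise deletion) and reports the dropped count.
#'
#' @param path path to a delimited text file (UTF-8, header row).
#' @param item_columns character vector of item column names.
#' @param weight_column optional name of a positive sample-weight column.
#' @param delim field delimiter; `NULL` (default) auto-detects among
#'   comma, tab and semicolon.
#' @param n_categories per-item category counts, see [response_matrix()].
#' @return a list with components `responses` (a [response_matrix()]),
#'   `weights` (numeric vector or `NULL`) and `n_dropped` (rows excluded
#'   by listwise deletion).
#' @export
read_responses <- function(path, item_columns, weight_column = NULL,
                           delim = NULL, n_categories = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- read.table(path, header = TRUE, sep = delim, quote = "\"",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(item_columns, weight_column), names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  items <- df[item_columns]
  for (j in seq_along(items)) {
    v <- items[[j]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric (row %d: '%s')",
                   item_columns[j],
                   which(!is.na(v))[1L], v[which(!is.na(v))[1L]]),
           call. = FALSE)
  }
  keep <- !Reduce(`|`, lapply(items, is.na))
  if (!is.null(weight_column)) keep <- keep & !is.na(df[[weight_column]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " row", if (n_dropped > 1L) "s" else "",
            " excluded (missing responses, listwise deletion)")
  if (!any(keep)) stop("no complete rows remain after listwise deletion",
                       call. = FALSE)
  rm <- response_matrix(as.matrix(items[keep, , drop = FALSE]),
                        item_labels = item_columns,
                        n_categories = n_categories)
  w <- NULL
  if (!is.null(weight_column)) {
    w <- as.numeric(df[[weight_column]][keep])
    if (any(w <= 0)) stop(sprintf(
      "weight column '%s' contains non-positive values (row %d)",
      weight_column, which(w <= 0)[1L]), call. = FALSE)
  }
  list(responses = rm, weights = w, n_dropped = n_dropped)
}

#' Write a response matrix (and optional weights) to CSV
#'
#' Round-trip companion of [read_responses()]: a written matrix re-reads
#' identically.
#'
#' @param rm a [response_matrix()].
#' @param path output file path.
#' @param weights optional positive weight vector, written as column `sw`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path, weights = NULL) {
  df <- as.data.frame(unclass(rm))
  names(df) <- item_labels(rm)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(rm))
    df$sw <- weights
  }
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
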