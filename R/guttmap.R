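#' Fit a Guttman error map
#'
#' The full pipeline: validate the responses, optionally rescale survey
#' weights to integer internal weights (and apply them either by direct
#' frequency weighting, the default, or by case expansion), order the items
#' by endorsement, count observed and independence-expected Guttman errors
#' per pair, and derive the e_ij percentage matrix and the Loevinger
#' coefficients. The result prints as a summary and plots as the map.
#'
#' @param data a data frame, a [response_matrix()], or a path to a
#'   delimited file (read via [read_responses()]).
#' @param items character vector of item columns; `NULL` (with a data
#'   frame/file) uses all non-weight columns.
#' @param sw sampling weights: a column name (data frame/file input) or a
#'   numeric vector; `NULL` for unweighted analysis.
#' @param scl scaling factor for the weight transform (default 1).
#' @param sclmsg print the weight-transform diagnostics (default `FALSE`).
#' @param item_order `"decreasing"` (default) or `"custom"`.
#' @param custom explicit item permutation when `item_order = "custom"`.
#' @param engine `"weighted"` (default; frequency-weighted counting with
#'   the integer internal weights) or `"expand"` (case expansion, the
#'   historical workaround; both give identical results).
#' @param n_categories per-item category counts, see [response_matrix()].
#' @param obs print the effective sample size (default `FALSE`).
#' @param mat print the full matrix report (default `FALSE`).
#' @param expand_cap row cap for the expansion engine (default 5e6).
#' @return an object of class `guttmap`: list with `responses`, `weights`
#'   (a `weight_vector` or `NULL`), `ordering`, `counts`, `error_map`, `h`,
#'   `n_eff` and `engine`.
#' @examples
#' rm <- generate_guttman(300, c(0.2, 0.4, 0.6, 0.8), error_rate = 0.1,
#'                        seed = 7)
#' fit <- guttman_error_map(rm)
#' fit$h$h_total
#' @export
guttman_error_map <- function(data, items = NULL, sw = NULL, scl = 1,
                              sclmsg = FALSE,
                              item_order = c("decreasing", "custom"),
                              custom = NULL,
                              engine = c("weighted", "expand"),
                              n_categories = NULL, obs = FALSE, mat = FALSE,
                              expand_cap = 5e6) {
  item_order <- match.arg(item_order)
  engine <- match.arg(engine)
  raw_w <- NULL
  if (is.character(data) && length(data) == 1L) {
    if (is.null(items)) stop("`items` is required with file input",
                             call. = FALSE)
    inp <- read_responses(data, items,
                          weight_column = if (is.character(sw)) sw,
                          n_categories = n_categories)
    rm <- inp$responses
    raw_w <- inp$weights
  } else if (inherits(data, "response_matrix")) {
    rm <- data
    if (is.character(sw)) stop("pass `sw` as a vector with matrix input",
                               call. = FALSE)
    raw_w <- sw
  } else if (is.data.frame(data)) {
    if (is.character(sw)) {
      if (!sw %in% names(data)) stop("weight column not found: ", sw,
                                     call. = FALSE)
      raw_w <- as.numeric(data[[sw]])
      if (is.null(items)) items <- setdiff(names(data), sw)
    } else {
      raw_w <- sw
      if (is.null(items)) items <- names(data)
    }
    keep <- !Reduce(`|`, lapply(data[items], is.na))
    dropped <- sum(!keep)
    if (dropped > 0L)
      message(dropped, " row(s) excluded (missing responses, listwise ",
              "deletion)")
    rm <- response_matrix(as.matrix(data[keep, items, drop = FALSE]),
                          item_labels = items, n_categories = n_categories)
    if (!is.null(raw_w)) raw_w <- raw_w[keep]
  } else {
    stop("`data` must be a data frame, response_matrix or file path",
         call. = FALSE)
  }

  wv <- NULL
  w_use <- NULL
  if (!is.null(raw_w)) {
    wv <- rescale_weights(raw_w, scl)
    if (isTRUE(sclmsg)) print(weight_diagnostics(raw_w, scl))
    if (engine == "expand") {
      rm_an <- expand_rows(rm, wv, cap = expand_cap)
    } else {
      rm_an <- rm
      w_use <- wv$sw1
    }
  } else {
    rm_an <- rm
  }

  endo <- endorsement(rm_an, w_use)
  ordering <- order_items(endo, mode = item_order, custom = custom)
  counts <- pair_counts(rm_an, ordering, w_use)
  em <- error_matrix(counts)
  hs <- loevinger(counts)
  if (isTRUE(obs))
    message("Effective sample size: ", format(counts$n_eff))
  if (isTRUE(mat)) mat_report(em, hs, counts$n_eff)
  structure(list(responses = rm, weights = wv, ordering = ordering,
                 counts = counts, error_map = em, h = hs,
                 n_eff = counts$n_eff, engine = engine),
            class = "guttmap")
}

#' @export
print.guttmap <- function(x, ...) {
  k <- length(x$error_map$labels)
  cat(sprintf("Guttman error map fit: %d items, effective n = %g%s\n",
              k, x$n_eff,
              if (is.null(x$weights)) "" else
                sprintf(" (weighted, scl = %g, engine = %s)",
                        x$weights$scl, x$engine)))
  print(x$ordering)
  cat("\n")
  mat_report(x$error_map, x$h, x$n_eff)
  invisible(x)
}

#' Plot method for fitted maps
#'
#' @param x a `guttmap` object from [guttman_error_map()].
#' @param ... arguments forwarded to [render_options()].
#' @return a ggplot object.
#' @export
plot.guttmap <- function(x, ...) {
  render_map(x$error_map, x$h, render_options(...))
}
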