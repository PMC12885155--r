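resolve_weights <- function(rm, weights) {
  if (is.null(weights)) return(rep(1, nrow(rm)))
  w <- if (inherits(weights, "weight_vector")) weights$sw1 else as.numeric(weights)
  if (length(w) != nrow(rm))
    stop("weights do not align with the rows of the response matrix",
         call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  w
}

#' Per-item endorsement
#'
#' Weighted mean response per item; for dichotomous items this is the
#' proportion of respondents endorsing the item. Endorsement drives the item
#' ordering on the map: the less frequently an item is endorsed, the higher
#' the intensity of the construct region it maps.
#'
#' @param rm a [response_matrix()].
#' @param weights optional row weights: a numeric vector or a
#'   `weight_vector` (its integer `sw1` is used). `NULL` means unit weights.
#' @return named numeric vector of weighted endorsements, one per item, in
#'   input item order.
#' @export
endorsement <- function(rm, weights = NULL) {
  w <- resolve_weights(rm, weights)
  setNames(as.numeric(crossprod(unclass(rm), w) / sum(w)), item_labels(rm))
}

#' Order items by endorsement
#'
#' Produces the item ordering used for the map axes and the easy/hard
#' orientation of pairs. `"decreasing"` sorts by endorsement from the most
#' to the least endorsed item (left to right), breaking ties by original
#' input position; `"custom"` applies a user-supplied permutation verbatim.
#'
#' @param endorsement named numeric vector from [endorsement()].
#' @param mode `"decreasing"` (default) or `"custom"`.
#' @param custom permutation of item indices or labels, required when
#'   `mode = "custom"`.
#' @return an object of class `item_ordering`: list with `order` (integer
#'   permutation into input positions), `endorsement` (input order) and
#'   `labels` (in display order).
#' @export
order_items <- function(endorsement, mode = c("decreasing", "custom"),
                        custom = NULL) {
  mode <- match.arg(mode)
  k <- length(endorsement)
  labs <- names(endorsement)
  if (is.null(labs)) labs <- paste0("i", seq_len(k))
  if (mode == "decreasing") {
    ord <- order(-endorsement)  # stable: ties keep input position
  } else {
    if (is.null(custom)) stop("`custom` is required when mode = \"custom\"",
                              call. = FALSE)
    ord <- if (is.character(custom)) match(custom, labs) else as.integer(custom)
    if (anyNA(ord) || length(ord) != k || !setequal(ord, seq_len(k)))
      stop("`custom` is not a valid permutation of the items", call. = FALSE)
  }
  structure(list(order = ord, endorsement = endorsement, labels = labs[ord]),
            class = "item_ordering")
}

#' @export
print.item_ordering <- function(x, ...) {
  cat("Item ordering:",
      paste(sprintf("%s (%.3f)", x$labels, x$endorsement[x$order]),
            collapse = " > "), "\n")
  invisible(x)
}

#' Observed and expected Guttman-error counts per item pair
#'
#' For every (unordered) item pair the observed Guttman-error mass `F` --
#' the weighted count of respondents passing the harder (less popular) item
#' step while failing the easier one -- and the mass `E` expected under
#' statistical independence of the items at their observed margins. For a
#' dichotomous pair with endorsements \eqn{p_a \ge p_b},
#' \deqn{F = \sum_i w_i [X_{ia} = 0][X_{ib} = 1], \quad
#'       E = n_{eff} (1 - p_a) p_b.}
#' Polytomous items are handled through their item steps (the indicators
#' \eqn{X_j \ge s}): each step pair contributes one observed-error count and
#' one independence expectation, the more popular step of the pair acting as
#' the easy one, and `F`, `E` are the sums over all step pairs of the item
#' pair. With all items dichotomous this reduces exactly to the rule above.
#'
#' A pair whose expectation is zero (an item endorsed by all or none) is
#' flagged undefined (`E = 0`) rather than silently zero.
#'
#' @param rm a [response_matrix()].
#' @param ordering an [order_items()] result; `NULL` computes the default
#'   decreasing-endorsement ordering.
#' @param weights optional row weights as in [endorsement()].
#' @return an object of class `pair_counts`: list with `F`, `E` (k x k
#'   symmetric matrices in display order, diagonal `NA`), `n_eff` (total
#'   analysed weight), `ordering` and `labels`.
#' @export
pair_counts <- function(rm, ordering = NULL, weights = NULL) {
  w <- resolve_weights(rm, weights)
  if (is.null(ordering)) ordering <- order_items(endorsement(rm, w))
  if (!inherits(ordering, "item_ordering"))
    stop("`ordering` must come from order_items()", call. = FALSE)
  k <- ncol(rm)
  n_eff <- sum(w)
  nc <- attr(rm, "n_categories")
  X <- unclass(rm)[, ordering$order, drop = FALSE]
  m <- nc[ordering$order] - 1L  # steps per item, display order

  # step indicator columns, grouped by item
  steps <- lapply(seq_len(k), function(j)
    vapply(seq_len(m[j]), function(s) as.numeric(X[, j] >= s),
           numeric(nrow(X))))
  pis <- lapply(steps, function(S) as.numeric(crossprod(S, w) / n_eff))

  Fm <- Em <- matrix(NA_real_, k, k, dimnames = list(ordering$labels,
                                                     ordering$labels))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      Fab <- Eab <- 0
      for (s in seq_len(m[a])) {
        for (t in seq_len(m[b])) {
          # the more popular step is the easy one; ties keep the item that
          # comes first in the display ordering as easy (the value of
          # e_ij is invariant to this choice)
          if (pis[[a]][s] >= pis[[b]][t]) {
            easy <- steps[[a]][, s]; hard <- steps[[b]][, t]
            p_easy <- pis[[a]][s];   p_hard <- pis[[b]][t]
          } else {
            easy <- steps[[b]][, t]; hard <- steps[[a]][, s]
            p_easy <- pis[[b]][t];   p_hard <- pis[[a]][s]
          }
          Fab <- Fab + sum(w * (1 - easy) * hard)
          Eab <- Eab + n_eff * (1 - p_easy) * p_hard
        }
      }
      Fm[a, b] <- Fm[b, a] <- Fab
      Em[a, b] <- Em[b, a] <- Eab
    }
  }
  structure(list(F = Fm, E = Em, n_eff = n_eff, ordering = ordering,
                 labels = ordering$labels),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("Guttman-error pair counts (%d items, effective n = %g)\n",
              length(x$labels), x$n_eff))
  cat("Observed F:\n"); print(round(x$F, 2))
  cat("Expected under independence E:\n"); print(round(x$E, 2))
  invisible(x)
}

#' Guttman-error percentage matrix
#'
#' Converts pair counts into the symmetric matrix of Guttman-error ratios
#' \eqn{e_{ij} = F_{ij} / E_{ij}} expressed in percent -- the quantity the
#' error map displays. The diagonal is absent (`NA`) and is never rendered
#' as a value; pairs with a zero independence expectation are undefined
#' (`NA`) and propagate as such.
#'
#' @param counts a [pair_counts()] object.
#' @return an object of class `error_map`: list with `e_percent` (k x k
#'   symmetric, `NA` diagonal), `ordering` and `labels`.
#' @export
error_matrix <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  e <- 100 * counts$F / counts$E
  e[!is.na(counts$E) & counts$E == 0] <- NA_real_
  structure(list(e_percent = e, ordering = counts$ordering,
                 labels = counts$labels, n_eff = counts$n_eff),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat("Guttman error percentages e_ij (%):\n")
  print(round(x$e_percent, 1))
  invisible(x)
}

#' Loevinger scalability coefficients
#'
#' Computes the Loevinger coefficients from Guttman-error counts:
#' per pair \eqn{h_{ij} = 1 - F_{ij}/E_{ij}}, per item
#' \eqn{h_i = 1 - \sum_j F_{ij} / \sum_j E_{ij}} over all pairs containing
#' item i, and for the scale \eqn{H = 1 - \sum\sum F / \sum\sum E} over all
#' unordered pairs. Undefined pairs (zero expectation) are excluded from the
#' item and scale sums with a warning.
#'
#' @param counts a [pair_counts()] object.
#' @return an object of class `h_summary`: list with `h_pair` (k x k
#'   symmetric), `h_item` (length k, display order) and `h_total`.
#' @export
loevinger <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  undef <- !is.na(counts$E) & counts$E == 0
  if (any(undef)) {
    warning(sum(undef[upper.tri(undef)]),
            " item pair(s) with zero expected Guttman errors excluded ",
            "from h_item/h_total", call. = FALSE)
  }
  Fm <- counts$F; Em <- counts$E
  Fm[undef] <- NA_real_; Em[undef] <- NA_real_
  h_pair <- 1 - Fm / Em
  h_item <- 1 - rowSums(Fm, na.rm = TRUE) / rowSums(Em, na.rm = TRUE)
  ut <- upper.tri(Fm)
  h_total <- 1 - sum(Fm[ut], na.rm = TRUE) / sum(Em[ut], na.rm = TRUE)
  structure(list(h_pair = h_pair,
                 h_item = setNames(h_item, counts$labels),
                 h_total = h_total, labels = counts$labels),
            class = "h_summary")
}

#' @export
print.h_summary <- function(x, ...) {
  cat("Loevinger h_ij:\n"); print(round(x$h_pair, 3))
  cat("Item h_i:\n"); print(round(x$h_item, 3))
  cat(sprintf("Scale H = %.3f (%s scalability)\n", x$h_total,
              classify_h(x$h_total)))
  invisible(x)
}

#' Plain-text matrix report
#'
#' Prints the full numeric companion of the map: the e_ij percentage matrix
#' (1 decimal), the pairwise, item and total Loevinger coefficients
#' (3 decimals), and the effective sample size.
#'
#' @param em an [error_matrix()] result.
#' @param hs a [loevinger()] result.
#' @param n_eff effective (weighted) sample size; taken from `em` if `NULL`.
#' @return the report lines, invisibly, as a character vector.
#' @export
mat_report <- function(em, hs, n_eff = NULL) {
  stopifnot(inherits(em, "error_map"), inherits(hs, "h_summary"))
  if (is.null(n_eff)) n_eff <- em$n_eff
  fmt_mat <- function(M, digits) {
    out <- format(round(M, digits), nsmall = digits)
    out[is.na(M)] <- "."
    mt <- matrix(out, nrow(M), dimnames = dimnames(M))
    paste(utils::capture.output(print(mt, quote = FALSE)), collapse = "\n")
  }
  lines <- c(
    sprintf("Effective sample size: %g", n_eff),
    "", "Guttman error percentages e_ij (%):", fmt_mat(em$e_percent, 1),
    "", "Loevinger pairwise coefficients h_ij:", fmt_mat(hs$h_pair, 3),
    "", "Loevinger item coefficients h_i:",
    paste(sprintf("  %s = %.3f", hs$labels, hs$h_item), collapse = "\n"),
    "", sprintf("Loevinger scale coefficient H = %.3f", hs$h_total))
  cat(lines, sep = "\n")
  invisible(lines)
}
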