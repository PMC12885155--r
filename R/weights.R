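# round to nearest integer, halves away from zero (weights are positive,
# so this is floor(x + 0.5)); base round() would round halves to even
round_half_up <- function(x) floor(x + 0.5)

#' Rescale sampling weights to positive integers
#'
#' Transforms positive survey weights into the integer internal weights used
#' for frequency-weighted counting or case expansion:
#' \deqn{sw_1 = round(sw_{orig} \cdot s / sw_{min})}
#' where \eqn{sw_{min}} is the minimum original weight and `s` (`scl`) is a
#' user scaling factor. Dividing by the minimum guarantees every observation
#' maps to at least `round(s)` copies, so no respondent is dropped by
#' rounding; larger `s` preserves more of the relative-weight resolution at
#' the cost of a larger expanded sample. Rounding is to the nearest integer,
#' halves away from zero.
#'
#' @param sw_orig positive numeric vector of original sampling weights.
#' @param scl scaling factor `s >= 1` (default 1).
#' @return an object of class `weight_vector`: a list with `sw_orig`,
#'   `sw_min`, `scl` and the integer internal weights `sw1`.
#' @examples
#' rescale_weights(c(0.311, 1.0, 2.052), scl = 100)$sw1  # 100 322 660
#' @export
rescale_weights <- function(sw_orig, scl = 1) {
  sw_orig <- as.numeric(sw_orig)
  if (length(sw_orig) < 1L || anyNA(sw_orig))
    stop("weights must be non-missing", call. = FALSE)
  if (any(sw_orig <= 0))
    stop(sprintf("non-positive sampling weight at position %d",
                 which(sw_orig <= 0)[1L]), call. = FALSE)
  if (!is.numeric(scl) || length(scl) != 1L || scl < 1)
    stop("`scl` must be a single number >= 1", call. = FALSE)
  sw_min <- min(sw_orig)
  sw1 <- as.numeric(round_half_up(sw_orig * scl / sw_min))
  structure(list(sw_orig = sw_orig, sw_min = sw_min, scl = scl, sw1 = sw1),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf(
    "Weight vector: n = %d, original range [%g, %g], scl = %g\n",
    length(x$sw_orig), min(x$sw_orig), max(x$sw_orig), x$scl))
  cat(sprintf("Internal integer weights sw1: range [%d, %d], %d unique values\n",
              as.integer(min(x$sw1)), as.integer(max(x$sw1)),
              length(unique(x$sw1))))
  invisible(x)
}

#' Expand a response matrix by integer weights
#'
#' Replicates each row of `rm` according to its integer internal weight so
#' that unweighted counting on the expanded data reproduces weighted point
#' estimates. Rows keep their stable input order. Provided for fidelity with
#' the expansion workaround; the frequency-weighted engine in
#' [pair_counts()] is equivalent and cheaper.
#'
#' @param rm a [response_matrix()].
#' @param wv a `weight_vector` from [rescale_weights()] aligned with the
#'   rows of `rm` (or a bare vector of positive integers).
#' @param cap abort if the expanded row count would exceed this (default
#'   5e6); lower `scl` to reduce it.
#' @return the expanded [response_matrix()].
#' @export
expand_rows <- function(rm, wv, cap = 5e6) {
  sw1 <- if (inherits(wv, "weight_vector")) wv$sw1 else as.numeric(wv)
  if (length(sw1) != nrow(rm))
    stop("weights do not align with the rows of `rm`", call. = FALSE)
  if (any(sw1 < 1) || any(sw1 != round(sw1)))
    stop("internal weights must be integers >= 1; use rescale_weights()",
         call. = FALSE)
  total <- sum(sw1)
  if (total > cap)
    stop(sprintf(paste0(
      "expansion would create %.0f rows (cap %.0f); ",
      "lower `scl` or raise `cap`"), total, cap), call. = FALSE)
  idx <- rep.int(seq_len(nrow(rm)), sw1)
  response_matrix(unclass(rm)[idx, , drop = FALSE],
                  item_labels = item_labels(rm),
                  n_categories = attr(rm, "n_categories"))
}

#' Diagnostics for the weight rescaling transform
#'
#' Summarises what the integer rescaling does to a weight vector -- the
#' information printed to the console under `sclmsg` -- to guide the choice
#' of `scl`: original and transformed ranges, how many distinct integer
#' weights survive, the total expanded sample size, and how many
#' observations naive rounding of the raw weights would have dropped
#' (rounded to 0) or left unexpanded (rounded to 1).
#'
#' @inheritParams rescale_weights
#' @return an object of class `weight_diagnostics` (a list), with a print
#'   method.
#' @export
weight_diagnostics <- function(sw_orig, scl = 1) {
  wv <- rescale_weights(sw_orig, scl)
  naive <- round_half_up(wv$sw_orig)
  structure(list(
    n = length(sw_orig),
    scl = scl,
    orig_min = min(wv$sw_orig), orig_max = max(wv$sw_orig),
    sw1_min = min(wv$sw1), sw1_max = max(wv$sw1),
    n_unique = length(unique(wv$sw1)),
    total_expanded = sum(wv$sw1),
    naive_dropped = sum(naive == 0),
    naive_unexpanded = sum(naive == 1)
  ), class = "weight_diagnostics")
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat("Sample-weight transformation (scl =", x$scl, ")\n")
  cat(sprintf("  original weights : n = %d, range [%g, %g]\n",
              x$n, x$orig_min, x$orig_max))
  cat(sprintf("  internal weights : range [%d, %d], %d unique integer values\n",
              as.integer(x$sw1_min), as.integer(x$sw1_max), x$n_unique))
  cat(sprintf("  expanded size    : %.0f rows\n", x$total_expanded))
  cat(sprintf(paste0(
    "  naive rounding of raw weights would drop %d observation(s) ",
    "(weight rounding to 0)\n  and leave %d unexpanded (rounding to 1)\n"),
    x$naive_dropped, x$naive_unexpanded))
  invisible(x)
}
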