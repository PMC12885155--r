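with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  code
}

#' Generate a noisy Guttman scalogram
#'
#' Simulates dichotomous responses from the cumulative-scale model: each
#' respondent draws a latent trait uniform on (0, 1) and endorses item j
#' exactly when the trait exceeds the item's difficulty -- a perfect
#' scalogram -- after which every response flips independently with
#' probability `error_rate`. With `error_rate = 0` the data contain no
#' Guttman errors and the scale coefficient is exactly 1; with
#' `error_rate = 0.5` responses are independent of the trait and the mean
#' pairwise error ratio approaches 100% as n grows.
#'
#' @param n number of respondents.
#' @param difficulties strictly increasing item difficulties in (0, 1);
#'   item j's expected endorsement is `1 - difficulties[j]`.
#' @param error_rate independent response-flip probability in `[0, 1]`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a dichotomous [response_matrix()] with items `i1..ik`.
#' @export
generate_guttman <- function(n, difficulties, error_rate = 0, seed = NULL) {
  stopifnot(n >= 1, length(difficulties) >= 2)
  if (is.unsorted(difficulties, strictly = TRUE) ||
      any(difficulties <= 0) || any(difficulties >= 1))
    stop("`difficulties` must be strictly increasing within (0, 1)",
         call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("`error_rate` must lie in [0, 1]", call. = FALSE)
  k <- length(difficulties)
  with_seed(seed, {
    trait <- runif(n)
    x <- outer(trait, difficulties, `>`) + 0L
    if (error_rate > 0) {
      flip <- matrix(rbinom(n * k, 1L, error_rate), n, k)
      x <- abs(x - flip)
    }
    response_matrix(x, item_labels = paste0("i", seq_len(k)))
  })
}

#' Emulate a data set by three-step resampling
#'
#' Produces a synthetic copy of a response matrix that preserves the
#' joint item profiles of the original while breaking the link to
#' individual records. Three steps: (1) the original data are trimmed
#' (uniform subsampling without replacement) or expanded (resampling with
#' replacement) to exactly `n_target` rows; (2) for each output row,
#' `n_target` candidate records are drawn with replacement from the step-1
#' data; (3) one of those candidates is selected uniformly to fill the row.
#' Steps 2-3 compose to a single uniform draw per row; `method = "direct"`
#' takes that shortcut (the two are distributionally equivalent),
#' `"three-step"` (default) performs the procedure literally.
#'
#' @param rm a [response_matrix()] (whole rows are resampled, preserving
#'   inter-item dependence).
#' @param n_target output size (default 1000).
#' @param seed integer seed; deterministic given the seed.
#' @param method `"three-step"` (literal) or `"direct"` (single uniform
#'   draw per row).
#' @return a [response_matrix()] with exactly `n_target` rows.
#' @export
emulate_dataset <- function(rm, n_target = 1000, seed = NULL,
                            method = c("three-step", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(rm, "response_matrix"))
  if (n_target < 1) stop("`n_target` must be at least 1", call. = FALSE)
  n <- nrow(rm)
  with_seed(seed, {
    base_idx <- if (n > n_target) sample.int(n, n_target, replace = FALSE)
                else if (n < n_target) sample.int(n, n_target, replace = TRUE)
                else seq_len(n)
    pick <- if (method == "three-step") {
      vapply(seq_len(n_target), function(r) {
        candidates <- sample.int(n_target, n_target, replace = TRUE)
        candidates[sample.int(n_target, 1L)]
      }, integer(1))
    } else {
      sample.int(n_target, n_target, replace = TRUE)
    }
    response_matrix(unclass(rm)[base_idx[pick], , drop = FALSE],
                    item_labels = item_labels(rm),
                    n_categories = attr(rm, "n_categories"))
  })
}

#' Generate a sampling-weight fixture
#'
#' Draws positive weights log-uniformly on `[low, high]`. The first two
#' entries are pinned to `low` and `high` so every fixture contains the
#' range endpoints by construction.
#'
#' @param n number of weights (at least 2 unless `low == high`).
#' @param low,high positive range bounds, `low <= high`.
#' @param seed integer seed.
#' @return numeric weight vector of length `n`.
#' @export
generate_weights <- function(n, low, high, seed = NULL) {
  if (!(low > 0 && high >= low)) stop("need 0 < low <= high", call. = FALSE)
  stopifnot(n >= 1)
  with_seed(seed, {
    w <- exp(runif(n, log(low), log(high)))
    if (n >= 1) w[1L] <- low
    if (n >= 2) w[2L] <- high
    w
  })
}

#' Write a fixture (responses + weights) with a reproducibility manifest
#'
#' Emits the CSV response table (weight column `sw` when given) alongside a
#' JSON manifest recording the seed and generation parameters.
#'
#' @param rm a [response_matrix()].
#' @param path CSV output path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @param weights optional weight vector.
#' @param seed,params seed and parameter list recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rm, path, weights = NULL, seed = NULL,
                          params = list()) {
  write_responses(rm, path, weights)
  manifest <- list(file = basename(path), n = nrow(rm),
                   items = item_labels(rm),
                   n_categories = attr(rm, "n_categories"),
                   has_weights = !is.null(weights),
                   seed = seed, params = params)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
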