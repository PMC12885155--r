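#' Traffic-light banding scheme for Guttman-error percentages
#'
#' Defines the acceptability bands and the colour gradient used by the map.
#' The bands partition `[0, Inf)` by the boundaries 50, 60, 70 (in percent,
#' the complements of Mokken's h cutoffs 0.5/0.4/0.3): up to 50% suggests no
#' problems; above 50 up to 60%, errors admissible with reservation; above
#' 60 up to 70%, borderline; above 70%, real scalability problems.
#'
#' The default gradient runs through seven stops from green (no error) over
#' greenish-yellow and yellow at the tolerable bands to orange and deep red
#' at complete error; the published palette's exact RGB values are not
#' recoverable, so these stops are a documented approximation and can be
#' replaced.
#'
#' @param boundaries increasing band boundaries in percent
#'   (default `c(50, 60, 70)`).
#' @param stops data frame with numeric `value` (percent, increasing,
#'   spanning 0..100) and character `color` (hex) columns.
#' @return an object of class `band_scheme`.
#' @export
band_scheme <- function(boundaries = c(50, 60, 70),
                        stops = default_stops()) {
  stopifnot(length(boundaries) == 3L, !is.unsorted(boundaries, strictly = TRUE))
  stopifnot(is.data.frame(stops), all(c("value", "color") %in% names(stops)),
            !is.unsorted(stops$value, strictly = TRUE),
            stops$value[1L] == 0, stops$value[nrow(stops)] == 100)
  structure(list(boundaries = boundaries,
                 labels = c("no-problems", "admissible-with-reservation",
                            "borderline", "problematic"),
                 stops = stops),
            class = "band_scheme")
}

default_stops <- function() {
  data.frame(
    value = c(0, 25, 50, 60, 70, 85, 100),
    color = c("#1A9850", "#66BD63", "#D9EF8B", "#FEE08B",
              "#FDAE61", "#D73027", "#A50026"),
    stringsAsFactors = FALSE)
}

#' Acceptability band of a Guttman-error percentage
#'
#' Classifies e_ij percentages into the four bands of [band_scheme()]:
#' `<= 50` no-problems, `(50, 60]` admissible-with-reservation, `(60, 70]`
#' borderline, `> 70` problematic (values above 100% are problematic too).
#'
#' @param e numeric vector of error percentages, `>= 0`.
#' @param scheme a [band_scheme()].
#' @return factor with the four band labels, in increasing severity.
#' @examples
#' error_band(c(14.3, 50, 50.01, 66.9, 120))
#' @export
error_band <- function(e, scheme = band_scheme()) {
  if (any(e < 0, na.rm = TRUE)) stop("error percentages must be >= 0",
                                     call. = FALSE)
  b <- scheme$boundaries
  cut(e, breaks = c(-Inf, b, Inf), labels = scheme$labels, right = TRUE)
}

#' Gradient colour of a Guttman-error percentage
#'
#' Maps an error percentage to a colour by piecewise-linear interpolation
#' (in RGB) between the scheme's colour stops. Values at or above 100 clamp
#' to the deepest red; negative input is clamped to the green endpoint.
#'
#' @inheritParams error_band
#' @return character vector of hex colours.
#' @export
error_color <- function(e, scheme = band_scheme()) {
  ramp <- grDevices::colorRamp(scheme$stops$color, space = "rgb")
  # map e through the stop positions so band boundaries land on their stops
  x <- pmin(pmax(e, 0), 100)
  t <- stats::approx(scheme$stops$value, seq(0, 1, length.out = nrow(scheme$stops)),
                     xout = x, rule = 2)$y
  out <- rep(NA_character_, length(e))
  ok <- !is.na(t)
  m <- ramp(t[ok])
  out[ok] <- rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  out
}

#' Mokken's qualitative categories for Loevinger coefficients
#'
#' Classifies h (pairwise, item or scale) by the conventional cutoffs:
#' below 0.3 poor, 0.3 to below 0.4 weak, 0.4 to below 0.5 moderate, 0.5
#' and above strong (the cutoff 0.5 itself is assigned to strong).
#'
#' @param h numeric vector of Loevinger coefficients, each `<= 1`.
#' @return factor with levels poor, weak, moderate, strong.
#' @examples
#' classify_h(c(0.863, 0.124, 0.4, 0.5))
#' @export
classify_h <- function(h) {
  if (any(h > 1 + 1e-12, na.rm = TRUE))
    stop("Loevinger coefficients cannot exceed 1", call. = FALSE)
  cut(h, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf),
      labels = c("poor", "weak", "moderate", "strong"), right = FALSE)
}
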