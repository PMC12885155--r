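fit_small <- function(seed = 21, n = 300, k = 4) {
  rm <- generate_guttman(n, seq(0.2, 0.8, length.out = k),
                         error_rate = 0.15, seed = seed)
  guttman_error_map(rm)
}

test_that("smooth = 0 reproduces the blockwise-constant field exactly", {
  fit <- fit_small()
  em <- fit$error_map
  k <- nrow(em$e_percent); res <- 11
  fld <- smooth_field(em, 0, res = res)
  cell <- ceiling(((seq_len(k * res)) - 0.5) / res)
  expected <- em$e_percent[cell, cell]
  dimnames(expected) <- NULL
  expect_equal(fld, expected)
})

test_that("full smoothing anchors the field at every cell centre", {
  fit <- fit_small()
  em <- fit$error_map
  k <- nrow(em$e_percent); res <- 11
  fld <- smooth_field(em, 100, res = res)
  centre <- function(i) res * i - (res - 1) / 2   # pixel index of centre
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) {
      expect_true(is.na(fld[centre(i), centre(j)]))
    } else {
      expect_equal(fld[centre(i), centre(j)], em$e_percent[i, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("smoothing a constant matrix returns a constant field", {
  em <- structure(list(
    e_percent = matrix(c(NA, 40, 40, 40, NA, 40, 40, 40, NA), 3, 3),
    labels = c("a", "b", "c")), class = "error_map")
  for (s in c(0, 30, 100)) {
    fld <- smooth_field(em, s, res = 5)
    expect_true(all(abs(fld[!is.na(fld)] - 40) < 1e-12))
  }
})

test_that("intermediate smoothing is the per-pixel convex blend", {
  fit <- fit_small()
  em <- fit$error_map
  f0 <- smooth_field(em, 0); f100 <- smooth_field(em, 100)
  f40 <- smooth_field(em, 40)
  expect_equal(f40, 0.6 * f0 + 0.4 * f100, tolerance = 1e-12)
  expect_error(smooth_field(em, 101), "0, 100")
  expect_error(smooth_field(em, -1), "0, 100")
})

test_that("the diagonal stays masked at every smoothing level", {
  fit <- fit_small()
  res <- 7
  cell <- ceiling((seq_len(4 * res) - 0.5) / res)
  on_diag <- outer(cell, cell, `==`)
  for (s in c(0, 25, 100)) {
    fld <- smooth_field(fit$error_map, s, res = res)
    expect_true(all(is.na(fld[on_diag])))
    expect_true(!anyNA(fld[!on_diag]))
  }
})

test_that("the map draws both triangles, annotated with formatted values", {
  fit <- fit_small()
  p <- render_map(fit$error_map, fit$h, render_options(font = "sans"))
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  tiles <- built$data[[1]]
  k <- 4
  expect_identical(nrow(tiles), as.integer(k * (k - 1)))  # no diagonal cells

  texts <- built$data[[2]]
  expect_identical(sort(unique(texts$label)),
                   sort(unique(sprintf("%.1f",
                     fit$error_map$e_percent[upper.tri(diag(k))]))))
  # symmetric: every annotation appears once per triangle
  expect_identical(nrow(texts), as.integer(k * (k - 1)))
})

test_that("valsize = 0 removes all annotations", {
  fit <- fit_small()
  p <- render_map(fit$error_map, fit$h,
                  render_options(valsize = 0, font = "sans"))
  built <- ggplot2::ggplot_build(p)
  classes <- vapply(p$layers, function(l) class(l$geom)[1], character(1))
  expect_false("GeomText" %in% classes)
})

test_that("item labels honour position, tith and itemh options", {
  fit <- fit_small()
  p_top <- render_map(fit$error_map, fit$h,
                      render_options(item_position = "top", itemh = TRUE,
                                     tith = TRUE, font = "sans"))
  expect_identical(p_top$scales$get_scales("x")$position, "top")
  expect_match(p_top$labels$title,
               sprintf("H = %.3f", fit$h$h_total), fixed = TRUE)
  p_bot <- render_map(fit$error_map, fit$h, render_options(font = "sans"))
  expect_identical(p_bot$scales$get_scales("x")$position, "bottom")
  expect_false(grepl("H =", p_bot$labels$title))
})

test_that("repeated SVG exports are byte-identical", {
  fit <- fit_small()
  p <- render_map(fit$error_map, fit$h, render_options(font = "sans"))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  export_map(p, f1, format = "svg")
  export_map(p, f2, format = "svg")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_match(readLines(f1, n = 2)[2], "<svg")
})

test_that("export covers the vector and raster formats", {
  fit <- fit_small()
  p <- render_map(fit$error_map, fit$h, render_options(font = "sans"))
  for (fmt in c("pdf", "png", "jpg", "ps")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_map(p, f, format = fmt, dpi = 72)
    expect_gt(file.size(f), 0)
  }
  expect_error(export_map(p, "out.bmp", format = "bmp"))
  expect_error(export_map(p, "no/such/dir/x.svg"), "directory")
})

test_that("smoothing changes only the colour field, never the annotations", {
  fit <- fit_small()
  p0 <- render_map(fit$error_map, fit$h,
                   render_options(smooth = 0, font = "sans"))
  p80 <- render_map(fit$error_map, fit$h,
                    render_options(smooth = 80, font = "sans"))
  lab0 <- ggplot2::ggplot_build(p0)$data[[2]]$label
  lab80 <- ggplot2::ggplot_build(p80)$data[[2]]$label
  expect_identical(sort(lab0), sort(lab80))
})
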