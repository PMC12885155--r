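make_rm <- function(patterns, counts, labels = c("A", "B")) {
  x <- do.call(rbind, mapply(function(p, n) matrix(p, n, length(p),
               byrow = TRUE), patterns, counts, SIMPLIFY = FALSE))
  response_matrix(x, item_labels = labels)
}

test_that("endorsement is the (weighted) mean response", {
  rm <- response_matrix(cbind(c(rep(1L, 7), rep(0L, 3)), rep(0L, 10)),
                        item_labels = c("a", "b"))
  expect_equal(unname(endorsement(rm)), c(0.7, 0))

  rm2 <- response_matrix(cbind(c(1L, 0L), c(1L, 1L)),
                         item_labels = c("a", "b"))
  expect_equal(unname(endorsement(rm2, weights = c(3, 1))[1]), 0.75)
  expect_error(endorsement(rm2, weights = c(1, 2, 3)), "align")
})

test_that("decreasing ordering sorts by endorsement with stable ties", {
  e <- c(i1 = 0.2, i2 = 0.9, i3 = 0.5)
  expect_identical(order_items(e)$order, c(2L, 3L, 1L))
  expect_identical(order_items(c(a = 0.5, b = 0.5))$order, c(1L, 2L))
  expect_identical(
    order_items(e, mode = "custom", custom = c("i3", "i1", "i2"))$labels,
    c("i3", "i1", "i2"))
  expect_error(order_items(e, mode = "custom", custom = c(1L, 1L, 2L)),
               "permutation")
  expect_error(order_items(e, mode = "custom"), "required")
})

test_that("pair counts match exhaustive enumeration of the joint table", {
  rm <- make_rm(list(c(1, 1), c(1, 0), c(0, 1), c(0, 0)), c(3, 4, 1, 2))
  pc <- pair_counts(rm)
  expect_equal(pc$F["A", "B"], 1)
  expect_equal(pc$E["A", "B"], 10 * 0.3 * 0.4)
  expect_equal(pc$n_eff, 10)

  em <- error_matrix(pc)
  expect_equal(em$e_percent["A", "B"], 100 * 1 / 1.2)
  hs <- loevinger(pc)
  expect_equal(hs$h_pair["A", "B"], 1 - 1 / 1.2)
  expect_equal(hs$h_total, 1 - 1 / 1.2)
})

test_that("a perfect scalogram has zero errors and H = 1", {
  rm <- make_rm(list(c(1, 1), c(1, 0), c(0, 0)), c(4, 3, 3))
  pc <- pair_counts(rm)
  expect_equal(pc$F["A", "B"], 0)
  expect_equal(error_matrix(pc)$e_percent["A", "B"], 0)
  expect_equal(loevinger(pc)$h_total, 1)
})

test_that("exact independence gives e = 100% and H = 0", {
  rm <- make_rm(list(c(1, 1), c(1, 0), c(0, 1), c(0, 0)), rep(25, 4))
  pc <- pair_counts(rm)
  expect_equal(pc$F["A", "B"], 25)
  expect_equal(pc$E["A", "B"], 25)
  expect_equal(error_matrix(pc)$e_percent["A", "B"], 100)
  expect_equal(loevinger(pc)$h_total, 0)
})

test_that("degenerate items yield undefined pairs, excluded with a warning", {
  rm <- response_matrix(cbind(rep(1L, 6), c(1L, 1L, 0L, 0L, 0L, 0L),
                              c(1L, 0L, 1L, 0L, 1L, 0L)),
                        item_labels = c("all1", "b", "c"))
  pc <- pair_counts(rm)
  expect_equal(unname(pc$E["all1", "b"]), 0)
  em <- error_matrix(pc)
  expect_true(is.na(em$e_percent["all1", "b"]))
  expect_warning(hs <- loevinger(pc), "zero expected")
  expect_true(is.finite(hs$h_total))
})

test_that("pairwise h equals the covariance oracle to 1e-12", {
  for (seed in 1:50) {
    rm <- random_binary_rm(200, 5, seed)
    fit <- guttman_error_map(rm)
    H_oracle <- in_display_order(oracle_h_matrix(rm), fit$ordering)
    expect_equal(unname(fit$h$h_pair), H_oracle, tolerance = 1e-12)
  }
})

test_that("weighted pairwise h equals the weighted covariance oracle", {
  for (seed in 1:10) {
    rm <- random_binary_rm(100, 4, seed)
    set.seed(seed + 1000)
    w <- sample(1:7, 100, replace = TRUE)
    pc <- pair_counts(rm, weights = w)
    H_oracle <- in_display_order(oracle_h_matrix(rm, w), pc$ordering)
    expect_equal(unname(loevinger(pc)$h_pair), H_oracle, tolerance = 1e-12)
  }
})

test_that("the error matrix is symmetric with an absent diagonal", {
  for (seed in 1:10) {
    em <- error_matrix(pair_counts(random_binary_rm(80, 5, seed)))
    expect_true(all(is.na(diag(em$e_percent))))
    off <- em$e_percent; diag(off) <- 0
    expect_identical(off, t(off))
    expect_true(all(off >= 0))
  }
})

test_that("coefficients are invariant to a global rescaling of the weights", {
  rm <- random_binary_rm(150, 4, 42)
  set.seed(99)
  w <- runif(150, 0.2, 3)
  base <- loevinger(pair_counts(rm, weights = w))
  for (c0 in c(0.01, 7, 1e4)) {
    alt <- loevinger(pair_counts(rm, weights = c0 * w))
    expect_equal(alt$h_pair, base$h_pair, tolerance = 1e-12)
    expect_equal(alt$h_total, base$h_total, tolerance = 1e-12)
  }
})

test_that("item and scale coefficients are ratio-of-sums aggregates", {
  rm <- random_binary_rm(120, 4, 7)
  pc <- pair_counts(rm)
  hs <- loevinger(pc)
  for (i in 1:4)
    expect_equal(unname(hs$h_item[i]),
                 1 - sum(pc$F[i, -i]) / sum(pc$E[i, -i]))
  ut <- upper.tri(pc$F)
  expect_equal(hs$h_total, 1 - sum(pc$F[ut]) / sum(pc$E[ut]))
  expect_true(hs$h_total <= 1 && all(hs$h_item <= 1))
})

test_that("polytomous items reduce to and extend the dichotomous rule", {
  # all-dichotomous data analysed as declared 2-category polytomous steps
  # must agree bit-for-bit with the direct dichotomous enumeration
  rm <- random_binary_rm(150, 4, 11)
  pc <- pair_counts(rm)
  X <- unclass(rm)[, pc$ordering$order]
  p <- unname(colMeans(X))
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(unname(pc$F[a, b]),
                 as.numeric(sum((1 - X[, a]) * X[, b])), tolerance = 0)
    expect_equal(unname(pc$E[a, b]), 150 * (1 - p[a]) * p[b],
                 tolerance = 1e-15)
  }

  # genuinely polytomous data match the step-sum covariance oracle
  for (seed in 1:10) {
    rmp <- random_poly_rm(150, 4, seed)
    fit <- guttman_error_map(rmp)
    H_oracle <- in_display_order(oracle_h_matrix(rmp), fit$ordering)
    expect_equal(unname(fit$h$h_pair), H_oracle, tolerance = 1e-12)
  }
})

test_that("the matrix report prints all sections at stated precision", {
  rm <- random_binary_rm(100, 3, 3)
  fit <- guttman_error_map(rm)
  out <- capture.output(lines <- mat_report(fit$error_map, fit$h))
  txt <- paste(out, collapse = "\n")
  expect_match(txt, "Effective sample size: 100")
  expect_match(txt, "Guttman error percentages")
  expect_match(txt, "pairwise coefficients")
  expect_match(txt, sprintf("H = %.3f", fit$h$h_total), fixed = TRUE)
  e12 <- fit$error_map$e_percent[1, 2]
  expect_match(txt, sprintf("%.1f", e12), fixed = TRUE)
})
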