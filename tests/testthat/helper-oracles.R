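# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's pair-counting code path: they work
# from weighted moments of the raw responses only.

# Loevinger h for one item pair from the covariance identity
# h = cov(Xa, Xb) / cov_max, with cov_max the covariance of the comonotone
# coupling of the two (step) margins. For dichotomous items with
# endorsements pa >= pb this is cov / (pb * (1 - pa)).
oracle_h_pair <- function(xa, xb, w = rep(1, length(xa))) {
  W <- sum(w)
  mu_a <- sum(w * xa) / W
  mu_b <- sum(w * xb) / W
  covab <- sum(w * xa * xb) / W - mu_a * mu_b
  # step proportions P(X >= s)
  ps_a <- vapply(seq_len(max(xa, 1)), function(s) sum(w * (xa >= s)) / W,
                 numeric(1))
  ps_b <- vapply(seq_len(max(xb, 1)), function(s) sum(w * (xb >= s)) / W,
                 numeric(1))
  cov_max <- sum(outer(ps_a, ps_b, pmin) - outer(ps_a, ps_b))
  if (cov_max == 0) return(NA_real_)
  covab / cov_max
}

# full oracle h_pair matrix in input item order
oracle_h_matrix <- function(rm, w = rep(1, nrow(rm))) {
  X <- unclass(rm)
  k <- ncol(X)
  H <- matrix(NA_real_, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k)
    H[a, b] <- H[b, a] <- oracle_h_pair(X[, a], X[, b], w)
  H
}

# random dichotomous response matrix with non-degenerate margins
random_binary_rm <- function(n, k, seed) {
  set.seed(seed)
  repeat {
    p <- runif(k, 0.15, 0.85)
    x <- matrix(rbinom(n * k, 1, rep(p, each = n)), n, k)
    if (all(colMeans(x) > 0 & colMeans(x) < 1)) break
  }
  response_matrix(x)
}

# random polytomous matrix (3 categories per item)
random_poly_rm <- function(n, k, seed) {
  set.seed(seed)
  x <- matrix(sample(0:2, n * k, replace = TRUE,
                     prob = c(0.4, 0.35, 0.25)), n, k)
  response_matrix(x, n_categories = 3L)
}

# reorder an oracle matrix into a fit's display ordering
in_display_order <- function(M, ordering) M[ordering$order, ordering$order]
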