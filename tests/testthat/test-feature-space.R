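random_patterns <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mean = 5), n, p)
  rownames(m) <- sprintf("S%02d", seq_len(n))
  m
}

test_that("rank-1 data concentrates all variance on the first component", {
  v <- c(1, 2, 3, 4)
  x <- outer(seq(0.5, 3, length.out = 8), v)  # points on a line
  rownames(x) <- sprintf("S%d", 1:8)
  fit <- fit_pca(x, mode = "COVARIANCE")
  expect_lt(abs(fit$variance_fractions[1] - 1), 1e-9)

  # near-rank-1 (so the second score column is not degenerate): every
  # channel correlates +-1 with component 1
  set.seed(13)
  x2 <- x + matrix(rnorm(length(x), sd = 1e-5), nrow(x))
  circ <- correlation_circle(fit_pca(x2, mode = "COVARIANCE"))
  expect_true(all(abs(abs(circ$cor_pc1) - 1) < 1e-6))
})

test_that("variance fractions and scores match a brute-force eigendecomposition", {
  for (mode in c("CORRELATION", "COVARIANCE")) {
    x <- random_patterns(6, 4, seed = 17)
    fit <- fit_pca(x, mode = mode)
    oracle <- brute_pca(x, mode = mode)
    k <- ncol(fit$scores)
    expect_equal(fit$variance_fractions[1:k], oracle$fractions[1:k],
                 tolerance = 1e-8)
    for (j in 1:k) {
      agree <- min(
        max(abs(fit$scores[, j] - oracle$scores[, j])),
        max(abs(fit$scores[, j] + oracle$scores[, j]))
      )
      expect_lt(agree, 1e-8)
    }
    # loadings orthonormal, fractions non-increasing
    g <- crossprod(fit$loadings)
    expect_equal(g, diag(ncol(g)), tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(diff(fit$variance_fractions) < 1e-12))
  }
})

test_that("duplicating every pattern leaves variance fractions unchanged", {
  x <- random_patterns(7, 5, seed = 23)
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("S%02d", 1:14)
  expect_equal(
    fit_pca(x, "CORRELATION")$variance_fractions[1:4],
    fit_pca(x2, "CORRELATION")$variance_fractions[1:4],
    tolerance = 1e-9
  )
})

test_that("sign convention makes the fit deterministic", {
  x <- random_patterns(10, 6, seed = 29)
  f1 <- fit_pca(x)
  f2 <- fit_pca(x)
  expect_identical(f1$scores, f2$scores)
  for (j in seq_len(ncol(f1$loadings))) {
    expect_gt(f1$loadings[which.max(abs(f1$loadings[, j])), j], 0)
  }
})

test_that("constant channels are refused in correlation mode", {
  x <- random_patterns(6, 4, seed = 31)
  x[, 2] <- 7
  expect_error(fit_pca(x, "CORRELATION"), class = "soundgate_degenerate_error")
  expect_silent(fit_pca(x, "COVARIANCE"))
})

test_that("correlation circle matches channel-by-channel Pearson correlations", {
  x <- random_patterns(9, 5, seed = 37)
  fit <- fit_pca(x)
  circ <- correlation_circle(fit)
  for (ch in 1:5) {
    expect_equal(circ$cor_pc1[ch], cor(x[, ch], fit$scores[, 1]), tolerance = 1e-8)
    expect_equal(circ$cor_pc2[ch], cor(x[, ch], fit$scores[, 2]), tolerance = 1e-8)
  }
  expect_true(all(abs(c(circ$cor_pc1, circ$cor_pc2)) <= 1 + 1e-12))
})

test_that("a channel carrying the between-category variance tops component 1", {
  set.seed(41)
  n_per <- 12
  x <- matrix(rnorm(3 * n_per * 5, sd = 0.05), 3 * n_per, 5)
  x[, 3] <- x[, 3] + rep(c(0, 4, 8), each = n_per)   # channel 3 separates groups
  rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  # covariance mode: per-channel standardization would equalize the variances
  fit <- fit_pca(x, "COVARIANCE")
  top <- attr(correlation_circle(fit), "top_channels")
  expect_equal(unname(top["pc1"]), 3)
})

test_that("category summaries use the population-SD ellipse convention", {
  scores <- rbind(c(3, 0), c(-3, 0), c(10, 1), c(12, -1), c(11, 0))
  rownames(scores) <- sprintf("S%d", 1:5)
  space <- structure(list(scores = scores, fitted_on = rownames(scores)),
                     class = "feature_space")
  labels <- c("VOICE", "VOICE", "MUSIC", "MUSIC", "MUSIC")
  s <- summarize_categories(space, labels, n_components = 2)
  v1 <- s[s$label == "VOICE" & s$component == 1, ]
  expect_equal(v1$barycenter, 0)
  expect_equal(v1$dispersion, 3)   # population SD of +-3, not sample SD
  m <- s[s$label == "MUSIC" & s$component == 1, ]
  expect_equal(m$barycenter, 11)
  expect_equal(m$n_items, 3)
  expect_error(summarize_categories(space, c(labels[-5], "BIRD")),
               class = "soundgate_data_error")
})

test_that("single-item categories have zero dispersion", {
  scores <- rbind(c(1, 2), c(5, 5), c(6, 6))
  rownames(scores) <- c("a", "b", "c")
  space <- structure(list(scores = scores, fitted_on = rownames(scores)),
                     class = "feature_space")
  s <- summarize_categories(space, c("VOICE", "MUSIC", "MUSIC"), 2)
  expect_true(all(s$dispersion[s$label == "VOICE"] == 0))
})

test_that("distance features match hand-computable and brute-force oracles", {
  # collinear fixture: A at 0 and 1, B at 10 and 11 (second dimension zero)
  scores <- cbind(c(0, 1, 10, 11), 0)
  rownames(scores) <- c("a0", "a1", "b0", "b1")
  space <- structure(list(scores = scores, fitted_on = rownames(scores)),
                     class = "feature_space")
  labels <- c("VOICE", "VOICE", "MUSIC", "MUSIC")
  d <- distance_features(space, labels, n_components = 2)
  expect_equal(d$within_distance, rep(1, 4))
  expect_equal(d$between_distance[1], mean(c(10, 11)))
  expect_equal(d$between_distance[4], mean(c(11, 10)))

  # coincident same-label points
  z <- matrix(1, 3, 2, dimnames = list(c("x", "y", "z"), NULL))
  zs <- structure(list(scores = rbind(z, c(5, 5), c(6, 6)),
                       fitted_on = c("x", "y", "z", "m1", "m2")),
                  class = "feature_space")
  dz <- distance_features(zs, c("VOICE", "VOICE", "VOICE", "MUSIC", "MUSIC"), 2)
  expect_equal(dz$within_distance[1:3], rep(0, 3))

  # randomized brute-force equivalence and permutation invariance
  for (seed in c(43, 47)) {
    set.seed(seed)
    sc <- matrix(rnorm(12 * 3), 12, 3)
    rownames(sc) <- sprintf("S%02d", 1:12)
    labs <- rep(category_labels(), each = 4)
    sp <- structure(list(scores = sc, fitted_on = rownames(sc)),
                    class = "feature_space")
    d1 <- distance_features(sp, labs, n_components = 2)
    oracle <- brute_distances(sc, labs, k = 2)
    expect_equal(d1$within_distance, oracle$within, tolerance = 1e-12)
    expect_equal(d1$between_distance, oracle$between, tolerance = 1e-12)

    perm <- sample(12)
    sp2 <- structure(list(scores = sc[perm, ], fitted_on = rownames(sc)[perm]),
                     class = "feature_space")
    d2 <- distance_features(sp2, labs[perm], n_components = 2)
    expect_equal(
      d2$within_distance[match(d1$stimulus_id, d2$stimulus_id)],
      d1$within_distance
    )
  }

  expect_error(
    distance_features(space, c("VOICE", "VOICE", "MUSIC", "ESOUND"), 2),
    class = "soundgate_parameter_error"
  )
})

test_that("global rescaling behaves as the PCA mode dictates", {
  x <- random_patterns(10, 4, seed = 53)
  labs <- rep(c("VOICE", "MUSIC"), each = 5)
  f1 <- fit_pca(x, "CORRELATION")
  f2 <- fit_pca(3 * x, "CORRELATION")
  expect_equal(f1$scores, f2$scores, tolerance = 1e-9)

  c1 <- fit_pca(x, "COVARIANCE")
  c2 <- fit_pca(3 * x, "COVARIANCE")
  d1 <- distance_features(c1, labs, 2)
  d2 <- distance_features(c2, labs, 2)
  expect_equal(d2$within_distance, 3 * d1$within_distance, tolerance = 1e-9)
})
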