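make_features <- function(n = 200, seed = 61) {
  set.seed(seed)
  data.frame(uncertainty_intolerance = rnorm(n), decision_noise = rnorm(n),
             processing_speed = rnorm(n), verbal_memory = rnorm(n),
             executive_function = rnorm(n))
}

test_that("PCA reconstructs the z-scored data with all components", {
  x <- make_features()
  r <- pca_with_permutation(x, n_perm = 20, seed = 62)
  z <- standardize_features(x)
  expect_equal(r$scores %*% t(r$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(r$explained_variance_ratio), 1)
  expect_true(all(diff(r$explained_variance_ratio) <= 1e-12))
})

test_that("independent features give flat spectrum and uniform p-values", {
  x <- make_features(n = 500, seed = 63)
  r <- pca_with_permutation(x, n_perm = 200, seed = 64)
  expect_true(all(abs(r$explained_variance_ratio - 0.2) < 0.06))
  p <- as.numeric(r$p_values)
  expect_gt(mean(p), 0.25)           # not skewed toward significance
  expect_gt(min(p), 1 / 201 - 1e-12) # +1 correction keeps p > 0
})

test_that("a correlated feature pair dominates PC1 with equal loadings", {
  set.seed(65)
  n <- 500
  base <- rnorm(n)
  x <- data.frame(f1 = base + rnorm(n, sd = sqrt(1 / 0.95^2 - 1) * 0),
                  f2 = 0.95 * base + sqrt(1 - 0.95^2) * rnorm(n),
                  f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n))
  x$f1 <- base
  r <- pca_with_permutation(x, n_perm = 50, seed = 66)
  l1 <- r$loadings[, 1]
  expect_equal(unname(abs(l1["f1"])), unname(abs(l1["f2"])),
               tolerance = 0.05)
  expect_gt(min(abs(l1[c("f1", "f2")])), max(abs(l1[c("f3", "f4", "f5")])))
})

test_that("ward clustering recovers well-separated blobs", {
  set.seed(67)
  centers <- rbind(c(0, 0, 0, 0, 0), c(10, 10, 0, 0, 0), c(0, 0, 10, 10, 10))
  truth <- rep(1:3, each = 50)
  x <- centers[truth, ] + matrix(rnorm(750), 150, 5)
  colnames(x) <- paste0("f", 1:5)
  r <- ward_cluster(x)
  expect_equal(r$selected_k, 3L)
  expect_equal(adjusted_rand_index(r$selected_labels, truth), 1)
  expect_true(all(r$metrics$k == 2:6))
  # weighted cluster means of z-scored features average to ~0
  sizes <- table(r$selected_labels)
  prof <- r$profiles
  wm <- colSums(prof * as.numeric(sizes)) / sum(sizes)
  expect_equal(unname(wm), rep(0, 5), tolerance = 1e-10)
})

test_that("duplicated points merge at height zero", {
  x <- matrix(rnorm(50), 10, 5)
  x <- rbind(x, x[1, ])
  tree <- hclust(dist(scale(x)), method = "ward.D2")
  expect_equal(min(tree$height), 0)
})

test_that("ICC(3,1) consistency behaves as designed", {
  set.seed(68)
  s1 <- rnorm(50, sd = 2)
  expect_equal(icc_consistency(s1, s1), 1)
  expect_equal(icc_consistency(s1, s1 + 5), 1)   # additive shift ignored
  s2 <- s1 + rnorm(50, sd = 0.5)
  expect_gt(icc_consistency(s1, s2), 0.8)
  # independent measurements: near zero
  iccs <- vapply(1:20, function(i) {
    icc_consistency(rnorm(200), rnorm(200))
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.05)
  expect_error(icc_consistency(1:2, 1:2), "length")
})

test_that("adjusted residuals match the direct formula and chisq stdres", {
  expect_equal(adjusted_residuals(matrix(10, 2, 2)), matrix(0, 2, 2))
  tab <- matrix(c(30, 10, 20, 40), 2, 2)
  r <- adjusted_residuals(tab)
  expect_equal(abs(r), matrix(abs(r[1, 1]), 2, 2))    # 2x2 identity
  expect_equal(sign(r), matrix(c(1, -1, -1, 1), 2, 2))
  # independent oracle on random 3x4 tables
  set.seed(69)
  for (i in 1:5) {
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    expect_equal(adjusted_residuals(tab),
                 suppressWarnings(stats::chisq.test(tab)$stdres),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(adjusted_residuals(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("subtype profiles summarize clusters on the z scale", {
  x <- make_features(60, seed = 70)
  one <- subtype_profiles(x, rep(1, 60), invert = character(0))
  expect_equal(unname(one[1, ]), rep(0, 5), tolerance = 1e-10)
  # profile of a cluster of identical rows equals that row
  z <- standardize_features(x)
  labs <- c(rep(1, 30), rep(2, 30))
  z[31:60, ] <- z[31, ][col(z[31:60, ])]
  prof <- subtype_profiles(z, labs, invert = character(0))
  expect_equal(unname(prof["cluster2", ]), unname(z[31, ]))
  # requested columns are sign-flipped
  prof2 <- subtype_profiles(x, labs)
  prof2_raw <- subtype_profiles(x, labs, invert = character(0))
  expect_equal(prof2[, "uncertainty_intolerance"],
               -prof2_raw[, "uncertainty_intolerance"])
  expect_error(subtype_profiles(x, factor(rep(1, 60), levels = 1:2)),
               "empty cluster")
})
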