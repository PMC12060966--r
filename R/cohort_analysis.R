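#' Z-score the feature columns of a cohort table
#'
#' @param x data frame or matrix of numeric features.
#' @return Matrix of z-scored columns.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  s <- apply(x, 2, sd)
  if (any(s == 0)) stop("constant feature column(s): ",
                        paste(colnames(x)[s == 0], collapse = ", "))
  scale(x)
}

#' PCA with a permutation test on the loadings
#'
#' PCA on z-scored features. The null distribution of each loading is built
#' by shuffling every feature column independently (destroying inter-feature
#' correlation while preserving marginals), re-running PCA, and matching
#' each null component to an observed component by maximal absolute
#' congruence (dot product of loading vectors), sign-aligned. Two-sided
#' p-values compare `|loading|` to its null.
#'
#' @param features data frame/matrix of numeric features (>= 10 rows).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Object of class `pca_permutation`: `explained_variance_ratio`,
#'   `loadings`, `scores`, `p_values`, `n_perm`, `seed`.
#' @export
pca_with_permutation <- function(features, n_perm = 1000L, seed = 1L) {
  z <- standardize_features(features)
  n <- nrow(z)
  d <- ncol(z)
  if (n < 10) stop("need at least 10 rows")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  load_obs <- pc$rotation
  set.seed(seed)
  exceed <- matrix(0, d, d, dimnames = dimnames(load_obs))
  for (i in seq_len(n_perm)) {
    zp <- apply(z, 2, sample)
    lp <- prcomp(zp, center = FALSE, scale. = FALSE)$rotation
    # match null components to observed ones by absolute congruence
    cong <- abs(crossprod(load_obs, lp))  # obs comp x null comp
    assigned <- integer(d)
    taken <- rep(FALSE, d)
    for (k in order(-apply(cong, 1, max))) {
      j <- which.max(ifelse(taken, -Inf, cong[k, ]))
      assigned[k] <- j
      taken[j] <- TRUE
    }
    for (k in seq_len(d)) {
      nl <- lp[, assigned[k]]
      exceed[, k] <- exceed[, k] + (abs(nl) >= abs(load_obs[, k]))
    }
  }
  p <- (exceed + 1) / (n_perm + 1)
  structure(list(explained_variance_ratio = evr, loadings = load_obs,
                 scores = pc$x, p_values = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pca_permutation")
}

silhouette_score <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- unique(labels)
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a_i <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b_i <- min(vapply(ks[ks != labels[i]], function(k)
      mean(d[i, labels == k]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b_i - a_i) / max(a_i, b_i) else 0
  }
  mean(s)
}

calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  grand <- colMeans(x)
  bss <- 0
  wss <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    bss <- bss + nrow(xi) * sum((ci - grand)^2)
    wss <- wss + sum(sweep(xi, 2, ci)^2)
  }
  (bss / (k - 1)) / (wss / (n - k))
}

davies_bouldin <- function(x, labels) {
  ks <- unique(labels)
  k <- length(ks)
  cent <- t(vapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE]),
                   numeric(ncol(x))))
  disp <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (disp[i] + disp[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

#' Ward hierarchical clustering with cluster-quality metrics
#'
#' Minimum-variance (Ward) agglomeration on Euclidean distances between
#' z-scored features. Every k in `k_range` is scored by silhouette,
#' Calinski-Harabasz and Davies-Bouldin; the selected k maximizes the
#' silhouette with Calinski-Harabasz as tie-break.
#'
#' @param features data frame/matrix of numeric features.
#' @param k_range candidate cluster counts.
#' @return Object of class `cluster_result`: `tree` (hclust), `labels`
#'   (list by k), `metrics` (data frame), `selected_k`,
#'   `selected_labels`, `profiles` (selected-k cluster means of z-scored
#'   features).
#' @export
ward_cluster <- function(features, k_range = 2:6) {
  z <- standardize_features(features)
  if (nrow(z) <= max(k_range)) stop("need more rows than max(k_range)")
  d <- dist(z)
  tree <- hclust(d, method = "ward.D2")
  labels <- lapply(k_range, function(k) cutree(tree, k = k))
  names(labels) <- k_range
  metrics <- data.frame(
    k = k_range,
    silhouette = vapply(labels, function(l) silhouette_score(d, l),
                        numeric(1)),
    calinski_harabasz = vapply(labels, function(l) calinski_harabasz(z, l),
                               numeric(1)),
    davies_bouldin = vapply(labels, function(l) davies_bouldin(z, l),
                            numeric(1)),
    row.names = NULL)
  best <- which(metrics$silhouette == max(metrics$silhouette))
  if (length(best) > 1)
    best <- best[which.max(metrics$calinski_harabasz[best])]
  selected_k <- k_range[best]
  sel <- labels[[as.character(selected_k)]]
  structure(list(tree = tree, labels = labels, metrics = metrics,
                 selected_k = selected_k, selected_labels = sel,
                 profiles = subtype_profiles(z, sel, invert = character(0))),
            class = "cluster_result")
}

#' Two-way consistency intraclass correlation (single measure)
#'
#' ICC(3,1): `(MS_rows - MS_error) / (MS_rows + MS_error)` from the
#' two-way participants x sessions ANOVA decomposition; insensitive to an
#' additive session offset.
#'
#' @param session1,session2 paired numeric vectors (n >= 3).
#' @return Scalar ICC.
#' @export
icc_consistency <- function(session1, session2) {
  stopifnot(length(session1) == length(session2), length(session1) >= 3)
  y <- cbind(session1, session2)
  n <- nrow(y)
  k <- ncol(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  grand <- mean(y)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows + ms_err == 0) stop("zero between- and within-participant variance")
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Adjusted Pearson residuals of a two-way contingency table
#'
#' `(O - E) / sqrt(E (1 - row_total/N) (1 - col_total/N))` per cell.
#'
#' @param tab matrix or table of counts with all margins > 0.
#' @return Matrix of adjusted residuals.
#' @export
adjusted_residuals <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  e <- outer(rs, cs) / n
  (tab - e) / sqrt(e * outer(1 - rs / n, 1 - cs / n))
}

#' Per-cluster mean feature profiles (radar data)
#'
#' Cluster means of z-scored features. For display, columns named in
#' `invert` (by default the two task-derived computational parameters) are
#' sign-flipped so that larger values always read as "better/more stable"
#' on a radar plot.
#'
#' @param features data frame/matrix (raw or z-scored) of features.
#' @param labels cluster labels aligned with rows.
#' @param invert column names to sign-flip in the returned profile.
#' @return Matrix: one row per cluster, one column per feature.
#' @export
subtype_profiles <- function(features, labels,
                             invert = c("uncertainty_intolerance",
                                        "decision_noise")) {
  z <- if (is.null(attr(features, "scaled:scale")))
    standardize_features(features) else as.matrix(features)
  stopifnot(length(labels) == nrow(z))
  if (any(table(labels) == 0)) stop("empty cluster")
  prof <- t(vapply(sort(unique(labels)), function(g)
    colMeans(z[labels == g, , drop = FALSE]), numeric(ncol(z))))
  rownames(prof) <- paste0("cluster", sort(unique(labels)))
  flip <- intersect(invert, colnames(prof))
  prof[, flip] <- -prof[, flip]
  prof
}
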