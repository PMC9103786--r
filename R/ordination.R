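#' PCA of expression profiles
#'
#' Samples are the observations, genes the variables. By default
#' expression is log2(TPM + 1)-transformed, which stabilizes the
#' heavy-tailed TPM scale before a variance-based decomposition. The
#' decomposition is deterministic up to sign; signs are fixed so that the
#' largest-magnitude loading of each component is positive.
#'
#' @param matrix expression matrix (genes x samples).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param center center genes across samples (default TRUE). With
#'   centering, a matrix whose samples are all identical carries no
#'   variance and is rejected; run with `center = FALSE` to ordinate raw
#'   profiles instead.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fractions, sum 1).
#' @export
run_pca <- function(matrix, log_transform = TRUE, center = TRUE) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  x <- t(matrix)
  if (log_transform) x <- log2(x + 1)
  xc <- if (center) scale(x, center = TRUE, scale = FALSE) else x
  if (all(abs(xc) < .Machine$double.eps^0.5)) stop("no variance", call. = FALSE)
  pc <- stats::prcomp(x, center = center, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total == 0) stop("no variance", call. = FALSE)
  # fixed sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = pc$sdev^2 / total,
                 center = center, log_transform = log_transform),
            class = "pca_result")
}

#' Euclidean distances between sample expression profiles
#'
#' Convenience wrapper producing the distance matrix fed to
#' [permanova()]: Euclidean distance on (by default) log2(TPM + 1)
#' profiles, the same matrix PCA decomposes.
#'
#' @param matrix expression matrix.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param method distance method passed to [stats::dist()].
#' @return `dist` object over samples.
#' @export
expression_distances <- function(matrix, log_transform = TRUE,
                                 method = "euclidean") {
  validate_expression_matrix(matrix)
  x <- t(matrix)
  if (log_transform) x <- log2(x + 1)
  stats::dist(x, method = method)
}

# one-way PERMANOVA pseudo-F from squared-distance partition
permanova_f <- function(d2, labels) {
  n <- nrow(d2)
  groups <- split(seq_len(n), labels)
  k <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: the pseudo-F statistic
#' partitions the total sum of squared inter-point distances into
#' between- and within-group components, and its null distribution is
#' obtained by permuting labels. p = (1 + #\{permuted F >= observed F\}) /
#' (n_permutations + 1), so the smallest attainable p is
#' 1/(n_permutations + 1).
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param labels group label per sample; at least 2 groups with at least
#'   2 members each.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional RNG seed set before permuting, for reproducibility.
#' @return list of class `permanova_result`: `f`, `p_value`,
#'   `n_permutations`, `ss_between`, `ss_within`, `df`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (length(labels) != n) stop("labels length does not match distance matrix",
                                call. = FALSE)
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric", call. = FALSE)
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d2 <- dm^2
  f_obs <- permanova_f(d2, labels)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    f_perm <- permanova_f(d2, sample(labels))
    if (f_perm >= f_obs) exceed <- exceed + 1L
  }
  k <- length(sizes)
  structure(list(f = f_obs, p_value = (1 + exceed) / (n_permutations + 1),
                 n_permutations = n_permutations,
                 df = c(between = k - 1, within = n - k)),
            class = "permanova_result")
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' Runs [permanova()] on every pair of labels and adjusts the permutation
#' p-values across pairs by Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return data.frame: label_a, label_b, f, p_value, p_adjusted.
#' @export
pairwise_permanova <- function(d, labels, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  if (!is.null(seed)) set.seed(seed)
  lv <- sort(unique(labels))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    idx <- labels %in% pr
    res <- permanova(dm[idx, idx], labels[idx], n_permutations, seed = NULL)
    data.frame(label_a = pr[1], label_b = pr[2], f = res$f,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Write PCA coordinates and variance fractions as TSV
#' @param pca `pca_result` from [run_pca()].
#' @param scores_path,variance_path output paths.
#' @export
write_pca_result <- function(pca, scores_path, variance_path) {
  sc <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(sc, scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  vf <- data.frame(component = paste0("PC", seq_along(pca$var_explained)),
                   var_explained = pca$var_explained)
  utils::write.table(vf, variance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scores_path)
}
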