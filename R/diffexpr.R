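#' Specify a two-population expression contrast
#'
#' Thresholds follow the study design this package reproduces: a gene is
#' differentially expressed when its mean-TPM fold change lies strictly
#' outside the window (`fc_low`, `fc_high`) = (0.8, 1.25) *and* the exact
#' tests pass FDR < `fdr_alpha` after q-value correction.
#'
#' @param name contrast label.
#' @param samples_a,samples_b disjoint, non-empty sample id vectors;
#'   fold change is mean(A)/mean(B).
#' @param fc_high,fc_low fold-change window bounds, `fc_low < 1 < fc_high`.
#' @param fdr_alpha FDR level in (0, 1).
#' @param pseudo pseudo-TPM added to both means before taking the ratio,
#'   guards against division by zero for genes at the expression floor.
#' @param library_scale per-sample factor used to integerize TPM for the
#'   exact tests (counts = round(sum over replicates of TPM x scale)).
#' @param qvalue_method `"storey"` (default) or `"bh"`.
#' @param test_mode `"both"` (default: binomial AND Fisher must pass FDR)
#'   or `"either"`.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(name, samples_a, samples_b,
                          fc_high = 1.25, fc_low = 0.8, fdr_alpha = 0.05,
                          pseudo = 0.01, library_scale = 10,
                          qvalue_method = c("storey", "bh"),
                          test_mode = c("both", "either")) {
  qvalue_method <- match.arg(qvalue_method)
  test_mode <- match.arg(test_mode)
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    stop("contrast '", name, "': a population has zero samples", call. = FALSE)
  }
  if (length(intersect(samples_a, samples_b)) > 0) {
    stop("contrast '", name, "': populations overlap", call. = FALSE)
  }
  if (!(fc_low < 1 && 1 < fc_high)) stop("need fc_low < 1 < fc_high", call. = FALSE)
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) stop("fdr_alpha must be in (0,1)", call. = FALSE)
  if (!(pseudo > 0)) stop("pseudo must be > 0", call. = FALSE)
  if (!(library_scale > 0)) stop("library_scale must be > 0", call. = FALSE)
  structure(list(name = name, samples_a = samples_a, samples_b = samples_b,
                 fc_high = fc_high, fc_low = fc_low, fdr_alpha = fdr_alpha,
                 pseudo = pseudo, library_scale = library_scale,
                 qvalue_method = qvalue_method, test_mode = test_mode),
            class = "contrast_spec")
}

#' Fold change between mean expression levels
#'
#' `(mean_a + pseudo) / (mean_b + pseudo)`. The pseudo-value affects only
#' genes near the expression floor, which are already subject to the
#' low-expression filter.
#'
#' @param mean_a,mean_b non-negative mean TPM (vectorized).
#' @param pseudo positive pseudo-TPM, default 0.01.
#' @return positive fold-change ratio.
#' @export
fold_change <- function(mean_a, mean_b, pseudo = 0.01) {
  stopifnot(all(mean_a >= 0), all(mean_b >= 0), pseudo > 0)
  (mean_a + pseudo) / (mean_b + pseudo)
}

# deterministic half-up rounding (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Integerize TPM into per-population aggregate counts
#'
#' The exact tests require integers while TPM is continuous: each sample's
#' TPM is scaled by `library_scale`, replicates are summed per population,
#' and the sum is rounded half-up.
#'
#' @param matrix expression matrix.
#' @param samples_a,samples_b sample ids of the two populations.
#' @param library_scale positive scale factor (default 10).
#' @return list with integer vectors `count_a`, `count_b` (one per gene).
#' @export
integerize_counts <- function(matrix, samples_a, samples_b, library_scale = 10) {
  stopifnot(library_scale > 0)
  count_a <- round_half_up(rowSums(matrix[, samples_a, drop = FALSE]) * library_scale)
  count_b <- round_half_up(rowSums(matrix[, samples_b, drop = FALSE]) * library_scale)
  list(count_a = count_a, count_b = count_b)
}

#' Two-sided exact binomial test for expression divergence
#'
#' Tests whether `count_a` of `count_a + count_b` aggregated counts is
#' compatible with population A's expected share of the integerized
#' library. Two-sided p-values sum the probabilities of all outcomes no
#' more likely than the observed one (the "minlike" convention, matching
#' Fisher's test). Both counts zero gives p = 1.
#'
#' @param count_a,count_b non-negative integer vectors.
#' @param expected_a_fraction expected A share in (0, 1); 0.5 for balanced
#'   designs.
#' @return vector of p-values in \[0, 1\].
#' @export
binomial_divergence_test <- function(count_a, count_b, expected_a_fraction = 0.5) {
  if (any(count_a != floor(count_a)) || any(count_b != floor(count_b))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!(expected_a_fraction > 0 && expected_a_fraction < 1)) {
    stop("expected_a_fraction must be in (0,1)", call. = FALSE)
  }
  n <- count_a + count_b
  p <- mapply(function(a, n) {
    if (n == 0) return(1)
    stats::binom.test(a, n, p = expected_a_fraction)$p.value
  }, count_a, n)
  pmin(pmax(p, 0), 1)
}

#' Two-sided Fisher exact test for expression divergence
#'
#' 2x2 table per gene: `[count_a, totals_a - count_a; count_b,
#' totals_b - count_b]` where the totals are the populations' integerized
#' library sizes. p is the sum of hypergeometric probabilities of tables
#' no more likely than the observed one.
#'
#' @param count_a,count_b per-gene counts (vectorized).
#' @param totals_a,totals_b population library totals (scalars or vectors).
#' @return vector of p-values in \[0, 1\].
#' @export
fisher_divergence_test <- function(count_a, count_b, totals_a, totals_b) {
  if (any(count_a > totals_a) || any(count_b > totals_b)) {
    stop("count exceeds its library total", call. = FALSE)
  }
  if (any(c(count_a, count_b, totals_a, totals_b) < 0)) {
    stop("table entries must be >= 0", call. = FALSE)
  }
  p <- mapply(function(a, b, ta, tb) {
    tab <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, count_a, count_b, totals_a, totals_b)
  pmin(pmax(p, 0), 1)
}

#' Estimate q-values from p-values
#'
#' `"bh"` is the Benjamini-Hochberg step-up procedure. `"storey"` scales
#' BH by an estimate of the null proportion pi0 = #\{p > 0.5\} / (0.5 m),
#' clamped to (0, 1]; with fewer than 20 p-values the pi0 estimate is too
#' unstable and the method falls back to BH. Both are monotone in p and
#' map equal p to equal q.
#'
#' @param p p-values in \[0, 1\].
#' @param method `"storey"` or `"bh"`.
#' @return q-values in \[0, 1\].
#' @export
estimate_qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  q_bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh" || m < 20) return(q_bh)
  pi0 <- mean(p > 0.5) / 0.5
  pi0 <- min(1, max(pi0, 1 / m))
  pi0 * q_bh
}

#' Run one two-population contrast over all genes
#'
#' Computes mean TPM per population, fold change, both exact tests on the
#' integerized counts, q-values across genes within this contrast, and the
#' combined significance verdict. Because TPM fixes each sample's library
#' at one million, population A's share of the total integerized library is
#' its replicate share: that share is the binomial null fraction, and the
#' notional per-population libraries (replicates x 1e6 x `library_scale`)
#' are the Fisher margins.
#'
#' @param matrix expression matrix containing the spec's samples.
#' @param spec a [contrast_spec()].
#' @return data.frame with one row per gene: `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `count_a`, `count_b`, `p_binomial`, `q_binomial`,
#'   `p_fisher`, `q_fisher`, `significant`, `direction` (`A_up` / `B_up` /
#'   `none`). The spec is attached as attribute `"spec"`.
#' @export
call_contrast <- function(matrix, spec) {
  validate_expression_matrix(matrix)
  stopifnot(inherits(spec, "contrast_spec"))
  missing <- setdiff(c(spec$samples_a, spec$samples_b), colnames(matrix))
  if (length(missing) > 0) {
    stop("contrast '", spec$name, "': sample(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mean_a <- rowMeans(matrix[, spec$samples_a, drop = FALSE])
  mean_b <- rowMeans(matrix[, spec$samples_b, drop = FALSE])
  fc <- fold_change(mean_a, mean_b, spec$pseudo)

  cnt <- integerize_counts(matrix, spec$samples_a, spec$samples_b,
                           spec$library_scale)
  # TPM normalization fixes every sample's library at 1e6, so population
  # A's share of the total integerized library is its replicate share
  # (0.5 for balanced designs) and the Fisher margins are the notional
  # integerized libraries -- not the sums over the analyzed gene subset,
  # which would absorb genuine subset-wide expression shifts into the null
  n_a <- length(spec$samples_a)
  n_b <- length(spec$samples_b)
  frac_a <- n_a / (n_a + n_b)
  total_a <- round_half_up(n_a * 1e6 * spec$library_scale)
  total_b <- round_half_up(n_b * 1e6 * spec$library_scale)
  p_binom <- binomial_divergence_test(cnt$count_a, cnt$count_b, frac_a)
  p_fish <- fisher_divergence_test(cnt$count_a, cnt$count_b, total_a, total_b)
  q_binom <- estimate_qvalues(p_binom, spec$qvalue_method)
  q_fish <- estimate_qvalues(p_fish, spec$qvalue_method)

  fc_out <- fc > spec$fc_high | fc < spec$fc_low
  tests_pass <- if (spec$test_mode == "both") {
    q_binom < spec$fdr_alpha & q_fish < spec$fdr_alpha
  } else {
    q_binom < spec$fdr_alpha | q_fish < spec$fdr_alpha
  }
  significant <- fc_out & tests_pass
  direction <- ifelse(!significant, "none",
                      ifelse(fc > spec$fc_high, "A_up", "B_up"))

  res <- data.frame(gene_id = rownames(matrix),
                    mean_a = mean_a, mean_b = mean_b, fold_change = fc,
                    count_a = cnt$count_a, count_b = cnt$count_b,
                    p_binomial = p_binom, q_binomial = q_binom,
                    p_fisher = p_fish, q_fisher = q_fish,
                    significant = significant, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "spec") <- spec
  res
}

#' Write a contrast result as TSV
#' @param result data.frame from [call_contrast()].
#' @param path output path.
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
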