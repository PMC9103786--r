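test_that("fold change is a pseudo-count ratio with reciprocal symmetry", {
  expect_equal(fold_change(7, 7), 1)
  set.seed(3)
  a <- runif(20, 0, 50); b <- runif(20, 0, 50)
  expect_equal(fold_change(a, b) * fold_change(b, a), rep(1, 20))
  # a 10-vs-8 gene sits exactly at 1.25 as pseudo -> 0 and must NOT pass ">1.25"
  fc <- fold_change(10, 8, pseudo = 1e-12)
  expect_equal(fc, 1.25, tolerance = 1e-9)
  expect_false(fc > 1.25 + 1e-9)
})

test_that("integerization sums replicates and rounds half-up", {
  mat <- expression_matrix(matrix(c(2.4, 0, 0, 0), 2, byrow = TRUE,
                                  dimnames = list(c("g1", "g0"), c("a1", "b1"))))
  cnt <- integerize_counts(mat, "a1", "b1", library_scale = 10)
  expect_equal(unname(cnt$count_a), c(24, 0))
  expect_equal(unname(cnt$count_b), c(0, 0))
  # deterministic half-up, not banker's rounding
  m2 <- expression_matrix(matrix(c(0.05, 0.25), 1,
                                 dimnames = list("g", c("a1", "b1"))))
  cnt2 <- integerize_counts(m2, "a1", "b1", library_scale = 10)
  expect_equal(unname(cnt2$count_a), 1)  # 0.5 -> 1 (round() would give 0)
  expect_equal(unname(cnt2$count_b), 3)  # 2.5 -> 3 (round() would give 2)
})

test_that("library scale changes counts but not fold-change verdicts", {
  sim <- quick_sim(c(cis_dominant = 30, null = 30), seed = 5)
  sheet <- sim$sheet[sim$sheet$tissue == "brain", ]
  a <- sheet$sample_id[sheet$population == "Cor"]
  b <- sheet$sample_id[sheet$population == "WL"]
  r1 <- call_contrast(sim$matrix[, sheet$sample_id],
                      contrast_spec("p", a, b, library_scale = 1))
  r100 <- call_contrast(sim$matrix[, sheet$sample_id],
                        contrast_spec("p", a, b, library_scale = 100))
  expect_false(identical(r1$count_a, r100$count_a))
  expect_equal(r1$fold_change, r100$fold_change)
  expect_identical(r1$fold_change > 1.25 | r1$fold_change < 0.8,
                   r100$fold_change > 1.25 | r100$fold_change < 0.8)
})

test_that("binomial divergence test matches brute-force enumeration", {
  expect_equal(binomial_divergence_test(50, 50, 0.5), 1.0)
  expect_equal(binomial_divergence_test(20, 0, 0.5), 2 * 0.5^20)
  expect_equal(binomial_divergence_test(20, 0, 0.5), binom_p_oracle(20, 20, 0.5))
  expect_equal(binomial_divergence_test(0, 0, 0.5), 1)
  # symmetry at fraction 0.5, and agreement with the oracle across cases
  for (ab in list(c(3, 9), c(17, 4), c(0, 12), c(25, 25))) {
    expect_equal(binomial_divergence_test(ab[1], ab[2], 0.5),
                 binomial_divergence_test(ab[2], ab[1], 0.5))
    for (f in c(0.3, 0.5, 0.62)) {
      expect_equal(binomial_divergence_test(ab[1], ab[2], f),
                   binom_p_oracle(ab[1], sum(ab), f), tolerance = 1e-10)
    }
  }
  expect_error(binomial_divergence_test(1.5, 2, 0.5), "integer")
})

test_that("Fisher divergence test matches hypergeometric enumeration", {
  expect_equal(fisher_divergence_test(5, 5, 100, 100), 1.0)
  expect_equal(fisher_divergence_test(0, 10, 10, 10), 2 / choose(20, 10))
  for (case in list(c(0, 10, 10, 10), c(4, 9, 30, 25), c(12, 2, 40, 40))) {
    expect_equal(fisher_divergence_test(case[1], case[2], case[3], case[4]),
                 fisher_p_oracle(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-9)
    # transposing the two rows leaves p unchanged
    expect_equal(fisher_divergence_test(case[1], case[2], case[3], case[4]),
                 fisher_divergence_test(case[2], case[1], case[4], case[3]))
  }
  expect_error(fisher_divergence_test(11, 0, 10, 10), "exceeds")
})

test_that("q-value estimation: BH hand-check, storey vs bh, monotonicity", {
  expect_equal(estimate_qvalues(rep(1, 30), "storey"), rep(1, 30))
  expect_equal(estimate_qvalues(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  # fewer than 20 p-values: storey falls back to BH
  expect_equal(estimate_qvalues(c(0.01, 0.02, 0.03, 0.04), "storey"),
               rep(0.04, 4))
  set.seed(9)
  for (rep in 1:5) {
    p <- c(rbeta(40, 0.3, 4), runif(40))  # enriched near 0 -> pi0 < 1
    q_bh <- estimate_qvalues(p, "bh")
    q_st <- estimate_qvalues(p, "storey")
    expect_true(all(q_st <= q_bh + 1e-12))
    # equal p must map to equal q
    p2 <- c(p, p[1])
    q2 <- estimate_qvalues(p2, "storey")
    expect_equal(q2[1], q2[length(q2)])
    # adding a constant never decreases q
    shift <- min(0.05, 1 - max(p))
    for (m in c("bh", "storey")) {
      expect_true(all(estimate_qvalues(p + shift, m) >=
                        estimate_qvalues(p, m) - 1e-12))
    }
  }
  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_contrast requires the fold window and both FDR verdicts", {
  # identical populations -> nothing significant
  vals <- matrix(rep(c(5, 8, 12), each = 6), 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c(paste0("a", 1:3), paste0("b", 1:3))))
  res <- call_contrast(expression_matrix(vals),
                       contrast_spec("id", paste0("a", 1:3), paste0("b", 1:3)))
  expect_false(any(res$significant))
  expect_true(all(res$direction == "none"))

  # true 4-fold difference, low noise -> significant with the right direction
  sim <- quick_sim(c(trans_dominant = 40), seed = 13, noise_cv = 0.05, effect = 2)
  sheet <- sim$sheet[sim$sheet$tissue == "brain", ]
  a <- sheet$sample_id[sheet$population == "Cor"]
  b <- sheet$sample_id[sheet$population == "WL"]
  res2 <- call_contrast(sim$matrix[, sheet$sample_id], contrast_spec("par", a, b))
  up_cor <- sim$truth$effect_log2 < 0  # WL down => Cor (A) up
  expect_gt(mean(res2$significant), 0.95)
  expect_true(all(res2$direction[res2$significant & up_cor] == "A_up"))
  expect_true(all(res2$direction[res2$significant & !up_cor] == "B_up"))

  # fold change beyond the window but counts too sparse for the tests
  m <- expression_matrix(matrix(c(1.5, 1.0), 1,
                                dimnames = list("g", c("a1", "b1"))))
  r <- call_contrast(m, contrast_spec("sparse", "a1", "b1", library_scale = 1))
  expect_gt(r$fold_change, 1.25)
  expect_gte(r$q_binomial, 0.05)
  expect_false(r$significant)

  expect_error(call_contrast(m, contrast_spec("bad", "a1", "zz")), "zz")
})

test_that("reversing a contrast preserves the significance set, flips direction", {
  sim <- quick_sim(c(cis_dominant = 25, null = 25), seed = 21)
  sheet <- sim$sheet[sim$sheet$tissue == "brain", ]
  a <- sheet$sample_id[sheet$population == "Cor"]
  b <- sheet$sample_id[sheet$population == "WL"]
  mat <- sim$matrix[, sheet$sample_id]
  fwd <- call_contrast(mat, contrast_spec("f", a, b))
  rev <- call_contrast(mat, contrast_spec("r", b, a))
  expect_identical(fwd$significant, rev$significant)
  expect_identical(fwd$direction == "A_up", rev$direction == "B_up")
})

test_that("null data stays near the nominal false-positive rate at default noise", {
  cfg <- simulation_config(genes_per_class = c(null = 200), tissues = "brain",
                           seed = 1)
  sim <- generate_null_dataset(cfg)
  sheet <- sim$sheet
  res <- call_contrast(sim$matrix,
                       contrast_spec("null",
                                     sheet$sample_id[sheet$population == "Cor"],
                                     sheet$sample_id[sheet$population == "WL"]))
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(res$significant), bound)
})
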