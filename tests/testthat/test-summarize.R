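test_that("published counts load and tabulation round-trips through calls", {
  s <- published_category_counts()
  expect_equal(nrow(s), 6)
  b1 <- s[s$tissue == "brain" & s$group == 1, ]
  expect_equal(unname(unlist(b1[CLASSIFIED])), c(11, 0, 4, 0, 1, 1))
  expect_equal(s$total, c(17, 17, 21, 21, 32, 32))
  calls <- expand_summary_to_calls(s)
  back <- tabulate_categories(calls)
  cols <- c("tissue", "group", CLASSIFIED, "total")
  expect_equal(as.data.frame(back)[, cols], as.data.frame(s)[, cols])
})

test_that("tabulation conserves genes and ignores ordering", {
  set.seed(51)
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:60),
    group = sample(1:2, 60, TRUE), tissue = sample(c("brain", "liver"), 60, TRUE),
    category = sample(c(CLASSIFIED, "no_parental_divergence", "ambiguous"),
                      60, TRUE),
    skew = "none", stringsAsFactors = FALSE)
  s <- tabulate_categories(calls)
  per_cell <- s$total + s$no_parental_divergence + s$ambiguous
  expect_equal(sum(per_cell), nrow(calls))
  for (i in seq_len(nrow(s))) {
    expect_equal(per_cell[i], sum(calls$tissue == s$tissue[i] &
                                    calls$group == s$group[i]))
  }
  # permutation invariance
  s2 <- tabulate_categories(calls[sample(nrow(calls)), ])
  expect_equal(s, s2)
  # empty input
  s0 <- tabulate_categories(calls[0, ])
  expect_equal(nrow(s0), 0)
})

test_that("cis/trans fractions reproduce the published derived statistics", {
  fr <- cis_trans_fractions(published_category_counts())
  pg <- fr$per_group
  expect_equal(pg$cis_pct[pg$tissue == "brain" & pg$group == 1], 64.7)
  expect_equal(pg$cis_pct[pg$tissue == "liver"], c(38.1, 33.3))
  expect_equal(pg$cis_pct[pg$tissue == "muscle"], c(34.4, 21.9))
  pt <- fr$per_tissue
  expect_equal(pt$trans_ratio[pt$tissue == "brain"], 0.59)
  expect_equal(pt$trans_ratio[pt$tissue == "liver"], 0.57)
  # muscle: rounded and truncated renderings both emitted
  expect_equal(pt$trans_ratio[pt$tissue == "muscle"], 0.69)
  expect_equal(pt$trans_ratio_truncated[pt$tissue == "muscle"], 0.68)
  expect_equal(fr$pooled$cis_pct, 31.4)
  expect_equal(fr$pooled$complement_pct, 68.6)
  # shares partition the classified set
  expect_equal(pg$cis_pct + pg$trans_pct + pg$conserved_pct,
               rep(100, 6), tolerance = 0.11)
})

test_that("degenerate summaries give exact or undefined fractions", {
  s <- category_summary_from_counts(data.frame(
    tissue = "brain", group = 1, cis_dominant = 5, trans_dominant = 0,
    trans_additive = 0, trans_overdominant = 0, trans_underdominant = 0,
    conserved = 0))
  fr <- cis_trans_fractions(s)
  expect_equal(fr$per_group$cis_pct, 100.0)
  expect_equal(fr$per_tissue$trans_ratio, 0.00)
  s0 <- category_summary_from_counts(data.frame(
    tissue = "brain", group = 1, cis_dominant = 0, trans_dominant = 0,
    trans_additive = 0, trans_overdominant = 0, trans_underdominant = 0,
    conserved = 0))
  expect_true(is.na(cis_trans_fractions(s0)$per_group$cis_pct))
})

test_that("dominance report reproduces the published counts and tallies skew", {
  s <- published_category_counts()
  dom <- dominance_report(s)
  pt <- dom$per_tissue
  expect_equal(pt$dominant_n[pt$tissue == "brain"], 21)
  expect_equal(pt$dominant_pct[pt$tissue == "brain"], 61.8)
  expect_equal(pt$dominant_pct[pt$tissue == "muscle"], 53.1)
  # computed liver fraction is 27/42; the published rounding is not imposed
  expect_equal(pt$dominant_pct[pt$tissue == "liver"], 64.3)
  expect_equal(sum(s$trans_overdominant[s$tissue == "liver"]), 4)

  calls <- data.frame(gene_id = c("a", "b", "c"), group = 1, tissue = "brain",
                      category = rep("trans_additive", 3), skew = "none")
  dom2 <- dominance_report(tabulate_categories(calls), calls)
  expect_equal(dom2$per_tissue$dominant_pct, 0)
  expect_null(dom2$skew)

  calls3 <- expand_summary_to_calls(s)
  dom3 <- dominance_report(s, calls3)
  skew_brain <- dom3$skew[dom3$skew$tissue == "brain", ]
  # brain: all 21 dominant genes Cor-skewed (cis maternal Cor in group 1,
  # trans paternal Cor in group 2)
  expect_equal(skew_brain$n[skew_brain$breed == "Cor"], 21)
})

test_that("fold-change spectrum counts sub-twofold DEGs", {
  contrast <- data.frame(gene_id = c("a", "b", "c"),
                         fold_change = c(1.3, 1.5, 4.0), significant = TRUE)
  sp <- fold_change_spectrum(contrast)
  expect_equal(sp$fraction_under_twofold, 2 / 3)
  expect_equal(sum(sp$histogram$count), 3)
  sp0 <- fold_change_spectrum(contrast[0, ])
  expect_true(is.na(sp0$fraction_under_twofold))
  # sign convention flip
  spB <- fold_change_spectrum(contrast, positive = "B")
  expect_equal(unname(spB$log2_fc), -unname(sp$log2_fc))

  # simulated log2 effects ~ N(0, 0.5): under-twofold fraction near the
  # closed-form normal probability
  set.seed(61)
  n <- 400
  lfc <- rnorm(n, 0, 0.5)
  sim <- data.frame(gene_id = sprintf("g%d", 1:n), fold_change = 2^lfc,
                    significant = TRUE)
  frac <- fold_change_spectrum(sim)$fraction_under_twofold
  p <- pnorm(1, 0, 0.5) - pnorm(-1, 0, 0.5)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cross-group consistency compares categories gene-wise", {
  calls <- rbind(
    data.frame(gene_id = c("a", "b", "c"), group = 1, tissue = "brain",
               category = c("cis_dominant", "trans_dominant", "no_parental_divergence")),
    data.frame(gene_id = c("a", "b", "c"), group = 2, tissue = "brain",
               category = c("cis_dominant", "trans_dominant", "cis_dominant")))
  expect_equal(cross_group_consistency(calls)$consistency, 1.0)
  calls$category[calls$group == 2] <- c("conserved", "trans_additive", "cis_dominant")
  expect_equal(cross_group_consistency(calls)$consistency, 0.0)

  # symmetric low-noise architecture classifies consistently across groups
  sim <- quick_sim(c(cis_dominant = 20, trans_additive = 20), seed = 71,
                   noise_cv = 0.05)
  calls1 <- classify_group(sim$matrix, sim$sheet, cross_group(1), tissue = "brain")
  calls2 <- classify_group(sim$matrix, sim$sheet, cross_group(2), tissue = "brain")
  cc <- cross_group_consistency(rbind(calls1, calls2))
  expect_gte(cc$consistency, 0.9)
})
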