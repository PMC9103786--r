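#' Regulatory-divergence categories
#'
#' The six "classified" categories plus the two excluded outcomes.
#' For a maternally inherited, allele-less W-linked gene, cis-regulatory
#' divergence makes the F1 track its maternal parent (maternal dominance),
#' while trans-acting divergence pulls the F1 away from the maternal level:
#' toward the paternal level (trans-dominant), between the parents
#' (additive), or beyond either parent (over-/under-dominant).
#'
#' @return character vector of category names.
#' @export
regulatory_categories <- function() {
  c("cis_dominant", "trans_dominant", "trans_additive",
    "trans_overdominant", "trans_underdominant", "conserved",
    "no_parental_divergence", "ambiguous")
}

# the six categories counted in summaries
classified_categories <- function() regulatory_categories()[1:6]

# core decision rule, vectorized over genes
classify_from_significance <- function(parental_sig, maternal_sig, paternal_sig,
                                       maternal_mean, paternal_mean, f1_mean) {
  n <- length(parental_sig)
  out <- character(n)
  lo <- pmin(maternal_mean, paternal_mean)
  hi <- pmax(maternal_mean, paternal_mean)
  for (i in seq_len(n)) {
    out[i] <- if (!parental_sig[i]) {
      "no_parental_divergence"
    } else if (!maternal_sig[i] && paternal_sig[i]) {
      "cis_dominant"
    } else if (!maternal_sig[i] && !paternal_sig[i]) {
      "conserved"
    } else if (maternal_sig[i] && !paternal_sig[i]) {
      "trans_dominant"
    } else if (f1_mean[i] > lo[i] && f1_mean[i] < hi[i]) {
      "trans_additive"
    } else if (f1_mean[i] > hi[i]) {
      "trans_overdominant"
    } else if (f1_mean[i] < lo[i]) {
      "trans_underdominant"
    } else {
      "ambiguous"  # exact tie with a parental mean
    }
  }
  out
}

# skew: which breed the F1 level is biased toward
skew_for_category <- function(category, group) {
  ifelse(category == "cis_dominant", group$maternal_population,
         ifelse(category == "trans_dominant", group$paternal_population,
                "none"))
}

#' Classify one gene's regulatory divergence
#'
#' Combines three contrast rows for the same gene — parent vs parent,
#' F1 vs maternal parent, F1 vs paternal parent — into a regulatory
#' category:
#' * parents not significantly different -> `no_parental_divergence`
#'   (cis/trans effects are masked);
#' * parents differ, F1 matches its maternal parent but differs from the
#'   paternal one -> `cis_dominant` (maternal dominance);
#' * parents differ, F1 differs from neither parent -> `conserved`;
#' * parents differ, F1 differs from the maternal parent but not the
#'   paternal one -> `trans_dominant` (paternal dominance);
#' * parents differ, F1 differs from both: `trans_additive` if the F1 mean
#'   lies strictly between the parental means, `trans_overdominant` above
#'   both, `trans_underdominant` below both, `ambiguous` on an exact tie.
#'
#' @param parental,f1_vs_maternal,f1_vs_paternal single rows of
#'   [call_contrast()] results for the same gene.
#' @param means named list or vector with `maternal`, `paternal`, `f1`
#'   mean TPM.
#' @param group a [cross_group()].
#' @return one-row data.frame: gene_id, group, category, skew,
#'   maternal_mean, paternal_mean, f1_mean.
#' @export
classify_gene <- function(parental, f1_vs_maternal, f1_vs_paternal, means, group) {
  ids <- c(parental$gene_id, f1_vs_maternal$gene_id, f1_vs_paternal$gene_id)
  if (length(unique(ids)) != 1) {
    stop("contrast rows refer to different genes: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  means <- as.list(means)
  category <- classify_from_significance(
    parental$significant, f1_vs_maternal$significant, f1_vs_paternal$significant,
    means$maternal, means$paternal, means$f1)
  data.frame(gene_id = parental$gene_id, group = group$group_id,
             category = category,
             skew = skew_for_category(category, group),
             maternal_mean = means$maternal, paternal_mean = means$paternal,
             f1_mean = means$f1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify all genes of one tissue for one cross group
#'
#' Selects the group's female samples of `tissue`, runs the three
#' contrasts (maternal vs paternal parents, F1 vs maternal, F1 vs
#' paternal) with q-values estimated across genes within each contrast,
#' and classifies every gene. The matrix should already be restricted to
#' expressed W-linked genes.
#'
#' @param matrix expression matrix.
#' @param sheet sample sheet covering the matrix samples.
#' @param group a [cross_group()].
#' @param tissue tissue label to analyse, or NULL to use all samples.
#' @param fc_high,fc_low,fdr_alpha,pseudo,library_scale,qvalue_method,test_mode
#'   threshold settings, see [contrast_spec()].
#' @return data.frame of per-gene calls with columns gene_id, group,
#'   tissue, category, skew, maternal_mean, paternal_mean, f1_mean; the
#'   three contrast results are attached as attribute `"contrasts"`.
#' @export
classify_group <- function(matrix, sheet, group, tissue = NULL,
                           fc_high = 1.25, fc_low = 0.8, fdr_alpha = 0.05,
                           pseudo = 0.01, library_scale = 10,
                           qvalue_method = "storey", test_mode = "both") {
  validate_expression_matrix(matrix)
  sheet <- females_only(sheet)
  if (!is.null(tissue)) sheet <- sheet[sheet$tissue == tissue, , drop = FALSE]
  sheet <- sheet[sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  pops <- list(maternal = group$maternal_population,
               paternal = group$paternal_population,
               f1 = group$f1_population)
  samples <- lapply(pops, function(p) sheet$sample_id[sheet$population == p])
  for (role in names(samples)) {
    if (length(samples[[role]]) == 0) {
      stop("no female ", role, " samples (population ", pops[[role]], ")",
           if (!is.null(tissue)) paste0(" for tissue ", tissue), call. = FALSE)
    }
  }
  mk <- function(name, a, b) {
    contrast_spec(name, a, b, fc_high = fc_high, fc_low = fc_low,
                  fdr_alpha = fdr_alpha, pseudo = pseudo,
                  library_scale = library_scale,
                  qvalue_method = qvalue_method, test_mode = test_mode)
  }
  parental <- call_contrast(matrix, mk("parental", samples$maternal, samples$paternal))
  f1_mat <- call_contrast(matrix, mk("f1_vs_maternal", samples$f1, samples$maternal))
  f1_pat <- call_contrast(matrix, mk("f1_vs_paternal", samples$f1, samples$paternal))

  category <- classify_from_significance(
    parental$significant, f1_mat$significant, f1_pat$significant,
    parental$mean_a, parental$mean_b, f1_mat$mean_a)
  calls <- data.frame(gene_id = parental$gene_id, group = group$group_id,
                      tissue = if (is.null(tissue)) NA_character_ else tissue,
                      category = category,
                      skew = skew_for_category(category, group),
                      maternal_mean = parental$mean_a,
                      paternal_mean = parental$mean_b,
                      f1_mean = f1_mat$mean_a,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(calls, "contrasts") <- list(parental = parental,
                                   f1_vs_maternal = f1_mat,
                                   f1_vs_paternal = f1_pat)
  calls
}

#' Exhaustive decision table for the classification rule
#'
#' Enumerates every combination of the three significance verdicts with
#' the F1 position relative to the parental means, as an explicit lookup
#' table. Serves as an oracle for [classify_gene()]: every combination
#' maps to exactly one category.
#'
#' @return data.frame with columns parental_sig, maternal_sig,
#'   paternal_sig, f1_position (`between` / `above` / `below` / `tie`),
#'   category.
#' @export
enumerate_decision_table <- function() {
  # literal rule table; a missing f1_position means "any position"
  rules <- data.frame(
    parental_sig = c(FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    maternal_sig = c(NA,    FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    paternal_sig = c(NA,    TRUE,  FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE),
    f1_position  = c(NA,    NA,    NA,    NA,    "between", "above", "below", "tie"),
    category = c("no_parental_divergence", "cis_dominant", "conserved",
                 "trans_dominant", "trans_additive", "trans_overdominant",
                 "trans_underdominant", "ambiguous"),
    stringsAsFactors = FALSE)
  grid <- expand.grid(parental_sig = c(FALSE, TRUE),
                      maternal_sig = c(FALSE, TRUE),
                      paternal_sig = c(FALSE, TRUE),
                      f1_position = c("between", "above", "below", "tie"),
                      stringsAsFactors = FALSE)
  grid$category <- vapply(seq_len(nrow(grid)), function(i) {
    hit <- (rules$parental_sig == grid$parental_sig[i]) &
      (is.na(rules$maternal_sig) | rules$maternal_sig == grid$maternal_sig[i]) &
      (is.na(rules$paternal_sig) | rules$paternal_sig == grid$paternal_sig[i]) &
      (is.na(rules$f1_position) | rules$f1_position == grid$f1_position[i])
    cat <- rules$category[hit]
    if (length(cat) != 1) stop("decision table is not a partition", call. = FALSE)
    cat
  }, character(1))
  grid
}

#' Write regulatory calls as TSV
#' @param calls data.frame from [classify_group()].
#' @param path output path.
#' @export
write_regulatory_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
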