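#' Cross-tabulate regulatory calls into a category summary
#'
#' One row per (tissue, group) with counts for the six classified
#' categories; genes excluded from classification
#' (`no_parental_divergence`) and `ambiguous` ties are tallied separately
#' so that the input gene count is conserved.
#'
#' @param calls data.frame of calls (columns tissue, group, category).
#' @return data.frame of class `category_summary` with columns tissue,
#'   group, the six category counts, `total` (their sum),
#'   `no_parental_divergence`, `ambiguous`.
#' @export
tabulate_categories <- function(calls) {
  cats <- classified_categories()
  if (nrow(calls) == 0) {
    out <- data.frame(tissue = character(0), group = integer(0))
    for (cc in cats) out[[cc]] <- integer(0)
    out$total <- integer(0)
    out$no_parental_divergence <- integer(0)
    out$ambiguous <- integer(0)
    class(out) <- c("category_summary", "data.frame")
    return(out)
  }
  key <- unique(calls[, c("tissue", "group")])
  key <- key[order(key$tissue, key$group), , drop = FALSE]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- calls[calls$tissue == key$tissue[i] & calls$group == key$group[i], ]
    counts <- vapply(cats, function(cc) sum(sub$category == cc), integer(1))
    cbind(data.frame(tissue = key$tissue[i], group = key$group[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(total = sum(counts),
                     no_parental_divergence = sum(sub$category == "no_parental_divergence"),
                     ambiguous = sum(sub$category == "ambiguous")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("category_summary", "data.frame")
  out
}

#' Build a category summary directly from published-style counts
#'
#' @param counts data.frame with columns tissue, group and the six
#'   category counts (as written by [write_category_summary()] or shipped
#'   in `inst/extdata`).
#' @return `category_summary` data.frame.
#' @export
category_summary_from_counts <- function(counts) {
  cats <- classified_categories()
  miss <- setdiff(c("tissue", "group", cats), colnames(counts))
  if (length(miss) > 0) {
    stop("counts table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- counts[, c("tissue", "group", cats)]
  if (any(out[cats] < 0) || any(out[cats] != floor(as.matrix(out[cats])))) {
    stop("category counts must be non-negative integers", call. = FALSE)
  }
  out$total <- rowSums(out[, cats])
  out$no_parental_divergence <- if ("no_parental_divergence" %in% colnames(counts))
    counts$no_parental_divergence else NA_integer_
  out$ambiguous <- if ("ambiguous" %in% colnames(counts))
    counts$ambiguous else NA_integer_
  class(out) <- c("category_summary", "data.frame")
  out
}

#' Load the packaged published category-count fixture
#'
#' Per-tissue, per-group counts of regulatory-divergence categories of
#' expressed W-linked genes from a published White Leghorn x Cornish Game
#' reciprocal-cross experiment (brain, liver and breast muscle of day-1
#' chicks); the worked example that the summary statistics reproduce.
#'
#' @return `category_summary` data.frame (6 rows: 3 tissues x 2 groups).
#' @export
published_category_counts <- function() {
  path <- system.file("extdata", "wl_cornish_category_counts.tsv",
                      package = "wregdiv", mustWork = TRUE)
  counts <- utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
  category_summary_from_counts(counts)
}

#' Expand a category summary into per-gene pseudo-calls
#'
#' Inverse of [tabulate_categories()] up to gene identity: emits one
#' synthetic call row per counted gene (gene ids `g<tissue><group>_<i>`),
#' with skew set from the category-implied breed for dominant categories.
#' Useful for driving call-level reports from published counts.
#'
#' @param summary `category_summary` data.frame.
#' @return data.frame of calls.
#' @export
expand_summary_to_calls <- function(summary) {
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    grp <- cross_group(summary$group[i])
    for (cc in classified_categories()) {
      n <- summary[[cc]][i]
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("g_%s_%d_%s_%d", summary$tissue[i], summary$group[i],
                          cc, seq_len(n)),
        group = summary$group[i], tissue = summary$tissue[i], category = cc,
        skew = skew_for_category(cc, grp),
        maternal_mean = NA_real_, paternal_mean = NA_real_, f1_mean = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# percentage helpers: NA (undefined), never NaN, on zero denominators
pct1 <- function(num, den) ifelse(den > 0, round(100 * num / den, 1), NA_real_)
ratio2 <- function(num, den) ifelse(den > 0, round(num / den, 2), NA_real_)
ratio2_trunc <- function(num, den) ifelse(den > 0, floor(100 * num / den) / 100, NA_real_)

#' Cis and trans shares of classified genes
#'
#' Percentages are reported to one decimal, ratios to two decimals.
#' Per (tissue, group): cis% = cis-dominant / six-category total x 100.
#' Per tissue (groups pooled): trans ratio = four trans subtypes / total,
#' given both rounded and truncated to two decimals (published tables mix
#' the two renderings). Pooled over all tissues and groups: the cis share
#' and its complement.
#'
#' @param summary `category_summary` data.frame.
#' @return list with data.frames `per_group`, `per_tissue` and list
#'   `pooled` (`cis_pct`, `complement_pct`, totals).
#' @export
cis_trans_fractions <- function(summary) {
  if (nrow(summary) == 0) stop("empty category summary", call. = FALSE)
  cats <- classified_categories()
  trans_cats <- c("trans_dominant", "trans_additive",
                  "trans_overdominant", "trans_underdominant")
  trans_n <- rowSums(summary[, trans_cats])
  per_group <- data.frame(
    tissue = summary$tissue, group = summary$group,
    total = summary$total,
    cis_pct = pct1(summary$cis_dominant, summary$total),
    trans_pct = pct1(trans_n, summary$total),
    conserved_pct = pct1(summary$conserved, summary$total),
    stringsAsFactors = FALSE)

  tissues <- unique(summary$tissue)
  per_tissue <- do.call(rbind, lapply(tissues, function(tt) {
    sub <- summary[summary$tissue == tt, ]
    tot <- sum(sub$total)
    tr <- sum(rowSums(sub[, trans_cats]))
    data.frame(tissue = tt, total = tot,
               cis_ratio = ratio2(sum(sub$cis_dominant), tot),
               trans_ratio = ratio2(tr, tot),
               trans_ratio_truncated = ratio2_trunc(tr, tot),
               stringsAsFactors = FALSE)
  }))

  tot_all <- sum(summary$total)
  cis_all <- sum(summary$cis_dominant)
  pooled <- list(total = tot_all, cis_n = cis_all,
                 cis_pct = pct1(cis_all, tot_all),
                 complement_pct = pct1(tot_all - cis_all, tot_all))
  list(per_group = per_group, per_tissue = per_tissue, pooled = pooled)
}

#' Dominant-expression fractions and breed-skew tallies
#'
#' A gene shows dominant expression when its call is `cis_dominant`
#' (maternal dominance) or `trans_dominant` (paternal dominance). The
#' per-tissue dominant fraction pools both cross groups. When call-level
#' skew is available the dominant genes are tallied by the breed they are
#' skewed toward.
#'
#' @param summary `category_summary` data.frame.
#' @param calls optional call data.frame with a `skew` column.
#' @return list with data.frame `per_tissue` (tissue, dominant_n, total,
#'   dominant_pct) and data.frame `skew` (tissue, breed, n) or NULL.
#' @export
dominance_report <- function(summary, calls = NULL) {
  tissues <- unique(summary$tissue)
  per_tissue <- do.call(rbind, lapply(tissues, function(tt) {
    sub <- summary[summary$tissue == tt, ]
    dom <- sum(sub$cis_dominant) + sum(sub$trans_dominant)
    tot <- sum(sub$total)
    data.frame(tissue = tt, dominant_n = dom, total = tot,
               dominant_pct = pct1(dom, tot), stringsAsFactors = FALSE)
  }))
  skew <- NULL
  if (!is.null(calls) && "skew" %in% colnames(calls)) {
    dom_calls <- calls[calls$category %in% c("cis_dominant", "trans_dominant") &
                         calls$skew != "none", , drop = FALSE]
    if (nrow(dom_calls) > 0) {
      tab <- as.data.frame(table(tissue = dom_calls$tissue, breed = dom_calls$skew),
                           stringsAsFactors = FALSE)
      colnames(tab)[3] <- "n"
      skew <- tab[order(tab$tissue, tab$breed), , drop = FALSE]
      rownames(skew) <- NULL
    }
  }
  list(per_tissue = per_tissue, skew = skew)
}

#' Signed log2 fold-change spectrum of parental DEGs
#'
#' Summarizes the direction and magnitude of parental expression
#' divergence. The sign convention is configurable: with
#' `positive = "A"`, positive values mean population A of the contrast is
#' up-regulated; `positive = "B"` flips the sign (used to report Cor-up
#' as positive when the contrast was WL vs Cor).
#'
#' @param contrast data.frame from [call_contrast()].
#' @param significant_only keep only significant genes (default TRUE).
#' @param positive which population gets positive sign, `"A"` or `"B"`.
#' @param breaks histogram breaks passed to [graphics::hist()] binning via
#'   [base::cut()]; default unit bins spanning the data.
#' @return list with `log2_fc` (named vector), `fraction_under_twofold`
#'   (NA when no genes), and `histogram` (data.frame bin/count).
#' @export
fold_change_spectrum <- function(contrast, significant_only = TRUE,
                                 positive = c("A", "B"), breaks = NULL) {
  positive <- match.arg(positive)
  sub <- if (significant_only) contrast[contrast$significant, , drop = FALSE] else contrast
  lfc <- log2(sub$fold_change)
  if (positive == "B") lfc <- -lfc
  names(lfc) <- sub$gene_id
  if (length(lfc) == 0) {
    return(list(log2_fc = lfc, fraction_under_twofold = NA_real_,
                histogram = data.frame(bin = character(0), count = integer(0))))
  }
  if (is.null(breaks)) {
    rng <- range(lfc)
    breaks <- seq(floor(rng[1]), ceiling(rng[2]) + 1e-9, by = 0.5)
  }
  cutbins <- cut(lfc, breaks = breaks, include.lowest = TRUE)
  hist_df <- as.data.frame(table(bin = cutbins), stringsAsFactors = FALSE)
  colnames(hist_df)[2] <- "count"
  list(log2_fc = lfc,
       fraction_under_twofold = mean(abs(lfc) < 1),
       histogram = hist_df)
}

#' Between-group consistency of regulatory categories
#'
#' For each tissue, the fraction of genes classified (i.e. not excluded
#' as `no_parental_divergence` or `ambiguous`) in *both* cross groups
#' that received the same category in the two groups.
#'
#' @param calls call data.frame covering both groups.
#' @return data.frame tissue, n_both (classified in both groups),
#'   n_consistent, consistency (NA when no gene qualifies).
#' @export
cross_group_consistency <- function(calls) {
  excl <- c("no_parental_divergence", "ambiguous")
  tissues <- unique(calls$tissue)
  do.call(rbind, lapply(tissues, function(tt) {
    g1 <- calls[calls$tissue == tt & calls$group == 1 & !(calls$category %in% excl), ]
    g2 <- calls[calls$tissue == tt & calls$group == 2 & !(calls$category %in% excl), ]
    shared <- intersect(g1$gene_id, g2$gene_id)
    same <- sum(g1$category[match(shared, g1$gene_id)] ==
                  g2$category[match(shared, g2$gene_id)])
    data.frame(tissue = tt, n_both = length(shared), n_consistent = same,
               consistency = if (length(shared) > 0) same / length(shared) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Write a category summary as TSV
#' @param summary `category_summary` data.frame.
#' @param path output path.
#' @export
write_category_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' All derived fractions as one report list
#'
#' Bundles [cis_trans_fractions()], [dominance_report()] and, when calls
#' are supplied, [cross_group_consistency()] into one structure suitable
#' for JSON serialization.
#'
#' @param summary `category_summary` data.frame.
#' @param calls optional call-level data.frame.
#' @return named list.
#' @export
derived_fractions <- function(summary, calls = NULL) {
  fr <- cis_trans_fractions(summary)
  dom <- dominance_report(summary, calls)
  out <- list(per_group = fr$per_group, per_tissue = fr$per_tissue,
              pooled = fr$pooled, dominance = dom$per_tissue,
              dominance_skew = dom$skew)
  if (!is.null(calls) && length(unique(calls$group)) == 2) {
    out$cross_group_consistency <- cross_group_consistency(calls)
  }
  out
}
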