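#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix of
#' normalized expression values (TPM) with unique, non-empty gene identifiers
#' as row names and unique sample identifiers as column names. All values
#' must be finite and non-negative.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @return the validated matrix, invisibly.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix must carry gene row names and sample column names",
         call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  invisible(values)
}

#' Build an expression matrix from values and identifiers
#'
#' @param values numeric matrix (genes x samples).
#' @param gene_ids,sample_ids identifiers; default to the dimnames of `values`.
#' @return validated numeric matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

#' Read a TPM expression table
#'
#' Expects a UTF-8 delimited text table whose first column holds gene ids
#' (header `gene_id`) and whose remaining columns are samples. Missing values
#' are disallowed; duplicated gene or sample ids and negative or non-numeric
#' cells are hard errors that name the offending entry.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return validated expression matrix (genes x samples).
#' @export
read_expression_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene id column and at least one sample",
                          call. = FALSE)
  gene_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 raw[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  expression_matrix(num, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]; round-trips values to the printed
#' precision of `digits` significant digits.
#'
#' @param matrix validated expression matrix.
#' @param path output path.
#' @param digits significant digits to print (default 15, lossless for
#'   doubles in practice).
#' @export
write_expression_table <- function(matrix, path, digits = 15) {
  validate_expression_matrix(matrix)
  out <- data.frame(gene_id = rownames(matrix),
                    signif(matrix, digits),
                    check.names = FALSE, row.names = NULL)
  colnames(out) <- c("gene_id", colnames(matrix))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Populations recognised by default
#'
#' `Cor` (Cornish Game) and `WL` (White Leghorn) are the parental breeds;
#' `CL` is the F1 of a Cor dam and WL sire, `LC` the reciprocal F1 of a WL
#' dam and Cor sire.
#' @export
default_populations <- function() c("Cor", "WL", "CL", "LC")

#' Read a sample sheet
#'
#' Tab-separated table with header columns `sample_id`, `population`, `sex`,
#' `tissue` and optionally `replicate`. Population labels outside
#' `allowed_populations` are rejected, as are duplicated sample ids.
#'
#' @param path file path.
#' @param allowed_populations character vector of accepted population labels.
#' @return data.frame with columns sample_id, population, sex, tissue,
#'   replicate.
#' @export
read_sample_sheet <- function(path, allowed_populations = default_populations()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # colClasses: "F"/"T" in the sex column must not become logicals
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           comment.char = "#", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no samples in sample sheet ", path, call. = FALSE)
  if ("replicate" %in% colnames(tab)) {
    tab$replicate <- as.integer(tab$replicate)
  }
  validate_sample_sheet(tab, allowed_populations)
}

#' Validate a sample sheet data.frame
#'
#' @inheritParams read_sample_sheet
#' @param sheet data.frame with the sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet, allowed_populations = default_populations()) {
  need <- c("sample_id", "population", "sex", "tissue")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup) > 0) {
    stop("sample(s) listed twice in sheet: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(sheet$population), allowed_populations)
  if (length(unknown) > 0) {
    stop("unknown population label(s) ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed_populations, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(sheet$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    stop("sex must be F or M, found: ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sheet$replicate)) {
    sheet$replicate <- stats::ave(seq_len(nrow(sheet)),
                                  sheet$population, sheet$tissue,
                                  FUN = seq_along)
  }
  sheet[, c(need, "replicate")]
}

#' Write a sample sheet as TSV
#' @param sheet validated sample sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (gene -> chromosome)
#'
#' Accepts either a two-column TSV (`gene_id`, `chromosome`, with or without
#' a header) or a BED file (`.bed` suffix; 0-based half-open, the `name`
#' column supplies the gene id). BED parsing uses rtracklayer when
#' available.
#'
#' @param path file path.
#' @return data.frame with columns gene_id, chromosome (and start/end for BED).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
      ann <- data.frame(gene_id = gr$name,
                        chromosome = as.character(gr$seqnames),
                        start = gr$start, end = gr$end,
                        stringsAsFactors = FALSE)
    } else {
      tab <- utils::read.table(path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
      if (ncol(tab) < 4) stop("BED annotation needs a name column", call. = FALSE)
      ann <- data.frame(gene_id = tab[[4]], chromosome = tab[[1]],
                        start = tab[[2]] + 1L, end = tab[[3]],
                        stringsAsFactors = FALSE)
    }
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (identical(tolower(tab[1, 1]), "gene_id")) tab <- tab[-1, , drop = FALSE]
    if (ncol(tab) < 2) stop("annotation TSV needs gene_id and chromosome columns",
                            call. = FALSE)
    ann <- data.frame(gene_id = as.character(tab[[1]]),
                      chromosome = as.character(tab[[2]]),
                      stringsAsFactors = FALSE)
  }
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup) > 0) {
    stop("duplicated gene id(s) in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(ann$chromosome))) stop("empty chromosome label in annotation",
                                         call. = FALSE)
  ann
}

#' Remove genes below an expression floor
#'
#' A gene is dropped iff its expression is below `threshold` in *all*
#' samples, i.e. retained when at least one sample reaches the floor
#' (default 0.5 TPM). Idempotent; the sample set is unchanged.
#'
#' @param matrix expression matrix.
#' @param threshold TPM floor, must be >= 0.
#' @return filtered expression matrix (possibly zero genes).
#' @export
filter_low_expression <- function(matrix, threshold = 0.5) {
  validate_expression_matrix(matrix)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  keep <- apply(matrix, 1, max) >= threshold
  matrix[keep, , drop = FALSE]
}

#' Subset an expression matrix to one chromosome
#'
#' @param matrix expression matrix.
#' @param annotation data.frame from [read_gene_annotation()].
#' @param chromosome chromosome label, e.g. `"W"`.
#' @param on_missing what to do with matrix genes absent from the
#'   annotation: `"error"` (default) or `"drop"` with a warning.
#' @return expression matrix restricted to genes on `chromosome`, input
#'   order preserved. An empty result is not an error.
#' @export
subset_by_chromosome <- function(matrix, annotation, chromosome,
                                 on_missing = c("error", "drop")) {
  validate_expression_matrix(matrix)
  on_missing <- match.arg(on_missing)
  missing <- setdiff(rownames(matrix), annotation$gene_id)
  if (length(missing) > 0) {
    msg <- paste0("gene(s) missing from annotation: ",
                  paste(utils::head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    if (on_missing == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropping", call. = FALSE)
  }
  chrom <- annotation$chromosome[match(rownames(matrix), annotation$gene_id)]
  keep <- !is.na(chrom) & chrom == chromosome
  matrix[keep, , drop = FALSE]
}

#' Restrict a sample sheet to females
#'
#' W-linked analysis is female-only (males are ZZ and carry no W); this is
#' the single explicit selection step applied before classification.
#'
#' @param sheet sample sheet data.frame.
#' @return the female rows of `sheet`.
#' @export
females_only <- function(sheet) {
  out <- sheet[sheet$sex == "F", , drop = FALSE]
  if (nrow(out) == 0) stop("no female samples", call. = FALSE)
  out
}

#' Define a reciprocal-cross group
#'
#' Group 1 compares the Cor dam line, WL sire line and their F1 (CL);
#' group 2 is the reciprocal (WL dam, Cor sire, F1 LC). The maternal
#' population is the one whose W chromosome the F1 inherits.
#'
#' @param group_id 1 or 2.
#' @return list with group_id, maternal_population, paternal_population,
#'   f1_population.
#' @export
cross_group <- function(group_id) {
  if (!group_id %in% c(1L, 2L)) stop("group_id must be 1 or 2", call. = FALSE)
  if (group_id == 1) {
    list(group_id = 1L, maternal_population = "Cor",
         paternal_population = "WL", f1_population = "CL")
  } else {
    list(group_id = 2L, maternal_population = "WL",
         paternal_population = "Cor", f1_population = "LC")
  }
}
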