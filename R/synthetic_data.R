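#' Configure a synthetic reciprocal-cross dataset
#'
#' The generator emulates the study design the pipeline targets: two
#' parental breeds (Cor, WL), reciprocal F1 females (CL = Cor dam x WL
#' sire; LC = WL dam x Cor sire), three tissues, and an unbalanced female
#' replicate layout (3 per population except 2 for LC, the cross that
#' yielded only two female chicks). Each gene is assigned a generating
#' regulatory class; per-tissue baselines are lognormal on the TPM scale
#' and replicate noise is multiplicative lognormal with a fixed
#' coefficient of variation.
#'
#' @param genes_per_class named integer vector mapping classes
#'   (`cis_dominant`, `trans_dominant`, `trans_additive`,
#'   `trans_overdominant`, `trans_underdominant`, `conserved`, `null`)
#'   to gene counts; unnamed classes default to 0.
#' @param baseline_log2_mean,baseline_log2_sd parameters of the per-gene,
#'   per-tissue baseline: TPM = 2^Normal(mean, sd). Defaults 5 and 2
#'   (median 32 TPM, comfortably above the 0.5 TPM expression floor).
#' @param effect_log2 absolute parental log2 fold-effect for divergent
#'   classes (default 3, i.e. 8-fold); the up-regulated breed is chosen
#'   at random per gene.
#' @param conserved_fold parental fold for the `conserved` class, just
#'   above the 1.25 significance window (default 1.3) with the F1 at the
#'   parental midpoint — the regime in which a conserved call is
#'   reachable.
#' @param dominance_excess multiplicative excess of over-dominant F1
#'   expression above the higher parent (and of under-dominant below the
#'   lower parent); default 2.
#' @param noise_cv replicate-level coefficient of variation of the
#'   multiplicative lognormal noise (default 0.15).
#' @param replicates named vector of female replicate counts per
#'   population (default `c(Cor = 3, WL = 3, CL = 3, LC = 2)`).
#' @param tissues tissue labels (default brain, liver, muscle).
#' @param include_males also emit male parental samples (same breed
#'   means), for exercising the females-only selection step.
#' @param additive_scale `"linear"` (arithmetic mean of parental TPM,
#'   default) or `"geometric"` for the additive F1 rule.
#' @param seed mandatory RNG seed; recorded in the output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genes_per_class = c(cis_dominant = 20,
                                                  trans_dominant = 20,
                                                  trans_additive = 20,
                                                  trans_overdominant = 20,
                                                  trans_underdominant = 20,
                                                  conserved = 10,
                                                  null = 40),
                              baseline_log2_mean = 5, baseline_log2_sd = 2,
                              effect_log2 = 3, conserved_fold = 1.3,
                              dominance_excess = 2, noise_cv = 0.15,
                              replicates = c(Cor = 3, WL = 3, CL = 3, LC = 2),
                              tissues = c("brain", "liver", "muscle"),
                              include_males = FALSE,
                              additive_scale = c("linear", "geometric"),
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  additive_scale <- match.arg(additive_scale)
  known <- c(classified_categories(), "null")
  bad <- setdiff(names(genes_per_class), known)
  if (length(bad) > 0) {
    stop("unknown gene class(es): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "), call. = FALSE)
  }
  if (any(genes_per_class < 0)) stop("gene counts must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (!all(c("Cor", "WL", "CL", "LC") %in% names(replicates))) {
    stop("replicates must name Cor, WL, CL, LC", call. = FALSE)
  }
  structure(list(genes_per_class = genes_per_class,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 effect_log2 = effect_log2, conserved_fold = conserved_fold,
                 dominance_excess = dominance_excess, noise_cv = noise_cv,
                 replicates = replicates, tissues = tissues,
                 include_males = include_males,
                 additive_scale = additive_scale, seed = as.integer(seed)),
            class = "simulation_config")
}

# F1 mean for one group given class and parental means
f1_mean_for_class <- function(class, maternal, paternal, excess, additive_scale) {
  switch(class,
         cis_dominant = maternal,
         trans_dominant = paternal,
         trans_additive = if (additive_scale == "linear") (maternal + paternal) / 2
                          else sqrt(maternal * paternal),
         trans_overdominant = max(maternal, paternal) * excess,
         trans_underdominant = min(maternal, paternal) / excess,
         conserved = (maternal + paternal) / 2,
         null = (maternal + paternal) / 2,  # parents equal for null genes
         stop("unknown class ", class, call. = FALSE))
}

# multiplicative lognormal noise with unit mean and the configured CV
noisy <- function(mean, n, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic reciprocal-cross dataset
#'
#' Per gene and tissue: the Cor mean is the baseline and the WL mean is
#' baseline x 2^(signed effect) (sign random per gene; zero for `null`
#' genes; log2(conserved_fold) magnitude for `conserved` genes). F1 means
#' follow the gene's class with maternal/paternal roles resolved per
#' cross group — the same gene therefore has CL tracking Cor where LC
#' tracks WL for a cis gene. Replicates are mean x lognormal noise with
#' unit expectation and the configured CV.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (expression matrix over all tissues),
#'   `sheet` (sample sheet) and `truth` (per-gene generating class,
#'   signed log2 effect, F1 rule, and per-tissue baselines).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  classes <- rep(names(config$genes_per_class), times = config$genes_per_class)
  n_genes <- length(classes)
  if (n_genes == 0) stop("config yields zero genes", call. = FALSE)
  gene_ids <- sprintf("SYNW%04d", seq_len(n_genes))

  effect_sign <- sample(c(1, -1), n_genes, replace = TRUE)
  effect <- ifelse(classes == "null", 0,
                   ifelse(classes == "conserved",
                          effect_sign * log2(config$conserved_fold),
                          effect_sign * config$effect_log2))

  baselines <- matrix(2^stats::rnorm(n_genes * length(config$tissues),
                                     config$baseline_log2_mean,
                                     config$baseline_log2_sd),
                      nrow = n_genes,
                      dimnames = list(gene_ids, config$tissues))

  reps <- config$replicates
  pops <- c("Cor", "WL", "CL", "LC")
  sheet_rows <- list()
  for (tt in config$tissues) {
    for (pp in pops) {
      for (r in seq_len(reps[[pp]])) {
        sheet_rows[[length(sheet_rows) + 1]] <-
          data.frame(sample_id = sprintf("%s_%s_F%d", pp, tt, r),
                     population = pp, sex = "F", tissue = tt, replicate = r,
                     stringsAsFactors = FALSE)
      }
    }
    if (config$include_males) {
      for (pp in c("Cor", "WL")) {
        for (r in seq_len(reps[[pp]])) {
          sheet_rows[[length(sheet_rows) + 1]] <-
            data.frame(sample_id = sprintf("%s_%s_M%d", pp, tt, r),
                       population = pp, sex = "M", tissue = tt, replicate = r,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  sheet <- do.call(rbind, sheet_rows)

  values <- matrix(0, nrow = n_genes, ncol = nrow(sheet),
                   dimnames = list(gene_ids, sheet$sample_id))
  for (tt in config$tissues) {
    mean_cor <- baselines[, tt]
    mean_wl <- baselines[, tt] * 2^effect
    # group 1: dam Cor, sire WL, F1 CL; group 2: dam WL, sire Cor, F1 LC
    mean_cl <- mean_lc <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      mean_cl[i] <- f1_mean_for_class(classes[i], mean_cor[i], mean_wl[i],
                                      config$dominance_excess, config$additive_scale)
      mean_lc[i] <- f1_mean_for_class(classes[i], mean_wl[i], mean_cor[i],
                                      config$dominance_excess, config$additive_scale)
    }
    pop_means <- list(Cor = mean_cor, WL = mean_wl, CL = mean_cl, LC = mean_lc)
    for (j in which(sheet$tissue == tt)) {
      mu <- pop_means[[sheet$population[j]]]
      values[, j] <- vapply(mu, function(m) noisy(m, 1, config$noise_cv),
                            numeric(1))
    }
  }

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      effect_log2 = effect, f1_rule = classes,
                      stringsAsFactors = FALSE)
  for (tt in config$tissues) truth[[paste0("baseline_", tt)]] <- baselines[, tt]

  list(matrix = expression_matrix(values), sheet = sheet, truth = truth,
       config = config)
}

#' Generate an all-null dataset for false-positive calibration
#'
#' Same machinery as [generate_dataset()] with every gene forced to the
#' `null` class (equal means everywhere), keeping the configured total
#' gene count.
#'
#' @param config a [simulation_config()].
#' @return as [generate_dataset()].
#' @export
generate_null_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$genes_per_class <- c(null = sum(config$genes_per_class))
  generate_dataset(config)
}

#' Write a synthetic truth table as TSV
#' @param truth data.frame from [generate_dataset()].
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
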