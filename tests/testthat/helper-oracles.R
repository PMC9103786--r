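# independent brute-force oracles for the exact tests, by enumeration

# two-sided binomial p (minlike): sum of outcome probabilities no larger
# than the observed outcome's probability
binom_p_oracle <- function(a, n, p) {
  if (n == 0) return(1)
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[a + 1] * (1 + 1e-7)])
}

# two-sided Fisher p for table [a, ta - a; b, tb - b] by enumerating all
# tables with the observed margins
fisher_p_oracle <- function(a, b, ta, tb) {
  k <- a + b
  xs <- max(0, k - tb):min(k, ta)
  probs <- dhyper(xs, ta, tb, k)
  obs <- dhyper(a, ta, tb, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small 2-gene x 3-sample matrix used across io tests
tiny_matrix <- function() {
  expression_matrix(matrix(0:5, nrow = 2, byrow = TRUE,
                           dimnames = list(c("g1", "g2"),
                                           c("s1", "s2", "s3"))))
}

# the real study layout: 23 chicks (Cor 3F+3M, WL 3F+3M, CL 3F+3M, LC 2F+3M)
design_sheet <- function(tissue = "brain") {
  rows <- list()
  layout <- list(Cor = c(F = 3, M = 3), WL = c(F = 3, M = 3),
                 CL = c(F = 3, M = 3), LC = c(F = 2, M = 3))
  for (pop in names(layout)) {
    for (sex in c("F", "M")) {
      n <- layout[[pop]][[sex]]
      if (n == 0) next
      for (r in seq_len(n)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s%d", pop, sex, r), population = pop,
          sex = sex, tissue = tissue, replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# quick simulated dataset for one tissue
quick_sim <- function(genes_per_class, seed, noise_cv = 0.15, effect = 3,
                      replicates = c(Cor = 3, WL = 3, CL = 3, LC = 2),
                      tissues = "brain", ...) {
  generate_dataset(simulation_config(genes_per_class = genes_per_class,
                                     noise_cv = noise_cv, effect_log2 = effect,
                                     replicates = replicates, tissues = tissues,
                                     seed = seed, ...))
}

CLASSIFIED <- c("cis_dominant", "trans_dominant", "trans_additive",
                "trans_overdominant", "trans_underdominant", "conserved")
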