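# fixtures built in code; all seeded

tiny_matrix <- function(n = 6, m = 4, seed = 1, mean = 10, sd = 0.5) {
  set.seed(seed)
  v <- 2^matrix(rnorm(n * m, mean, sd), n, m,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("apt%02d", seq_len(m))))
  intensity_matrix(v)
}

small_config <- function(seed = 1, n_proteins = 100, ...) {
  generator_config(seed = seed, n_proteins = n_proteins, ...)
}

# config with no planted effects anywhere
null_config <- function(seed = 1, n_proteins = 100, ...) {
  generator_config(seed = seed, n_proteins = n_proteins,
                   effect_model = "null",
                   covariate_effects = c(sex = 0, age = 0, bmi = 0,
                                         fasting = 0), ...)
}

# minimal hand-built annotation table
make_annotations <- function(aptamer_id, gene_symbol = aptamer_id,
                             subcellular_class = "intracellular") {
  out <- data.frame(aptamer_id = aptamer_id,
                    target_full_name = paste("Protein", gene_symbol),
                    gene_symbol = gene_symbol,
                    uniprot = NA_character_,
                    subcellular_class = rep_len(subcellular_class,
                                                length(aptamer_id)),
                    secretome_location = "none",
                    secretome_function = "none",
                    stringsAsFactors = FALSE)
  out$tissue_panels <- rep(list(character(0)), nrow(out))
  out$immune_panels <- rep(list(character(0)), nrow(out))
  out$mito <- FALSE
  out$neutrophil_release <- FALSE
  class(out) <- c("aptamer_annotation", "data.frame")
  out
}

# hand-built diff table
make_diff <- function(aptamer_id, log2fc, p, q = NULL) {
  data.frame(aptamer_id = aptamer_id, log2fc = log2fc, p = p,
             q = if (is.null(q)) adjust_fdr_bh(p) else q,
             stringsAsFactors = FALSE)
}
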