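#' Configuration for the synthetic dataset generator
#'
#' Defaults state the cohort structure the pipeline was designed around:
#' 50 cases (ME) vs 29 controls (HC), ~6,400 proteins measured by ~7,300
#' aptamers with ~12% of proteins carried by two or more aptamers, subcellular
#' class shares 53.4/25.9/17.6/3.0% (intracellular / membrane-associated /
#' secreted / unannotated), group effects shifting intracellular proteins
#' down and secreted proteins up on the log2 scale, covariate confounding
#' (sex, age, BMI, overnight fasting with the fasting imbalance confined to
#' cases), and a noisy antibody-platform replicate.
#'
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param n_me,n_hc group sample counts.
#' @param n_proteins number of distinct proteins (gene symbols).
#' @param duplication_rate fraction of proteins carried by 2 aptamers.
#' @param inter_aptamer_rho target Pearson correlation between duplicate
#'   aptamers of one protein (noise-sharing mixture; see vignette).
#' @param class_fractions named fractions summing to 1 over either the four
#'   reported groups (`intracellular`, `membrane`, `secreted`, `unannotated`;
#'   membrane is split evenly into `membrane`/`membrane_secreted`) or the five
#'   annotation classes.
#' @param effect_model named list mapping subcellular class to `c(mean, sd)`
#'   of the planted per-protein log2 group shift; `"null"` sets all to zero.
#' @param covariate_effects named sds of per-aptamer covariate slopes on log2
#'   intensity for `sex`, `age`, `bmi`, `fasting` (covariates centered).
#' @param noise_sd residual sd on the log2 scale.
#' @param outlier_samples count of displaced samples injected post hoc.
#' @param outlier_magnitude their displacement on the log10 scale.
#' @param fasting_me_fraction fraction of ME samples fasting (HC never fast).
#' @param platform_noise_sd log2-scale noise of the immunoassay replicate.
#' @param flip_fraction fraction of immunoassay analytes with planted
#'   discordant (group-mirrored) signal.
#' @param panel_rate per-panel membership probability for tissue/immune
#'   panels.
#' @param panel_coupling tilt of panel membership toward planted effects;
#'   0 (default) makes membership independent of the planted log2FC.
#' @return a list of class `generator_config`
#' @export
generator_config <- function(seed = 1L,
                             n_me = 50L, n_hc = 29L,
                             n_proteins = 6408L,
                             duplication_rate = 786 / 6408,
                             inter_aptamer_rho = 0.5,
                             class_fractions = c(intracellular = 0.534,
                                                 membrane = 0.259,
                                                 secreted = 0.176,
                                                 unannotated = 0.031),
                             effect_model = list(
                               intracellular = c(-0.3, 0.15),
                               membrane = c(0.15, 0.15),
                               membrane_secreted = c(0.15, 0.15),
                               secreted = c(0.3, 0.15),
                               unannotated = c(0, 0.15)),
                             covariate_effects = c(sex = 0.05, age = 0.005,
                                                   bmi = 0.01, fasting = 0.05),
                             noise_sd = 0.3,
                             outlier_samples = 0L,
                             outlier_magnitude = 1.0,
                             fasting_me_fraction = 0.22,
                             platform_noise_sd = 0.3,
                             flip_fraction = 0,
                             panel_rate = 0.03,
                             panel_coupling = 0) {
  if (identical(effect_model, "null"))
    effect_model <- lapply(stats::setNames(nm = .SUBCELLULAR_CLASSES),
                           function(cl) c(0, 0))
  class_fractions <- .normalize_class_fractions(class_fractions)
  cfg <- list(seed = as.integer(seed), n_me = as.integer(n_me),
              n_hc = as.integer(n_hc), n_proteins = as.integer(n_proteins),
              duplication_rate = duplication_rate,
              inter_aptamer_rho = inter_aptamer_rho,
              class_fractions = class_fractions,
              effect_model = effect_model,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              outlier_samples = as.integer(outlier_samples),
              outlier_magnitude = outlier_magnitude,
              fasting_me_fraction = fasting_me_fraction,
              platform_noise_sd = platform_noise_sd,
              flip_fraction = flip_fraction,
              panel_rate = panel_rate,
              panel_coupling = panel_coupling)
  .validate_config(cfg)
  structure(cfg, class = "generator_config")
}

.normalize_class_fractions <- function(cf) {
  if (is.null(names(cf)) || any(names(cf) == ""))
    stop("class_fractions must be named")
  if (setequal(names(cf), c("intracellular", "membrane", "secreted",
                            "unannotated"))) {
    cf <- c(intracellular = unname(cf["intracellular"]),
            membrane = unname(cf["membrane"]) / 2,
            membrane_secreted = unname(cf["membrane"]) / 2,
            secreted = unname(cf["secreted"]),
            unannotated = unname(cf["unannotated"]))
  }
  miss <- setdiff(.SUBCELLULAR_CLASSES, names(cf))
  cf[miss] <- 0
  cf <- cf[.SUBCELLULAR_CLASSES]
  if (abs(sum(cf) - 1) > 1e-9) stop("class_fractions must sum to 1")
  cf
}

.validate_config <- function(cfg) {
  stopifnot(cfg$n_me >= 0, cfg$n_hc >= 0, cfg$n_proteins >= 0,
            cfg$duplication_rate >= 0, cfg$duplication_rate <= 1,
            cfg$noise_sd >= 0)
  if (cfg$inter_aptamer_rho < 0 || cfg$inter_aptamer_rho > 1)
    stop("inter_aptamer_rho must be in [0,1]")
  invisible(cfg)
}

.rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= lower)) {
    bad <- x <= lower
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Sample metadata mirroring the cohort's covariate structure.
.generate_metadata <- function(cfg) {
  n <- cfg$n_me + cfg$n_hc
  ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("ME", cfg$n_me), rep("HC", cfg$n_hc))
  sex <- ifelse(stats::runif(n) < 0.77, "F", "M")
  age <- .rtrunc_norm(n, 40, 10, 18)
  bmi <- .rtrunc_norm(n, 24, 4, 15)
  fasting <- ifelse(group == "ME",
                    stats::runif(n) < cfg$fasting_me_fraction, FALSE)
  metabotype <- ifelse(group == "ME",
                       sample(c("M1", "M2", "M3"), n, replace = TRUE), "none")
  sf36pf <- ifelse(group == "ME",
                   pmin(100, pmax(0, stats::rnorm(n, 31.2, 19.3))), NA_real_)
  steps <- ifelse(group == "ME", .rtrunc_norm(n, 3021, 2001, 0), NA_real_)
  data.frame(sample_id = ids, group = group, sex = sex, age = age, bmi = bmi,
             fasting = fasting, metabotype = metabotype, sf36pf = sf36pf,
             mean_steps = steps, platform = "aptamer",
             stringsAsFactors = FALSE)
}

# Protein/aptamer scaffold: classes drawn per protein, ~duplication_rate of
# proteins carried by two aptamers.
.generate_scaffold <- function(cfg) {
  np <- cfg$n_proteins
  protein <- sprintf("GENE%05d", seq_len(np))
  cls <- sample(.SUBCELLULAR_CLASSES, np, replace = TRUE,
                prob = cfg$class_fractions)
  dup <- stats::runif(np) < cfg$duplication_rate
  n_apt_per_protein <- ifelse(dup, 2L, 1L)
  protein_of <- rep(seq_len(np), n_apt_per_protein)
  apt_id <- sprintf("seq.%05d.%d", protein_of,
                    unlist(lapply(n_apt_per_protein, seq_len)))
  list(protein = protein, class = cls, protein_of = protein_of,
       aptamer_id = apt_id)
}

#' Generate a full synthetic dataset
#'
#' Draws intensities as `2^(baseline + covariate terms + group * delta +
#' correlated noise)`: per-protein planted log2 group shifts delta are drawn
#' from the class-conditional effect model and shared by duplicate aptamers;
#' duplicate aptamers mix a protein-common noise component with an
#' idiosyncratic one (`sqrt(rho)*common + sqrt(1-rho)*own`) so their expected
#' pairwise Pearson correlation equals `inter_aptamer_rho` when no other
#' shared signal is present. The truth table records every planted
#' per-aptamer log2FC exactly once.
#'
#' @param config a [generator_config()]
#' @return list with `matrix` ([intensity_matrix()]), `annotations`
#'   (as from [load_annotations()]), `metadata` (data.frame), and `truth`
#'   (data.frame: `aptamer_id`, `protein_id`, `subcellular_class`,
#'   `planted_log2fc`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_me + config$n_hc < 4)
    stop("need at least 4 samples for downstream models")
  set.seed(config$seed)
  meta <- .generate_metadata(config)
  sc <- .generate_scaffold(config)
  n <- nrow(meta)
  m <- length(sc$aptamer_id)
  np <- config$n_proteins

  # per-protein planted effect, shared by its aptamers
  em <- config$effect_model
  delta_p <- vapply(seq_len(np), function(i) {
    par <- em[[sc$class[i]]]
    stats::rnorm(1, par[1], par[2])
  }, 0)
  delta <- delta_p[sc$protein_of]

  # centered covariates; per-aptamer random slopes with the configured sds
  g <- as.numeric(meta$group == "ME")
  X <- cbind(sex = as.numeric(meta$sex == "F") - mean(meta$sex == "F"),
             age = meta$age - mean(meta$age),
             bmi = meta$bmi - mean(meta$bmi),
             fasting = as.numeric(meta$fasting) - mean(meta$fasting))
  ce <- config$covariate_effects
  slopes <- vapply(colnames(X),
                   function(j) stats::rnorm(m, 0, ce[[j]]),
                   numeric(m))                     # m x 4

  baseline <- stats::rnorm(m, 10, 1.5)
  rho <- config$inter_aptamer_rho
  common <- matrix(stats::rnorm(n * np, 0, config$noise_sd), n, np)
  idio <- matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  eps <- sqrt(rho) * common[, sc$protein_of, drop = FALSE] +
    sqrt(1 - rho) * idio

  log2v <- matrix(baseline, n, m, byrow = TRUE) +
    X %*% t(slopes) + outer(g, delta) + eps
  values <- 2^log2v
  dimnames(values) <- list(meta$sample_id, sc$aptamer_id)

  ann <- generate_annotation_panels(config, scaffold = sc, delta = delta)
  truth <- data.frame(aptamer_id = sc$aptamer_id,
                      protein_id = sc$protein[sc$protein_of],
                      subcellular_class = sc$class[sc$protein_of],
                      planted_log2fc = delta, stringsAsFactors = FALSE)
  out <- list(matrix = intensity_matrix(values), annotations = ann,
              metadata = meta, truth = truth)
  if (config$outlier_samples > 0) {
    inj <- inject_outliers(out$matrix, k = config$outlier_samples,
                           magnitude = config$outlier_magnitude,
                           seed = config$seed + 1L)
    out$matrix <- inj$matrix
    out$outlier_ids <- inj$outlier_ids
  }
  out
}

.TISSUE_PANELS <- c("brain", "liver", "intestine", "skeletal_muscle",
                    "lymphoid", "bone_marrow")
.IMMUNE_PANELS <- c("B_cells", "dendritic_cells", "granulocytes",
                    "monocytes", "NK_cells", "T_cells")

#' Generate an aptamer annotation table with panel memberships
#'
#' Subcellular classes follow `class_fractions`; tissue, immune, secretome,
#' mitochondrial and neutrophil-release memberships are drawn independently
#' of the planted effects unless `panel_coupling` is nonzero, in which case
#' membership probability is tilted multiplicatively by
#' `exp(coupling * delta)`.
#'
#' @param config a [generator_config()]
#' @param seed optional seed override (defaults to `config$seed`); ignored
#'   when called internally from [generate_dataset()] (which has already
#'   seeded the stream).
#' @param scaffold,delta internal use by [generate_dataset()].
#' @return an annotation data.frame as from [load_annotations()]
#' @export
generate_annotation_panels <- function(config, seed = NULL, scaffold = NULL,
                                       delta = NULL) {
  stopifnot(inherits(config, "generator_config"))
  internal <- !is.null(scaffold)
  if (!internal) {
    set.seed(if (is.null(seed)) config$seed else as.integer(seed))
    scaffold <- .generate_scaffold(config)
    if (is.null(delta)) delta <- numeric(length(scaffold$aptamer_id))
  }
  sc <- scaffold
  m <- length(sc$aptamer_id)
  cls <- sc$class[sc$protein_of]
  tilt <- if (config$panel_coupling == 0) rep(1, m)
          else exp(config$panel_coupling * delta)
  draw_panel <- function() stats::runif(m) < pmin(1, config$panel_rate * tilt)
  tissue <- lapply(seq_len(m), function(i) character(0))
  for (p in .TISSUE_PANELS) {
    inp <- draw_panel()
    tissue[inp] <- lapply(tissue[inp], function(v) c(v, p))
  }
  immune <- lapply(seq_len(m), function(i) character(0))
  for (p in .IMMUNE_PANELS) {
    inp <- draw_panel()
    immune[inp] <- lapply(immune[inp], function(v) c(v, p))
  }
  secreted_like <- cls %in% c("secreted", "membrane_secreted")
  loc <- ifelse(secreted_like,
                sample(setdiff(.SECRETOME_LOCATIONS, "none"), m,
                       replace = TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.08, 0.08, 0.05, 0.05,
                                0.09, 0.05)),
                "none")
  fun <- ifelse(secreted_like,
                sample(setdiff(.SECRETOME_FUNCTIONS, "none"), m,
                       replace = TRUE,
                       prob = c(0.2, 0.2, 0.1, 0.15, 0.15, 0.1, 0.1)),
                "none")
  mito <- stats::runif(m) < pmin(1, 0.06 * tilt)
  neut <- stats::runif(m) < pmin(1, 0.023 * tilt)
  out <- data.frame(
    aptamer_id = sc$aptamer_id,
    target_full_name = paste0("Protein ", sc$protein[sc$protein_of]),
    gene_symbol = sc$protein[sc$protein_of],
    uniprot = sprintf("P%05d", sc$protein_of),
    subcellular_class = cls,
    secretome_location = loc,
    secretome_function = fun,
    stringsAsFactors = FALSE)
  out$tissue_panels <- tissue
  out$immune_panels <- immune
  out$mito <- mito
  out$neutrophil_release <- neut
  class(out) <- c("aptamer_annotation", "data.frame")
  out
}

#' Inject displaced outlier samples
#'
#' Shifts `k` randomly chosen samples by `magnitude` on the log10 scale
#' across a random half of the aptamers; the displaced sample ids are
#' returned as ground truth for QC-recovery tests.
#'
#' @param matrix an [intensity_matrix()]
#' @param k number of samples to displace (`k = 0` returns the input)
#' @param magnitude log10-scale displacement, must be positive
#' @param seed integer seed
#' @return list with `matrix` and `outlier_ids`
#' @export
inject_outliers <- function(matrix, k, magnitude = 1.0, seed = 1L) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (magnitude <= 0) stop("magnitude must be positive")
  n <- nrow(matrix$values)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0) return(list(matrix = matrix, outlier_ids = character(0)))
  set.seed(as.integer(seed))
  ids <- sample(rownames(matrix$values), k)
  v <- matrix$values
  # each displaced sample gets its own random half of the aptamers
  for (id in ids) {
    cols <- sample(ncol(v), floor(ncol(v) / 2))
    v[id, cols] <- v[id, cols] * 10^magnitude
  }
  list(matrix = intensity_matrix(v, matrix$mask), outlier_ids = ids)
}

#' Generate a noisy cross-platform (immunoassay) replicate
#'
#' Per analyte, the protein-level consensus signal (mean log2 intensity over
#' the protein's aptamers) plus platform noise; a `flip_fraction` of analytes
#' get their ME-vs-HC group difference mirrored to plant discordance.
#'
#' @param matrix the aptamer [intensity_matrix()]
#' @param mapping data.frame with columns `analyte_id` and `aptamer_ids`
#'   (`;`-separated aptamer ids measuring the analyte's protein)
#' @param config a [generator_config()] (uses `platform_noise_sd`,
#'   `flip_fraction`, `seed`)
#' @param group optional ME/HC factor aligned to samples; required when
#'   `flip_fraction > 0`
#' @return list with `matrix` (immunoassay `intensity_matrix`, same sample
#'   ids) and `flipped_analytes`
#' @export
generate_cross_platform_replicate <- function(matrix, mapping, config,
                                              group = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"),
            inherits(config, "generator_config"))
  if (is.null(mapping) || nrow(mapping) == 0) stop("empty analyte mapping")
  set.seed(config$seed + 2L)
  lv <- log2_values(matrix)
  n <- nrow(lv)
  cons <- vapply(seq_len(nrow(mapping)), function(i) {
    apts <- strsplit(as.character(mapping$aptamer_ids[i]), ";",
                     fixed = TRUE)[[1]]
    apts <- intersect(apts, colnames(lv))
    if (length(apts) == 0)
      stop("mapping row ", i, " matches no aptamer columns")
    rowMeans(lv[, apts, drop = FALSE], na.rm = TRUE)
  }, numeric(n))
  if (n == 1L) cons <- matrix(cons, nrow = 1L)
  colnames(cons) <- as.character(mapping$analyte_id)
  rownames(cons) <- rownames(lv)
  flipped <- character(0)
  if (config$flip_fraction > 0) {
    if (is.null(group)) stop("`group` required when flip_fraction > 0")
    pick <- stats::runif(ncol(cons)) < config$flip_fraction
    flipped <- colnames(cons)[pick]
    gme <- group == "ME"
    for (a in flipped) {
      dlt <- mean(cons[gme, a]) - mean(cons[!gme, a])
      cons[gme, a] <- cons[gme, a] - 2 * dlt
    }
  }
  noise <- matrix(stats::rnorm(length(cons), 0, config$platform_noise_sd),
                  nrow(cons), ncol(cons))
  out <- 2^(cons + noise)
  meta_mask <- matrix("observed", nrow(out), ncol(out))
  list(matrix = intensity_matrix(out, meta_mask),
       flipped_analytes = flipped)
}
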