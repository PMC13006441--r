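#' serumscape: cross-system profiling of aptamer-based serum proteomics
#'
#' Case-control analysis of aptamer affinity-proteomics intensity matrices:
#' QC and outlier handling, duplicate-aptamer resolution, covariate-adjusted
#' moderated differential abundance, multivariate group tests, compartment and
#' tissue footprint statistics, correlation networks, and cross-platform
#' validation, plus a seeded synthetic-data generator.
#'
#' @keywords internal
"_PACKAGE"

# Recognized missing-value tokens in input tables (single documented
# convention; see the methods vignette).
.MISSING_TOKENS <- c("", "NA", "NaN")

.SUBCELLULAR_CLASSES <- c("intracellular", "membrane", "membrane_secreted",
                          "secreted", "unannotated")
.SECRETOME_LOCATIONS <- c("blood", "IC&M", "ECM", "GI_tract", "brain",
                          "male_RS", "female_RS", "other_tissues", "unknown",
                          "none")
.SECRETOME_FUNCTIONS <- c("CPP", "Enz", "HOR", "I&D", "INFL", "TR", "other",
                          "none")

#' Construct an intensity matrix
#'
#' The pipeline's central container: a samples-by-aptamers matrix of positive
#' intensities (relative fluorescence units) together with a per-cell status
#' mask distinguishing observed, masked (set to missing by QC or on input),
#' and imputed cells.
#'
#' @param values numeric matrix, samples in rows, aptamers in columns, with
#'   unique row and column names. Observed cells must be strictly positive.
#' @param mask character matrix of the same shape with entries in
#'   `c("observed", "masked", "imputed")`. Defaults to all-observed with
#'   non-finite cells masked.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `mask`.
#' @export
intensity_matrix <- function(values, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample (row) and aptamer (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate aptamer ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (is.null(mask)) {
    mask <- matrix("observed", nrow(values), ncol(values),
                   dimnames = dimnames(values))
    mask[!is.finite(values)] <- "masked"
  }
  if (!identical(dim(mask), dim(values)))
    stop("`mask` must have the same shape as `values`")
  if (!all(mask %in% c("observed", "masked", "imputed")))
    stop("mask entries must be observed/masked/imputed")
  dimnames(mask) <- dimnames(values)
  obs <- mask == "observed"
  bad <- which(obs & (!is.finite(values) | values <= 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive observed intensity at [%s, %s]",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  structure(list(values = values, mask = mask), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d samples x %d aptamers (%d masked, %d imputed)\n",
              nrow(x$values), ncol(x$values),
              sum(x$mask == "masked"), sum(x$mask == "imputed")))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by sample and/or aptamer ids
#'
#' @param x an [intensity_matrix()]
#' @param samples,aptamers character or integer indices; `NULL` keeps all.
#' @return the subsetted `intensity_matrix`
#' @export
subset_matrix <- function(x, samples = NULL, aptamers = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(samples)) samples <- rownames(x$values)
  if (is.null(aptamers)) aptamers <- colnames(x$values)
  intensity_matrix(x$values[samples, aptamers, drop = FALSE],
                   x$mask[samples, aptamers, drop = FALSE])
}

# Detect tab vs comma from the header line; explicit `dialect` wins.
.detect_sep <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") return("\t")
  if (dialect == "comma") return(",")
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

.read_table <- function(path, dialect = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, dialect)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = .MISSING_TOKENS, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Load a sample-by-aptamer intensity matrix from TSV/CSV
#'
#' Expects a header row of aptamer ids and sample ids in the first column
#' (samples in rows). Cells equal to `""`, `"NA"` or `"NaN"` become masked;
#' any other non-numeric cell is a hard error, as is a non-positive observed
#' value.
#'
#' @param path file path
#' @param dialect `"auto"` (default; tab vs comma sniffed from the header),
#'   `"tab"` or `"comma"`.
#' @return an [intensity_matrix()]
#' @export
load_intensity_matrix <- function(path, dialect = "auto") {
  df <- .read_table(path, dialect)
  if (ncol(df) < 2) stop("intensity table needs sample-id column plus data")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate aptamer ids in ", path)
  raw <- df[-1]
  num <- vapply(raw, function(col) {
    if (is.numeric(col)) as.numeric(col)
    else suppressWarnings(as.numeric(as.character(col)))
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  # anything that failed numeric conversion but was not a missing token
  for (j in seq_along(raw)) {
    if (is.numeric(raw[[j]])) next
    txt <- as.character(raw[[j]])
    bad <- which(!is.na(txt) & is.na(num[, j]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell at [%s, %s]: \"%s\"",
                   ids[bad[1]], names(raw)[j], txt[bad[1]]))
  }
  dimnames(num) <- list(ids, names(raw))
  bad <- which(!is.na(num) & num <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive observed intensity at [%s, %s]",
                 ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  intensity_matrix(num)
}

# split a ";"-separated membership cell into a character vector
.split_sets <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

.coerce_enum <- function(x, levels, fallback, what, warn_env) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- fallback
  bad <- !(x %in% levels)
  if (any(bad)) {
    warn_env$n <- warn_env$n + sum(bad)
    x[bad] <- fallback
  }
  x
}

#' Load an aptamer annotation table
#'
#' Reads per-aptamer identity (target name, gene symbol, UniProt) and the
#' panel/class memberships used by the footprint analyses. Set-valued columns
#' (`tissue_panels`, `immune_panels`) are `;`-separated. Unknown class tokens
#' map to `unannotated`/`none` with a single warning reporting the count.
#'
#' @param path file path to a TSV/CSV with an `aptamer_id` column; other
#'   recognized columns: `target_full_name`, `gene_symbol`, `uniprot`,
#'   `subcellular_class`, `tissue_panels`, `immune_panels`,
#'   `secretome_location`, `secretome_function`, `mito`,
#'   `neutrophil_release`. Missing columns are filled with empty defaults.
#' @param dialect see [load_intensity_matrix()]
#' @return a data.frame of class `aptamer_annotation` with list-columns for
#'   the panel sets and logical `mito`/`neutrophil_release`.
#' @export
load_annotations <- function(path, dialect = "auto") {
  df <- .read_table(path, dialect)
  if (!"aptamer_id" %in% names(df))
    stop("annotation table lacks an `aptamer_id` column")
  n <- nrow(df)
  get <- function(col, default) if (col %in% names(df)) df[[col]] else rep(default, n)
  warn_env <- new.env(); warn_env$n <- 0L
  out <- data.frame(
    aptamer_id = as.character(df$aptamer_id),
    target_full_name = as.character(get("target_full_name", NA_character_)),
    gene_symbol = as.character(get("gene_symbol", NA_character_)),
    uniprot = as.character(get("uniprot", NA_character_)),
    subcellular_class = .coerce_enum(get("subcellular_class", NA),
                                     .SUBCELLULAR_CLASSES, "unannotated",
                                     "subcellular_class", warn_env),
    secretome_location = .coerce_enum(get("secretome_location", NA),
                                      .SECRETOME_LOCATIONS, "none",
                                      "secretome_location", warn_env),
    secretome_function = .coerce_enum(get("secretome_function", NA),
                                      .SECRETOME_FUNCTIONS, "none",
                                      "secretome_function", warn_env),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$aptamer_id))
    stop("duplicate aptamer_id in annotation table")
  out$tissue_panels <- .split_sets(get("tissue_panels", ""))
  out$immune_panels <- .split_sets(get("immune_panels", ""))
  mito <- get("mito", FALSE)
  out$mito <- !is.na(mito) & (mito %in% c(TRUE, "TRUE", "true", "1", 1))
  neut <- get("neutrophil_release", FALSE)
  out$neutrophil_release <-
    !is.na(neut) & (neut %in% c(TRUE, "TRUE", "true", "1", 1))
  if (warn_env$n > 0)
    warning(sprintf("%d unrecognized class token(s) mapped to unannotated/none",
                    warn_env$n))
  class(out) <- c("aptamer_annotation", "data.frame")
  out
}

#' Load a sample metadata table
#'
#' @param path TSV/CSV with columns `sample_id`, `group` (`ME`/`HC`), `sex`,
#'   `age`, `bmi`, `fasting`; optional `metabotype`, `sf36pf`, `mean_steps`,
#'   `platform`.
#' @param dialect see [load_intensity_matrix()]
#' @return data.frame with one row per sample
#' @export
load_sample_metadata <- function(path, dialect = "auto") {
  df <- .read_table(path, dialect)
  need <- c("sample_id", "group", "sex", "age", "bmi", "fasting")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(paste(df$sample_id,
                          if ("platform" %in% names(df)) df$platform else "")))
    stop("duplicate sample_id in metadata")
  if (any(!is.na(df$age) & df$age <= 0)) stop("age must be positive")
  if (any(!is.na(df$bmi) & df$bmi <= 0)) stop("bmi must be positive")
  df$fasting <- df$fasting %in% c(TRUE, "TRUE", "true", "1", 1)
  if (!"platform" %in% names(df)) df$platform <- "aptamer"
  if (!"metabotype" %in% names(df)) df$metabotype <- NA_character_
  if (!"sf36pf" %in% names(df)) df$sf36pf <- NA_real_
  if (!"mean_steps" %in% names(df)) df$mean_steps <- NA_real_
  df
}

#' Write a result table (or intensity matrix) to TSV/CSV
#'
#' Deterministic column order, full float precision, UTF-8. List-columns
#' (panel sets) are serialized `;`-separated; an `intensity_matrix` is written
#' samples-in-rows with masked cells as `NA` (the mask itself can be saved
#' alongside via `mask_path`).
#'
#' @param records a data.frame of results or an [intensity_matrix()]
#' @param path output file path; extension `.csv` selects comma, else tab
#' @param mask_path optional path to also write the mask matrix (only for
#'   `intensity_matrix` input)
#' @return `path`, invisibly
#' @export
write_results_table <- function(records, path, mask_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (inherits(records, "intensity_matrix")) {
    vals <- records$values
    vals[records$mask == "masked"] <- NA_real_
    df <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_df(df, path, sep)
    if (!is.null(mask_path)) {
      mdf <- data.frame(sample_id = rownames(records$mask), records$mask,
                        check.names = FALSE, stringsAsFactors = FALSE)
      .write_df(mdf, mask_path, sep)
    }
    return(invisible(path))
  }
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ";"), "")
  }
  .write_df(df, path, sep)
  invisible(path)
}

.write_df <- function(df, path, sep) {
  # format numerics at full double precision (17 significant digits
  # round-trips exactly)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, "")
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
}

# log2-transformed copy of the observed/imputed values (masked cells NA)
log2_values <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  v[x$mask == "masked"] <- NA_real_
  log2(v)
}
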