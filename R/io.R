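#' Path to a packaged example data file
#'
#' The package ships small plain-text fixtures: `ccd_antioxidant.csv` (the published
#' 22-run composite-design antioxidant table), `dpph_inhibition.csv` (the
#' five mean inhibition points of the optimal extract) and
#' `hplc_anova_components.csv` (the published ANOVA sums of squares and degrees of
#' freedom of the chromatographic model).
#'
#' @param name File name; empty lists the available files.
#' @return Absolute path to the file.
#' @export
chemoextract_example <- function(name = "") {
  if (!nzchar(name))
    return(dir(system.file("extdata", package = "chemoextract")))
  p <- system.file("extdata", name, package = "chemoextract", mustWork = TRUE)
  p
}

read_csv_checked <- function(path, required, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(schema, " file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

check_numeric_cols <- function(df, cols, path, schema) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- is.na(num) & !is.na(v)
      if (any(bad))
        stop(schema, " file ", path, ": non-numeric value in column '", cl,
             "', row ", which(bad)[1L], call. = FALSE)
      df[[cl]] <- num
    }
    if (anyNA(df[[cl]]))
      stop(schema, " file ", path, ": missing value in column '", cl,
           "', row ", which(is.na(df[[cl]]))[1L], call. = FALSE)
  }
  df
}

#' Read a design table from CSV
#'
#' Expects columns `run_id`, one natural-unit column per factor, and
#' optionally `replicate_group`. Factor ranges come from the supplied
#' `factors` specs.
#'
#' @param path CSV path (a `#` header comment is allowed).
#' @param factors List of [factor_spec()] whose names match the columns.
#' @return A `doe_design`; runs sharing identical natural levels share a
#'   replicate group.
#' @export
read_design_csv <- function(path, factors) {
  factors <- check_factor_list(factors)
  fnames <- factor_names(factors)
  df <- read_csv_checked(path, c("run_id", fnames), "design")
  df <- check_numeric_cols(df, fnames, path, "design")
  if (anyDuplicated(df$run_id))
    stop("design file ", path, ": duplicate run_id '",
         df$run_id[duplicated(df$run_id)][1L], "'", call. = FALSE)
  design_from_levels(df[, fnames], factors, scale = "natural",
                     run_id = df$run_id)
}

#' Read a multiresponse table from CSV
#'
#' @param path CSV with a `run_id` column plus one numeric column per
#'   response.
#' @return Runs x responses numeric matrix with run ids as rownames.
#' @export
read_response_csv <- function(path) {
  df <- read_csv_checked(path, "run_id", "responses")
  if (anyDuplicated(df$run_id))
    stop("responses file ", path, ": duplicate run_id", call. = FALSE)
  resp <- setdiff(names(df), "run_id")
  if (length(resp) < 1L) stop("responses file ", path, ": no response columns",
                              call. = FALSE)
  df <- check_numeric_cols(df, resp, path, "responses")
  m <- as.matrix(df[, resp, drop = FALSE])
  rownames(m) <- df$run_id
  m
}

#' Read a wide spectra table from CSV
#'
#' @param path CSV with a `wavelength_nm` column plus one absorbance column
#'   per run.
#' @param design Optional `doe_design` supplying per-run factor labels (runs
#'   are matched by column name against `run_id`).
#' @return A `spectra_set` (factor labels empty when no design is given).
#' @export
read_spectra_csv <- function(path, design = NULL) {
  df <- read_csv_checked(path, "wavelength_nm", "spectra")
  runs <- setdiff(names(df), "wavelength_nm")
  df <- check_numeric_cols(df, c("wavelength_nm", runs), path, "spectra")
  X <- t(as.matrix(df[, runs, drop = FALSE]))
  if (!is.null(design)) {
    idx <- match(runs, design$runs$run_id)
    if (anyNA(idx))
      stop("spectra file ", path, ": run(s) absent from design: ",
           paste(runs[is.na(idx)], collapse = ", "), call. = FALSE)
    fct <- as.data.frame(natural_levels(design))[idx, , drop = FALSE]
    fct[] <- lapply(fct, as.character)
  } else {
    fct <- data.frame(run = runs, stringsAsFactors = FALSE)
  }
  rownames(X) <- runs
  spectra_set(df$wavelength_nm, X, fct)
}

#' Read DPPH absorbance records from CSV
#'
#' Long format: `concentration_mg_per_ml`, `t0`, `t1`, one row per replicate;
#' replicates at the same concentration are averaged before the inhibition
#' computation, and `t0` must be constant within a concentration.
#'
#' @param path CSV path.
#' @return Data frame with one row per concentration: `concentration`,
#'   `t0`, `t1_mean`, `n_replicates`, `inhibition_pct`.
#' @export
read_dpph_csv <- function(path) {
  req <- c("concentration_mg_per_ml", "t0", "t1")
  df <- read_csv_checked(path, req, "dpph")
  df <- check_numeric_cols(df, req, path, "dpph")
  sp <- split(df, df$concentration_mg_per_ml)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(concentration = d$concentration_mg_per_ml[1L],
               t0 = mean(d$t0), t1_mean = mean(d$t1),
               n_replicates = nrow(d))
  }))
  out$inhibition_pct <- inhibition_percent(out$t0, out$t1_mean)
  rownames(out) <- NULL
  out[order(out$concentration), ]
}

#' Write a result table as CSV with a provenance header
#'
#' Every file the pipeline writes starts with comment lines recording the
#' package version, a hash of the configuration, and the seeds used, so any
#' output can be traced back to its run.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Named list folded into the header comment (e.g. seeds).
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, meta = list()) {
  hdr <- c(paste0("# chemoextract ",
                  as.character(utils::packageVersion("chemoextract"))),
           sprintf("# %s: %s", names(meta),
                   vapply(meta, function(v) paste(format(v), collapse = ","), "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The published 22-run composite-design antioxidant table
#'
#' Convenience loader for the packaged fixture: the face-centered composite
#' design actually run (22 rows after replication at six vertices and the
#' center), with the absorbance-drop response.
#'
#' @return List with `design` (a `doe_design` over the widened factor
#'   ranges) and `response` (named vector Y).
#' @export
load_ccd_table <- function() {
  path <- chemoextract_example("ccd_antioxidant.csv")
  factors <- chamomile_factors("ccd")
  d <- read_design_csv(path, factors)
  df <- utils::read.csv(path, comment.char = "#")
  list(design = d, response = stats::setNames(df$Y, df$run_id))
}
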