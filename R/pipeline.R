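#' Run the chemometric workflow from a configuration
#'
#' Config-driven orchestration of the three analysis chains: multiresponse
#' table -> PC1 composite response -> response-surface model with ANOVA and
#' optimum; spectra -> SNV -> ASCA with permutation/bootstrap significance;
#' DPPH records -> calibration line and IC50. Stages run only when their
#' inputs are configured; every stage's parameters and seeds are logged into
#' the output files and the JSON summary.
#'
#' Configuration keys (a YAML/JSON file path or an equivalent nested list):
#' \describe{
#'   \item{output_dir}{Directory for result files (created if needed).}
#'   \item{factors}{List of `name`/`low`/`high`/`unit` entries.}
#'   \item{design}{Path to the design CSV.}
#'   \item{responses}{Path to the multiresponse CSV (enables the PC1+RSM
#'     chain). A `response` column name in the design file may be used
#'     instead via `response_column`.}
#'   \item{spectra}{Path to the wide spectra CSV (enables the ASCA chain).}
#'   \item{dpph}{Path to the DPPH CSV (enables the IC50 chain).}
#'   \item{alpha, grid_step, wavelength_window, n_perm, n_boot, seed}{Stage
#'     parameters; defaults 0.05, 0.05, c(220, 400), 999, 1000, 1.}
#' }
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @return Invisibly, a list with the fitted objects and the summary that was
#'   written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || !length(config))
    stop("usage: run_pipeline(<config list or file>) with at least one input stage",
         call. = FALSE)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  grid_step <- config$grid_step %||% 0.05
  n_perm <- config$n_perm %||% 999L
  n_boot <- config$n_boot %||% 1000L
  seed <- config$seed %||% 1L
  window <- config$wavelength_window %||% c(220, 400)
  meta <- list(seed = seed, alpha = alpha,
               config_hash = config_digest(config))
  summary <- list(seed = seed)
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  needs_design <- !is.null(config$responses) || !is.null(config$dpph_design) ||
    !is.null(config$spectra) || !is.null(config$response_column)
  design <- NULL
  if (!is.null(config$design)) {
    design <- stage("design", {
      if (is.null(config$factors)) stop("config$factors is required")
      factors <- lapply(config$factors, function(f)
        factor_spec(f$name, f$low, f$high, f$unit %||% ""))
      read_design_csv(config$design, factors)
    })
    summary$n_runs <- nrow(design$coded)
  } else if (needs_design) {
    stop("stage 'design' failed: a design file is required", call. = FALSE)
  }

  response <- NULL
  if (!is.null(config$responses)) {
    response <- stage("pc1", {
      areas <- read_response_csv(config$responses)
      areas <- areas[design$runs$run_id, , drop = FALSE]
      pca <- pca_model(autoscale(areas))
      write_output_csv(data.frame(run_id = rownames(pca$scores),
                                  round(pca$scores, 6)),
                       file.path(out_dir, "pc1_scores.csv"), meta)
      write_output_csv(data.frame(response = rownames(pca$loadings),
                                  round(pca$loadings, 6)),
                       file.path(out_dir, "pc1_loadings.csv"), meta)
      summary$pc1_variance_pct <- pca$explained_variance_pct[1L]
      pc1_response(pca)
    })
  } else if (!is.null(config$response_column)) {
    response <- stage("response", {
      df <- utils::read.csv(config$design, comment.char = "#")
      stats::setNames(df[[config$response_column]], df$run_id)
    })
  }

  if (!is.null(response)) {
    stage("rsm", {
      fit <- fit_quadratic(design, response)
      red <- reduce_hierarchical(fit, alpha = alpha)
      an <- anova_lack_of_fit(red)
      opt <- optimize_response(red, grid_step = grid_step)
      write_output_csv(red$tests, file.path(out_dir, "coefficients.csv"), meta)
      an_df <- data.frame(origin = rownames(an), as.data.frame(an))
      write_output_csv(an_df, file.path(out_dir, "anova.csv"), meta)
      write_output_csv(opt$grid, file.path(out_dir, "surface.csv"), meta)
      summary$model_terms <- red$terms
      summary$eliminated_terms <- red$eliminated
      summary$adj_r_squared_pct <- 100 * attr(an, "adj_r_squared")
      summary$optimum <- as.list(opt$optimum_natural)
      summary$optimum_predicted <- opt$value
      results$model <- red
    })
  }

  if (!is.null(config$spectra)) {
    stage("asca", {
      sp <- read_spectra_csv(config$spectra, design)
      sp <- crop_spectra(sp, window[1], window[2])
      sp <- snv(sp)
      dec <- asca_decompose(sp)
      perm <- lapply(stats::setNames(nm = dec$terms), function(tm)
        permutation_test(sp, tm, n_perm = n_perm, seed = seed)$p)
      boot <- lapply(stats::setNames(nm = dec$terms), function(tm)
        bootstrap_loadings(sp, tm, component = 1L, n_boot = n_boot,
                           seed = seed))
      for (tm in dec$terms)
        write_output_csv(boot[[tm]],
                         file.path(out_dir, paste0("asca_loadings_", tm, ".csv")),
                         c(meta, list(n_boot = n_boot)))
      write_output_csv(
        data.frame(term = dec$terms,
                   variance_pct = unname(dec$effect_variance_pct),
                   permutation_p = unlist(perm)),
        file.path(out_dir, "asca_effects.csv"), c(meta, list(n_perm = n_perm)))
      summary$asca_variance_pct <- as.list(dec$effect_variance_pct)
      summary$asca_permutation_p <- perm
      results$asca <- dec
    })
  }

  if (!is.null(config$dpph)) {
    stage("dpph", {
      rec <- read_dpph_csv(config$dpph)
      cal <- fit_inhibition_line(rec$concentration, rec$inhibition_pct)
      write_output_csv(
        data.frame(slope = cal$slope, intercept = cal$intercept,
                   r_squared = cal$r_squared, ic50 = cal$ic50,
                   ic50_se = cal$ic50_se),
        file.path(out_dir, "ic50.csv"), meta)
      summary$ic50 <- cal$ic50
      summary$ic50_se <- cal$ic50_se
      summary$dpph_r_squared <- cal$r_squared
      results$dpph <- cal
    })
  }

  if (is.null(response) && is.null(config$spectra) && is.null(config$dpph))
    stop("usage: config enables no stage (responses/spectra/dpph all absent)",
         call. = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(summary = summary)))
}

config_digest <- function(config) {
  s <- paste(deparse(config), collapse = "")
  # small rolling hash; enough to tie outputs to a configuration
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}
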