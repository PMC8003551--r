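#' Run the full modelling-and-optimization pipeline
#'
#' Sequences the whole analysis on one designed experiment: full quadratic
#' fits with per-term ANOVA for every response, significance-based model
#' reduction with natural-unit equations, MLP surrogates, the
#' RSM/reduced-RSM/ANN comparison table, desirability optimization, and
#' (when a chemometric panel is supplied) the Pearson correlation matrix.
#' All tabular results are written as CSV next to a resolved-configuration
#' file and a run log.
#'
#' @param design A `design_table` or path to a design CSV (then `factors`
#'   is required).
#' @param outdir Output directory (created if needed).
#' @param factors Factor list when `design` is a path.
#' @param responses Response columns to model (default: all in the design).
#' @param alpha Reduction significance level.
#' @param seed Seed for the ANN stage.
#' @param ann_restarts Restarts per ANN (default 25; raise for final runs).
#' @param resolution Desirability grid resolution.
#' @param panel Optional samples x variables data frame for the correlation
#'   stage (e.g. [extract_panel()]).
#' @return Invisibly, a list with the fitted objects and the paths written.
#' @examples
#' \donttest{
#' out <- run_extraction_pipeline(coffee_husk_design(), tempdir(),
#'                                ann_restarts = 5)
#' }
#' @export
run_extraction_pipeline <- function(design, outdir, factors = NULL,
                                    responses = NULL, alpha = 0.05,
                                    seed = 1, ann_restarts = 25,
                                    resolution = 21, panel = NULL) {
  if (is.character(design)) {
    if (is.null(factors))
      stop("'factors' is required when 'design' is a file path",
           call. = FALSE)
    design <- read_design(design, factors)
  }
  stopifnot(inherits(design, "design_table"))
  if (is.null(responses)) responses <- design_responses(design)
  if (!length(responses)) stop("design has no response columns",
                               call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, file) {
    path <- file.path(outdir, file)
    utils::write.csv(df, path, row.names = FALSE)
    paths[[file]] <<- path
    path
  }
  log_lines <- c(sprintf("%s pipeline start", format(Sys.time(),
                                                     "%Y-%m-%dT%H:%M:%S")),
                 sprintf("R %s, rsmopt %s", getRversion(),
                         as.character(utils::packageVersion("rsmopt"))),
                 sprintf("runs=%d responses=%s alpha=%g seed=%d restarts=%d",
                         nrow(design), paste(responses, collapse = ","),
                         alpha, seed, ann_restarts))

  full <- lapply(responses, function(r) rsm_quad(design, r))
  names(full) <- responses
  reduced <- lapply(full, reduce_model, alpha = alpha)

  anova_rows <- do.call(rbind, lapply(responses, function(r) {
    a <- anova(full[[r]])
    beta <- coef(full[[r]])
    a$beta <- beta[match(a$term, names(beta))]
    cbind(response = r, as.data.frame(a))
  }))
  put(anova_rows, "anova_full_models.csv")

  red_rows <- do.call(rbind, lapply(responses, function(r) {
    m <- reduced[[r]]
    nc <- natural_coef(m)
    data.frame(response = r, term = names(nc), coefficient = unname(nc),
               r2 = m$r2, f_value = m$f_value, p_value = m$p_value,
               stringsAsFactors = FALSE)
  }))
  put(red_rows, "reduced_models_natural.csv")

  set.seed(seed)
  anns <- lapply(responses, function(r)
    mlp_surrogate(design, r, restarts = ann_restarts, seed = seed))
  names(anns) <- responses

  put(comparison_table(design,
                       list(RSM = full, RSM_ST = reduced, ANN = anns)),
      "model_comparison.csv")

  opt <- maximize_desirability(full, design, resolution = resolution)
  put(cbind(optimum = rownames(opt$optima), opt$optima),
      "desirability_optima.csv")

  conditions <- opt$optima[names(design_factors(design))]
  pred_rows <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    pt <- conditions[i, , drop = FALSE]
    do.call(rbind, lapply(responses, function(r) {
      pr <- predict(full[[r]], pt)
      pa <- predict(anns[[r]], pt)
      data.frame(optimum = i, response = r, predicted_rsm = pr,
                 predicted_ann = pa, cv_rsm_ann = cv_percent(pr, pa),
                 stringsAsFactors = FALSE)
    }))
  }))
  put(pred_rows, "predictions_at_optima.csv")

  if (!is.null(panel)) {
    pm <- pearson_matrix(panel)
    put(data.frame(variable = rownames(pm$r), pm$r, check.names = FALSE),
        "correlation_matrix.csv")
  }

  cfg <- c(sprintf("alpha: %g", alpha), sprintf("seed: %d", seed),
           sprintf("ann_restarts: %d", ann_restarts),
           sprintf("resolution: %d", resolution),
           sprintf("responses: %s", paste(responses, collapse = ", ")))
  writeLines(cfg, file.path(outdir, "pipeline_config.txt"))
  log_lines <- c(log_lines,
                 sprintf("%s pipeline done: %d artifacts",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                         length(paths)))
  writeLines(log_lines, file.path(outdir, "pipeline_log.txt"))
  invisible(list(full = full, reduced = reduced, ann = anns,
                 optimization = opt, paths = paths))
}
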