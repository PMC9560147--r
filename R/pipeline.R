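#' Pipeline configuration
#'
#' Assembles and validates the configuration for a full analysis run:
#' task geometry, solver options, capacity grid, synthetic cohort, and
#' fitting choices. Every field has a default; the resolved configuration
#' is written beside the outputs of \code{\link{run_pipeline}}.
#'
#' @param geometry \code{"default"}, \code{"mini"}, \code{"reduced"}, or a
#'   \code{panel_geometry} object.
#' @param beta1_values,beta2_values capacity grids for
#'   \code{\link{capacity_grid}}.
#' @param solver a \code{\link{solver_options}} list.
#' @param n_subjects cohort size (default 19, the study's cohort).
#' @param true_hypothesis ground-truth hypothesis of the generated cohort,
#'   or \code{"mixed"} to alternate.
#' @param alpha0,alpha1,alpha2 generative regression coefficients.
#' @param link generative and fitted link function.
#' @param noise_fraction residual SD as a fraction of the across-condition
#'   spread of each subject's noiseless betas (default 0.25, the stated
#'   recovery noise level).
#' @param n_trials behavioural trials per subject.
#' @param fit_links links fitted during model comparison.
#' @param n_shuffles shuffle count for the behaviour correlation.
#' @param seed global seed; all per-subject seeds derive from it.
#' @param output_dir where \code{run_pipeline} writes its files.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(geometry = "reduced",
                            beta1_values = c(2, 20, 500),
                            beta2_values = c(2, 20, 500),
                            solver = solver_options(),
                            n_subjects = 19L,
                            true_hypothesis = "H1_prospective",
                            alpha0 = 0.2, alpha1 = 0.5, alpha2 = 0.1,
                            link = "linear",
                            noise_fraction = 0.25,
                            n_trials = 120L,
                            fit_links = "linear",
                            n_shuffles = 1000L,
                            seed = 1L,
                            output_dir = tempfile("planinfo_run")) {
  if (is.character(geometry))
    geometry <- match.arg(geometry, c("default", "mini", "reduced"))
  else stopifnot(inherits(geometry, "panel_geometry"))
  stopifnot(noise_fraction >= 0, n_subjects >= 1)
  if (!true_hypothesis %in% c(hypotheses, "mixed"))
    stop("unknown hypothesis: ", true_hypothesis)
  structure(list(geometry = geometry,
                 beta1_values = beta1_values, beta2_values = beta2_values,
                 solver = solver, n_subjects = as.integer(n_subjects),
                 true_hypothesis = true_hypothesis,
                 alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 link = link, noise_fraction = noise_fraction,
                 n_trials = as.integer(n_trials),
                 fit_links = fit_links, n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Small end-to-end configuration for smoke tests
#' @param output_dir run directory.
#' @param seed global seed.
#' @return a \code{pipeline_config} on the reduced task with a 2x2 grid and
#'   5 subjects.
#' @export
smoke_config <- function(output_dir = tempfile("planinfo_smoke"), seed = 1L)
  pipeline_config(geometry = "reduced",
                  beta1_values = c(20, 500), beta2_values = c(20, 500),
                  n_subjects = 5L, n_shuffles = 200L,
                  seed = seed, output_dir = output_dir)

resolve_geometry <- function(g) {
  if (inherits(g, "panel_geometry")) return(g)
  switch(g, default = default_geometry(), mini = mini_geometry(),
         reduced = reduced_geometry())
}

#' Run the full analysis pipeline
#'
#' Executes: task build, capacity-grid solve, synthetic-cohort generation,
#' per-subject grid-search fitting under both hypotheses, group comparison
#' of R2 and LOOCV error, and the behaviour correlation. All tabular
#' outputs are written as CSV, summaries as JSON, together with a run
#' manifest listing content hashes; identical configuration and seed
#' reproduce identical files.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the run manifest and all in-memory
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  task <- stage("task_build", build_task(resolve_geometry(config$geometry)))
  grid <- stage("grid_solve",
                capacity_grid(task, config$beta1_values, config$beta2_values,
                              opts = config$solver))

  cohort <- stage("cohort_synthesis", {
    hyp <- if (config$true_hypothesis == "mixed")
      rep(hypotheses, length.out = config$n_subjects)
    else rep(config$true_hypothesis, config$n_subjects)
    bmax1 <- max(config$beta1_values); bmax2 <- max(config$beta2_values)
    specs <- lapply(seq_len(config$n_subjects), function(i) {
      sp <- subject_spec(sprintf("sub-%02d", i), hypothesis = hyp[i],
                         beta1 = bmax1, beta2 = bmax2,
                         alpha0 = config$alpha0, alpha1 = config$alpha1,
                         alpha2 = config$alpha2, link = config$link,
                         noise_sd = 0, n_trials = config$n_trials,
                         seed = config$seed * 10000L + i)
      sp$noise_sd <- config$noise_fraction * noiseless_spread(sp, grid)
      sp
    })
    generate_cohort(specs, grid)
  })

  fits <- stage("fitting", {
    rows <- list()
    for (s in cohort$subjects) for (h in hypotheses)
      for (lk in config$fit_links) {
        gf <- grid_search_fit(s, grid, h, lk)
        prof_b <- grid_profile(grid, h, gf$best$beta1, gf$best$beta2)
        nt <- nested_f_test(s, prof_b, lk)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, hypothesis = h, link = lk,
          beta1 = gf$best$beta1, beta2 = gf$best$beta2,
          alpha0 = gf$best$alpha0, alpha1 = gf$best$alpha1,
          alpha2 = gf$best$alpha2,
          R2 = gf$best$R2, RSS = gf$best$RSS,
          F_nested = nt$F, p_nested = nt$p,
          loocv_mse = loocv_information_fit(s, prof_b, lk),
          R2_not_bounded = gf$not_bounded$R2,
          EU_best = attr(prof_b, "EU"),
          error_rate = s$error_rate)
      }
    do.call(rbind, rows)
  })

  comparisons <- stage("group_comparison", {
    lk <- config$fit_links[1]
    f1 <- fits[fits$hypothesis == "H1_prospective" & fits$link == lk, ]
    f0 <- fits[fits$hypothesis == "H0_delayed" & fits$link == lk, ]
    list(
      R2_H1_vs_H0 = compare_group(f1$R2, f0$R2, "paired_rmANOVA"),
      R2_H1_vs_H0_wilcoxon = compare_group(f1$R2, f0$R2,
                                           "wilcoxon_signrank"),
      loocv_H1_vs_H0 = compare_group(f0$loocv_mse, f1$loocv_mse,
                                     "paired_rmANOVA"),
      R2_bounded_vs_not = compare_group(f1$R2, f1$R2_not_bounded,
                                        "paired_rmANOVA"))
  })

  behavior <- stage("behavior_correlation", {
    lk <- config$fit_links[1]
    f1 <- fits[fits$hypothesis == "H1_prospective" & fits$link == lk, ]
    if (stats::sd(f1$EU_best) == 0 || stats::sd(f1$error_rate) == 0) NULL
    else behavior_correlation(f1$EU_best, f1$error_rate,
                              n_shuffles = config$n_shuffles,
                              seed = config$seed)
  })

  stage("write_outputs", {
    utils::write.csv(grid$summary, file.path(out, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cohort), file.path(out, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$manifest, file.path(out, "cohort_manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(comparisons, unclass),
      file.path(out, "group_comparisons.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      if (is.null(behavior)) list() else unclass(behavior),
      file.path(out, "behavior.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    cfg <- config
    cfg$solver <- unclass(cfg$solver)
    if (inherits(cfg$geometry, "panel_geometry"))
      cfg$geometry <- list(n_panels = cfg$geometry$n_panels,
                           offsets = cfg$geometry$offsets)
    jsonlite::write_json(unclass(cfg),
                         file.path(out, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  files <- sort(setdiff(list.files(out), "run_manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))))
  jsonlite::write_json(list(seed = config$seed, files = manifest),
                       file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(manifest = manifest, task = task, grid = grid,
                 cohort = cohort, fits = fits, comparisons = comparisons,
                 behavior = behavior, output_dir = out))
}
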