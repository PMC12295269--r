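#' Assemble (or load) a pipeline configuration
#'
#' A configuration names the cohort source — either `input` paths
#' (abundance + metadata CSV and family-map CSV in the package dialect,
#' see [read_cohort()]) or a `synthetic` block forwarded to
#' [synthetic_spec()] — plus preprocessing thresholds, concomitant
#' overrides, per-k search settings, an output directory and the seed that
#' feeds every source of randomness. Validation is fail-fast: referenced
#' paths must exist before any computation starts.
#'
#' @param config a list, or the path of a YAML file holding one
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("pipeline_config: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    preprocessing = list(exclude_samples = character(0),
                         max_missing_frac = 0.2, sd_mult = 3,
                         max_outlier_frac = 0.10, scale = "log10"),
    concomitant_overrides = NULL,
    contrast_scope = "per_family",
    search = list(list(k = 4, threshold = 0.58, min_accuracy = 0,
                       top_n = 10, loocv = FALSE)),
    output_dir = "results", seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  pp <- defaults$preprocessing
  pp[names(config$preprocessing)] <- config$preprocessing
  config$preprocessing <- pp
  has_input <- !is.null(config$input)
  has_syn <- !is.null(config$synthetic)
  if (!has_input && !has_syn) {
    stop("pipeline_config: provide either 'input' paths or a 'synthetic' block")
  }
  if (has_input) {
    for (p in c(config$input$data_csv, config$input$family_csv)) {
      if (is.null(p) || !file.exists(p)) {
        stop("pipeline_config: input file missing or not found: ",
             if (is.null(p)) "(unset)" else p)
      }
    }
  }
  structure(config, class = "pipeline_config")
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the whole analysis pipeline
#'
#' Stages in order: cohort acquisition (synthetic generation or CSV
#' input), cleaning filters, concomitant scoring and selection, both
#' residual variants, group contrasts and per-family residual
#' correlations, and the configured panel searches. Every artifact is a
#' text file (CSV/JSON/YAML) under `output_dir`, listed with its MD5 hash
#' in `manifest.json`; a rerun with the same configuration and seed
#' reproduces identical artifacts. Per-stage timings go to a separate
#' `run_log.json` so the manifest itself is reproducible.
#'
#' @param config a [pipeline_config()] (or a list / YAML path for one)
#' @return invisibly, a list with `status` (0 on success), `manifest`
#'   and the in-memory stage results
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  artifacts <- character(0)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  # --- cohort ---------------------------------------------------------
  coh <- clock("cohort", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      if (is.null(args$families)) args$families <- study_like_families()
      spec <- do.call(synthetic_spec, args)
      x <- generate_cohort(spec)
      write_cohort(x, out("cohort.csv"), out("family_map.csv"))
      write_spec(spec, out("synthetic_spec.yaml"))
      artifacts <- c(artifacts, out(c("cohort.csv", "family_map.csv",
                                      "synthetic_spec.yaml")))
      x
    } else {
      read_cohort(config$input$data_csv, config$input$family_csv)
    }
  })

  # --- preprocessing --------------------------------------------------
  pp <- config$preprocessing
  clean <- clock("preprocess", preprocess_cohort(
    coh, names = pp$exclude_samples, max_missing_frac = pp$max_missing_frac,
    sd_mult = pp$sd_mult, max_outlier_frac = pp$max_outlier_frac,
    scale = pp$scale))
  write_filter_report(clean$reports, out("filter_report.json"))
  artifacts <- c(artifacts, out("filter_report.json"))

  # --- normalization --------------------------------------------------
  norm <- clock("normalize", {
    fams <- unique(clean$cohort$family_map)
    scorable <- fams[vapply(fams, function(f)
      length(family_members(clean$cohort, f)) >= 3, TRUE)]
    scores <- lapply(scorable, function(f) score_concomitants(clean$cohort, f))
    names(scores) <- scorable
    conc <- select_concomitants(scores, overrides = config$concomitant_overrides)
    list(scores = scores, concomitants = conc,
         report = concomitant_report(scores, conc),
         res_wg = compute_residuals(clean$cohort, conc, include_group = TRUE),
         res_ng = compute_residuals(clean$cohort, conc, include_group = FALSE))
  })
  utils::write.csv(do.call(rbind, norm$scores), out("concomitant_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(norm$report, out("concomitant_report.csv"), row.names = FALSE)
  utils::write.csv(norm$res_ng$residuals, out("residuals_without_group.csv"))
  utils::write.csv(norm$res_wg$residuals, out("residuals_with_group.csv"))
  artifacts <- c(artifacts, out(c("concomitant_scores.csv", "concomitant_report.csv",
                                  "residuals_without_group.csv",
                                  "residuals_with_group.csv")))

  # --- contrasts + correlations ---------------------------------------
  contr <- clock("contrast", group_contrasts(
    clean$cohort, norm$concomitants, scope = config$contrast_scope))
  utils::write.csv(contr, out("group_contrasts.csv"), row.names = FALSE)
  artifacts <- c(artifacts, out("group_contrasts.csv"))
  for (f in unique(norm$res_wg$family_map)) {
    cols <- sum(norm$res_wg$family_map == f)
    if (cols < 2) next
    cm <- residual_correlations(norm$res_wg, f)
    fn <- out(paste0("correlations_", gsub("[^A-Za-z0-9]+", "_", f), ".csv"))
    utils::write.csv(cm$r, fn)
    artifacts <- c(artifacts, fn)
  }

  # --- panel search ---------------------------------------------------
  searches <- clock("search", lapply(config$search, function(sc) {
    res <- search_panels(
      norm$res_ng, k = sc$k, candidates = sc$candidates,
      threshold = if (is.null(sc$threshold)) 0.58 else sc$threshold,
      min_accuracy = if (is.null(sc$min_accuracy)) 0 else sc$min_accuracy,
      top_n = if (is.null(sc$top_n)) 10 else sc$top_n,
      loocv = isTRUE(sc$loocv))
    fn <- out(sprintf("panels_k%d%s.csv", sc$k,
                      if (isTRUE(sc$loocv)) "_loocv" else ""))
    utils::write.csv(
      cbind(format_panel_table(res, norm$res_ng$family_map, contr)),
      fn, row.names = FALSE)
    artifacts <<- c(artifacts, fn)
    res
  }))

  # --- manifest + run log ---------------------------------------------
  manifest <- list(
    package = "metabolda",
    version = as.character(utils::packageVersion("metabolda")),
    seed = config$seed,
    config_hash = unname(md5_of_text(jsonlite::toJSON(
      unclass(config), auto_unbox = TRUE, null = "null", force = TRUE))),
    artifacts = as.list(md5_of(artifacts))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  jsonlite::write_json(timings, out("run_log.json"), auto_unbox = TRUE)

  invisible(list(status = 0L, manifest = manifest, cohort = clean$cohort,
                 reports = clean$reports, normalization = norm,
                 contrasts = contr, searches = searches))
}

md5_of_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}
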