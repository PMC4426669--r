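# Known configuration keys per section, with defaults. The config file
# is a flat "key: value" format with [section] headers; unknown
# sections or keys are rejected before any stage runs.
.config_defaults <- function() {
  list(
    run = list(stages = c("screen", "cofractionation", "kinetics",
                          "dose_response"),
               outdir = "isribtools_run", seed = 0),
    screen = list(preset = "demo", n_genes = 500, depth = 1e6,
                  dispersion = 0, cells_per_shrna = 100,
                  pseudocount = 0.5, tau_sel = 3, tau_base = 2),
    cofractionation = list(preset = "dimer", noise_cv = 0.2,
                           window = 6:9, reference = "eIF2B4"),
    kinetics = list(presets = c("gef_basal", "gef_isrib"),
                    model = "three_param", noise_sd = 0.02),
    dose_response = list(presets = c("A1", "A17"))
  )
}

parse_config_value <- function(x) {
  parts <- trimws(strsplit(x, ",")[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) num else parts
}

#' Read a pipeline run configuration
#'
#' Flat `key: value` text format with `[section]` headers; `#` starts a
#' comment; list values are comma-separated. Every key must belong to
#' the known-key registry (unknown keys are rejected), and every
#' stochastic stage inherits the run seed unless overridden.
#'
#' @param path config file path.
#' @return a validated `run_config` (nested list).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl(":", ln, fixed = TRUE)) stopf("malformed config line: %s", ln)
    if (is.null(section)) stopf("key outside any [section]: %s", ln)
    kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1]]
    cfg[[section]][[trimws(kv[1])]] <- parse_config_value(kv[2])
  }
  run_config(cfg)
}

#' Build and validate a run configuration
#'
#' @param config nested list of sections (see [read_run_config()] for
#'   the file form); missing keys take defaults.
#' @return a `run_config` object.
#' @export
run_config <- function(config = list()) {
  defaults <- .config_defaults()
  bad_sec <- setdiff(names(config), names(defaults))
  if (length(bad_sec)) {
    stopf("unknown config section(s): %s", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      stopf("unknown key(s) in [%s]: %s", sec, paste(bad, collapse = ", "))
    }
  }
  cfg <- defaults
  for (sec in names(config)) {
    cfg[[sec]] <- modifyList(cfg[[sec]], config[[sec]])
  }
  bad_stage <- setdiff(cfg$run$stages, names(defaults)[-1])
  if (length(bad_stage)) {
    stopf("unknown stage(s): %s", paste(bad_stage, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the full target-identification pipeline
#'
#' Executes the selected stages in order — screen scoring,
#' co-fractionation, kinetics, dose-response — on synthetic inputs
#' generated from the configured presets, writing every intermediate
#' table and a JSON run report under the configured output directory.
#' Deterministic for a fixed configuration (modulo the report's
#' timestamp field). A stage failure aborts the run naming the stage;
#' tables already written are retained.
#'
#' @param config a `run_config` (or a nested list accepted by
#'   [run_config()]).
#' @return the run report (nested list), invisibly; also written to
#'   `<outdir>/run_report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  outdir <- config$run$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$run$seed
  report <- list(package_version = as.character(packageVersion("isribtools")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 config = unclass(config), stages = list())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  for (stage in config$run$stages) {
    report$stages[[stage]] <- switch(
      stage,
      screen = run_stage("screen", function()
        pipeline_screen(config$screen, seed, outdir)),
      cofractionation = run_stage("cofractionation", function()
        pipeline_cofrac(config$cofractionation, seed, outdir)),
      kinetics = run_stage("kinetics", function()
        pipeline_kinetics(config$kinetics, seed, outdir)),
      dose_response = run_stage("dose_response", function()
        pipeline_dose(config$dose_response, seed, outdir)))
  }
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

pipeline_screen <- function(cfg, seed, outdir) {
  design <- if (identical(cfg$preset, "demo")) {
    demo_screen_design(n_genes = cfg$n_genes)
  } else {
    null_screen_design(n_genes = cfg$n_genes)
  }
  lib <- generate_library(design, seed = seed)
  counts <- simulate_sorted_screen(lib, design, depth = cfg$depth,
                                   dispersion = cfg$dispersion,
                                   cells_per_shrna = cfg$cells_per_shrna,
                                   seed = seed + 1)
  write_table(counts, file.path(outdir, "bin_counts.tsv"), "bin_counts")
  eps <- compute_epsilon(compute_frequencies(counts, cfg$pseudocount), lib)
  scores <- gene_pvalues(eps, lib)
  write_result_tsv(scores, file.path(outdir, "gene_scores.tsv"))
  conds <- design$conditions
  calls <- classify_modifiers(scores[scores$condition == conds[1], ],
                              scores[scores$condition == conds[2], ],
                              tau_sel = cfg$tau_sel, tau_base = cfg$tau_base)
  write_result_tsv(calls, file.path(outdir, "modifier_calls.tsv"))
  hits <- calls[calls$class != "none", ]
  list(seed = seed, params = cfg,
       n_shrnas = nrow(lib), n_genes = design$n_genes,
       calls = split(hits$gene_id, hits$class))
}

pipeline_cofrac <- function(cfg, seed, outdir) {
  design <- dimer_gradient_design(noise_cv = cfg$noise_cv)
  tab_ctrl <- simulate_gradient(design, "ctrl", seed = seed)
  tab_drug <- simulate_gradient(design, "drug", seed = seed)
  write_table(tab_ctrl, file.path(outdir, "gradient_ctrl.tsv"),
              "fraction_intensity")
  write_table(tab_drug, file.path(outdir, "gradient_drug.tsv"),
              "fraction_intensity")
  win <- cfg$window
  prof_ctrl <- normalize_profiles(tab_ctrl, window = win)
  prof_drug <- normalize_profiles(tab_drug, window = win)
  corr <- correlate_to_reference(prof_drug, cfg$reference)
  write_result_tsv(corr, file.path(outdir, "correlation.tsv"))
  shift <- detect_shift(prof_ctrl, prof_drug)
  write_result_tsv(shift, file.path(outdir, "shift.tsv"))
  list(seed = seed, params = cfg,
       top_correlated = corr$protein_id[corr$R > 0.98 & !is.na(corr$R)],
       max_shift = shift$protein_id[which.max(shift$delta)])
}

pipeline_kinetics <- function(cfg, seed, outdir) {
  fits <- lapply(cfg$presets, function(p) {
    preset <- decay_preset(p, noise_sd = cfg$noise_sd)
    d <- simulate_decay(preset, seed = seed)
    write_table(d, file.path(outdir, sprintf("decay_%s.tsv", p)), "decay")
    fit <- fit_decay(d, model = cfg$model)
    list(preset = p, k = fit$k, t_half = fit$t_half,
         plateau = fit$plateau, converged = fit$converged)
  })
  names(fits) <- cfg$presets
  out <- list(seed = seed, params = cfg, fits = fits)
  if (all(c("gef_basal", "gef_isrib") %in% cfg$presets)) {
    out$fold_acceleration <-
      fits$gef_basal$t_half / fits$gef_isrib$t_half
  }
  write_result_tsv(
    data.frame(preset = cfg$presets,
               k = vapply(fits, `[[`, numeric(1), "k"),
               t_half = vapply(fits, `[[`, numeric(1), "t_half")),
    file.path(outdir, "kinetic_fits.tsv"))
  out
}

pipeline_dose <- function(cfg, seed, outdir) {
  fits <- lapply(cfg$presets, function(a) {
    d <- simulate_dose_response(dose_preset(a), seed = seed)
    write_table(d, file.path(outdir, sprintf("dose_%s.tsv", a)),
                "dose_response")
    fit <- fit_4pl(d)
    list(analog = a, ec50_molar = fit$ec50, ec50 = format_molar(fit$ec50),
         hill = fit$hill, converged = fit$converged)
  })
  names(fits) <- cfg$presets
  write_result_tsv(
    data.frame(analog = cfg$presets,
               ec50_molar = vapply(fits, `[[`, numeric(1), "ec50_molar")),
    file.path(outdir, "potency.tsv"))
  list(seed = seed, params = cfg, fits = fits)
}
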