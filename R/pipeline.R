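# Orchestration: fit -> predict -> measure -> compare, plus the comparison
# statistics (deviation, Shapiro-Wilk normality, one-way ANOVA for left vs
# right and across sections).

#' Compare predicted and measured per-section deformation
#'
#' Computes the mean absolute deviation between matched predicted and
#' measured values, Shapiro-Wilk normality per group, and one-way ANOVA
#' F-tests of the measured deformation for left vs right and across
#' sections. Significance is reported at the two tiers 0.05 (significant)
#' and 0.005 (highly significant). By default groups pool section means per
#' side; set `pool = "none"` to use every supplied row.
#'
#' @param predicted,measured data.frames with columns `section`,
#'   `deformation_mm` and optionally `side`; matched on section (+ side when
#'   present in both).
#' @param predicted_dynamic,measured_dynamic optional data.frames of the
#'   same shape for the dynamic condition.
#' @param pool `"side_section"` (default; one value per side x section) or
#'   `"none"`.
#' @return object of class `comparison_report`: `deviation` (static and,
#'   when supplied, dynamic, mm), `normality` (per-group Shapiro-Wilk),
#'   `anova` (left-vs-right and across-sections F and p with tier labels),
#'   and the matched table `matched`.
#' @export
compare_deformation <- function(predicted, measured,
                                predicted_dynamic = NULL,
                                measured_dynamic = NULL,
                                pool = c("side_section", "none")) {
  pool <- match.arg(pool)
  matched <- match_deformation(predicted, measured)
  deviation <- list(static = mean(abs(matched$predicted_mm - matched$measured_mm)))
  matched_dyn <- NULL
  if (!is.null(predicted_dynamic) && !is.null(measured_dynamic)) {
    matched_dyn <- match_deformation(predicted_dynamic, measured_dynamic)
    deviation$dynamic <- mean(abs(matched_dyn$predicted_mm - matched_dyn$measured_mm))
  }
  groups <- measured
  if (pool == "side_section" && !is.null(groups$side))
    groups <- stats::aggregate(deformation_mm ~ section + side, groups, mean)
  normality <- normality_by(groups)
  anova <- rbind(anova_row(groups, "side", "left_vs_right"),
                 anova_row(groups, "section", "across_sections"))
  structure(list(deviation = deviation, normality = normality,
                 anova = anova, matched = matched,
                 matched_dynamic = matched_dyn,
                 n = nrow(groups)),
            class = "comparison_report")
}

match_deformation <- function(predicted, measured) {
  for (d in list(predicted, measured))
    if (!all(c("section", "deformation_mm") %in% names(d)))
      stopf("data.frames need columns `section` and `deformation_mm`")
  keys <- intersect(c("section", "side"),
                    intersect(names(predicted), names(measured)))
  m <- merge(predicted, measured, by = keys, suffixes = c("_pred", "_meas"))
  if (nrow(m) == 0L) stopf("no matching section/side keys between predicted and measured")
  data.frame(m[keys],
             predicted_mm = m$deformation_mm_pred,
             measured_mm = m$deformation_mm_meas)
}

normality_by <- function(groups) {
  key <- if (!is.null(groups$side)) groups$side else rep("all", nrow(groups))
  sp <- split(groups$deformation_mm, key)
  do.call(rbind, lapply(names(sp), function(g) {
    x <- sp[[g]]
    if (length(x) < 3L || diff(range(x)) == 0) {
      warnf("group '%s': n = %d, normality test skipped", g, length(x))
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_))
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value)
  }))
}

anova_row <- function(groups, factor_col, label) {
  if (is.null(groups[[factor_col]]) ||
      length(unique(groups[[factor_col]])) < 2L) {
    return(data.frame(comparison = label, F = NA_real_, p = NA_real_,
                      tier = "not testable"))
  }
  fit <- stats::aov(deformation_mm ~ factor(g),
                    data = data.frame(deformation_mm = groups$deformation_mm,
                                      g = groups[[factor_col]]))
  tab <- summary(fit)[[1L]]
  if (nrow(tab) < 2L || is.na(tab[1L, "F value"]))
    return(data.frame(comparison = label, F = NA_real_, p = NA_real_,
                      tier = "not testable"))
  p <- tab[1L, "Pr(>F)"]
  data.frame(comparison = label, F = tab[1L, "F value"], p = p,
             tier = significance_tier(p))
}

significance_tier <- function(p) {
  if (is.na(p)) "not testable"
  else if (p < 0.005) "p < 0.005"
  else if (p < 0.05) "p < 0.05"
  else "p > 0.05"
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  static deviation: %.3f mm over %d matched values\n",
              x$deviation$static, nrow(x$matched)))
  if (!is.null(x$deviation$dynamic))
    cat(sprintf("  dynamic deviation: %.3f mm\n", x$deviation$dynamic))
  for (i in seq_len(nrow(x$anova)))
    cat(sprintf("  ANOVA %s: F = %.3f, %s\n", x$anova$comparison[i],
                x$anova$F[i], x$anova$tier[i]))
  invisible(x)
}

#' Default pipeline configuration
#'
#' All tunable pipeline parameters with their defaults: the legging sample,
#' tissue constants (the literature Neo-Hookean pair), damping, RK4 step,
#' forcing, and the synthetic-fixture settings.
#'
#' @param seed global seed.
#' @return nested list; serialisable to/from YAML.
#' @export
default_config <- function(seed = 1L) {
  list(
    version = 1L,
    seed = as.integer(seed),
    sample = 4L,
    tissue = list(C1_pa = 5000, D1_per_pa = 1.4e-7),
    dynamic = list(enabled = TRUE, damping_ns_per_m = 5, dt_s = 1e-4,
                   t_end_s = 0.25, forcing_amplitude_n = 1,
                   forcing_frequency_hz = 60, mass_kg = 0.2),
    synth = list(image_size = 512L, pixel_scale_mm_per_px = 0.7,
                 deformation_mm = c(3, 2.8, 2.5, 2.2, 1.8, 1.5)),
    measure = list(n_angles = 360L, n_resample = 720L,
                   marker_threshold = 200L)
  )
}

load_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_config(), config)
}

tissue_from_config <- function(cfg) {
  tissue_model(C1 = cfg$tissue$C1_pa, D1 = cfg$tissue$D1_per_pa)
}

#' Measure per-section deformation from a synthetic fixture tree
#'
#' Runs the measurement side over a [synth_fixtures()] manifest: extracts
#' the control and garment contours of every section/side image, builds
#' centroid-anchored profiles and returns the per-section mean deformation
#' together with every [deformation_profile()].
#'
#' @param dir fixture directory containing `manifest.json`.
#' @param cfg configuration list (see [default_config()]).
#' @return list with `table` (section, side, deformation_mm, truth_mm) and
#'   `profiles`.
#' @export
measure_fixture_tree <- function(dir, cfg = default_config()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  marker <- marker_predicate(cfg$measure$marker_threshold)
  rows <- list(); profiles <- list()
  for (entry in manifest$sections) {
    for (side in names(entry$sides)) {
      s <- entry$sides[[side]]
      prof <- lapply(c(s$control_image, s$garment_image), function(f) {
        img <- png::readPNG(file.path(dir, f))
        pts <- extract_contour(img, marker, manifest$pixel_scale)
        cross_section_profile(pts, section_id = entry$section, side = side,
                              condition = if (grepl("control", f)) "control"
                                          else "garment",
                              n_angles = cfg$measure$n_angles,
                              n_resample = cfg$measure$n_resample,
                              pixel_scale = manifest$pixel_scale)
      })
      d <- deformation_profile(prof[[1L]], prof[[2L]])
      profiles[[paste0(entry$section, "_", side)]] <- d
      rows[[length(rows) + 1L]] <- data.frame(
        section = entry$section, side = side, deformation_mm = d$mean,
        truth_mm = s$deformation_mm)
    }
  }
  list(table = do.call(rbind, rows), profiles = profiles)
}

#' Run the full pipeline
#'
#' Executes fit-fabric -> predict-sections -> measure-scans -> compare on a
#' fixture tree (generated with [synth_fixtures()] when `synth = TRUE`),
#' writing versioned JSON/CSV artifacts and a log to `out_dir`. Outputs are
#' deterministic given the config and seed (timestamps only appear in the
#' log).
#'
#' @param config configuration list or YAML path (see [default_config()]);
#'   `NULL` for defaults.
#' @param out_dir output directory for artifacts.
#' @param data_dir fixture directory; defaults to `<out_dir>/fixtures`.
#' @param synth generate the fixture tree before running (default TRUE).
#' @return a [compare_deformation()] report (invisibly), with the predicted
#'   and measured tables attached as attributes.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("ldrun"),
                         data_dir = NULL, synth = TRUE) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(data_dir)) data_dir <- file.path(out_dir, "fixtures")
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  logf("limbdeform %s; seed=%d sample=%d",
       as.character(utils::packageVersion("limbdeform")), cfg$seed, cfg$sample)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    logf("stage %s: done", name)
    res
  }
  if (synth)
    stage("synth", synth_fixtures(
      data_dir, seed = cfg$seed, sample = cfg$sample,
      image_size = cfg$synth$image_size,
      pixel_scale = cfg$synth$pixel_scale_mm_per_px,
      deformation_mm = unlist(cfg$synth$deformation_mm)))
  if (!file.exists(file.path(data_dir, "manifest.json")))
    stopf("stage 'measure': missing control/garment fixtures in %s (no manifest.json); a control condition is mandatory",
          data_dir)
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                  simplifyVector = FALSE)

  fabric <- stage("fit-fabric", {
    recs <- read_stress_strain_csv(file.path(data_dir, manifest$stress_strain))
    fit_fabric(recs, mass = cfg$dynamic$mass_kg,
               label = sprintf("sample %d (fitted)", cfg$sample))
  })
  tissue <- tissue_from_config(cfg)

  predicted <- stage("predict", {
    secs <- lapply(manifest$sections, function(e)
      limb_section_geometry(e$section, e$limb_radius_mm,
                            e$garment_circumference_mm, e$section_height_mm))
    tab <- predict_sections(fabric, secs, tissue)
    data.frame(section = tab$section, deformation_mm = tab$deformation_mm,
               pressure_pa = tab$pressure_pa, stretch_mm = tab$stretch_mm)
  })

  measured <- stage("measure", measure_fixture_tree(data_dir, cfg))

  dynamic <- NULL
  if (isTRUE(cfg$dynamic$enabled)) {
    dynamic <- stage("simulate-dynamic", {
      dy <- cfg$dynamic
      do.call(rbind, lapply(seq_along(manifest$sections), function(i) {
        e <- manifest$sections[[i]]
        P <- predicted$pressure_pa[i]
        sys <- dynamic_system(mass = max(dy$mass_kg, 1e-6),
                              damping = dy$damping_ns_per_m,
                              forcing = sinusoidal_forcing(dy$forcing_amplitude_n,
                                                           dy$forcing_frequency_hz),
                              pressure = P)
        tr <- simulate_dynamic(sys, e$limb_radius_mm, tissue,
                               t_end = dy$t_end_s, dt = dy$dt_s,
                               section_height = e$section_height_mm,
                               cycle_period = 1 / dy$forcing_frequency_hz)
        last <- tr$cycles[nrow(tr$cycles), ]
        data.frame(section = e$section, mean_mm = last$mean,
                   max_mm = last$max, min_mm = last$min)
      }))
    })
  }

  report <- stage("compare",
                  compare_deformation(predicted, measured$table))

  utils::write.csv(predicted, file.path(out_dir, "predicted.csv"),
                   row.names = FALSE)
  utils::write.csv(measured$table, file.path(out_dir, "measured.csv"),
                   row.names = FALSE)
  if (!is.null(dynamic))
    utils::write.csv(dynamic, file.path(out_dir, "dynamic.csv"),
                     row.names = FALSE)
  result <- list(
    schema = "limbdeform/report/v1",
    config = cfg,
    fabric = unclass(fabric),
    deviation_mm = report$deviation,
    anova = report$anova,
    normality = report$normality,
    predicted = predicted,
    measured = measured$table,
    dynamic = dynamic)
  jsonlite::write_json(result, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  logf("report written: deviation static %.3f mm", report$deviation$static)
  attr(report, "predicted") <- predicted
  attr(report, "measured") <- measured$table
  attr(report, "dynamic") <- dynamic
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `fit-fabric <csv>`, `predict`, `measure`, `simulate-dynamic`,
#' `compare <predicted.csv> <measured.csv>`, `synth`, `run`. Common flags:
#' `--config <yaml>`, `--seed <int>`, `--out-dir <dir>`, `--data-dir <dir>`,
#' `--log-level <level>`. Exit status: 0 success, 2 invalid input, 3 stage
#' failure.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
ld_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: limbdeform <fit-fabric|predict|measure|simulate-dynamic|compare|synth|run> [options]\n")
    return(invisible(2L))
  }
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L])
  status <- tryCatch({
    cfg <- load_config(opts$options[["config"]])
    if (!is.null(opts$options[["seed"]]))
      cfg$seed <- as.integer(opts$options[["seed"]])
    out_dir <- opts$options[["out-dir"]] %||% "limbdeform_out"
    data_dir <- opts$options[["data-dir"]] %||% file.path(out_dir, "fixtures")
    switch(cmd,
      "synth" = {
        synth_fixtures(data_dir, seed = cfg$seed, sample = cfg$sample,
                       image_size = cfg$synth$image_size,
                       pixel_scale = cfg$synth$pixel_scale_mm_per_px,
                       deformation_mm = unlist(cfg$synth$deformation_mm))
        cat("fixtures written to", data_dir, "\n"); 0L
      },
      "fit-fabric" = {
        if (length(opts$positional) < 1L)
          stopf("fit-fabric needs a stress-strain CSV path")
        fab <- fit_fabric(read_stress_strain_csv(opts$positional[1L]))
        print(fab); 0L
      },
      "predict" = ,
      "measure" = ,
      "simulate-dynamic" = ,
      "run" = {
        rep <- run_pipeline(cfg, out_dir = out_dir, data_dir = data_dir,
                            synth = !dir.exists(data_dir) ||
                                    !file.exists(file.path(data_dir, "manifest.json")))
        print(rep); 0L
      },
      "compare" = {
        if (length(opts$positional) < 2L)
          stopf("compare needs predicted and measured CSV paths")
        rep <- compare_deformation(
          utils::read.csv(opts$positional[1L]),
          utils::read.csv(opts$positional[2L]))
        print(rep); 0L
      },
      { cat("unknown subcommand:", cmd, "\n"); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^stage ", conditionMessage(e))) 3L else 2L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_args <- function(args) {
  options <- list(); positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        options[[key]] <- TRUE
      } else {
        options[[key]] <- args[i + 1L]
        i <- i + 1L
      }
    } else positional <- c(positional, a)
    i <- i + 1L
  }
  list(options = options, positional = positional)
}
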