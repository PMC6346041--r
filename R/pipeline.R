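#' Two-group comparison with Student's t-test
#'
#' Compares two groups given either raw values or `(mean, se, n)` summaries,
#' with the pooled-variance two-tailed Student's t-test
#' (`df = n_a + n_b - 2`); Welch's correction is available behind a flag for
#' raw input. Summary input reconstructs each group variance as `n * se^2`.
#' Both entry points agree exactly when the raw values have the same mean,
#' standard error and n as the summaries.
#'
#' @param a,b numeric vectors of raw per-subject values, or lists with
#'   `mean`, `se`, `n`.
#' @param welch use Welch's unequal-variance test (raw input only).
#' @return a `group_stats` list: per-group `mean`, `se`, `n`; `t`, `df`,
#'   `p` (two-tailed), `significant` at the 0.05 level.
#' @export
group_compare <- function(a, b, welch = FALSE) {
  summarize <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "se", "n") %in% names(x)))
      if (x$n < 2) stop("need n >= 2 per group", call. = FALSE)
      if (x$se <= 0) stop("standard error must be positive", call. = FALSE)
      list(mean = x$mean, se = x$se, n = x$n, raw = NULL)
    } else {
      if (length(x) < 2) stop("need n >= 2 per group", call. = FALSE)
      list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
           n = length(x), raw = x)
    }
  }
  ga <- summarize(a); gb <- summarize(b)
  if (!is.null(ga$raw) && !is.null(gb$raw)) {
    ht <- stats::t.test(ga$raw, gb$raw, var.equal = !welch)
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  } else {
    if (welch)
      stop("Welch's test needs raw values in both groups", call. = FALSE)
    va <- ga$n * ga$se^2   # = sample variance
    vb <- gb$n * gb$se^2
    df <- ga$n + gb$n - 2
    s2 <- ((ga$n - 1) * va + (gb$n - 1) * vb) / df
    t_stat <- (ga$mean - gb$mean) / sqrt(s2 * (1 / ga$n + 1 / gb$n))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(
    group_a = ga[c("mean", "se", "n")], group_b = gb[c("mean", "se", "n")],
    t = t_stat, df = df, p = p, significant = p < 0.05,
    test = if (welch) "welch" else "student"), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf(
    "<group_stats> %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
    x$group_a$mean, x$group_a$se, x$group_a$n,
    x$group_b$mean, x$group_b$se, x$group_b$n))
  cat(sprintf("  t = %.3f, df = %.3g, p = %.4g%s\n", x$t, x$df, x$p,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' Export a parameter map as CSV or rendered PNG
#'
#' CSV: the exact `H x W` grid with `NA` for invalid pixels. PNG: a viridis
#' rendering with the color range set to the 2nd-98th percentile of the
#' valid values (widened by one unit when degenerate); invalid pixels are
#' fully transparent.
#'
#' @param map a [new_parameter_map()].
#' @param path output file.
#' @param format `"csv"` or `"png"` (default from the file extension).
#' @export
export_map <- function(map, path,
                       format = ifelse(grepl("\\.png$", path, TRUE),
                                       "png", "csv")) {
  format <- match.arg(format, c("csv", "png"))
  if (format == "csv") return(write_map_csv(map, path))
  v <- map$values
  ok <- is.finite(v)
  H <- nrow(v); W <- ncol(v)
  rgba <- array(0, dim = c(H, W, 4))
  if (any(ok)) {
    rng <- stats::quantile(v[ok], c(0.02, 0.98), names = FALSE)
    if (diff(rng) <= 0) rng <- rng + c(-1, 1)
    pal <- grDevices::hcl.colors(256, "viridis")
    idx <- pmin(255, pmax(0, floor(255 * (v - rng[1]) / diff(rng)))) + 1L
    colm <- grDevices::col2rgb(pal[idx]) / 255
    rgba[, , 1][ok] <- colm[1, ][ok]
    rgba[, , 2][ok] <- colm[2, ][ok]
    rgba[, , 3][ok] <- colm[3, ][ok]
    rgba[, , 4][ok] <- 1
  }
  png::writePNG(rgba, path)
  invisible(path)
}

pipeline_schema <- list(
  top = c("seed", "output_dir", "input", "conditioning", "metrics", "cv",
          "log_level"),
  input = c("simulation", "movies"),
  movies = c("voltage", "calcium"),
  cv = c("channel", "act_method", "window", "order", "r2_min",
         "speed_bounds", "fiber_angle_rad", "use_stimulus_site",
         "min_vectors"),
  metric = c("name", "channel", "beat_index", "params", "label")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Schema-checks a pipeline config (a list, or a path to a JSON/YAML file)
#' before any computation; unknown keys are rejected. The config must supply
#' `output_dir` and an `input` block holding either `simulation` (arguments
#' of [simulation_config()]) or `movies` (paths for [read_movie()]).
#'
#' @param config list or path to a `.json`/`.yaml`/`.yml` file.
#' @return the validated config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check_keys(config, pipeline_schema$top, "config")
  if (is.null(config$output_dir)) stop("`output_dir` is required", call. = FALSE)
  if (is.null(config$input)) stop("`input` block is required", call. = FALSE)
  check_keys(config$input, pipeline_schema$input, "input")
  if (is.null(config$input$simulation) && is.null(config$input$movies))
    stop("input must hold `simulation` or `movies`", call. = FALSE)
  if (!is.null(config$input$movies))
    check_keys(config$input$movies, pipeline_schema$movies, "input$movies")
  if (!is.null(config$conditioning))
    check_keys(config$conditioning,
               c(names(formals(conditioning_config)), "normalize"),
               "conditioning")
  if (!is.null(config$cv)) check_keys(config$cv, pipeline_schema$cv, "cv")
  for (m in config$metrics)
    check_keys(m, pipeline_schema$metric, "metrics entry")
  config
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the input movies, conditions them, builds the SNR
#' mask, computes the requested per-pixel metric maps, optionally estimates
#' conduction velocity, and writes all artifacts (maps as CSV and PNG,
#' center-pixel traces as CSV, CV summary and run manifest as JSON) into
#' `output_dir`. Re-running with identical config and seed reproduces
#' identical numeric artifacts. Any stage failure aborts with the stage name
#' and removes partial outputs.
#'
#' @param config list or file path, see [validate_pipeline_config()].
#' @return invisibly, a list with the manifest, the maps, and the CV summary.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$output_dir
  created <- character(0)
  emit <- function(writer, obj, file) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    created <<- c(created, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stage <- "load"
    truth <- NULL
    if (!is.null(config$input$simulation)) {
      sim_args <- config$input$simulation
      if (!is.null(config$seed) && is.null(sim_args$seed))
        sim_args$seed <- config$seed
      sim <- do.call(simulation_config, sim_args)
      rec <- simulate_recording(sim)
      movies <- list(voltage = rec$voltage, calcium = rec$calcium)
      truth <- rec$truth
    } else {
      movies <- lapply(config$input$movies, read_movie)
    }
    stage <- "condition"
    cc_args <- config$conditioning
    normalize <- !isFALSE(cc_args$normalize)
    cc_args$normalize <- NULL
    cc <- do.call(conditioning_config, cc_args %||% list())
    conditioned <- lapply(movies, condition_movie, config = cc,
                          normalize = normalize)
    stage <- "mask"
    masks <- lapply(conditioned, build_mask, config = cc)
    stage <- "metrics"
    maps <- list()
    summary_rows <- list()
    for (m in config$metrics %||% list()) {
      ch <- m$channel %||% "voltage"
      if (is.null(conditioned[[ch]]))
        stop("metric requests missing channel `", ch, "`")
      pm <- parameter_map(conditioned[[ch]], masks[[ch]], metric = m$name,
                          beat_index = m$beat_index %||% 1L,
                          params = m$params %||% list())
      label <- m$label %||% paste0(ch, "_", m$name)
      maps[[label]] <- pm
      emit(write_map_csv, pm, paste0(label, ".csv"))
      emit(export_map, pm, paste0(label, ".png"))
      summary_rows[[label]] <- list(
        metric = label, units = pm$units,
        mean = map_mean(pm), n_valid = sum(is.finite(pm$values)))
    }
    stage <- "cv"
    cvs <- NULL
    if (!is.null(config$cv)) {
      cvc <- config$cv
      ch <- cvc$channel %||% "voltage"
      act <- parameter_map(conditioned[[ch]], masks[[ch]],
                           metric = "activation_time",
                           params = list(act_method =
                             cvc$act_method %||% "level_crossing"))
      field <- velocity_field(act,
        spacing_mm = conditioned[[ch]]$pixel_spacing_mm,
        window = cvc$window %||% 5L, order = cvc$order %||% 2L,
        r2_min = cvc$r2_min %||% 0.9,
        speed_bounds = unlist(cvc$speed_bounds) %||% c(0.05, 2.0))
      stim <- if (isTRUE(cvc$use_stimulus_site) && !is.null(truth))
        truth$config$stimulus_site
      cvs <- cv_summary(field, fiber_angle = cvc$fiber_angle_rad,
                        min_vectors = cvc$min_vectors %||% 20L,
                        stimulus_site = stim)
      emit(write_velocity_csv, field, "velocity_field.csv")
      emit(function(x, p) jsonlite::write_json(unclass(x), p,
             auto_unbox = TRUE, digits = NA), cvs, "cv_summary.json")
      summary_rows$cv <- list(metric = "conduction_velocity", units = "m/s",
                              cv_long = cvs$cv_long_m_per_s,
                              cv_trans = cvs$cv_trans_m_per_s,
                              anisotropy_ratio = cvs$anisotropy_ratio)
    }
    stage <- "export"
    for (ch in names(conditioned)) {
      d <- dim(conditioned[[ch]]$frames)
      tr <- pixel_trace(conditioned[[ch]],
                        max(1L, d[2] %/% 2L), max(1L, d[3] %/% 2L))
      emit(write_trace_csv, tr, paste0(ch, "_center_trace.csv"))
      emit(write_mask, masks[[ch]], paste0(ch, "_mask.csv"))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("optomap")),
      seed = config$seed, config = config,
      mask_counts = lapply(masks, function(m)
        list(included = sum(m$include), total = length(m$include))),
      summary = summary_rows)
    if (!is.null(cvs))
      manifest$cv_exclusions <- list()
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             digits = NA, null = "null",
                                             force = TRUE),
         manifest, "manifest.json")
    list(manifest = manifest, maps = maps, cv = cvs, masks = masks,
         truth = truth)
  }, error = function(e) {
    unlink(created)
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
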