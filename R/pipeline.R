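#' Read and validate a pipeline configuration
#'
#' YAML configuration with a global \code{seed}, an \code{out_dir} and one
#' block per stage (\code{simulate, variogram, softdata, krige, cokrige,
#' bme, validate, experiment}).  Unknown keys are rejected and numeric knobs
#' are range-checked at load time.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated config list of class \code{pipeline_config}.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known_top <- c("seed", "out_dir", "stages", "simulate", "variogram",
                 "softdata", "krige", "cokrige", "bme", "validate",
                 "experiment")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$seed <- cfg$seed %||% 1L
  check_num(cfg$seed, "seed", 0, 2^31 - 1)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$stages <- cfg$stages %||% c("simulate", "variogram", "softdata",
                                  "krige", "bme", "validate")
  sim <- cfg$simulate %||% list()
  known_sim <- c("grid", "mean", "variogram", "link", "residual")
  unknown <- setdiff(names(sim), known_sim)
  if (length(unknown))
    stop("unknown simulate keys: ", paste(unknown, collapse = ", "))
  if (!is.null(sim$variogram)) check_vgm_block(sim$variogram, "simulate")
  if (!is.null(sim$residual)) check_vgm_block(sim$residual, "residual")
  if (!is.null(sim$link)) {
    check_num(sim$link$a, "link a", 0, Inf)
    check_num(sim$link$b, "link b", -10, 10)
  }
  for (blk in c("variogram", "krige", "cokrige", "bme", "validate",
                "experiment")) {
    b <- cfg[[blk]] %||% list()
    for (key in intersect(names(b),
                          c("n_neighbors", "n_hard_neighbors",
                            "n_soft_neighbors", "n_holdout")))
      check_num(b[[key]], paste(blk, key), 0, 10000)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_num <- function(x, what, lo, hi) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < lo || x > hi)
    stop(sprintf("config key '%s' must be a number in [%g, %g]", what, lo, hi))
  invisible(TRUE)
}

check_vgm_block <- function(v, what) {
  if (!all(c("kind", "nugget", "sill", "range") %in% names(v)))
    stop(sprintf("%s variogram block needs keys kind, nugget, sill, range",
                 what))
  if (!v$kind %in% c("gaussian", "spherical"))
    stop(sprintf("%s variogram kind must be gaussian or spherical", what))
  check_num(v$nugget, paste(what, "nugget"), 0, Inf)
  check_num(v$sill, paste(what, "sill"), 0, Inf)
  check_num(v$range, paste(what, "range"), 1e-12, Inf)
  invisible(TRUE)
}

vgm_from_block <- function(v) {
  variogram_model(v$kind, nugget = v$nugget, psill = v$sill - v$nugget,
                  range = v$range)
}

#' Run the estimation pipeline
#'
#' Executes the requested stages in dependency order, writing plain-text
#' artifacts (CSV, ESRI ASCII grids, JSON) into \code{out_dir}:
#' \describe{
#'   \item{simulate}{\code{temperature.asc}, \code{flux.asc},
#'     \code{hard.csv} (the 49 flux samples).}
#'   \item{variogram}{\code{variogram_empirical.csv},
#'     \code{variogram_model.json}.}
#'   \item{softdata}{\code{arrhenius_fit.json}, \code{soft_data.csv}.}
#'   \item{krige / cokrige / bme}{estimate (and SD) grids plus a per-target
#'     CSV.}
#'   \item{validate}{\code{validation.csv}, the hold-out method comparison.}
#'   \item{experiment}{\code{experiment.csv} and its aggregate
#'     \code{experiment_summary.csv}.}
#' }
#' A stage that needs an artifact produced by an earlier stage errors with
#' the name of the stage to run first.  Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A \code{\link{read_config}} result, a path to a YAML file,
#'   or a config-shaped list.
#' @param dry_run Print the stage plan and return without computing?
#' @param verbose Log a line per completed stage?
#' @return Invisibly, a named list of the file paths written.
#' @export
run_pipeline <- function(config, dry_run = FALSE, verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_config(config)
  order_all <- c("simulate", "variogram", "softdata", "krige", "cokrige",
                 "bme", "validate", "experiment")
  stages <- order_all[order_all %in% cfg$stages]
  if (dry_run) {
    cat("pipeline plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(list()))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop(sprintf("missing artifact %s: run the '%s' stage first", f, stage))
    pth(f)
  }
  conf <- day2_defaults()
  sim <- cfg$simulate %||% list()
  if (!is.null(sim$mean))
    conf$temp_model$mean <- sim$mean
  if (!is.null(sim$variogram))
    conf$temp_model$variogram <- vgm_from_block(sim$variogram)
  if (!is.null(sim$residual))
    conf$residual_model$variogram <- vgm_from_block(sim$residual)
  if (!is.null(sim$link))
    conf$link <- c(a = sim$link$a, b = sim$link$b)

  written <- list()
  log_stage <- function(stage, t0, files) {
    if (verbose)
      message(sprintf("[%s] done in %.2f s -> %s", stage,
                      as.numeric(Sys.time()) - t0,
                      paste(basename(unlist(files)), collapse = ", ")))
  }
  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    files <- switch(stage,
      simulate = {
        s <- simulate_plot(conf, cfg$seed)
        list(write_ascii_grid(s$temp, pth("temperature.asc")),
             write_ascii_grid(s$flux, pth("flux.asc")),
             write_point_csv(s$hard, pth("hard.csv")))
      },
      variogram = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        emp <- empirical_variogram(hard)
        mod <- fit_best_variogram(emp)
        utils::write.csv(data.frame(lag = emp$lag, gamma = emp$gamma,
                                    npairs = emp$npairs),
                         pth("variogram_empirical.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(kind = mod$kind, nugget = mod$nugget,
               sill = mod$nugget + mod$psill, range = mod$range,
               r2 = mod$fit_r2),
          pth("variogram_model.json"), auto_unbox = TRUE, digits = NA)
        list(pth("variogram_empirical.csv"), pth("variogram_model.json"))
      },
      softdata = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        temp <- read_ascii_grid(need("temperature.asc", "simulate"))
        fit <- fit_arrhenius(field_value_at(temp, hard$locations),
                             hard$values)
        jsonlite::write_json(
          list(a = fit$a, b = fit$b, n = fit$n, CR = fit$CR, S_TP = fit$S_TP,
               S_TT = fit$S_TT, T_bar = fit$T_bar, t_crit = fit$t_crit),
          pth("arrhenius_fit.json"), auto_unbox = TRUE, digits = NA)
        soft <- make_soft_data(fit, temp, exclude = hard$locations)
        df <- do.call(rbind, lapply(soft, function(s)
          data.frame(x = s$location[1], y = s$location[2], center = s$center,
                     scale = s$scale, df = s$df,
                     lower_trunc = s$lower_trunc)))
        utils::write.csv(df, pth("soft_data.csv"), row.names = FALSE)
        list(pth("arrhenius_fit.json"), pth("soft_data.csv"))
      },
      krige = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        mod <- model_from_json(need("variogram_model.json", "variogram"))
        nn <- (cfg$krige %||% list())$n_neighbors %||% 16
        res <- ordinary_kriging(hard, mod, grid_coords(conf$flux_spec), nn)
        write_estimate(res$estimate, conf$flux_spec, pth("ok_estimate.asc"))
        utils::write.csv(res, pth("ok_estimates.csv"), row.names = FALSE)
        list(pth("ok_estimate.asc"), pth("ok_estimates.csv"))
      },
      cokrige = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        temp <- read_ascii_grid(need("temperature.asc", "simulate"))
        mod <- model_from_json(need("variogram_model.json", "variogram"))
        temp_at <- point_samples(hard$locations,
                                 field_value_at(temp, hard$locations))
        mod_x <- fit_best_variogram(empirical_cross_variogram(hard, temp_at))
        mod_t <- fit_best_variogram(
          empirical_variogram(field_to_points(temp)))
        nn <- (cfg$cokrige %||% list())$n_neighbors %||% 16
        res <- cokriging(hard, field_to_points(temp),
                         coregionalization(mod, mod_t, mod_x),
                         grid_coords(conf$flux_spec), nn, nn)
        write_estimate(res$estimate, conf$flux_spec, pth("cook_estimate.asc"))
        utils::write.csv(res, pth("cook_estimates.csv"), row.names = FALSE)
        list(pth("cook_estimate.asc"), pth("cook_estimates.csv"))
      },
      bme = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        mod <- model_from_json(need("variogram_model.json", "variogram"))
        soft <- soft_from_csv(need("soft_data.csv", "softdata"))
        b <- cfg$bme %||% list()
        gk <- general_knowledge(mean(hard$values), mod)
        res <- bme_map(hard, soft, gk, conf$flux_spec,
                       b$n_hard_neighbors %||% 12, b$n_soft_neighbors %||% 3,
                       estimator = b$estimator %||% "mean")
        write_ascii_grid(res$estimate, pth("bme_estimate.asc"))
        write_ascii_grid(res$sd, pth("bme_sd.asc"))
        list(pth("bme_estimate.asc"), pth("bme_sd.asc"))
      },
      validate = {
        hard <- read_point_csv(need("hard.csv", "simulate"))
        temp <- read_ascii_grid(need("temperature.asc", "simulate"))
        v <- cfg$validate %||% list()
        rep_ <- compare_methods(hard, temp, v, seed = cfg$seed)
        utils::write.csv(rep_, pth("validation.csv"), row.names = FALSE)
        list(pth("validation.csv"))
      },
      experiment = {
        e <- cfg$experiment %||% list()
        seeds <- cfg$seed + seq_len(e$reps %||% 10) - 1L
        res <- sampling_density_experiment(
          conf, schemes = unlist(e$schemes %||% c(9, 21, 37)),
          seeds = seeds)
        utils::write.csv(res, pth("experiment.csv"), row.names = FALSE)
        utils::write.csv(aggregate_experiment(res),
                         pth("experiment_summary.csv"), row.names = FALSE)
        list(pth("experiment.csv"), pth("experiment_summary.csv"))
      })
    written[[stage]] <- unlist(files)
    log_stage(stage, t0, files)
  }
  invisible(written)
}

model_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  variogram_model(j$kind, nugget = j$nugget, psill = j$sill - j$nugget,
                  range = j$range, fit_r2 = j$r2 %||% NA_real_)
}

soft_from_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    soft_datum(c(df$x[i], df$y[i]), df$center[i], df$scale[i], df$df[i],
               df$lower_trunc[i]))
}

write_estimate <- function(values, spec, path) {
  write_ascii_grid(grid_field(spec, matrix(values, nrow = spec$n_y,
                                           ncol = spec$n_x, byrow = TRUE)),
                   path)
}
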