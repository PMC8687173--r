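#' Load an experiment configuration from a YAML file
#'
#' The file holds flat keys; anything omitted falls back to the study
#' defaults of [experiment_config()]. Recognized keys: `cohort`,
#' `horizon_min`, `step_min`, `mc_runs`, `seed`, `R`, `Q` (12 values),
#' `P0` (12 values), `init_mean` (12 values), `kappa`, `nprime`,
#' `burnin_min`, `noisy_truth`, `random_init`, `flavours`,
#' `meal_doses_g`, `meal_starts_min`, `meal_rate_g_min`, plus any model
#' parameter symbol (e.g. `VG`, `kp1`, `BW`) applied as a field override
#' of the cohort profile. Unknown keys are rejected; all validation
#' errors are reported together.
#'
#' @param path file path; an empty or missing-key file yields the full
#'   default normal-cohort configuration.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

.config_keys <- c("cohort", "horizon_min", "step_min", "mc_runs", "seed",
                  "R", "Q", "P0", "init_mean", "kappa", "nprime",
                  "burnin_min", "noisy_truth", "random_init", "flavours",
                  "meal_doses_g", "meal_starts_min", "meal_rate_g_min")

config_from_list <- function(raw) {
  param_keys <- names(.parameter_profiles$normal)
  problems <- character()
  unknown <- setdiff(names(raw), c(.config_keys, param_keys))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  for (key in c("Q", "P0", "init_mean")) {
    if (!is.null(raw[[key]]) && length(unlist(raw[[key]])) != 12L)
      problems <- c(problems, paste0(key, " must have 12 entries"))
  }
  if (!is.null(raw$meal_doses_g) && !is.null(raw$meal_starts_min) &&
      length(raw$meal_doses_g) != length(raw$meal_starts_min))
    problems <- c(problems,
                  "meal_doses_g and meal_starts_min must have equal length")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  cohort <- raw$cohort %||% "normal"
  overrides <- raw[intersect(names(raw), param_keys)]
  params <- do.call(cohort_parameters, c(list(cohort = cohort), overrides))

  meals <- standard_meal_schedule()
  if (!is.null(raw$meal_doses_g) || !is.null(raw$meal_starts_min)) {
    meals <- meal_schedule(
      dose_mg = unlist(raw$meal_doses_g %||% c(37, 74, 74)) * 1000,
      start_min = unlist(raw$meal_starts_min %||% c(120, 420, 960)),
      rate_mg_min = (raw$meal_rate_g_min %||% 3.7) * 1000)
  } else if (!is.null(raw$meal_rate_g_min)) {
    meals <- standard_meal_schedule(rate_g_min = raw$meal_rate_g_min)
  }

  experiment_config(
    cohort = cohort, meals = meals,
    horizon = raw$horizon_min %||% 1440,
    dt = raw$step_min %||% 1,
    Q = if (is.null(raw$Q)) c(1, rep(0.1, 11)) else unlist(raw$Q),
    R = raw$R %||% 16,
    P0 = if (is.null(raw$P0)) c(400^2, 0.1, 0.1, 0.1, 200^2, 0.3,
                                100, 10, 10, 30, 0.1, 0.5)
         else unlist(raw$P0),
    init_mean = if (is.null(raw$init_mean)) NULL else unlist(raw$init_mean),
    mc_runs = raw$mc_runs %||% 50,
    seed = raw$seed %||% 1,
    flavours = unlist(raw$flavours %||% c("ukf", "cqkf")),
    kappa = raw$kappa %||% (3 - 12),
    nprime = raw$nprime %||% 2,
    burnin_min = raw$burnin_min %||% 60,
    noisy_truth = raw$noisy_truth %||% TRUE,
    random_init = raw$random_init %||% TRUE,
    params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(c, path))`
#' reproduces `c`.
#'
#' @param config an [experiment_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  prof <- .parameter_profiles[[config$cohort]]
  cur <- unclass(config$params)[names(prof)]
  overrides <- cur[mapply(function(a, b) !isTRUE(all.equal(a, b)), cur, prof)]
  out <- c(list(
    cohort = config$cohort,
    horizon_min = config$horizon,
    step_min = config$dt,
    mc_runs = config$mc_runs,
    seed = config$seed,
    R = config$R,
    Q = as.numeric(diag(config$Q)),
    P0 = as.numeric(diag(config$P0)),
    init_mean = as.numeric(config$init_mean),
    kappa = config$kappa,
    nprime = config$nprime,
    burnin_min = config$burnin_min,
    noisy_truth = config$noisy_truth,
    random_init = config$random_init,
    flavours = as.list(config$flavours),
    meal_doses_g = as.numeric(config$meals$dose) / 1000,
    meal_starts_min = as.numeric(config$meals$start),
    meal_rate_g_min = if (nrow(config$meals))
      config$meals$rate[1] / 1000 else 3.7
  ), overrides)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a simulated trajectory to CSV
#'
#' Columns: `t_min`, the twelve states, `G_mg_dl`, `I_pmol_l`, `EGP`,
#' `Ra`, `Uid`, `E`, `S`; one row per sampling instant, header mandatory.
#'
#' @param traj a [simulate_model()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("t_min", STATE_NAMES, "G_mg_dl", "I_pmol_l",
            "EGP", "Ra", "Uid", "E", "S")
  write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Export a filter result to CSV
#'
#' Columns: `t_min`, the posterior mean of each state (`mean_*`), the
#' posterior standard deviation of each state (`sd_*`), `innovation` and
#' `innovation_variance`.
#'
#' @param fit a [run_filter()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(fit, path) {
  out <- data.frame(t_min = fit$t_min)
  m <- fit$mean; colnames(m) <- paste0("mean_", STATE_NAMES)
  s <- fit$sd; colnames(s) <- paste0("sd_", STATE_NAMES)
  out <- cbind(out, m, s)
  out$innovation <- fit$innovation
  out$innovation_variance <- fit$innovation_variance
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export RMSE series to CSV
#'
#' Columns: `t_min` plus one column per state per filter
#' (`<flavour>_<state>`).
#'
#' @param ... one or more [monte_carlo_rmse()] results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rmse_csv <- function(..., path) {
  series <- list(...)
  out <- data.frame(t_min = series[[1]]$t_min)
  for (s in series) {
    block <- as.data.frame(s)[, STATE_NAMES]
    colnames(block) <- paste0(attr(s, "flavour"), "_", STATE_NAMES)
    out <- cbind(out, block)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, as YAML next to the outputs: the configuration echo, the seeds
#' in use, the package version and an MD5 checksum per output file, so a
#' run can be reproduced and verified from the manifest alone.
#'
#' @param config the [experiment_config()] used.
#' @param outputs character vector of output file paths.
#' @param path manifest destination (default `manifest.yaml` next to the
#'   first output).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs,
                           path = file.path(dirname(outputs[1]),
                                            "manifest.yaml")) {
  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  manifest <- list(
    package = "glucofilt",
    version = as.character(utils::packageVersion("glucofilt")),
    base_seed = config$seed,
    trial_seeds = config$seed + seq_len(config$mc_runs),
    config = yaml::read_yaml(cfg_file),
    checksums = as.list(tools::md5sum(outputs))
  )
  unlink(cfg_file)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
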