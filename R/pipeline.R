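# One-command reproduction pipeline: simulate (or read) a track ensemble,
# run the MSD / ageing / ergodicity analyses, and write every table plus a
# machine-readable summary into one output directory. Tables are the
# contract; plotting is left to the caller.

#' Pipeline configuration
#'
#' Flat key-value configuration for \code{\link{run_pipeline}}. Either
#' \code{input} (a track-table path) or \code{sim} (an
#' \code{\link{hfbm_params}} object plus \code{n_traj}) must be supplied.
#'
#' @param input path to a canonical track table, or \code{NULL} to simulate.
#' @param sim_params \code{\link{hfbm_params}} used when simulating.
#' @param n_traj number of simulated trajectories.
#' @param window_intermediate,window_long power-law fit windows (s).
#' @param t_a_list ageing times (s).
#' @param thresholds minimum-duration thresholds for the conditional
#'   analyses (s).
#' @param eb_lag lag for the amplitude-scatter and EB analyses (s).
#' @param etmsd_lag lag for the e-tMSD-vs-duration decay (s).
#' @param min_traj minimum trajectories per duration group.
#' @param n_boot bootstrap resamples.
#' @param seed master seed, recorded in every output.
#' @param out_dir output directory.
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input = NULL, sim_params = hfbm_params(),
                            n_traj = 2000L,
                            window_intermediate = c(0.2, 2),
                            window_long = c(3, 20),
                            t_a_list = c(0, 2, 5),
                            thresholds = c(0, 4, 8),
                            eb_lag = 0.2, etmsd_lag = 0.2,
                            min_traj = 50L, n_boot = 100L,
                            seed = 1L, out_dir = tempfile("hfbmtrack_run_")) {
  structure(list(input = input, sim_params = sim_params,
                 n_traj = as.integer(n_traj),
                 window_intermediate = window_intermediate,
                 window_long = window_long, t_a_list = t_a_list,
                 thresholds = thresholds, eb_lag = eb_lag,
                 etmsd_lag = etmsd_lag, min_traj = as.integer(min_traj),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

#' Run the full analysis pipeline
#'
#' Stages: input (read or simulate the track table), MSD curves (all kinds,
#' all ageing times, all duration thresholds), power-law and exponential
#' fits, EB tables, amplitude scatter with a generalized-Gamma fit, and a
#' machine-readable summary with the three headline flags (\code{ergodic},
#' \code{ages}, \code{spurious_subdiffusion}). Any stage error aborts with
#' the stage name; partial outputs are kept next to a \code{FAILED} marker.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the output directory path, invisibly; the summary is in
#'   \code{summary.json} there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  logline <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)),
                               file = logf, append = TRUE)
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  logline("seed = %d, R %s, hfbmtrack %s", config$seed,
          getRversion(),
          tryCatch(as.character(utils::packageVersion("hfbmtrack")),
                   error = function(e) "devel"))

  ens <- stage("input", {
    if (!is.null(config$input)) read_tracks(config$input)
    else simulate_hfbm_ensemble(config$n_traj, config$sim_params,
                                seed = config$seed)
  })
  stage("input", write_tracks(ens, file.path(out, "tracks.csv")))
  wi <- config$window_intermediate; wl <- config$window_long

  curves <- stage("msd", {
    cl <- list()
    for (ta in config$t_a_list) {
      if (ta >= max(duration(ens))) {
        logline("msd: skipping t_a = %g s (exceeds all durations)", ta)
        next
      }
      cl[[length(cl) + 1L]] <- emsd(ens, t_a = ta, max_lag = wl[2])
      cl[[length(cl) + 1L]] <- etmsd(ens, t_a = ta, max_lag = wi[2])
    }
    for (tau in setdiff(config$thresholds, 0))
      cl[[length(cl) + 1L]] <- emsd(ens, T_min = tau, max_lag = wl[2])
    utils::write.csv(msd_table(cl), file.path(out, "msd_curves.csv"),
                     row.names = FALSE)
    cl
  })

  fits <- stage("fits", {
    pooled <- curves[[1L]]
    fit_int <- fit_power_law(pooled, wi, with_offset = TRUE)
    fit_long <- fit_power_law(pooled, wl)
    cond <- conditional_diffusion_profile(
      ens, thresholds = pmax(config$thresholds, min(duration(ens))),
      window = wi, min_traj = config$min_traj, with_offset = TRUE)
    prof <- tryCatch(
      etmsd_vs_duration(ens, config$etmsd_lag, min_traj = config$min_traj,
                        n_boot = config$n_boot, seed = config$seed),
      error = function(e) NULL)
    out_fits <- list(
      seed = config$seed,
      intermediate = list(window = wi, alpha = fit_int$alpha,
                          D_alpha = fit_int$D_alpha, offset = fit_int$offset),
      long = list(window = wl, alpha = fit_long$alpha,
                  D_alpha = fit_long$D_alpha),
      conditional = list(gamma = cond$fit$gamma,
                         table = cond$table),
      etmsd_vs_duration = if (!is.null(prof))
        list(lag = config$etmsd_lag, a = prof$fit$a, b = prof$fit$b,
             a_ci = prof$fit$a_ci, b_ci = prof$fit$b_ci))
    .write_json(out_fits, file.path(out, "fits.json"))
    list(int = fit_int, long = fit_long, cond = cond, prof = prof)
  })

  ageing <- stage("ageing", {
    if (max(duration(ens)) <= max(config$t_a_list))
      stop("ageing times exceed every trajectory duration")
    sw <- ageing_sweep(ens, config$t_a_list, wi, n_boot = config$n_boot,
                       seed = config$seed, with_offset = TRUE)
    utils::write.csv(sw$amplitudes, file.path(out, "ageing_amplitudes.csv"),
                     row.names = FALSE)
    sw
  })

  ergo <- stage("ergodicity", {
    sc <- amplitude_scatter(ens, config$eb_lag)
    utils::write.csv(data.frame(zeta = sc$zeta),
                     file.path(out, "zeta.csv"), row.names = FALSE)
    for (md in c("binned", "min_duration")) {
      eb <- tryCatch(eb_vs_duration(ens, config$eb_lag, mode = md,
                                    min_traj = config$min_traj),
                     error = function(e) NULL)
      if (!is.null(eb))
        utils::write.csv(eb$table, file.path(out, paste0("eb_", md, ".csv")),
                         row.names = FALSE)
    }
    gg <- tryCatch(fit_generalized_gamma(sc, seed = config$seed),
                   error = function(e) NULL)
    if (!is.null(gg))
      .write_json(list(a = gg$a, b = gg$b, nu = gg$nu, loglik = gg$loglik,
                       n_used = gg$n_used, n_excluded = gg$n_excluded,
                       seed = config$seed),
                  file.path(out, "gengamma.json"))
    list(scatter = sc, gengamma = gg)
  })

  stage("summary", {
    ec <- emsd(ens, max_lag = wi[2])
    tc <- etmsd(ens, max_lag = wi[2])
    sel <- ec$lag_s >= wi[1] & ec$lag_s <= wi[2] & ec$count >= 10L
    common <- intersect(ec$lag_s[sel], tc$lag_s[tc$count >= 10L])
    rel <- abs(tc$msd_um2[match(common, tc$lag_s)] -
                 ec$msd_um2[match(common, ec$lag_s)]) /
      ec$msd_um2[match(common, ec$lag_s)]
    ergodic <- length(rel) > 0 && max(rel) < 0.05
    tab <- fits$cond$table
    sub_alpha <- tryCatch(
      fit_power_law(emsd(ens, T_min = max(config$thresholds),
                         max_lag = wl[2]), wl)$alpha,
      error = function(e) NA_real_)
    spurious <- is.finite(fits$long$alpha) && fits$long$alpha < 1 &&
      is.finite(sub_alpha) && (sub_alpha - fits$long$alpha) > 0.3
    .write_json(list(
      seed = config$seed, n_traj = length(ens$trajectories),
      ergodic = ergodic, max_rel_emsd_etmsd = if (length(rel)) max(rel),
      ages = ageing$ages,
      spurious_subdiffusion = spurious,
      alpha_intermediate = fits$int$alpha,
      alpha_long_pooled = fits$long$alpha,
      alpha_long_conditional = sub_alpha,
      gamma_conditional = fits$cond$fit$gamma,
      etmsd_decay_b = if (!is.null(fits$prof)) fits$prof$fit$b),
      file.path(out, "summary.json"))
  })
  logline("done")
  invisible(out)
}
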