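#' Diagnostic plots for trajectories, estimates and RMSE curves
#'
#' Writes PNG panels mirroring the study's figure layout: truth versus
#' estimate for the gastric states, the glucose states and the insulin
#' states (with meal ingestion shown as bars on a secondary axis), plus
#' per-filter RMSE panels. Plotting is skipped silently when no PNG
#' device is available.
#'
#' @param trial a [run_single_trial()] result (or `NULL` to skip the
#'   trajectory panels).
#' @param rmse list of [monte_carlo_rmse()] results (or `NULL`).
#' @param out_dir output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
plot_outputs <- function(trial = NULL, rmse = NULL, out_dir = ".") {
  if (!isTRUE(capabilities("png"))) return(invisible(character()))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  if (!is.null(trial)) {
    groups <- list(
      gastric = c("Qsto1", "Qsto2", "Qgut"),
      glucose = c("Gp", "Gt"),
      insulin_mass = c("Ipo", "Il", "Ip"),
      insulin_signal = c("Id", "I1", "X"),
      secretion = c("Y")
    )
    meals <- trial$truth$config$meals
    for (g in names(groups)) {
      f <- file.path(out_dir, paste0("trajectory_", g, ".png"))
      grDevices::png(f, width = 900, height = 300 * length(groups[[g]]))
      graphics::par(mfrow = c(length(groups[[g]]), 1),
                    mar = c(4, 4, 2, 4))
      for (st in groups[[g]]) {
        tt <- trial$truth$t_min[-1]
        truth <- trial$truth$states[-1, st]
        est <- trial$fit$mean[, st]
        graphics::matplot(tt, cbind(truth, est), type = "l",
                          lty = c(1, 2), col = c("black", "red"),
                          xlab = "t (min)", ylab = st, main = st)
        if (nrow(meals)) {
          usr <- graphics::par("usr")
          bar_h <- 0.15 * (usr[4] - usr[3])
          graphics::rect(meals$start, usr[3], meals$end, usr[3] + bar_h,
                         col = grDevices::adjustcolor("steelblue", 0.4),
                         border = NA)
          graphics::axis(4, at = c(usr[3], usr[3] + bar_h),
                         labels = c(0, round(meals$rate[1] / 1000, 1)))
          graphics::mtext("meal (g/min)", side = 4, line = 2, cex = 0.7)
        }
        graphics::legend("topright", c("truth", "estimate"),
                         lty = c(1, 2), col = c("black", "red"), bty = "n")
      }
      grDevices::dev.off()
      written <- c(written, f)
    }
  }

  for (s in rmse) {
    flv <- attr(s, "flavour")
    f <- file.path(out_dir, paste0("rmse_", flv, ".png"))
    grDevices::png(f, width = 1000, height = 800)
    graphics::par(mfrow = c(4, 3), mar = c(3, 4, 2, 1))
    for (st in STATE_NAMES) {
      graphics::plot(s$t_min, s[[st]], type = "l", xlab = "t (min)",
                     ylab = "RMSE", main = paste(toupper(flv), st))
    }
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
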