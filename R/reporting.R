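## Human-readable outputs: policy tables, trajectory panels, run manifests.

#' Format the policy comparison table
#'
#' Scenario, projected 2032 prevalence and percent reduction relative to
#' base, printed to one decimal place.
#'
#' @param outcomes A [run_policy_comparison()] result (or any data frame with
#'   columns `scenario`, `prevalence_2032`, `base_prevalence_2032`,
#'   `pct_reduction`).
#' @param digits Decimal places for the reduction column (default 1).
#' @return The formatted `data.frame`, invisibly; printed as a side effect.
#' @export
report_policy_table <- function(outcomes, digits = 1) {
  df <- as.data.frame(outcomes)
  if (nrow(df) == 0L) {
    base <- attr(outcomes, "trajectories")$BASE
    if (!is.null(base)) {
      ey <- attr(outcomes, "eval_year") %||% 2032
      df <- data.frame(scenario = "BASE",
                       prevalence_2032 = traj_value(base, "prevalence.avg", ey),
                       base_prevalence_2032 = traj_value(base, "prevalence.avg", ey),
                       pct_reduction = 0)
    }
  }
  fmt <- df
  fmt$prevalence_2032 <- sprintf("%.4f", fmt$prevalence_2032)
  fmt$base_prevalence_2032 <- sprintf("%.4f", fmt$base_prevalence_2032)
  fmt$pct_reduction <- sprintf(paste0("%.", digits, "f"), fmt$pct_reduction)
  cat(sprintf("Policy comparison (prevalence at %s, percent reduction vs base)\n",
              attr(outcomes, "eval_year") %||% 2032))
  print.data.frame(fmt, row.names = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.policy_outcomes <- function(x, ...) {
  report_policy_table(x)
  invisible(x)
}

#' Plot policy trajectories
#'
#' Four panels (tax, programme funding, retailer compliance, combined), each
#' showing the averaged prevalence over time for the relevant scenarios with
#' the base case drawn in every panel. Headless-safe: draws on the active
#' device only.
#'
#' @param x A [run_policy_comparison()] result with attached trajectories.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.policy_outcomes <- function(x, ...) {
  trajs <- attr(x, "trajectories")
  if (is.null(trajs) || is.null(trajs$BASE))
    stop("no trajectories attached to these outcomes")
  panels <- list(`Excise tax` = c("TAX_144", "TAX_220"),
                 `Programme funding` = "FUNDING_20",
                 `Retailer compliance` = "COMPLIANCE_95",
                 `All policies combined` = "ALL_COMBINED")
  panels <- lapply(panels, intersect, names(trajs))
  keep <- vapply(panels, length, 0L) > 0
  if (!any(keep)) panels <- list(`Base case` = character(0)) else panels <- panels[keep]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(panels)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  base <- trajs$BASE
  yrs <- base$times
  for (nm in names(panels)) {
    series <- c(list(BASE = traj_value(base, "prevalence.avg")),
                lapply(setNames(panels[[nm]], panels[[nm]]), function(s)
                  traj_value(trajs[[s]], "prevalence.avg")))
    graphics::matplot(yrs, do.call(cbind, series), type = "l", lty = seq_along(series),
                      col = 1, lwd = c(2, rep(1, length(series) - 1)),
                      xlab = "Year", ylab = "Past-30-day smoking rate", main = nm)
    graphics::legend("bottomleft", legend = names(series),
                     lty = seq_along(series), lwd = c(2, rep(1, length(series) - 1)),
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Records the configuration (hashed and verbatim), seed, package version and
#' timestamp of a run, sufficient to reproduce it.
#'
#' @param path Output JSON path.
#' @param config Named list describing the run configuration.
#' @param seed Integer seed used for the run (or `NULL`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(config = config,
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("smokedyn")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
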