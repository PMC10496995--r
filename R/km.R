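#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct
#' event times, with subjects censored at an event time kept in the risk
#' set for that time (the standard convention).
#'
#' @param surv Survival table (`sample`, `time`, `event`).
#' @return `data.frame` of class `km_curve`: `time` (distinct event
#'   times, increasing), `survival`, `at_risk`, `n_events`.
#' @export
km_estimate <- function(surv) {
  if (nrow(surv) < 1L) stop("empty survival table")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], survival = fit$surv[keep],
                    at_risk = fit$n.risk[keep], n_events = fit$n.event[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Sums, over the distinct event times, the observed minus
#' hypergeometric-expected events in the first group and the matching
#' hypergeometric variances; the statistic `(sum O - E)^2 / sum V` is
#' referred to chi-square with 1 degree of freedom. No continuity
#' correction is applied.
#'
#' @param surv Survival table aligned with `groups`.
#' @param groups Two-level grouping vector (e.g. `"high"`/`"low"`).
#' @return List with `chi2`, `p`, and `obs_minus_exp` for the first group
#'   level (its sign says which group had excess events).
#' @export
logrank_test <- function(surv, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L) stop("exactly 2 non-empty groups are required")
  if (length(groups) != nrow(surv)) stop("one group label per sample is required")
  if (sum(surv$event) < 1) stop("log-rank test needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ groups,
                            rho = 0)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE),
       obs_minus_exp = unname(sd_$obs[1L] - sd_$exp[1L]))
}

#' Plot Kaplan-Meier curves to a file
#'
#' Step plot of one or more KM curves with optional censoring ticks,
#' written deterministically to a PDF.
#'
#' @param curves List of `km_curve` objects (see [km_estimate()]).
#' @param labels Legend labels, one per curve.
#' @param path Output file path (PDF).
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
km_plot <- function(curves, labels = names(curves), path, main = "Overall survival") {
  if (length(curves) == 0L) stop("no curves to plot")
  if (is.null(labels)) labels <- paste("group", seq_along(curves))
  cols <- seq_along(curves) + 1L
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  xmax <- max(vapply(curves, function(k) max(k$time), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Time", ylab = "Survival probability", main = main)
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$survival)), col = cols[i],
                    do.points = FALSE, lwd = 2)
  }
  graphics::legend("bottomleft", legend = labels, col = cols, lwd = 2,
                   bty = "n")
  invisible(path)
}

#' Write KM curves as TSV
#' @param curves Named list of `km_curve` objects.
#' @param path Output file path.
#' @param params Named list recorded in the comment header.
#' @export
write_km <- function(curves, path, params = list()) {
  tab <- do.call(rbind, lapply(names(curves), function(g) {
    k <- curves[[g]]
    data.frame(group = g, time = k$time, survival = k$survival,
               at_risk = k$at_risk, n_events = k$n_events)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
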