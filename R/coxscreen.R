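#' Univariate Cox proportional-hazards fit for one covariate
#'
#' Maximises the Cox partial likelihood (Efron tie correction by default)
#' by Newton-Raphson from beta = 0, reporting the coefficient, its
#' standard error from the observed information, and the two-sided Wald
#' p-value `2 * (1 - pnorm(|beta| / se))`. Fits whose coefficient runs
#' past `diverge_at` in absolute value are flagged as non-converged
#' (monotone likelihood: the covariate separates the risk sets), since a
#' divergent fit cannot support a direction call.
#'
#' @param covariate Numeric vector, one value per sample of `surv`.
#' @param surv Survival table (`sample`, `time`, `event`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param diverge_at |beta| beyond which the fit is flagged divergent.
#' @return List with `beta`, `hr = exp(beta)`, `se`, `wald_p`, `n_used`,
#'   `n_events`, `converged`.
#' @export
fit_cox_univariate <- function(covariate, surv, ties = c("efron", "breslow"),
                               diverge_at = 15) {
  ties <- match.arg(ties)
  if (length(covariate) != nrow(surv)) {
    stop("need one covariate value per survival row")
  }
  keep <- complete.cases(covariate, surv$time, surv$event)
  covariate <- covariate[keep]
  time <- surv$time[keep]
  event <- surv$event[keep]
  if (sum(event) < 2) stop("Cox screening needs at least 2 events")
  if (length(unique(covariate)) < 2L) stop("covariate is constant")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ covariate, ties = ties,
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 50))
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1L, 1L]))
  converged <- is.finite(beta) && abs(beta) < diverge_at
  list(beta = beta, hr = exp(beta), se = se,
       wald_p = 2 * pnorm(abs(beta) / se, lower.tail = FALSE),
       n_used = length(covariate), n_events = sum(event),
       converged = converged)
}

#' Screen gene sets for survival association by univariate Cox regression
#'
#' Fits one univariate Cox model per gene set, regressing overall
#' survival on that set's NES across samples. Sets with Wald p below
#' `p_threshold` are retained and labelled by hazard-ratio direction:
#' `risk` for HR > 1 (higher enrichment, higher hazard) and `protective`
#' for HR < 1; everything else (including divergent fits) is `dropped`.
#' Samples missing from either input are removed listwise per screen.
#'
#' @param nes An `enrichment_matrix` (or bare set x sample NES matrix).
#' @param surv Survival table (`sample`, `time`, `event`).
#' @param p_threshold Retention threshold on the two-sided Wald p-value.
#' @param ties Tie correction passed to [fit_cox_univariate()].
#' @param require_retained If `TRUE`, error when no set is retained
#'   (useful in pipelines where an empty screen cannot proceed).
#' @param min_overlap,min_events Minimum usable samples / events.
#' @return `data.frame` with one row per set: `set`, `beta`, `hr`, `se`,
#'   `wald_p`, `direction`, `n_used`.
#' @export
screen_gene_sets <- function(nes, surv, p_threshold = 0.05,
                             ties = c("efron", "breslow"),
                             require_retained = FALSE,
                             min_overlap = 10L, min_events = 2L) {
  ties <- match.arg(ties)
  grid <- if (inherits(nes, "enrichment_matrix")) nes$nes else nes
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold must be in [0, 1]")
  common <- intersect(colnames(grid), surv$sample)
  if (length(common) < min_overlap) {
    stop("only ", length(common), " samples shared between NES and survival ",
         "(need >= ", min_overlap, ")")
  }
  sv <- surv[match(common, surv$sample), , drop = FALSE]
  if (sum(sv$event) < min_events) {
    stop("fewer than ", min_events, " events among shared samples")
  }
  grid <- grid[, common, drop = FALSE]
  rows <- lapply(rownames(grid), function(k) {
    f <- tryCatch(fit_cox_univariate(grid[k, ], sv, ties = ties),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(set = k, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, wald_p = NA_real_,
                        direction = "dropped", n_used = length(common)))
    }
    dir <- if (!f$converged) {
      warning("divergent Cox fit for set ", k, "; dropped from scoring")
      "dropped"
    } else if (f$wald_p < p_threshold) {
      if (f$hr > 1) "risk" else "protective"
    } else "dropped"
    data.frame(set = k, beta = f$beta, hr = f$hr, se = f$se,
               wald_p = f$wald_p, direction = dir, n_used = f$n_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (require_retained && !any(out$direction != "dropped")) {
    stop("no gene set passed the survival screen at p < ", p_threshold,
         "; consider a larger cohort or a different threshold")
  }
  out
}

#' Write a screening result table as TSV
#' @param screen Screen `data.frame` from [screen_gene_sets()].
#' @param path Output file path.
#' @param params Named list recorded in the comment header.
#' @export
write_screen <- function(screen, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  write.table(screen, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
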