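#' Combine NES values into the stemness gene score
#'
#' For each sample, the SGS is the sum of NES over the risk-direction sets
#' minus the sum over the protective-direction sets:
#' `SGS_s = sum_{k in risk} NES[k, s] - sum_{j in protective} NES[j, s]`.
#'
#' @param nes An `enrichment_matrix` (or bare set x sample NES matrix).
#' @param risk_sets Names of sets with HR > 1 in the survival screen.
#' @param protective_sets Names of sets with HR < 1.
#' @return Named numeric vector, one SGS per sample.
#' @export
compute_sgs <- function(nes, risk_sets, protective_sets = character()) {
  grid <- if (inherits(nes, "enrichment_matrix")) nes$nes else nes
  risk_sets <- as.character(risk_sets)
  protective_sets <- as.character(protective_sets)
  if (length(risk_sets) + length(protective_sets) == 0L) {
    stop("at least one risk or protective set is required")
  }
  overlap <- intersect(risk_sets, protective_sets)
  if (length(overlap) > 0L) {
    stop("set(s) listed as both risk and protective: ",
         paste(overlap, collapse = ", "))
  }
  unknown <- setdiff(c(risk_sets, protective_sets), rownames(grid))
  if (length(unknown) > 0L) {
    stop("unknown set name(s): ", paste(unknown, collapse = ", "))
  }
  colSums(grid[risk_sets, , drop = FALSE]) -
    colSums(grid[protective_sets, , drop = FALSE])
}

#' Stratify samples into high/low groups at the median score
#'
#' The cutoff is the sample median (mean of the middle two values for
#' even n). A sample is `high` iff its score strictly exceeds the cutoff;
#' scores tied at the cutoff go to `low` — the conservative call, since a
#' tied patient is not labelled high-risk. A frozen `cutoff` (e.g. from a
#' training cohort) can be supplied to stratify a validation cohort.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param cutoff Optional fixed cutoff overriding the median.
#' @return `data.frame` with columns `sample`, `sgs`, `group`
#'   (`"high"`/`"low"`), and attribute `cutoff`.
#' @export
stratify_median <- function(scores, cutoff = NULL) {
  if (length(scores) < 2L) stop("stratification needs at least 2 samples")
  if (anyNA(scores)) stop("scores must not be missing")
  if (is.null(cutoff)) {
    if (length(unique(scores)) == 1L) {
      stop("all scores identical; no stratification possible")
    }
    cutoff <- median(scores)
  }
  grp <- ifelse(scores > cutoff, "high", "low")
  out <- data.frame(sample = names(scores) %||% seq_along(scores),
                    sgs = unname(scores), group = grp,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cutoff") <- cutoff
  out
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with the normal
#' approximation, tie correction and continuity correction — the standard
#' pairwise comparison for scores or infiltration abundances between SGS
#' groups.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector aligned with `values`.
#' @return List with `statistic` (U for the first group level) and `p`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L) stop("exactly 2 non-empty groups are required")
  ht <- suppressWarnings(
    wilcox.test(values[groups == levels(groups)[1L]],
                values[groups == levels(groups)[2L]],
                alternative = "two.sided", exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Write a score table as TSV
#' @param scores `data.frame` from [stratify_median()].
#' @param path Output file path.
#' @param params Named list recorded in the comment header.
#' @export
write_scores <- function(scores, path, params = list()) {
  params$cutoff <- attr(scores, "cutoff")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  write.table(scores, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
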