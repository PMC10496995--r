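#' Per-cell stemness gene scores
#'
#' Scores every cell of a single-cell matrix with the same ssGSEA + SGS
#' machinery as the bulk path: average-tie ranks (so the many zeros of a
#' sparse matrix tie deterministically), range normalisation computed
#' within the cell matrix being scored, and the signed risk-minus-
#' protective combination with direction labels taken from a prior bulk
#' survival screen (per-cell survival does not exist, so directions are
#' transferred, not re-screened). Cells with all-zero expression have no
#' rank information and are excluded with a warning.
#'
#' @param x Gene x cell expression matrix.
#' @param sets Named list of gene sets.
#' @param risk_sets,protective_sets Direction labels from a bulk screen
#'   (see [screen_gene_sets()]).
#' @param alpha ssGSEA rank-weighting exponent.
#' @return Named numeric vector of per-cell SGS values (flagged cells
#'   absent).
#' @export
score_cells <- function(x, sets, risk_sets, protective_sets = character(),
                        alpha = 0.25) {
  validate_expression(x)
  zero <- colSums(x != 0) == 0L
  if (any(zero)) {
    warning("excluding ", sum(zero), " all-zero cell(s): ",
            paste(utils::head(colnames(x)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    x <- x[, !zero, drop = FALSE]
    if (ncol(x) == 0L) stop("no cells left after excluding all-zero cells")
  }
  enr <- score_all(x, sets, alpha = alpha, norm = "global_range")
  compute_sgs(enr, risk_sets, protective_sets)
}

#' Aggregate per-cell scores to patients and stratify at the median
#'
#' Takes the arithmetic mean of each patient's cell scores, then applies
#' the median split over patient means — the patient-level analogue of
#' the bulk stratification.
#'
#' @param cell_scores Named numeric vector of per-cell SGS (see
#'   [score_cells()]).
#' @param cell_to_patient `data.frame` with columns `cell`, `patient`
#'   covering every scored cell.
#' @return `data.frame` of class `cell_score_table` with one row per
#'   cell: `cell`, `patient`, `cell_sgs`, `patient_mean_sgs`,
#'   `patient_group`; attributes `patient_table` (per-patient summary)
#'   and `cutoff`.
#' @export
aggregate_patients <- function(cell_scores, cell_to_patient) {
  if (is.null(names(cell_scores))) stop("cell scores must be named by cell id")
  map <- cell_to_patient[match(names(cell_scores), cell_to_patient$cell), ]
  if (anyNA(map$patient)) {
    stop("unmapped cell(s): ",
         paste(names(cell_scores)[is.na(map$patient)], collapse = ", "))
  }
  lost <- setdiff(unique(cell_to_patient$patient), unique(map$patient))
  if (length(lost) > 0L) {
    stop("patient(s) with zero retained cells: ", paste(lost, collapse = ", "))
  }
  means <- tapply(cell_scores, map$patient, mean)
  strat <- stratify_median(stats::setNames(as.numeric(means), names(means)))
  grp <- stats::setNames(strat$group, strat$sample)
  out <- data.frame(cell = names(cell_scores), patient = map$patient,
                    cell_sgs = unname(cell_scores),
                    patient_mean_sgs = as.numeric(means[map$patient]),
                    patient_group = unname(grp[map$patient]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("cell_score_table", "data.frame")
  attr(out, "patient_table") <- data.frame(
    patient = strat$sample, mean_sgs = strat$sgs, group = strat$group,
    n_cells = as.integer(table(map$patient)[strat$sample]),
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- attr(strat, "cutoff")
  out
}

#' Score a single-cell cohort end to end
#'
#' Convenience wrapper: [score_cells()] then [aggregate_patients()].
#'
#' @inheritParams score_cells
#' @inheritParams aggregate_patients
#' @return A `cell_score_table` (see [aggregate_patients()]).
#' @export
score_single_cell <- function(x, sets, risk_sets,
                              protective_sets = character(),
                              cell_to_patient, alpha = 0.25) {
  aggregate_patients(
    score_cells(x, sets, risk_sets, protective_sets, alpha = alpha),
    cell_to_patient)
}
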