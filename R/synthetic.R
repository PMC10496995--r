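#' Random gene-set collection for simulation
#'
#' Draws `n_sets` sets of `set_size` genes from a universe of `n_genes`
#' synthetic gene ids. Sets may overlap; overlap is what makes planted
#' activity bleed between sets, as real stemness collections do.
#'
#' @param n_genes Universe size.
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors (`SET01`, `SET02`, ...), with
#'   attribute `gene_universe` holding all gene ids.
#' @export
make_gene_sets <- function(n_genes = 1000L, n_sets = 36L, set_size = 25L,
                           seed = 1L) {
  if (set_size > n_genes) stop("set_size cannot exceed n_genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(k) sample(genes, set_size))
  })
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  attr(sets, "source_label") <- "synthetic_stemness_sets"
  attr(sets, "gene_universe") <- genes
  sets
}

# Exponential censoring rate whose expected censored fraction over the
# subject-specific death rates equals `target`. P(censor first) for
# subject i is lc / (lc + rate_i); solve for lc by root finding on a log
# grid (monotone in lc, bracket always exists for target in (0, 1)).
censoring_rate <- function(death_rates, target) {
  f <- function(log_lc) mean(exp(log_lc) / (exp(log_lc) + death_rates)) - target
  lo <- log(min(death_rates)) - 20
  hi <- log(max(death_rates)) + 20
  exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Generate a bulk expression cohort with survival-linked gene-set activity
#'
#' Each sample s carries one latent activity per gene set,
#' `a[k, s] ~ N(0, 1)`. Expression is
#' `x[g, s] = mu_g + signal_strength * sum_{k: g in S_k} a[k, s] + eps`,
#' with baseline `mu_g ~ N(6, 2)` (a log2-expression-like scale) and
#' `eps ~ N(0, noise_sd)`. Survival follows a proportional-hazards
#' exponential model: death time `~ Exp(lambda0 * exp(sum_k beta_k a[k, s]))`,
#' with an independent exponential censoring time whose rate is solved so
#' the expected censored fraction equals `censor_rate`. Genes in
#' overlapping sets receive summed activity contributions. The whole
#' draw is reproducible from `seed`.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param sets Named list of gene sets (see [make_gene_sets()]); its
#'   `gene_universe` attribute, if present, fixes the gene ids.
#' @param effects Named numeric of true log-hazard coefficients beta_k per
#'   unit activity; unnamed sets get beta = 0 (null).
#' @param signal_strength Expression units added per unit activity.
#' @param noise_sd Per-gene residual standard deviation.
#' @param censor_rate Target censored fraction, strictly inside (0, 1).
#' @param lambda0 Baseline hazard (events per time unit).
#' @param seed Integer seed.
#' @return List with `expression` (gene x sample matrix), `survival`
#'   (`sample`, `time`, `event`), and `truth` (set effects, latent
#'   activities, baseline hazard, target censor rate, seed).
#' @export
generate_bulk <- function(n_samples = 200L, n_genes = 1000L,
                          sets = make_gene_sets(n_genes),
                          effects = NULL, signal_strength = 1,
                          noise_sd = 1, censor_rate = 0.3,
                          lambda0 = 0.1, seed = 1L) {
  if (censor_rate <= 0 || censor_rate >= 1) {
    stop("censor_rate must lie strictly between 0 and 1")
  }
  genes <- attr(sets, "gene_universe") %||% sprintf("g%05d", seq_len(n_genes))
  if (length(genes) != n_genes) {
    stop("gene universe of `sets` has ", length(genes),
         " genes but n_genes = ", n_genes)
  }
  bad <- setdiff(unlist(sets), genes)
  if (length(bad) > 0L) stop("gene set members outside the gene universe")
  beta <- stats::setNames(rep(0, length(sets)), names(sets))
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), names(sets))
    if (length(unknown) > 0L) {
      stop("effects for unknown set(s): ", paste(unknown, collapse = ", "))
    }
    beta[names(effects)] <- effects
  }
  memb <- vapply(sets, function(s) genes %in% s, logical(n_genes))
  with_seed(seed, {
    mu <- rnorm(n_genes, mean = 6, sd = 2)
    act <- matrix(rnorm(length(sets) * n_samples), nrow = length(sets),
                  dimnames = list(names(sets), NULL))
    x <- mu + signal_strength * (memb %*% act) +
      matrix(rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes)
    ids <- sprintf("s%04d", seq_len(n_samples))
    dimnames(x) <- list(genes, ids)
    colnames(act) <- ids
    rate <- lambda0 * exp(drop(crossprod(act, beta)))
    death <- rexp(n_samples, rate)
    lc <- censoring_rate(rate, censor_rate)
    cens <- rexp(n_samples, lc)
    surv <- data.frame(sample = ids, time = pmin(death, cens),
                       event = as.integer(death <= cens),
                       stringsAsFactors = FALSE)
    truth <- list(set_effects = beta, activities = act,
                  baseline_hazard = lambda0, censor_rate = censor_rate,
                  censoring_hazard = lc, seed = seed)
    list(expression = x, survival = surv, truth = truth)
  })
}

#' Generate a single-cell cohort with planted patient-level activity shifts
#'
#' Each patient p has one latent activity per set, shared by all of that
#' patient's cells: `a[k, p] ~ N(0, 1)` for unshifted sets, while the
#' sets named in `shifted_sets` carry the planted activity
#' `a[k, p] = shift_p` exactly, so the patient ordering of planted
#' activity is ground truth rather than a random draw. Each cell adds
#' independent expression noise, and
#' values are then zeroed independently with probability `dropout_rate`
#' (Bernoulli dropout, the sparse single-cell analogue). With
#' `dropout_rate = 0` the per-cell model is the bulk generator's
#' expression model with the patient activity in place of the sample
#' activity.
#'
#' @param n_patients,cells_per_patient Cohort dimensions
#'   (`cells_per_patient >= 2`).
#' @param sets Named list of gene sets.
#' @param patient_effects Numeric activity shift per patient (recycled
#'   names `P1`, `P2`, ... if unnamed).
#' @param shifted_sets Which sets receive the patient shift; defaults to
#'   the first set.
#' @param signal_strength,noise_sd As in [generate_bulk()].
#' @param dropout_rate Probability in `[0, 1)` that a value is zeroed.
#' @param seed Integer seed.
#' @return List with `expression` (gene x cell matrix), `cell_to_patient`
#'   (`data.frame` cell, patient), and `truth` (shifts, shifted sets,
#'   patient activities, dropout rate, seed).
#' @export
generate_single_cell <- function(n_patients = 2L, cells_per_patient = 200L,
                                 sets = make_gene_sets(500L, n_sets = 10L),
                                 patient_effects = rep(0, n_patients),
                                 shifted_sets = names(sets)[1L],
                                 signal_strength = 1, noise_sd = 1,
                                 dropout_rate = 0.5, seed = 1L) {
  if (cells_per_patient < 2L) stop("cells_per_patient must be at least 2")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  if (length(patient_effects) != n_patients) {
    stop("one activity shift per patient is required")
  }
  if (!all(shifted_sets %in% names(sets))) stop("unknown shifted set name")
  pat_ids <- names(patient_effects) %||% sprintf("P%d", seq_len(n_patients))
  names(patient_effects) <- pat_ids
  genes <- attr(sets, "gene_universe") %||%
    sort(unique(unlist(sets)))
  n_genes <- length(genes)
  memb <- vapply(sets, function(s) genes %in% s, logical(n_genes))
  with_seed(seed, {
    mu <- rnorm(n_genes, mean = 6, sd = 2)
    act <- matrix(rnorm(length(sets) * n_patients), nrow = length(sets),
                  dimnames = list(names(sets), pat_ids))
    act[shifted_sets, ] <- rep(patient_effects, each = length(shifted_sets))
    n_cells <- n_patients * cells_per_patient
    cell_pat <- rep(pat_ids, each = cells_per_patient)
    x <- mu + signal_strength * (memb %*% act[, cell_pat, drop = FALSE]) +
      matrix(rnorm(n_genes * n_cells, sd = noise_sd), nrow = n_genes)
    if (dropout_rate > 0) {
      x[matrix(runif(length(x)) < dropout_rate, nrow = n_genes)] <- 0
    }
    cell_ids <- sprintf("%s_c%04d", cell_pat,
                        rep(seq_len(cells_per_patient), n_patients))
    dimnames(x) <- list(genes, cell_ids)
    list(expression = x,
         cell_to_patient = data.frame(cell = cell_ids, patient = cell_pat,
                                      stringsAsFactors = FALSE),
         truth = list(patient_effects = patient_effects,
                      shifted_sets = shifted_sets,
                      activities = act, dropout_rate = dropout_rate,
                      seed = seed))
  })
}
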