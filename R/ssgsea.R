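#' Rank genes within one sample
#'
#' Ranks run 1..N with the most highly expressed gene at rank N. Ties take
#' the average rank by default, which keeps scoring deterministic — this
#' matters for sparse single-cell columns where most values tie at zero.
#'
#' @param x Gene x sample expression matrix.
#' @param sample Sample (column) id.
#' @param tie_rule `"average"` (default) or `"min"`.
#' @return Named numeric vector of per-gene ranks.
#' @export
rank_genes <- function(x, sample, tie_rule = c("average", "min")) {
  tie_rule <- match.arg(tie_rule)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  if (nrow(x) < 2L) stop("ranking needs at least 2 genes")
  rank(x[, sample], ties.method = tie_rule)
}

#' Single-sample enrichment score for one gene set
#'
#' Conceptually, the score walks the genes in decreasing rank order and
#' sums, over all N positions, the difference between the rank-weighted
#' in-set empirical CDF (weights `rank^alpha`, normalised by the total
#' in-set weight) and the unweighted out-of-set CDF. That sum has a
#' closed form, which is what is evaluated here:
#' `ES = sum_{g in S} r_g^alpha * r_g / sum_{g in S} r_g^alpha
#'       - sum_{g notin S} r_g / (N - |S|)`
#' i.e. the alpha-weighted mean rank of the set minus the mean rank of
#' its complement. For tied ranks (average tie rule) this equals the walk
#' averaged over all orderings of the tied genes, so the ES never depends
#' on the input gene order. Positive ES means the set concentrates among
#' highly expressed genes. Set genes absent from the ranked universe are
#' dropped first.
#'
#' @param ranks Named per-gene ranks (from [rank_genes()]).
#' @param gene_set Character vector of gene ids.
#' @param alpha Non-negative rank-weighting exponent.
#' @return ES scalar.
#' @export
enrichment_score <- function(ranks, gene_set, alpha = 0.25) {
  memb <- matrix(names(ranks) %in% gene_set, ncol = 1L,
                 dimnames = list(NULL, "set"))
  unname(es_core(matrix(ranks, ncol = 1L), memb, alpha)[1L, 1L])
}

# Closed-form ES grid. R: N x S matrix of per-sample ranks; memb: N x K
# logical membership matrix on the same gene order. Returns K x S.
es_core <- function(R, memb, alpha) {
  if (alpha < 0) stop("alpha must be non-negative")
  n <- nrow(R)
  sizes <- colSums(memb)
  if (any(sizes == 0L)) {
    stop("gene set(s) with empty intersection with the expression matrix: ",
         paste(colnames(memb)[sizes == 0L], collapse = ", "))
  }
  if (any(sizes >= n)) {
    stop("gene set(s) covering every gene in the matrix: ",
         paste(colnames(memb)[sizes >= n], collapse = ", "))
  }
  m <- memb * 1
  w <- R^alpha
  mean_in <- crossprod(m, w * R) / crossprod(m, w)
  in_r <- crossprod(m, R)
  tot <- matrix(colSums(R), nrow = ncol(m), ncol = ncol(R), byrow = TRUE)
  mean_out <- (tot - in_r) / (n - sizes)
  es <- mean_in - mean_out
  dimnames(es) <- list(colnames(memb), colnames(R))
  es
}

#' Score every gene set in every sample (ssGSEA) and normalise
#'
#' Computes the raw enrichment score of each set in each sample (see
#' [enrichment_score()]), then divides the whole grid by one
#' normalisation constant. Under `norm = "global_range"` the constant is
#' `max(ES) - min(ES)` over all sets and samples, giving normalised
#' enrichment scores (NES) on a cohort-comparable scale; `norm = "none"`
#' returns the raw ES as NES. Sets with no gene in the matrix are dropped
#' with a warning; sets shrinking below `min_size` genes after
#' intersection are dropped too.
#'
#' @param x Gene x sample expression matrix.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param alpha Rank-weighting exponent; 0.25 is the customary ssGSEA
#'   default.
#' @param norm `"global_range"` (default) or `"none"`.
#' @param tie_rule Rank tie rule, see [rank_genes()].
#' @param min_size Minimum post-intersection set size retained.
#' @return An `enrichment_matrix`: list with `es` and `nes` (set x sample
#'   matrices), `alpha`, `norm`, `norm_constant`, `source_label`.
#' @export
score_all <- function(x, sets, alpha = 0.25,
                      norm = c("global_range", "none"),
                      tie_rule = c("average", "min"), min_size = 2L) {
  norm <- match.arg(norm)
  tie_rule <- match.arg(tie_rule)
  validate_expression(x)
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  genes <- rownames(x)
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  sizes <- colSums(memb)
  drop <- sizes < min_size | sizes >= length(genes)
  if (all(drop)) stop("no gene set overlaps the expression matrix")
  if (any(drop)) {
    warning("dropping ", sum(drop), " gene set(s) with < ", min_size,
            " genes in (or covering all of) the matrix: ",
            paste(names(sets)[drop], collapse = ", "))
    memb <- memb[, !drop, drop = FALSE]
  }
  R <- apply(x, 2L, rank, ties.method = tie_rule)
  es <- es_core(R, memb, alpha)
  nc <- switch(norm,
    global_range = {
      rng <- max(es) - min(es)
      if (rng == 0) stop("all enrichment scores identical; cannot range-normalise")
      rng
    },
    none = 1
  )
  structure(list(es = es, nes = es / nc, alpha = alpha, norm = norm,
                 norm_constant = nc,
                 source_label = attr(sets, "source_label") %||% "gene_sets"),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf(
    "enrichment_matrix: %d set(s) x %d sample(s) [%s]\n  alpha = %g, norm = %s (constant %.6g)\n",
    nrow(x$nes), ncol(x$nes), x$source_label, x$alpha, x$norm, x$norm_constant))
  invisible(x)
}

#' ssGSEA infiltration scores for stromal/immune signatures
#'
#' Identical scoring contract to [score_all()]; kept as a named entry
#' point for cell-type signature collections (e.g. the 28 stromal and
#' immune signatures used for microenvironment profiling) so outputs
#' carry their own provenance label.
#'
#' @inheritParams score_all
#' @param signatures Named list of cell-type signatures.
#' @return An `enrichment_matrix` (see [score_all()]).
#' @export
infiltration_scores <- function(x, signatures, alpha = 0.25,
                                norm = c("global_range", "none")) {
  out <- score_all(x, signatures, alpha = alpha, norm = match.arg(norm))
  out$source_label <- attr(signatures, "source_label") %||% "infiltration_signatures"
  out
}

#' Write the NES grid of an enrichment matrix as TSV
#' @param enr An `enrichment_matrix`.
#' @param path Output file path.
#' @export
write_enrichment <- function(enr, path) {
  write_expression(enr$nes, path, id_column = "set",
                   params = list(alpha = enr$alpha, norm = enr$norm,
                                 norm_constant = enr$norm_constant,
                                 source = enr$source_label))
}
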