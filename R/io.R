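#' Read a gene x sample expression matrix from TSV/CSV
#'
#' The first column holds gene identifiers and the header row sample
#' identifiers. Lines starting with `#` (the comment header written by
#' [write_expression()]) are skipped. Duplicate gene rows are collapsed by
#' the per-sample maximum, the usual policy when several probesets map to
#' one gene and the most highly expressed one is kept.
#'
#' @param path File path.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @param na_policy What to do with missing values: `"error"` (default),
#'   `"drop_gene"` (remove genes with any NA), or `"zero"` (replace by 0).
#' @return Numeric matrix, genes in rows, samples in columns, with unique
#'   row and column names.
#' @export
read_expression <- function(path, delimiter = "\t",
                            na_policy = c("error", "drop_gene", "zero")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("expression file is empty or has no sample columns: ", path)
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in expression header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes <- as.character(df[[1L]])
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyDuplicated(genes)) {
    # collapse duplicate gene rows by per-sample maximum
    x <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(x[i, , drop = FALSE], 2L, max)
    }))
    x <- x[unique(genes), , drop = FALSE]
  } else {
    rownames(x) <- genes
  }
  colnames(x) <- samples
  if (anyNA(x)) {
    x <- switch(na_policy,
      error = stop("missing values in expression matrix (na_policy = \"error\")"),
      drop_gene = x[!apply(is.na(x), 1L, any), , drop = FALSE],
      zero = {x[is.na(x)] <- 0; x}
    )
  }
  validate_expression(x)
  x
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (nrow(x) < 2L) stop("expression matrix needs at least 2 genes")
  if (ncol(x) < 1L) stop("expression matrix needs at least 1 sample")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x)) stop("expression matrix contains missing values")
  invisible(x)
}

comment_header <- function(params) {
  c(sprintf("# stemscore %s", PIPELINE_VERSION()),
    sprintf("# %s=%s", names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), "")))
}

#' Write an expression matrix (or any set x sample grid) as TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them exactly. A `#` comment header records the package
#' version and any parameters supplied.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @param id_column Name of the first (identifier) column.
#' @param params Named list recorded in the comment header.
#' @export
write_expression <- function(x, path, id_column = "gene", params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are removed, preserving first occurrence.
#'
#' @param path GMT file path.
#' @param source_label Provenance label stored as an attribute.
#' @return Named list of character vectors of gene ids, with attribute
#'   `source_label`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(bad, collapse = ", "))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene set(s): ", paste(nm[empty], collapse = ", "))
  attr(sets, "source_label") <- source_label
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field (second GMT column), recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' Expects header columns `sample`, `time`, `event`, plus optional `batch`
#' and `subtype`. Times must be non-negative and in one consistent unit
#' (declared by the caller, never converted); `event` is 1 for an observed
#' death/event and 0 for censoring.
#'
#' @param path TSV file path (`#` comment lines skipped).
#' @return `data.frame` with columns `sample`, `time`, `event` and any
#'   optional columns present.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample <- as.character(df$sample)
  validate_survival(df)
}

validate_survival <- function(df) {
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in survival table")
  if (anyNA(df$time) || any(df$time < 0)) {
    stop("survival times must be non-negative and non-missing")
  }
  if (anyNA(df$event) || !all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)")
  }
  df
}

#' Write a survival table as TSV with a comment header
#' @param surv Survival `data.frame` (see [read_survival()]).
#' @param path Output file path.
#' @param params Named list recorded in the comment header.
#' @export
write_survival <- function(surv, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  write.table(surv, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transform raw counts to TPM (optionally log2)
#'
#' Per sample, each gene's count is divided by its length in kilobases and
#' the rates are rescaled to sum to one million.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Named numeric vector of gene lengths in base pairs;
#'   must cover every gene in `counts`.
#' @param log2_transform If `TRUE`, return `log2(TPM + 1)`.
#' @return Matrix of TPM (or log2(TPM+1)) values, same shape as `counts`.
#' @export
tpm_transform <- function(counts, gene_lengths, log2_transform = FALSE) {
  validate_expression(counts)
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss) > 0L) {
    stop("gene length missing for: ", paste(miss, collapse = ", "))
  }
  len_kb <- gene_lengths[rownames(counts)] / 1000
  if (any(len_kb <= 0)) stop("gene lengths must be positive")
  rate <- counts / len_kb
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ", paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  if (log2_transform) log2(tpm + 1) else tpm
}

#' Remove additive batch effects by per-gene batch-mean centering
#'
#' For each gene, every value has its batch mean subtracted and the
#' unweighted mean of the batch means added back, so after correction all
#' batches share the same per-gene mean while within-batch variation is
#' untouched. This is the per-gene centering used to merge cohorts before
#' enrichment scoring; it assumes values are on a comparable (typically
#' log) scale and adjusts no covariates.
#'
#' @param x Gene x sample expression matrix (log scale recommended).
#' @param batch Character/factor vector of batch labels, one per sample
#'   (recycled against `colnames(x)` by position).
#' @return Corrected matrix, same shape as `x`.
#' @export
batch_center <- function(x, batch) {
  validate_expression(x)
  if (length(batch) != ncol(x)) stop("one batch label per sample is required")
  if (anyNA(batch)) stop("batch labels must not be missing")
  batch <- as.factor(droplevels(as.factor(batch)))
  if (nlevels(batch) < 2L) stop("batch correction needs at least 2 batches")
  # per-gene batch means: genes x batches
  bm <- vapply(levels(batch), function(b)
    rowMeans(x[, batch == b, drop = FALSE]), numeric(nrow(x)))
  grand <- rowMeans(bm)  # unweighted mean of batch means
  x - bm[, as.integer(batch), drop = FALSE] + grand
}

#' Read a Matrix Market sparse cell matrix with row/column id files
#'
#' Convenience loader for the triplet export common in single-cell work:
#' an `.mtx` file plus one-id-per-line gene and barcode files.
#'
#' @param mtx_path Matrix Market file (genes x cells).
#' @param genes_path,barcodes_path Plain-text id files, one id per line.
#' @return Dense numeric matrix, genes x cells.
#' @export
read_expression_mm <- function(mtx_path, genes_path, barcodes_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path, warn = FALSE)
  colnames(m) <- readLines(barcodes_path, warn = FALSE)
  validate_expression(m)
  m
}

#' Report survival samples missing from an expression matrix
#'
#' @param x Expression matrix.
#' @param surv Survival table.
#' @return Character vector of survival sample ids absent from `x`
#'   (invisibly); a message lists them when any are found.
#' @export
report_unmatched <- function(x, surv) {
  miss <- setdiff(surv$sample, colnames(x))
  if (length(miss) > 0L) {
    message(length(miss), " survival sample(s) absent from expression matrix: ",
            paste(utils::head(miss, 10L), collapse = ", "),
            if (length(miss) > 10L) ", ..." else "")
  }
  invisible(miss)
}
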