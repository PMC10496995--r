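#' Read / write a pipeline configuration
#'
#' Configurations are plain YAML with the fields of [run_pipeline()]'s
#' `config` argument; round-tripping through the file is lossless.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message("[stemscore] stage: ", name)
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[stemscore] stage %s done (%.2f s)", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the SGS pipeline end to end
#'
#' Orchestrates enrich (ssGSEA NES) -> screen (univariate Cox per set) ->
#' score (signed SGS) -> stratify (median split) -> survdiff (KM +
#' log-rank) from one configuration, writing `nes.tsv`, `screen.tsv`,
#' `scores.tsv`, `km.tsv` and `manifest.json` to the output directory.
#' Any stage error aborts with the stage name and removes partial
#' outputs.
#'
#' @param config Named list (or YAML path) with fields: `expression`,
#'   `gmt`, `survival` (input file paths), `out_dir`, and optionally
#'   `alpha` (default 0.25), `norm` (`"global_range"`), `p_threshold`
#'   (0.05), `cutoff` (`"median"` or a number for a frozen cutoff),
#'   `na_policy` (`"error"`), `delimiter` (tab).
#' @param quiet Suppress stage messages.
#' @return The run manifest (named list, also written as
#'   `manifest.json`): parameters, input checksums, retained sets by
#'   direction, group sizes, log-rank chi-square and p-value.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  need <- c("expression", "gmt", "survival", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L) stop("config missing field(s): ",
                              paste(miss, collapse = ", "))
  for (f in c("expression", "gmt", "survival")) {
    if (!file.exists(config[[f]])) stop("config input does not exist: ",
                                        config[[f]])
  }
  alpha <- config$alpha %||% 0.25
  norm <- config$norm %||% "global_range"
  p_threshold <- config$p_threshold %||% 0.05
  cutoff <- config$cutoff %||% "median"
  na_policy <- config$na_policy %||% "error"
  delimiter <- config$delimiter %||% "\t"
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- file.path(config$out_dir,
                    c("nes.tsv", "screen.tsv", "scores.tsv", "km.tsv",
                      "manifest.json", "config.yaml"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outs))

  x <- pipeline_stage("load", quiet, {
    read_expression(config$expression, delimiter = delimiter,
                    na_policy = na_policy)
  })
  sets <- pipeline_stage("load", quiet, read_gmt(config$gmt))
  surv <- pipeline_stage("load", quiet, {
    sv <- read_survival(config$survival)
    report_unmatched(x, sv)
    sv
  })
  params <- list(alpha = alpha, norm = norm, p_threshold = p_threshold,
                 cutoff = cutoff)
  enr <- pipeline_stage("enrich", quiet, {
    e <- score_all(x, sets, alpha = alpha, norm = norm)
    write_enrichment(e, outs[1L])
    e
  })
  screen <- pipeline_stage("screen", quiet, {
    sc <- screen_gene_sets(enr, surv, p_threshold = p_threshold,
                           require_retained = TRUE)
    write_screen(sc, outs[2L], params = params)
    sc
  })
  risk <- screen$set[screen$direction == "risk"]
  protective <- screen$set[screen$direction == "protective"]
  scores <- pipeline_stage("score", quiet, {
    sgs <- compute_sgs(enr, risk, protective)
    st <- stratify_median(sgs, cutoff = if (is.numeric(cutoff)) cutoff)
    write_scores(st, outs[3L], params = params)
    st
  })
  surv_matched <- surv[match(scores$sample, surv$sample), , drop = FALSE]
  keep <- !is.na(surv_matched$sample)
  km <- pipeline_stage("survdiff", quiet, {
    sv <- surv_matched[keep, , drop = FALSE]
    grp <- scores$group[keep]
    curves <- lapply(split(seq_len(nrow(sv)), grp), function(i)
      km_estimate(sv[i, , drop = FALSE]))
    lr <- logrank_test(sv, grp)
    write_km(curves, outs[4L], params = params)
    list(curves = curves, logrank = lr)
  })
  manifest <- list(
    pipeline_version = PIPELINE_VERSION(),
    parameters = params,
    inputs = as.list(tools::md5sum(c(expression = config$expression,
                                     gmt = config$gmt,
                                     survival = config$survival))),
    n_samples_scored = nrow(scores),
    retained_sets = list(risk = as.list(risk),
                         protective = as.list(protective)),
    cutoff_used = attr(scores, "cutoff"),
    group_sizes = as.list(table(scores$group)),
    logrank = list(chi2 = km$logrank$chi2, p = km$logrank$p),
    outputs = as.list(basename(outs[1:4]))
  )
  jsonlite::write_json(manifest, outs[5L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_config(config, outs[6L])
  ok <- TRUE
  invisible(manifest)
}
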