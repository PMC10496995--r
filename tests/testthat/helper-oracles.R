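# Independent oracles used across the suite. These deliberately use the
# slow, literal definitions, not the package's vectorized code paths.

# Naive position-by-position ssGSEA walk: at each position of the
# decreasing-rank ordering, accumulate the weighted in-set CDF against the
# uniform out-of-set CDF and sum the differences.
naive_es_walk <- function(ranks, gene_set, alpha) {
  ord <- order(ranks, decreasing = TRUE)
  r <- ranks[ord]
  inset <- names(ranks)[ord] %in% gene_set
  n <- length(r)
  m <- sum(inset)
  stopifnot(m > 0, m < n)
  r_s <- sum(r[inset]^alpha)
  es <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) cum_in <- cum_in + r[i]^alpha else cum_out <- cum_out + 1
    es <- es + cum_in / r_s - cum_out / (n - m)
  }
  unname(es)
}

# Cox partial log-likelihood evaluated from its definition, with Efron or
# Breslow handling of tied event times.
partial_loglik <- function(beta, time, event, x, ties = "efron") {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    deaths <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(deaths)
    sum_risk <- sum(exp(eta[risk]))
    sum_dead <- sum(exp(eta[deaths]))
    ll <- ll + sum(eta[deaths])
    if (ties == "efron") {
      for (l in seq_len(d) - 1L) {
        ll <- ll - log(sum_risk - (l / d) * sum_dead)
      }
    } else {
      ll <- ll - d * log(sum_risk)
    }
  }
  ll
}

# Maximiser of the partial likelihood by 1-D search (independent of any
# Newton iteration).
grid_cox_beta <- function(time, event, x, ties = "efron", bound = 10) {
  stats::optimize(function(b) partial_loglik(b, time, event, x, ties),
                  interval = c(-bound, bound), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Random small ssGSEA instance: continuous expression (no rank ties), one
# random proper subset as the gene set.
random_instance <- function(n_genes, set_size = NULL) {
  genes <- paste0("G", seq_len(n_genes))
  expr <- stats::setNames(rnorm(n_genes), genes)
  if (is.null(set_size)) set_size <- sample(2:(n_genes - 1L), 1L)
  list(ranks = rank(expr), set = sample(genes, set_size), genes = genes)
}

# Tiny two-set collection over a named universe, for io/pipeline tests.
toy_sets <- function() {
  structure(list(UP = c("gA", "gB", "gC"), DOWN = c("gD", "gE")),
            source_label = "toy")
}
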