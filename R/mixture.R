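#' Multinomial mixture model
#'
#' The abstract twin of a WTA network: mixing priors `pi_k` over `K` hidden
#' causes and, for each input group `j`, a `K x V_j` table of conditional
#' probabilities `p_k,j(v)`.
#'
#' @param priors Probability vector of length `K`.
#' @param conditionals List over groups; element `j` is a `K x V_j` matrix
#'   with rows summing to 1.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(priors, conditionals) {
  stopifnot(is.numeric(priors), length(priors) >= 1,
            all(priors >= 0), abs(sum(priors) - 1) < 1e-9,
            is.list(conditionals), length(conditionals) >= 1)
  K <- length(priors)
  for (p in conditionals) {
    stopifnot(is.matrix(p), nrow(p) == K, all(p >= 0),
              all(abs(rowSums(p) - 1) < 1e-9))
  }
  structure(list(priors = as.numeric(priors), conditionals = conditionals,
                 K = K, n_groups = length(conditionals)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K = %d causes, %d groups (values: %s)\n",
              x$K, x$n_groups,
              paste(vapply(x$conditionals, ncol, integer(1)),
                    collapse = " ")))
  cat("  priors:", sprintf("%.3f", x$priors), "\n")
  invisible(x)
}

#' Random mixture model
#'
#' Draws priors and conditional tables from Dirichlet distributions;
#' `concentration < 1` produces well-separated (peaked) conditionals.
#'
#' @param K Number of hidden causes.
#' @param n_values Values per group (integer vector).
#' @param concentration Dirichlet concentration for the conditionals.
#' @param prior_concentration Dirichlet concentration for the priors.
#' @return A [mixture_model()].
#' @export
random_mixture_model <- function(K, n_values, concentration = 0.5,
                                 prior_concentration = 5) {
  rdir <- function(n, a) {
    g <- matrix(stats::rgamma(n * length(a), shape = a), nrow = n,
                byrow = TRUE)
    g / rowSums(g)
  }
  priors <- drop(rdir(1, rep(prior_concentration, K)))
  conds <- lapply(n_values, function(v) rdir(K, rep(concentration, v)))
  mixture_model(priors, conds)
}

#' Sample evidence vectors from a mixture model
#'
#' @param model A [mixture_model()].
#' @param n Number of samples.
#' @param missing_prob Probability that a group's value is masked to `NA`,
#'   independently per (sample, group).
#' @return List with `data` (n x m integer matrix, `NA` = missing) and
#'   `labels` (the generating causes).
#' @export
sample_evidence <- function(model, n, missing_prob = 0) {
  z <- sample.int(model$K, n, replace = TRUE, prob = model$priors)
  m <- model$n_groups
  x <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    p <- model$conditionals[[j]]
    V <- ncol(p)
    # inverse-CDF draw per sample from the row of its cause
    u <- stats::runif(n)
    cum <- t(apply(p, 1, cumsum))
    x[, j] <- 1L + rowSums(u > cum[z, , drop = FALSE] + 1e-15)
  }
  if (missing_prob > 0) {
    x[matrix(stats::runif(n * m) < missing_prob, n, m)] <- NA_integer_
  }
  list(data = x, labels = z)
}

#' Map WTA weights and excitabilities to a mixture model
#'
#' `pi_k = exp(b_k) / sum_l exp(b_l)` and, per group `j`,
#' `p_k,j(v) = exp(w_k,i(j,v)) / sum_{i in G_j} exp(w_k,i)`. Weights need
#' not be normalized; any constant added to all weights of one neuron's
#' group (including the positive-weight offset `log c` and the
#' missing-value offset) cancels in the ratio.
#'
#' @param network A [wta_network()] (or a weight matrix with
#'   `excitabilities` given separately).
#' @param code A [population_code()] whose channels index the weight
#'   columns.
#' @param excitabilities Override for the excitability vector.
#' @return A [mixture_model()].
#' @export
weights_to_model <- function(network, code, excitabilities = NULL) {
  W <- if (is.matrix(network)) network else network$weights
  b <- if (!is.null(excitabilities)) excitabilities else
    network$excitabilities
  stopifnot(ncol(W) == code$n_channels)
  if (any(code$n_values < 1)) stop("empty input group in population code")
  conds <- lapply(seq_len(code$n_groups), function(j) {
    ew <- exp(W[, group_channels(code, j), drop = FALSE])
    ew / rowSums(ew)
  })
  mixture_model(softmax(b), conds)
}

#' Build a WTA network that encodes a mixture model exactly
#'
#' Inverse of [weights_to_model()]: `w = log p + log c`, `b = log pi`.
#'
#' @param model A [mixture_model()].
#' @param code A [population_code()] matching the model's groups.
#' @param offset_c Positive weight offset.
#' @return A [wta_network()].
#' @export
network_from_model <- function(model, code, offset_c = 1) {
  stopifnot(code$n_groups == model$n_groups,
            all(code$n_values ==
                  vapply(model$conditionals, ncol, integer(1))))
  W <- matrix(0, model$K, code$n_channels)
  for (j in seq_len(code$n_groups)) {
    W[, group_channels(code, j)] <- log(model$conditionals[[j]]) +
      log(offset_c)
  }
  wta_network(model$K, code$n_channels, offset_c = offset_c,
              weights = W, excitabilities = log(model$priors))
}

#' Posterior over hidden causes given (possibly partial) evidence
#'
#' `P(k | x) proportional to pi_k * prod_{j observed} p_k,j(x_j)`; missing
#' groups (`NA`) contribute no factor, i.e. they are marginalized out.
#' Computed in log space.
#'
#' @param model A [mixture_model()].
#' @param evidence Integer vector of length `n_groups` with `NA` for
#'   missing groups.
#' @return Probability vector over the `K` causes.
#' @export
posterior <- function(model, evidence) {
  stopifnot(length(evidence) == model$n_groups)
  lp <- log(model$priors)
  for (j in which(!is.na(evidence))) {
    lp <- lp + log(model$conditionals[[j]][, evidence[j]])
  }
  if (all(lp == -Inf)) {
    stop("evidence has zero probability under every cause: ",
         paste(evidence, collapse = ","))
  }
  softmax(lp)
}

#' Log-likelihood of a dataset under a mixture model
#'
#' `sum_n log sum_k pi_k prod_{j observed} p_k,j(x_nj)`, with missing
#' groups dropped from the product. A zero-probability datum contributes
#' `-Inf` with a warning.
#'
#' @param model A [mixture_model()].
#' @param data Integer matrix (`n x n_groups`, `NA` = missing).
#' @return Scalar log-likelihood (natural log).
#' @export
log_likelihood <- function(model, data) {
  data <- matrix(as.integer(data), ncol = model$n_groups)
  ll_n <- datum_log_liks(model, data)
  if (any(ll_n == -Inf)) warning("zero-probability datum in log-likelihood")
  sum(ll_n)
}

# per-datum log p(x); internal
datum_log_liks <- function(model, data) {
  n <- nrow(data); K <- model$K
  lp <- matrix(log(model$priors), n, K, byrow = TRUE)
  for (j in seq_len(model$n_groups)) {
    obs <- !is.na(data[, j])
    if (!any(obs)) next
    lcond <- log(model$conditionals[[j]])  # K x V
    lp[obs, ] <- lp[obs, ] + t(lcond[, data[obs, j], drop = FALSE])
  }
  mx <- apply(lp, 1, max)
  ifelse(mx == -Inf, -Inf, mx + log(rowSums(exp(lp - mx))))
}

#' Fit a multinomial mixture by batch Expectation Maximization
#'
#' Standard EM for the multinomial mixture: the E-step computes
#' responsibilities from the current model (missing groups drop their
#' factors) and the M-step re-estimates priors and conditionals as
#' responsibility-weighted frequencies (data with a missing group are
#' excluded from that group's counts). The log-likelihood is
#' non-decreasing over iterations. This is the exact oracle against which
#' the spike-based learner is compared.
#'
#' @param data Integer matrix (`n x m`, `NA` = missing).
#' @param K Number of mixture components (>= 1).
#' @param n_values Values per group; default inferred from the data.
#' @param n_iter Number of EM iterations.
#' @param seed Optional seed for the random responsibility initialization.
#' @return List with `model` (a [mixture_model()]), `loglik` (trace, one
#'   entry per iteration) and `responsibilities` (final `n x K` matrix).
#' @export
batch_em_fit <- function(data, K, n_values = NULL, n_iter = 50,
                         seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  n <- nrow(data); m <- ncol(data)
  if (n == 0L) stop("empty dataset")
  if (is.null(n_values)) {
    n_values <- apply(data, 2, function(col) max(col, 1L, na.rm = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  # init from random responsibilities (all strictly positive)
  resp <- matrix(stats::rgamma(n * K, shape = 1), n, K)
  resp <- resp / rowSums(resp)
  m_step <- function(resp) {
    priors <- colMeans(resp)
    conds <- lapply(seq_len(m), function(j) {
      obs <- !is.na(data[, j])
      tab <- matrix(0, K, n_values[j])
      for (v in seq_len(n_values[j])) {
        sel <- obs & data[, j] == v
        tab[, v] <- colSums(resp[sel, , drop = FALSE])
      }
      tot <- rowSums(tab)
      # a component with no observed mass in this group: uniform row
      tab[tot == 0, ] <- 1 / n_values[j]
      tot[tot == 0] <- 1
      tab / tot
    })
    mixture_model(priors / sum(priors), conds)
  }
  model <- m_step(resp)
  loglik <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    # E-step
    lp <- matrix(log(model$priors), n, K, byrow = TRUE)
    for (j in seq_len(m)) {
      obs <- !is.na(data[, j])
      if (!any(obs)) next
      lcond <- log(model$conditionals[[j]])
      lp[obs, ] <- lp[obs, ] + t(lcond[, data[obs, j], drop = FALSE])
    }
    mx <- apply(lp, 1, max)
    ll_n <- mx + log(rowSums(exp(lp - mx)))
    loglik[it] <- sum(ll_n)
    resp <- exp(lp - ll_n)
    # M-step
    model <- m_step(resp)
  }
  list(model = model, loglik = loglik, responsibilities = resp)
}
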