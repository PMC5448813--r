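#' Random-effects Bayesian model selection
#'
#' Variational estimation of the population frequencies of K models from a
#' subjects-by-models log-evidence matrix, treating the model identity of
#' each subject as a random effect with a Dirichlet population prior.
#' Iterates the standard fixed point
#' \deqn{u_{nk} \propto \exp\{L_{nk} + \psi(\alpha_k) -
#'   \psi(\textstyle\sum_j \alpha_j)\}, \qquad
#'   \alpha = \alpha_0 + \textstyle\sum_n u_n}
#' with a flat prior \eqn{\alpha_0 = 1} until the counts converge.
#'
#' @param log_evidence Matrix, subjects x models, log evidences in nats.
#' @param alpha0 Prior Dirichlet count per model (default 1).
#' @param max_iter,tol Convergence controls (default 500 iterations,
#'   `max |d alpha| < 1e-6`).
#' @return An object of class `pc_bms`: `alpha` (posterior Dirichlet
#'   counts), `expected_freq` (posterior mean frequencies), `u` (posterior
#'   model assignments per subject), `free_energy` (variational bound on
#'   the group log evidence), `converged`, `iterations`.
#' @examples
#' L <- matrix(c(0, 0, 10, 0), 2, 2)
#' rfx_bms(L)$expected_freq
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, max_iter = 500, tol = 1e-6) {
  L <- as.matrix(log_evidence)
  if (ncol(L) < 2) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(L))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(L); K <- ncol(L)
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  converged <- FALSE
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    w <- sweep(L, 2, elog_r, `+`)
    w <- w - apply(w, 1, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  # variational free energy (ELBO) of the random-effects model
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * elog_r)
  u_safe <- pmax(u, 1e-300)
  f <- sum(u * (L + rep(elog_r, each = n) - log(u_safe))) - kl_dir
  structure(list(alpha = alpha,
                 expected_freq = alpha / sum(alpha),
                 u = u, free_energy = f,
                 converged = converged, iterations = it,
                 log_evidence = L, alpha0 = a0),
            class = "pc_bms")
}

#' @export
print.pc_bms <- function(x, ...) {
  cat("Random-effects BMS over", length(x$alpha), "models\n")
  cat("  alpha:        ", paste(round(x$alpha, 3), collapse = "  "), "\n")
  cat("  expected freq:", paste(round(x$expected_freq, 3), collapse = "  "),
      "\n")
  if (!x$converged) cat("  WARNING: fixed point did not converge\n")
  invisible(x)
}

#' Exceedance probabilities
#'
#' Monte-Carlo estimate of the probability, under the posterior Dirichlet,
#' that each model is the most frequent in the population.
#'
#' @param alpha Posterior Dirichlet counts (from [rfx_bms()]), or a
#'   `pc_bms` object.
#' @param n_samples Dirichlet samples (default 1e6).
#' @param seed Integer seed.
#' @return Vector of exceedance probabilities (sums to 1).
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = NULL) {
  if (inherits(alpha, "pc_bms")) alpha <- alpha$alpha
  if (any(alpha <= 0)) stop("'alpha' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- length(alpha)
  # argmax of Dirichlet draws == argmax of independent Gamma draws
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  tabulate(max.col(g, ties.method = "first"), K) / n_samples
}

#' Protected exceedance probabilities and Bayes omnibus risk
#'
#' Discounts the exceedance probabilities by the posterior probability
#' (Bayes omnibus risk, BOR) that model frequencies are all equal, i.e.
#' that observed evidence differences arose by chance. The null free
#' energy fixes equal frequencies r = 1/K, so
#' \eqn{F_0 = \sum_n \log \frac{1}{K}\sum_k e^{L_{nk}}}; the alternative
#' free energy is the variational bound from [rfx_bms()]. Then
#' \deqn{BOR = \frac{1}{1 + e^{F_1 - F_0}}, \qquad
#'   PXP_k = XP_k (1 - BOR) + BOR / K.}
#'
#' @param log_evidence Subjects-by-models log-evidence matrix.
#' @param bms A `pc_bms` from [rfx_bms()] (computed if `NULL`).
#' @param n_samples,seed Passed to [exceedance_prob()].
#' @return List with `pxp`, `xp`, `bor`, `bms`.
#' @export
protected_exceedance <- function(log_evidence, bms = NULL,
                                 n_samples = 1e6, seed = NULL) {
  L <- as.matrix(log_evidence)
  if (is.null(bms)) bms <- rfx_bms(L)
  K <- ncol(L)
  xp <- exceedance_prob(bms$alpha, n_samples = n_samples, seed = seed)
  # null model: equal frequencies, subjects marginalised over models
  mx <- apply(L, 1, max)
  f0 <- sum(mx + log(rowMeans(exp(L - mx))))
  f1 <- bms$free_energy
  bor <- 1 / (1 + exp(f1 - f0))
  list(pxp = xp * (1 - bor) + bor / K, xp = xp, bor = bor, bms = bms)
}
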