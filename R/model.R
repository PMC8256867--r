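#' Configuration for the variational factor-analysis fit
#'
#' Collects every tunable of [fit_tfa()]. The model decomposes log-normalized
#' expression as `Y = W Z + noise`, with normal priors on the loadings W
#' (variance `1/delta_k` on prior-target entries, `0.001` elsewhere), an
#' automatic-relevance-determination Gamma(1e-3, 1e-3) hyperprior on each
#' factor precision `delta_k`, Beta(0.5, 0.5) priors on the activities Z, and
#' Gamma(1, 1) priors on the per-gene noise scales. Inference is mean-field
#' automatic-differentiation variational inference (ADVI): fully factorized
#' Gaussians on unconstrained transforms (identity for W, logit for Z, log
#' for delta and the noise scales), optimized by stochastic gradient ascent
#' on the ELBO.
#'
#' @param seed integer RNG seed; the fit is bitwise reproducible given it.
#' @param max_iterations maximum gradient steps, default 20000.
#' @param elbo_eval_every evaluate the ELBO every this many steps, default 100.
#' @param elbo_window number of trailing ELBO evaluations averaged in the
#'   convergence check, default 2.
#' @param rel_tol stop when the mean relative ELBO change over the trailing
#'   window falls below this, default 0.01.
#' @param n_posterior_draws posterior sample count used for the reported
#'   means, default 300.
#' @param grad_mc_samples Monte Carlo samples per gradient step, default 1.
#' @param elbo_mc_samples Monte Carlo samples per ELBO evaluation, default 100.
#' @param learning_rate base Adam step size, default 0.05; decays as
#'   `(1 + 1e-3 t)^-0.5`.
#' @param prior_scale_reading `"variance"` (default) reads the second normal
#'   parameter as a variance (`1/delta_k`, `0.001`); `"sd"` reads it as a
#'   standard deviation.
#' @param noise_model `"per_gene"` (default) gives every gene its own noise
#'   scale; `"shared"` uses a single scale.
#' @param center_rows subtract each gene's mean across cells before fitting,
#'   default `FALSE` (the model has no intercept term).
#' @param off_target_scale the near-zero prior variance (or sd, under the
#'   `"sd"` reading) for loadings without ChIP-seq support, default 0.001.
#' @param verbose print iteration/ELBO progress, default `FALSE`.
#' @return A list of class `tfa_config`.
#' @export
model_config <- function(seed = 1L,
                         max_iterations = 20000L,
                         elbo_eval_every = 100L,
                         elbo_window = 2L,
                         rel_tol = 0.01,
                         n_posterior_draws = 300L,
                         grad_mc_samples = 1L,
                         elbo_mc_samples = 100L,
                         learning_rate = 0.05,
                         prior_scale_reading = c("variance", "sd"),
                         noise_model = c("per_gene", "shared"),
                         center_rows = FALSE,
                         off_target_scale = 0.001,
                         verbose = FALSE) {
  prior_scale_reading <- match.arg(prior_scale_reading)
  noise_model <- match.arg(noise_model)
  stopifnot(rel_tol > 0, n_posterior_draws >= 1, max_iterations >= 1,
            elbo_eval_every >= 1, elbo_window >= 1, grad_mc_samples >= 1,
            elbo_mc_samples >= 1, learning_rate > 0, off_target_scale > 0)
  structure(list(seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 elbo_eval_every = as.integer(elbo_eval_every),
                 elbo_window = as.integer(elbo_window),
                 rel_tol = rel_tol,
                 n_posterior_draws = as.integer(n_posterior_draws),
                 grad_mc_samples = as.integer(grad_mc_samples),
                 elbo_mc_samples = as.integer(elbo_mc_samples),
                 learning_rate = learning_rate,
                 prior_scale_reading = prior_scale_reading,
                 noise_model = noise_model,
                 center_rows = isTRUE(center_rows),
                 off_target_scale = off_target_scale,
                 verbose = isTRUE(verbose)),
            class = c("tfa_config", "list"))
}

# Fixed prior hyperparameters (Gamma as shape/rate).
.ard_shape <- 1e-3
.ard_rate <- 1e-3
.beta_a <- 0.5
.beta_b <- 0.5
.noise_shape <- 1
.noise_rate <- 1

#' Fit the prior-structured Bayesian factor-analysis model
#'
#' Decomposes a log-normalized gene x cell matrix `Y` into loadings `W`
#' (genes x TFs) and per-cell TF activities `Z` (TFs x cells), where each
#' column of `W` is gated by the ChIP-seq target-prior mask: entries with
#' prior support get a `N(0, 1/delta_k)` prior whose precision `delta_k` is
#' learned per factor (automatic relevance determination), and entries
#' without support get a near-zero `N(0, 0.001)` prior. Activities have
#' Beta(0.5, 0.5) priors, so `Z` lives in (0, 1). The posterior is
#' approximated by mean-field ADVI; reported `W_mean` and `Z_mean` are means
#' of `n_posterior_draws` draws from the fitted variational posterior.
#'
#' Optimization stops when the mean relative change of the ELBO across the
#' trailing evaluation window drops below `rel_tol`, or at `max_iterations`.
#'
#' @param y an [expression_matrix()] with `state = "log_normalized"`, genes
#'   ordered exactly as `prior$gene_ids`.
#' @param prior a [build_prior_matrix()] result.
#' @param config a [model_config()].
#' @return An object of class `tfa_fit`: `W_mean` (genes x TFs), `Z_mean`
#'   (TFs x cells, entries in (0, 1)), `delta_mean`, `noise_mean`,
#'   `elbo_trace` (data frame: iteration, elbo), `converged`, `config`,
#'   `mask`.
#' @export
fit_tfa <- function(y, prior, config = model_config()) {
  stopifnot(inherits(y, "expr_matrix"), inherits(prior, "target_prior"),
            inherits(config, "tfa_config"))
  if (y$state != "log_normalized")
    stop("fit_tfa expects log-normalized expression")
  if (!identical(y$gene_ids, prior$gene_ids))
    stop("gene ids of the expression matrix and the prior mask must match ",
         "exactly, in order")
  Y <- y$values
  if (any(!is.finite(Y))) stop("non-finite values in expression matrix")
  mask <- prior$mask
  N <- nrow(Y); M <- ncol(Y); K <- ncol(mask)
  if (N < K) stop("need at least as many genes as factors (N >= K)")
  if (M < 2) stop("need at least 2 cells")
  zero_col <- colSums(mask) == 0
  if (any(zero_col))
    stop("all-zero mask column(s): ",
         paste(prior$tf_names[zero_col], collapse = ", "),
         " (unidentifiable factor)")
  if (config$center_rows) Y <- Y - rowMeans(Y)

  set.seed(config$seed)
  variance_reading <- config$prior_scale_reading == "variance"
  per_gene <- config$noise_model == "per_gene"
  v0 <- config$off_target_scale
  off_prec <- if (variance_reading) 1 / v0 else 1 / v0^2
  n1 <- colSums(mask)                       # prior-supported entries per TF
  n_noise <- if (per_gene) N else 1L

  # Variational parameters: mean and log-sd per unconstrained coordinate.
  mu_W <- matrix(0, N, K); om_W <- matrix(log(0.1), N, K)
  mu_Z <- matrix(0, K, M); om_Z <- matrix(log(0.1), K, M)
  mu_d <- rep(0, K);       om_d <- rep(log(0.1), K)
  mu_e <- rep(0, n_noise); om_e <- rep(log(0.1), n_noise)

  # log joint + log |Jacobian|, dropping parameter-free constants
  logjoint <- function(W, Z, d, e) {
    R <- Y - W %*% Z
    ie2 <- 1 / e^2
    ll <- if (per_gene)
      -0.5 * sum(rowSums(R^2) * ie2) - M * sum(log(e))
    else
      -0.5 * sum(R^2) * ie2 - N * M * log(e)
    S <- colSums(mask * W^2)
    S0 <- sum((1 - mask) * W^2)
    lw <- if (variance_reading)
      0.5 * sum(n1 * log(d)) - 0.5 * sum(d * S) - 0.5 * off_prec * S0
    else
      sum(n1 * log(d)) - 0.5 * sum(d^2 * S) - 0.5 * off_prec * S0
    ld <- sum(.ard_shape * log(d) - .ard_rate * d)
    lz <- sum(.beta_a * log(Z) + .beta_b * log1p(-Z))
    le <- sum(.noise_shape * log(e) - .noise_rate * e)
    ll + lw + ld + lz + le
  }

  elbo_const <- {
    n_par <- N * K + K * M + K + n_noise
    lik_c <- -0.5 * N * M * log(2 * pi)
    w_c <- -0.5 * sum(n1) * log(2 * pi) -
      0.5 * (N * K - sum(n1)) *
        log(2 * pi * (if (variance_reading) v0 else v0^2))
    d_c <- K * (.ard_shape * log(.ard_rate) - lgamma(.ard_shape))
    z_c <- -K * M * lbeta(.beta_a, .beta_b)
    e_c <- n_noise * (.noise_shape * log(.noise_rate) - lgamma(.noise_shape))
    ent_c <- 0.5 * n_par * log(2 * pi * exp(1))
    lik_c + w_c + d_c + z_c + e_c + ent_c
  }

  elbo_estimate <- function(n_samples) {
    acc <- 0
    for (s in seq_len(n_samples)) {
      W <- mu_W + exp(om_W) * matrix(stats::rnorm(N * K), N, K)
      Z <- stats::plogis(mu_Z + exp(om_Z) * matrix(stats::rnorm(K * M), K, M))
      d <- exp(mu_d + exp(om_d) * stats::rnorm(K))
      e <- exp(mu_e + exp(om_e) * stats::rnorm(n_noise))
      acc <- acc + logjoint(W, Z, d, e)
    }
    acc / n_samples + sum(om_W) + sum(om_Z) + sum(om_d) + sum(om_e) +
      elbo_const
  }

  # Adam state per parameter block, shaped like the parameter itself
  adam <- function(proto) list(m = proto * 0, v = proto * 0)
  st <- list(mu_W = adam(mu_W), om_W = adam(om_W),
             mu_Z = adam(mu_Z), om_Z = adam(om_Z),
             mu_d = adam(mu_d), om_d = adam(om_d),
             mu_e = adam(mu_e), om_e = adam(om_e))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  adam_step <- function(state, grad, lr, t) {
    state$m <- b1 * state$m + (1 - b1) * grad
    state$v <- b2 * state$v + (1 - b2) * grad^2
    mhat <- state$m / (1 - b1^t)
    vhat <- state$v / (1 - b2^t)
    list(state = state, delta = lr * mhat / (sqrt(vhat) + adam_eps))
  }

  trace_iter <- integer(0)
  trace_elbo <- numeric(0)
  rel_changes <- numeric(0)
  converged <- FALSE
  ns <- config$grad_mc_samples

  for (t in seq_len(config$max_iterations)) {
    gmu_W <- matrix(0, N, K); gom_W <- matrix(0, N, K)
    gmu_Z <- matrix(0, K, M); gom_Z <- matrix(0, K, M)
    gmu_d <- rep(0, K); gom_d <- rep(0, K)
    gmu_e <- rep(0, n_noise); gom_e <- rep(0, n_noise)
    for (s in seq_len(ns)) {
      eW <- matrix(stats::rnorm(N * K), N, K); sW <- exp(om_W)
      eZ <- matrix(stats::rnorm(K * M), K, M); sZ <- exp(om_Z)
      ed <- stats::rnorm(K); sd_ <- exp(om_d)
      ee <- stats::rnorm(n_noise); se <- exp(om_e)
      W <- mu_W + sW * eW
      uZ <- mu_Z + sZ * eZ; Z <- stats::plogis(uZ)
      d <- exp(mu_d + sd_ * ed)
      e <- exp(mu_e + se * ee)

      R <- Y - W %*% Z
      ie2 <- 1 / e^2
      Rw <- R * ie2          # per-gene: length-N ie2 recycles down columns
      # grad wrt W (unconstrained = identity)
      precW <- if (variance_reading)
        sweep(mask, 2L, d, "*") + (1 - mask) * off_prec
      else
        sweep(mask, 2L, d^2, "*") + (1 - mask) * off_prec
      gW <- Rw %*% t(Z) - precW * W
      # grad wrt logit(Z): likelihood chained through Z(1-Z), plus
      # Beta prior + Jacobian which collapse to a - (a+b) Z
      gZ <- (t(W) %*% Rw) * (Z * (1 - Z)) +
        (.beta_a - (.beta_a + .beta_b) * Z)
      # grad wrt log(delta)
      S <- colSums(mask * W^2)
      gd <- if (variance_reading)
        n1 / 2 + .ard_shape - d * (S / 2 + .ard_rate)
      else
        n1 + .ard_shape - d^2 * S - .ard_rate * d
      # grad wrt log(noise scale)
      SS <- rowSums(R^2)
      ge <- if (per_gene)
        -M + SS * ie2 + .noise_shape - .noise_rate * e
      else
        -N * M + sum(SS) * ie2 + .noise_shape - .noise_rate * e
      gmu_W <- gmu_W + gW; gom_W <- gom_W + gW * sW * eW
      gmu_Z <- gmu_Z + gZ; gom_Z <- gom_Z + gZ * sZ * eZ
      gmu_d <- gmu_d + gd; gom_d <- gom_d + gd * sd_ * ed
      gmu_e <- gmu_e + ge; gom_e <- gom_e + ge * se * ee
    }
    inv <- 1 / ns
    lr <- config$learning_rate * (1 + 1e-3 * t)^-0.5
    up <- adam_step(st$mu_W, gmu_W * inv, lr, t)
    st$mu_W <- up$state; mu_W <- mu_W + up$delta
    up <- adam_step(st$om_W, gom_W * inv + 1, lr, t)   # +1: entropy gradient
    st$om_W <- up$state; om_W <- om_W + up$delta
    up <- adam_step(st$mu_Z, gmu_Z * inv, lr, t)
    st$mu_Z <- up$state; mu_Z <- mu_Z + up$delta
    up <- adam_step(st$om_Z, gom_Z * inv + 1, lr, t)
    st$om_Z <- up$state; om_Z <- om_Z + up$delta
    up <- adam_step(st$mu_d, gmu_d * inv, lr, t)
    st$mu_d <- up$state; mu_d <- mu_d + up$delta
    up <- adam_step(st$om_d, gom_d * inv + 1, lr, t)
    st$om_d <- up$state; om_d <- om_d + up$delta
    up <- adam_step(st$mu_e, gmu_e * inv, lr, t)
    st$mu_e <- up$state; mu_e <- mu_e + up$delta
    up <- adam_step(st$om_e, gom_e * inv + 1, lr, t)
    st$om_e <- up$state; om_e <- om_e + up$delta

    if (t %% config$elbo_eval_every == 0L) {
      elbo <- elbo_estimate(config$elbo_mc_samples)
      trace_iter <- c(trace_iter, t)
      trace_elbo <- c(trace_elbo, elbo)
      if (config$verbose)
        message(sprintf("iter %6d  ELBO %.2f", t, elbo))
      ne <- length(trace_elbo)
      if (ne >= 2L) {
        rel_changes <- c(rel_changes,
                         abs((trace_elbo[ne] - trace_elbo[ne - 1L]) /
                               trace_elbo[ne - 1L]))
        if (length(rel_changes) >= config$elbo_window &&
            mean(utils::tail(rel_changes, config$elbo_window)) <
              config$rel_tol) {
          converged <- TRUE
          break
        }
      }
    }
  }

  # Posterior means from draws of the fitted variational distribution
  nd <- config$n_posterior_draws
  W_acc <- matrix(0, N, K); Z_acc <- matrix(0, K, M)
  d_acc <- rep(0, K); e_acc <- rep(0, n_noise)
  for (s in seq_len(nd)) {
    W_acc <- W_acc + mu_W + exp(om_W) * matrix(stats::rnorm(N * K), N, K)
    Z_acc <- Z_acc +
      stats::plogis(mu_Z + exp(om_Z) * matrix(stats::rnorm(K * M), K, M))
    d_acc <- d_acc + exp(mu_d + exp(om_d) * stats::rnorm(K))
    e_acc <- e_acc + exp(mu_e + exp(om_e) * stats::rnorm(n_noise))
  }
  W_mean <- W_acc / nd
  Z_mean <- Z_acc / nd
  dimnames(W_mean) <- list(prior$gene_ids, prior$tf_names)
  dimnames(Z_mean) <- list(prior$tf_names, y$cell_ids)

  structure(list(W_mean = W_mean,
                 Z_mean = Z_mean,
                 delta_mean = stats::setNames(d_acc / nd, prior$tf_names),
                 noise_mean = if (per_gene)
                   stats::setNames(e_acc / nd, prior$gene_ids)
                 else e_acc / nd,
                 elbo_trace = data.frame(iteration = trace_iter,
                                         elbo = trace_elbo),
                 converged = converged,
                 config = config,
                 mask = prior),
            class = "tfa_fit")
}

#' @export
print.tfa_fit <- function(x, ...) {
  cat(sprintf(
    "<tfa_fit> %d genes x %d TFs x %d cells; %s after %d iterations\n",
    nrow(x$W_mean), nrow(x$Z_mean), ncol(x$Z_mean),
    if (x$converged) "converged" else "stopped",
    if (nrow(x$elbo_trace)) max(x$elbo_trace$iteration) else 0L))
  invisible(x)
}

#' Rank a TF's target genes by posterior weight
#'
#' Orders genes by the posterior mean of the TF's loading column: descending
#' for `sign = "positive"` (preferred targets), ascending for
#' `sign = "negative"` (repression-like weights). Ties break by gene id.
#'
#' @param fit a [fit_tfa()] result.
#' @param tf TF name (a column of `W_mean`).
#' @param top_n number of genes to return.
#' @param sign `"positive"` or `"negative"`.
#' @return data frame with columns `gene`, `weight`, strongest first.
#' @export
rank_targets <- function(fit, tf, top_n, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(fit, "tfa_fit"), top_n >= 1)
  if (!tf %in% colnames(fit$W_mean))
    stop("unknown TF: ", tf)
  w <- fit$W_mean[, tf]
  genes <- rownames(fit$W_mean)
  ord <- if (sign == "positive") order(-w, genes) else order(w, genes)
  ord <- utils::head(ord, top_n)
  data.frame(gene = genes[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Reconstruct expression from a fit
#'
#' Returns the posterior-mean reconstruction `W_mean %*% Z_mean`, used for
#' residual diagnostics.
#'
#' @param fit a [fit_tfa()] result.
#' @return gene x cell numeric matrix.
#' @export
reconstruct <- function(fit) {
  stopifnot(inherits(fit, "tfa_fit"))
  fit$W_mean %*% fit$Z_mean
}
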