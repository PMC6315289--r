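# Capture-time-anchored Gaussian-process pseudotime model.
#
# Model: tau_c ~ Normal(k_c, sigma_tau^2) for capture time k_c; for each
# transcript g the (row-centered) expression vector over cells is multivariate
# Normal with covariance psi_g * K0(tau) + omega_g * I, where K0 is the
# squared-exponential kernel exp(-(tau_c - tau_c')^2 / (2 l^2)) with shared
# length-scale l. psi_g (amplitude) and omega_g (noise) carry half-Normal
# priors scaled to each transcript's variance.
#
# The joint posterior is explored with adaptive random-walk
# Metropolis-within-Gibbs. Because K0 is shared across transcripts, a single
# eigendecomposition per tau proposal prices all per-transcript likelihoods:
# with K0 = V diag(lam) V' and a_g = V' y_g, the per-transcript log-likelihood
# is -0.5 * sum_i [ log(psi_g lam_i + omega_g) + a_gi^2 / (psi_g lam_i + omega_g) ].

.sq_exp_kernel <- function(tau, l) {
  d <- outer(tau, tau, "-")
  exp(-d * d / (2 * l * l))
}

# eigen state shared across transcripts for a given tau
.kernel_state <- function(tau, l, tY) {
  e <- eigen(.sq_exp_kernel(tau, l), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(lam = lam, A = crossprod(e$vectors, tY), V = e$vectors)
}

# vector of per-transcript log-likelihoods given eigen state
.gene_logliks <- function(state, psi, omega) {
  d <- outer(state$lam, psi) + rep(omega, each = length(state$lam))
  if (any(d < 1e-300)) return(rep(-Inf, length(psi)))
  -0.5 * (colSums(log(d)) + colSums(state$A * state$A / d)) -
    0.5 * length(state$lam) * log(2 * pi)
}

#' Fit the capture-time-anchored pseudotime model
#'
#' Samples the joint posterior over per-cell pseudotimes and per-transcript
#' kernel amplitude/noise by adaptive Metropolis-within-Gibbs MCMC (see the
#' methods vignette; the model is the standard capture-prior GP pseudotime
#' model, the sampler is this package's own since no gradient-based PPL is
#' assumed). Cells enter the model sorted by cell id so results do not depend
#' on input file order.
#'
#' @param m Working matrix restricted to the analysis transcripts
#'   (transcripts x cells, transformed scale).
#' @param cells Cell records covering every column of `m`.
#' @param config A [run_config()]; uses `sigma_tau_h`, `length_scale_h` and the
#'   `mcmc_*` fields.
#' @return A `pseudotime_fit` list: `tau_hat` (named posterior means, hours),
#'   `tau_draws` (draws x cells), `psi_hat`, `omega_hat`, `offset` (per-gene
#'   mean), `cells`, `diagnostics` (acceptance rates, per-cell effective sample
#'   sizes) and the hyperparameters used.
#' @export
fit_pseudotime <- function(m, cells, config) {
  cells <- align_cells(m, cells)
  if (length(unique(cells$capture_time_h)) < 2L) stop("need >= 2 capture groups")
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  cells <- cells[ord, , drop = FALSE]

  offset <- rowMeans(m)
  Yc <- m - offset
  tY <- t(Yc)                       # cells x transcripts, fixed
  n <- ncol(m); G <- nrow(m)
  k <- cells$capture_time_h
  sigma_tau <- config$sigma_tau_h
  l <- config$length_scale_h
  vg <- pmax(apply(m, 1L, stats::var), 1e-6)   # half-Normal prior scales

  n_iter <- config$mcmc_warmup + config$mcmc_draws
  chains <- max(1L, config$mcmc_chains)

  run_chain <- function(chain_seed) withr::with_seed(chain_seed, {
    tau <- as.numeric(k)
    lpsi <- log(vg / 2); lomega <- log(vg / 2)
    state <- .kernel_state(tau, l, tY)
    ll <- .gene_logliks(state, exp(lpsi), exp(lomega))
    step_tau <- rep(max(sigma_tau / 2, 1e-4), n)
    step_h <- rep(0.4, G)           # shared step shape for psi and omega
    step_h2 <- rep(0.4, G)
    acc_tau <- numeric(n); acc_psi <- 0; acc_omega <- 0
    tau_draws <- matrix(NA_real_, config$mcmc_draws, n,
                        dimnames = list(NULL, colnames(m)))
    psi_sum <- numeric(G); omega_sum <- numeric(G)

    half_norm_lp <- function(x, scale) -x * x / (2 * scale * scale)

    for (it in seq_len(n_iter)) {
      gain <- if (it <= config$mcmc_warmup) min(0.25, 5 / it) else 0
      # --- per-cell pseudotime updates ---
      for (c_ix in sample.int(n)) {
        prop <- tau
        prop[c_ix] <- tau[c_ix] + stats::rnorm(1L, 0, step_tau[c_ix])
        new_state <- .kernel_state(prop, l, tY)
        new_ll <- .gene_logliks(new_state, exp(lpsi), exp(lomega))
        lr <- sum(new_ll) - sum(ll) +
          stats::dnorm(prop[c_ix], k[c_ix], sigma_tau, log = TRUE) -
          stats::dnorm(tau[c_ix], k[c_ix], sigma_tau, log = TRUE)
        acc <- is.finite(lr) && log(stats::runif(1L)) < lr
        if (acc) { tau <- prop; state <- new_state; ll <- new_ll }
        if (gain > 0) step_tau[c_ix] <- step_tau[c_ix] * exp(gain * ((acc) - 0.3))
        if (it > config$mcmc_warmup) acc_tau[c_ix] <- acc_tau[c_ix] + acc
      }
      # --- vectorized amplitude updates ---
      prop <- lpsi + stats::rnorm(G, 0, step_h)
      new_ll <- .gene_logliks(state, exp(prop), exp(lomega))
      lr <- new_ll - ll +
        half_norm_lp(exp(prop), vg) - half_norm_lp(exp(lpsi), vg) +
        prop - lpsi                  # log-scale Jacobian
      acc <- is.finite(lr) & log(stats::runif(G)) < lr
      lpsi[acc] <- prop[acc]; ll[acc] <- new_ll[acc]
      if (gain > 0) step_h <- step_h * exp(gain * (acc - 0.3))
      if (it > config$mcmc_warmup) acc_psi <- acc_psi + mean(acc)
      # --- vectorized noise updates ---
      prop <- lomega + stats::rnorm(G, 0, step_h2)
      new_ll <- .gene_logliks(state, exp(lpsi), exp(prop))
      lr <- new_ll - ll +
        half_norm_lp(exp(prop), vg) - half_norm_lp(exp(lomega), vg) +
        prop - lomega
      acc <- is.finite(lr) & log(stats::runif(G)) < lr
      lomega[acc] <- prop[acc]; ll[acc] <- new_ll[acc]
      if (gain > 0) step_h2 <- step_h2 * exp(gain * (acc - 0.3))
      if (it > config$mcmc_warmup) acc_omega <- acc_omega + mean(acc)

      if (it > config$mcmc_warmup) {
        d_ix <- it - config$mcmc_warmup
        tau_draws[d_ix, ] <- tau
        psi_sum <- psi_sum + exp(lpsi)
        omega_sum <- omega_sum + exp(lomega)
      }
    }
    list(tau_draws = tau_draws,
         psi_hat = psi_sum / config$mcmc_draws,
         omega_hat = omega_sum / config$mcmc_draws,
         acc_tau = acc_tau / config$mcmc_draws,
         acc_psi = acc_psi / config$mcmc_draws,
         acc_omega = acc_omega / config$mcmc_draws)
  })

  res <- lapply(seq_len(chains), function(ch) run_chain(config$mcmc_seed + ch - 1L))
  tau_draws <- do.call(rbind, lapply(res, `[[`, "tau_draws"))
  tau_hat <- colMeans(tau_draws)
  ess <- apply(tau_draws, 2L, .ess)
  diagnostics <- list(
    accept_tau = rowMeans(vapply(res, `[[`, numeric(n), "acc_tau")),
    accept_psi = mean(vapply(res, `[[`, numeric(1L), "acc_psi")),
    accept_omega = mean(vapply(res, `[[`, numeric(1L), "acc_omega")),
    ess_tau = ess, min_ess_tau = min(ess),
    divergences = NA_integer_)       # not defined for MH; kept for interface parity
  structure(list(
    tau_hat = tau_hat, tau_draws = tau_draws,
    psi_hat = stats::setNames(Reduce(`+`, lapply(res, `[[`, "psi_hat")) / chains, rownames(m)),
    omega_hat = stats::setNames(Reduce(`+`, lapply(res, `[[`, "omega_hat")) / chains, rownames(m)),
    offset = offset, cells = cells, sigma_tau_h = sigma_tau,
    length_scale_h = l, genes = rownames(m),
    diagnostics = diagnostics), class = "pseudotime_fit")
}

# initial-monotone-sequence flavoured effective sample size
.ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1L]
  pos <- which(rho < 0.05)
  cut <- if (length(pos)) pos[1L] - 1L else length(rho)
  n / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' @export
print.pseudotime_fit <- function(x, ...) {
  cat("pseudotime_fit:", length(x$tau_hat), "cells,", length(x$genes),
      "transcripts\n")
  cat("  sigma_tau =", x$sigma_tau_h, "h; length-scale =", x$length_scale_h, "h\n")
  cat("  tau_hat range:", sprintf("%.1f .. %.1f h", min(x$tau_hat), max(x$tau_hat)), "\n")
  cat("  min ESS(tau):", sprintf("%.0f", x$diagnostics$min_ess_tau), "\n")
  invisible(x)
}

#' Roughness of an expression profile under an ordering
#'
#' Root mean squared successive difference:
#' `R = sqrt( (1/(N-1)) * sum_i (x_(i+1) - x_(i))^2 )` with `(i)` indexing
#' cells in the given ordering. Smooth orderings have low roughness.
#'
#' @param profile Per-cell expression values.
#' @param ordering Permutation of `seq_along(profile)`; default identity.
#' @return Non-negative scalar.
#' @export
roughness <- function(profile, ordering = seq_along(profile)) {
  n <- length(profile)
  if (n < 2L) stop("roughness needs >= 2 cells")
  if (length(ordering) != n || !setequal(ordering, seq_len(n))) {
    stop("ordering must be a permutation of the profile indices")
  }
  sqrt(mean(diff(profile[ordering])^2))
}

# mean over transcripts of per-transcript roughness; X is transcripts x cells
.mean_roughness <- function(X, ordering) {
  Xo <- X[, ordering, drop = FALSE]
  D <- Xo[, -1L, drop = FALSE] - Xo[, -ncol(Xo), drop = FALSE]
  mean(sqrt(rowMeans(D * D)))
}

#' Permutation roughness test of an inferred cell ordering
#'
#' The observed statistic is the mean per-transcript roughness when cells are
#' ordered by `tau_hat` (ties broken by cell id). The null distribution comes
#' from `n_perm` uniformly random orderings; the add-one estimator
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)` never reports zero and
#' counts ties against the alternative.
#'
#' @param m Working matrix (transcripts x cells).
#' @param tau_hat Named pseudotime estimates covering the columns of `m`.
#' @param n_perm Number of random orderings (>= 1).
#' @param seed Optional RNG seed for the permutations.
#' @return List: `statistic`, `p_value`, `null` (the null draws), `n_perm`,
#'   `seed`.
#' @export
roughness_permutation_test <- function(m, tau_hat, n_perm = 999L, seed = NULL) {
  if (ncol(m) < 3L) stop("roughness test needs >= 3 cells")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(names(tau_hat)) || !all(colnames(m) %in% names(tau_hat))) {
    stop("tau_hat must be named and cover every cell in the matrix")
  }
  tau <- tau_hat[colnames(m)]
  obs_ord <- order(tau, colnames(m))
  observed <- .mean_roughness(m, obs_ord)
  draw_null <- function() {
    vapply(seq_len(n_perm),
           function(i) .mean_roughness(m, sample.int(ncol(m))), numeric(1L))
  }
  null <- if (is.null(seed)) draw_null() else withr::with_seed(seed, draw_null())
  p <- (1 + sum(null <= observed)) / (n_perm + 1)
  list(statistic = observed, p_value = p, null = null,
       n_perm = as.integer(n_perm), seed = seed)
}
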