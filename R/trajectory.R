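# Per-transcript GP expression trajectories over inferred pseudotimes, and the
# KL-divergence statistic between trajectory posteriors at representative
# start/end pseudotimes.

#' Representative start and end pseudotimes
#'
#' Medians of the pseudotime estimates over the first and last capture groups
#' (naive ESCs and 48 h EpiLCs in the motivating design). Even-sized groups
#' take the mean of the two middle values (the usual sample median).
#'
#' @param tau_hat Named per-cell pseudotimes, or a `pseudotime_fit`.
#' @param cells Cell records for those cells.
#' @param start_h,end_h Capture times defining the two groups; default the
#'   smallest and largest capture time present.
#' @return Numeric `c(t_start, t_end)`.
#' @export
representative_pseudotimes <- function(tau_hat, cells, start_h = NULL, end_h = NULL) {
  if (inherits(tau_hat, "pseudotime_fit")) tau_hat <- tau_hat$tau_hat
  if (is.null(start_h)) start_h <- min(cells$capture_time_h)
  if (is.null(end_h)) end_h <- max(cells$capture_time_h)
  grp <- function(h, label) {
    ids <- cells$cell_id[cells$capture_time_h == h]
    if (!length(ids)) stop("no cells in the ", label, " capture group (", h, " h)")
    stats::median(tau_hat[ids])
  }
  c(t_start = grp(start_h, "start"), t_end = grp(end_h, "end"))
}

# negative log marginal likelihood on the eigenbasis of K0
.gp_nll <- function(lpar, lam, a) {
  d <- exp(lpar[1L]) * lam + exp(lpar[2L])
  if (any(d < 1e-300)) return(Inf)
  0.5 * (sum(log(d)) + sum(a * a / d)) + 0.5 * length(a) * log(2 * pi)
}

#' Fit a GP expression trajectory for one transcript
#'
#' Standard GP regression of expression on pseudotime with a
#' squared-exponential kernel whose length-scale is fixed (shared with the
#' pseudotime model); amplitude `psi` and observation noise `omega` are fitted
#' by maximizing the marginal likelihood unless supplied. The per-transcript
#' mean offset is the sample mean.
#'
#' @param expr Expression values (working scale), one per cell.
#' @param tau_hat Pseudotimes, same length and order as `expr`.
#' @param length_scale Kernel length-scale (hours).
#' @param psi,omega Fixed hyperparameters; when `NULL` (default) both are
#'   fitted by marginal likelihood.
#' @param gene Gene id used in error messages.
#' @return A `gene_trajectory` object; evaluate it with
#'   [predict_trajectory()].
#' @export
fit_gene_trajectory <- function(expr, tau_hat, length_scale,
                                psi = NULL, omega = NULL, gene = "gene") {
  if (length(expr) != length(tau_hat)) stop("expr and tau_hat lengths differ")
  if (length(expr) < 3L) stop("need >= 3 cells to fit a trajectory")
  offset <- mean(expr)
  yc <- expr - offset
  e <- eigen(.sq_exp_kernel(tau_hat, length_scale), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  a <- drop(crossprod(e$vectors, yc))
  if (is.null(psi) || is.null(omega)) {
    v <- max(stats::var(expr), 1e-8)
    init <- log(c(psi %||% (v / 2), omega %||% (v / 2)))
    fixed_psi <- !is.null(psi); fixed_omega <- !is.null(omega)
    obj <- function(p) {
      lp <- init
      lp[c(!fixed_psi, !fixed_omega)] <- p
      .gp_nll(lp, lam, a)
    }
    free <- c(!fixed_psi, !fixed_omega)
    if (sum(free) == 2L) {
      opt <- stats::optim(init[free], obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 5000L))
    } else {
      o <- stats::optimize(function(p) obj(p), interval = c(-25, 15), tol = 1e-10)
      opt <- list(par = o$minimum, value = o$objective)
    }
    if (!is.finite(opt$value)) {
      stop("non-finite marginal likelihood while fitting trajectory for ", gene)
    }
    lp <- init; lp[free] <- opt$par
    psi <- exp(lp[1L]); omega <- exp(lp[2L])
    logml <- -opt$value
  } else {
    logml <- -.gp_nll(log(c(psi, omega)), lam, a)
    if (!is.finite(logml)) {
      stop("non-finite marginal likelihood while fitting trajectory for ", gene)
    }
  }
  structure(list(gene = gene, tau = tau_hat, offset = offset,
                 psi = psi, omega = omega, length_scale = length_scale,
                 lam = lam, V = e$vectors, a = a, logml = logml),
            class = "gene_trajectory")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate a fitted trajectory posterior
#'
#' Returns the posterior mean and sd of the trajectory at new pseudotimes.
#' `type = "latent"` (default) gives the noise-free latent function;
#' `"predictive"` adds the observation noise variance.
#'
#' @param traj A `gene_trajectory`.
#' @param t Pseudotimes (hours) at which to evaluate.
#' @param type `"latent"` or `"predictive"`.
#' @return data.frame with columns `t`, `mu`, `s`.
#' @export
predict_trajectory <- function(traj, t, type = c("latent", "predictive")) {
  type <- match.arg(type)
  d <- traj$psi * traj$lam + traj$omega
  out <- vapply(t, function(tt) {
    kstar <- traj$psi * exp(-(tt - traj$tau)^2 / (2 * traj$length_scale^2))
    b <- drop(crossprod(traj$V, kstar))
    mu <- traj$offset + sum(b * traj$a / d)
    v <- traj$psi - sum(b * b / d)
    if (type == "predictive") v <- v + traj$omega
    c(mu, sqrt(max(v, 0)))
  }, numeric(2L))
  data.frame(t = t, mu = out[1L, ], s = out[2L, ])
}

#' @export
print.gene_trajectory <- function(x, ...) {
  cat(sprintf("gene_trajectory '%s': %d cells, psi=%.4g, omega=%.4g, l=%g h\n",
              x$gene, length(x$tau), x$psi, x$omega, x$length_scale))
  invisible(x)
}

#' KL divergence between two univariate Gaussians
#'
#' `KL(N(mu1, s1^2) || N(mu2, s2^2)) =
#'  ln(s2/s1) + (s1^2 + (mu1 - mu2)^2) / (2 s2^2) - 1/2`, in nats.
#'
#' @param mu1,s1 Mean and sd of the first Gaussian (`s1 > 0`).
#' @param mu2,s2 Mean and sd of the second Gaussian (`s2 > 0`).
#' @return Non-negative divergence in nats. Vectorized.
#' @export
gaussian_kl <- function(mu1, s1, mu2, s2) {
  if (any(s1 <= 0) || any(s2 <= 0)) stop("standard deviations must be positive")
  log(s2 / s1) + (s1^2 + (mu1 - mu2)^2) / (2 * s2^2) - 0.5
}

#' KL-divergence expression change of one trajectory
#'
#' Evaluates the trajectory posterior at the representative start and end
#' pseudotimes and returns the KL divergence between the two Gaussians, in the
#' configured direction. Symmetrized = `0.5 * (KL(start||end) + KL(end||start))`.
#'
#' @param traj A `gene_trajectory`.
#' @param t_start,t_end Representative pseudotimes (hours).
#' @param direction `"symmetrized"` (default), `"start_to_end"` or
#'   `"end_to_start"`.
#' @param type Posterior type passed to [predict_trajectory()].
#' @return List: `D` (nats), `mu_start`, `s_start`, `mu_end`, `s_end`.
#' @export
kl_expression_change <- function(traj, t_start, t_end,
                                 direction = c("symmetrized", "start_to_end",
                                               "end_to_start"),
                                 type = c("latent", "predictive")) {
  direction <- match.arg(direction)
  type <- match.arg(type)
  p <- predict_trajectory(traj, c(t_start, t_end), type = type)
  kl12 <- gaussian_kl(p$mu[1L], p$s[1L], p$mu[2L], p$s[2L])
  kl21 <- gaussian_kl(p$mu[2L], p$s[2L], p$mu[1L], p$s[1L])
  D <- switch(direction,
              start_to_end = kl12,
              end_to_start = kl21,
              symmetrized = 0.5 * (kl12 + kl21))
  list(D = D, mu_start = p$mu[1L], s_start = p$s[1L],
       mu_end = p$mu[2L], s_end = p$s[2L])
}

#' Rank transcripts by KL divergence
#'
#' Descending divergence; ties broken by ascending gene id; rank 1 is the
#' largest divergence.
#'
#' @param records data.frame with columns `gene` and `D`.
#' @return The data.frame sorted with an added `rank` column.
#' @export
rank_transcripts <- function(records) {
  if (anyNA(records$D)) stop("divergence missing for some transcripts")
  ord <- order(-records$D, records$gene)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit trajectories and rank all transcripts by KL divergence
#'
#' Pipeline stage chaining [representative_pseudotimes()],
#' [fit_gene_trajectory()] (fresh marginal-likelihood fit per transcript,
#' pseudotimes fixed at their point estimates) and [kl_expression_change()],
#' then [rank_transcripts()].
#'
#' @param m Working matrix (all transcripts to rank).
#' @param tau_hat Named per-cell pseudotimes (or a `pseudotime_fit`).
#' @param cells Cell records.
#' @param config A [run_config()]; uses `length_scale_h`, `kl_direction`,
#'   `kl_latent`.
#' @return Ranked data.frame: gene, D (nats), rank, mu/s at both endpoints,
#'   t_start, t_end, direction.
#' @export
kl_rank_transcripts <- function(m, tau_hat, cells, config) {
  if (inherits(tau_hat, "pseudotime_fit")) tau_hat <- tau_hat$tau_hat
  rep_t <- representative_pseudotimes(tau_hat, cells)
  tau <- tau_hat[colnames(m)]
  type <- if (config$kl_latent) "latent" else "predictive"
  rows <- lapply(rownames(m), function(g) {
    traj <- fit_gene_trajectory(m[g, ], tau, config$length_scale_h, gene = g)
    kl <- kl_expression_change(traj, rep_t[1L], rep_t[2L],
                               direction = config$kl_direction, type = type)
    data.frame(gene = g, D = kl$D, mu_start = kl$mu_start, s_start = kl$s_start,
               mu_end = kl$mu_end, s_end = kl$s_end, stringsAsFactors = FALSE)
  })
  out <- rank_transcripts(do.call(rbind, rows))
  out$t_start <- rep_t[1L]; out$t_end <- rep_t[2L]
  out$direction <- config$kl_direction
  out
}
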