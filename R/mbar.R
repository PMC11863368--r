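#' Multistate Bennett acceptance ratio (MBAR) estimator
#'
#' Estimates the dimensionless free energy of every state from pooled reduced
#' potentials by solving the MBAR self-consistency equations
#' \deqn{f_i = -\log \sum_n \frac{\exp(-u_{i,n})}{\sum_k N_k \exp(f_k - u_{k,n})}}
#' with all exponential sums evaluated through log-sum-exp (overflow safety is
#' part of the contract, not an optimisation). The solver runs self-consistent
#' iteration with Newton acceleration on the equivalent convex objective,
#' starting from `f = 0`, until the largest self-consistent update falls below
#' `tolerance`. Free energies are anchored at `f[1] = 0`.
#'
#' The asymptotic covariance of the estimates is computed from the normalised
#' weight matrix `W` (`W[n, k] = exp(f_k - u_{k,n}) / sum_j N_j exp(f_j -
#' u_{j,n})`) via the spectral form of `W^T (I - W N W^T)^+ W`, evaluated in
#' K x K space from the eigendecomposition of `W^T W`.
#'
#' @param data a [reduced_potentials()] object (or a plain K x N matrix, in
#'   which case `n_k` must be supplied).
#' @param n_k sample counts per state when `data` is a bare matrix.
#' @param tolerance convergence tolerance on the maximum free-energy residual
#'   (kT), default 1e-8.
#' @param max_iterations iteration cap; non-convergence is an error that
#'   reports the final residual.
#' @param compute_covariance set `FALSE` to skip the covariance (faster for
#'   repeated calibration fits).
#' @return An object of class `"mbar"` with components `f` (kT, anchored),
#'   `covariance` (anchored covariance matrix, kT^2), `W` (N x K weight
#'   matrix), `n_k`, `lambdas`, `temperature`, `iterations`, `residual`.
#'   Methods: [coef.mbar()], [vcov.mbar()], [summary.mbar()], [delta_f()].
#' @examples
#' sys <- gen_harmonic_alchemy(c(1, 4), n_samples = 2000, seed = 7)
#' fit <- mbar(sys$potentials)
#' delta_f(fit)  # close to log(4)/2 = 0.693
#' @export
mbar <- function(data, n_k = NULL, tolerance = 1e-8, max_iterations = 10000,
                 compute_covariance = TRUE) {
  if (!inherits(data, "reduced_potentials")) {
    if (is.null(n_k)) stop("supply a reduced_potentials object or 'n_k'", call. = FALSE)
    data <- reduced_potentials(data, n_k)
  }
  u <- data$u
  nk <- data$n_k
  if (all(nk == 0L)) stop("at least one state must be sampled", call. = FALSE)
  k <- nrow(u)
  n <- ncol(u)
  sampled <- nk > 0L
  log_nk <- ifelse(sampled, log(nk), -Inf)

  f <- numeric(k)
  # One self-consistent sweep: returns the updated (anchored) f.
  sc_update <- function(f) {
    log_denom <- col_logsumexp(log_nk + f - u)      # length n
    fn <- -vapply(seq_len(k), function(i) logsumexp(-u[i, ] - log_denom),
                  numeric(1))
    fn - fn[1L]
  }

  residual <- Inf
  iter <- 0L
  newton_ok <- TRUE
  while (iter < max_iterations) {
    iter <- iter + 1L
    f_new <- sc_update(f)
    residual <- max(abs(f_new - f))
    if (!all(is.finite(f_new))) {
      stop("MBAR update produced non-finite free energies", call. = FALSE)
    }
    f <- f_new
    if (residual <= tolerance) break
    # Newton acceleration on the convex objective once the iterates settle.
    if (newton_ok && residual < 1) {
      step <- tryCatch(.mbar_newton_step(u, nk, f), error = function(e) NULL)
      if (is.null(step)) {
        newton_ok <- FALSE
      } else {
        f_try <- f + step
        f_try <- f_try - f_try[1L]
        f_chk <- sc_update(f_try)
        res_try <- max(abs(f_chk - f_try))
        if (is.finite(res_try) && res_try < residual) {
          f <- f_chk
          residual <- res_try
          if (residual <= tolerance) break
        }
      }
    }
  }
  if (residual > tolerance) {
    stop(sprintf("MBAR did not converge in %d iterations (residual %.3e > %.3e)",
                 iter, residual, tolerance), call. = FALSE)
  }

  log_denom <- col_logsumexp(log_nk + f - u)
  w <- exp(t(f - u) - log_denom)                    # N x K, colSums = 1 (sampled)
  eff <- colSums(w)
  if (any(sampled & eff < 1e-12)) {
    stop(sprintf("state %s has zero effective samples; covariance is singular",
                 paste(which(sampled & eff < 1e-12), collapse = ", ")),
         call. = FALSE)
  }

  covariance <- if (compute_covariance) .mbar_covariance(w, nk) else NULL

  structure(
    list(f = f, covariance = covariance, W = w, n_k = nk,
         lambdas = data$lambdas, temperature = data$temperature,
         iterations = iter, residual = residual, tolerance = tolerance),
    class = "mbar"
  )
}

# Newton step for the convex MBAR objective
#   F(f) = sum_n log(sum_k N_k exp(f_k - u_kn)) - sum_k N_k f_k,
# solved in the K-1 coordinates with f_1 pinned at 0.
.mbar_newton_step <- function(u, nk, f) {
  k <- nrow(u)
  log_nk <- ifelse(nk > 0L, log(nk), -Inf)
  log_denom <- col_logsumexp(log_nk + f - u)
  w <- exp(t(f - u) - log_denom)                    # N x K (no N_k factor)
  wn <- sweep(w, 2L, nk, "*")                       # N_k * w
  grad <- colSums(wn) - nk
  hess <- -crossprod(wn)                            # - sum_n (N w)(N w)^T
  diag(hess) <- diag(hess) + colSums(wn)
  free <- 2:k
  step <- numeric(k)
  step[free] <- solve(hess[free, free, drop = FALSE], -grad[free])
  step
}

# Asymptotic covariance of the anchored free energies from the weight matrix.
.mbar_covariance <- function(w, nk) {
  k <- ncol(w)
  a <- crossprod(w)                                 # K x K, = V S^2 V^T
  e <- eigen(a, symmetric = TRUE)
  s <- sqrt(pmax(e$values, 0))
  v <- e$vectors
  inner <- diag(k) - (s * t(v)) %*% (nk * v) %*% diag(s, k)
  inner <- (inner + t(inner)) / 2
  ei <- eigen(inner, symmetric = TRUE)
  keep <- ei$values > max(ei$values, 1) * 1e-10
  pinv <- ei$vectors[, keep, drop = FALSE] %*%
    (t(ei$vectors[, keep, drop = FALSE]) / ei$values[keep])
  theta <- v %*% diag(s, k) %*% pinv %*% diag(s, k) %*% t(v)
  # anchor at state 1: cov(f_i - f_1, f_j - f_1)
  cov_anchored <- theta - outer(theta[, 1L], rep(1, k)) -
    outer(rep(1, k), theta[1L, ]) + theta[1L, 1L]
  cov_anchored <- (cov_anchored + t(cov_anchored)) / 2
  cov_anchored[1L, ] <- 0
  cov_anchored[, 1L] <- 0
  cov_anchored
}

#' Free-energy difference between two states of an MBAR fit
#'
#' @param fit an `"mbar"` object.
#' @param from,to state indices (default: first to last).
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @return Named vector with `df` and its standard error `se`.
#' @export
delta_f <- function(fit, from = 1L, to = length(fit$f), units = c("kT", "kJ/mol")) {
  stopifnot(inherits(fit, "mbar"))
  units <- match.arg(units)
  df <- fit$f[to] - fit$f[from]
  se <- if (is.null(fit$covariance)) NA_real_ else {
    v <- fit$covariance[from, from] + fit$covariance[to, to] -
      2 * fit$covariance[from, to]
    sqrt(max(v, 0))
  }
  out <- c(df = df, se = se)
  if (units == "kJ/mol") out <- kt_to_kjmol(out, fit$temperature)
  out
}

#' @export
coef.mbar <- function(object, ...) {
  stats::setNames(object$f, paste0("f", seq_along(object$f)))
}

#' @export
vcov.mbar <- function(object, ...) object$covariance

#' @export
print.mbar <- function(x, ...) {
  d <- delta_f(x)
  cat(sprintf("MBAR fit: %d states, %d samples; converged in %d iterations (residual %.2e)\n",
              length(x$f), nrow(x$W), x$iterations, x$residual))
  cat(sprintf("  total delta f = %.4f +/- %.4f kT (%.3f +/- %.3f kJ/mol at %g K)\n",
              d["df"], d["se"],
              kt_to_kjmol(d["df"], x$temperature),
              kt_to_kjmol(d["se"], x$temperature), x$temperature))
  invisible(x)
}

#' @export
summary.mbar <- function(object, ...) {
  se <- if (is.null(object$covariance)) rep(NA_real_, length(object$f)) else
    sqrt(pmax(diag(object$covariance), 0))
  out <- data.frame(
    state = seq_along(object$f),
    lambda = object$lambdas,
    n_samples = object$n_k,
    f_kT = object$f,
    se_kT = se,
    f_kjmol = kt_to_kjmol(object$f, object$temperature),
    se_kjmol = kt_to_kjmol(se, object$temperature)
  )
  class(out) <- c("summary.mbar", "data.frame")
  out
}

#' Extract an MBAR fit as a [free_energy_set()]
#'
#' @param fit an `"mbar"` object with covariance.
#' @return A [free_energy_set()].
#' @export
as_free_energy_set <- function(fit) {
  stopifnot(inherits(fit, "mbar"))
  free_energy_set(fit$f, fit$covariance, fit$temperature)
}
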