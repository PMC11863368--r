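# Two-state reference estimators: exponential averaging (Zwanzig) and the
# Bennett acceptance ratio. In this package they serve as analytic baselines
# and cross-checks for the MBAR solver.

#' Exponential (Zwanzig) free-energy average
#'
#' `delta f = -log(mean(exp(-w)))` for dimensionless work samples `w`,
#' evaluated through log-sum-exp so that large work values cannot overflow.
#' For Gaussian work with mean `mu` and variance `s2`, the large-sample limit
#' is `mu - s2/2`.
#'
#' @param w numeric vector of dimensionless work samples (at least one,
#'   all finite).
#' @return The free-energy difference in kT.
#' @export
exp_estimate <- function(w) {
  w <- as.numeric(w)
  if (length(w) < 1L) stop("'w' must contain at least one sample", call. = FALSE)
  if (any(!is.finite(w))) stop("'w' must be finite", call. = FALSE)
  -(logsumexp(-w) - log(length(w)))
}

#' Bennett acceptance ratio (BAR) for a pair of states
#'
#' Solves the Bennett implicit equation for the dimensionless free-energy
#' difference between two states from forward work samples (drawn in state 0,
#' evaluated as `u_1 - u_0`) and reverse work samples (drawn in state 1,
#' evaluated as `u_0 - u_1`):
#' \deqn{\sum_F \frac{1}{1 + e^{M + w_F - \Delta f}} =
#'       \sum_R \frac{1}{1 + e^{-M + w_R + \Delta f}}, \quad M = \log N_F/N_R.}
#' The left-hand side minus the right-hand side is monotone in `delta f`, so
#' the root is found by bisection/secant via [stats::uniroot()] on an
#' automatically expanded bracket. All sums use log-sum-exp.
#'
#' @param w_forward,w_reverse dimensionless work samples in the two
#'   directions; both non-empty and finite.
#' @param tolerance root tolerance in kT (default 1e-10).
#' @return The free-energy difference `delta f` (state 0 to state 1) in kT.
#' @export
bar_estimate <- function(w_forward, w_reverse, tolerance = 1e-10) {
  wf <- as.numeric(w_forward)
  wr <- as.numeric(w_reverse)
  if (length(wf) < 1L || length(wr) < 1L) {
    stop("both work directions must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(wf)) || any(!is.finite(wr))) {
    stop("work samples must be finite", call. = FALSE)
  }
  m <- log(length(wf) / length(wr))
  # g(x) = log sum_F fermi(x - wf - m) - log sum_R fermi(wr + m - x), increasing.
  g <- function(x) {
    logsumexp(-log1pexp(m + wf - x)) - logsumexp(-log1pexp(-m + wr + x))
  }
  # bracket around the two one-directional EXP estimates
  cand <- c(exp_estimate(wf), -exp_estimate(wr))
  lo <- min(cand) - 1
  hi <- max(cand) + 1
  while (g(lo) > 0) lo <- lo - 2 * (hi - lo + 1)
  while (g(hi) < 0) hi <- hi + 2 * (hi - lo + 1)
  stats::uniroot(g, c(lo, hi), tol = tolerance, maxiter = 10000L)$root
}

#' MBAR state-overlap matrix
#'
#' The row-stochastic matrix `O[i, j] = sum_n W[n, i] * W[n, j] * N_j` of
#' expected sampling weights: row `i` gives the probability that a sample
#' effectively drawn from state `i`'s reweighted distribution originated in
#' each state. Identical states give every entry `1/K` (equal sample counts);
#' vanishing off-diagonal entries flag disjoint neighbours.
#'
#' @param fit a converged [mbar()] fit.
#' @return K x K numeric matrix; each row sums to 1.
#' @export
overlap_matrix <- function(fit) {
  stopifnot(inherits(fit, "mbar"))
  crossprod(fit$W) %*% diag(fit$n_k, length(fit$n_k))
}

#' Wu-Kofke overlap bias measure for a pair of states
#'
#' A scalar diagnostic of whether the samples of two neighbouring lambda
#' states overlap well enough for reliable free-energy estimation. For the
#' direction that samples state a and targets state b it evaluates
#' \deqn{\Pi_{a \to b} = \sqrt{2 \ln N_a} - \sqrt{2 s_a},}
#' where `N_a` is the number of samples in state a and `s_a` is the relative
#' entropy (dissipated reduced work) of state a with respect to state b,
#' estimated as the mean forward reduced work minus the BAR free-energy
#' difference. The reported value is the minimum over the two directions --
#' the measure grows with sampling and shrinks as the distributions separate.
#' Values below 0.5 indicate inadequate overlap; following common practice
#' the pair is then flagged with a recommendation to insert an additional
#' lambda window between the two states (the boundary `Pi = 0.5` itself
#' passes).
#'
#' @param data a [reduced_potentials()] object.
#' @param pair integer vector of two state indices (default the first two).
#' @return Object of class `"pi_bias"`: list with `pi`, `adequate`
#'   (`pi >= 0.5`), the per-direction values, `delta_f`, and `recommendation`
#'   (non-`NULL` only when inadequate).
#' @export
pi_bias_measure <- function(data, pair = c(1L, 2L)) {
  stopifnot(inherits(data, "reduced_potentials"))
  pair <- as.integer(pair)
  if (length(pair) != 2L || any(pair < 1L) || any(pair > nrow(data$u))) {
    stop("'pair' must index two states of the set", call. = FALSE)
  }
  a <- pair[1L]; b <- pair[2L]
  na <- data$n_k[a]; nb <- data$n_k[b]
  if (na < 10L || nb < 10L) {
    stop("the bias measure is undefined below 10 samples per state", call. = FALSE)
  }
  offsets <- c(0L, cumsum(data$n_k))
  idx_a <- (offsets[a] + 1L):(offsets[a] + na)
  idx_b <- (offsets[b] + 1L):(offsets[b] + nb)
  w_f <- data$u[b, idx_a] - data$u[a, idx_a]   # sampled in a, toward b
  w_r <- data$u[a, idx_b] - data$u[b, idx_b]   # sampled in b, toward a
  df <- bar_estimate(w_f, w_r)
  s_a <- max(mean(w_f) - df, 0)                # relative entropies, >= 0
  s_b <- max(mean(w_r) + df, 0)
  pi_ab <- sqrt(2 * log(na)) - sqrt(2 * s_a)
  pi_ba <- sqrt(2 * log(nb)) - sqrt(2 * s_b)
  pi_val <- min(pi_ab, pi_ba)
  adequate <- pi_val >= 0.5
  structure(
    list(pi = pi_val, adequate = adequate,
         pi_forward = pi_ab, pi_reverse = pi_ba,
         delta_f = df, pair = pair,
         recommendation = if (!adequate) {
           sprintf("insert an additional lambda window between states %d and %d",
                   a, b)
         } else NULL),
    class = "pi_bias"
  )
}

#' @export
print.pi_bias <- function(x, ...) {
  cat(sprintf("Wu-Kofke bias measure, states %d-%d: Pi = %.3f (%s)\n",
              x$pair[1L], x$pair[2L], x$pi,
              if (x$adequate) "adequate overlap" else "INADEQUATE"))
  if (!is.null(x$recommendation)) cat("  recommendation:", x$recommendation, "\n")
  invisible(x)
}

#' Overlap diagnostics for every adjacent pair of a lambda ladder
#'
#' @param data a [reduced_potentials()] object with at least two sampled
#'   states.
#' @param fit optional converged [mbar()] fit used for the overlap matrix
#'   (computed if missing).
#' @return Object of class `"overlap_report"`: the K x K overlap matrix, a
#'   data frame of per-adjacent-pair Pi values with adequacy flags, and any
#'   window-insertion recommendations.
#' @export
overlap_report <- function(data, fit = NULL) {
  stopifnot(inherits(data, "reduced_potentials"))
  if (is.null(fit)) fit <- mbar(data, compute_covariance = FALSE)
  k <- nrow(data$u)
  pairs <- if (k > 1L) lapply(seq_len(k - 1L), function(i) {
    pi_bias_measure(data, c(i, i + 1L))
  }) else list()
  tab <- data.frame(
    state_a = vapply(pairs, function(p) p$pair[1L], integer(1)),
    state_b = vapply(pairs, function(p) p$pair[2L], integer(1)),
    pi = vapply(pairs, function(p) p$pi, numeric(1)),
    adequate = vapply(pairs, function(p) p$adequate, logical(1))
  )
  structure(list(overlap = overlap_matrix(fit), pairs = tab,
                 recommendations = unlist(lapply(pairs, `[[`, "recommendation"))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Adjacent-pair overlap (Wu-Kofke Pi, gate at 0.5):\n")
  print(x$pairs, row.names = FALSE, digits = 3)
  if (length(x$recommendations)) {
    cat("Recommendations:\n")
    for (r in x$recommendations) cat("  -", r, "\n")
  }
  invisible(x)
}
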