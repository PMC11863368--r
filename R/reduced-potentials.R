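#' Reduced-potential sample set
#'
#' Container for the dimensionless reduced potentials of alchemical samples:
#' `u[k, n]` is the reduced potential (potential energy over kT) of sample `n`
#' evaluated at state `k`, for all samples pooled across the sampled states.
#' This is the standard input of the multistate free-energy estimators.
#'
#' @param u numeric matrix, K states x N total samples, all finite.
#' @param n_k integer vector of length K: number of samples drawn from each
#'   state. Must sum to `ncol(u)`. States with `n_k = 0` are evaluation-only.
#' @param lambdas numeric vector of length K: the lambda schedule, strictly
#'   increasing within `[0, 1]`. Defaults to an even grid.
#' @param temperature temperature in kelvin used when converting to kJ/mol.
#' @return An object of class `"reduced_potentials"`.
#' @export
reduced_potentials <- function(u, n_k, lambdas = NULL, temperature = 300) {
  u <- as.matrix(u)
  if (!is.numeric(u) || !all(is.finite(u))) {
    stop("reduced potentials must be finite numeric values", call. = FALSE)
  }
  k <- nrow(u)
  n_k <- as.integer(round(n_k))
  if (length(n_k) != k || any(n_k < 0)) {
    stop("'n_k' must give a non-negative sample count for each of the ",
         k, " states", call. = FALSE)
  }
  if (sum(n_k) != ncol(u)) {
    stop(sprintf("sample counts (sum %d) do not match the number of columns of 'u' (%d)",
                 sum(n_k), ncol(u)), call. = FALSE)
  }
  if (is.null(lambdas)) {
    lambdas <- if (k == 1L) 0 else seq(0, 1, length.out = k)
  }
  if (length(lambdas) != k || any(diff(lambdas) <= 0) ||
      any(lambdas < 0) || any(lambdas > 1)) {
    stop("'lambdas' must be strictly increasing within [0, 1], one per state",
         call. = FALSE)
  }
  stop_if_not_scalar_positive(temperature, "temperature")
  structure(
    list(u = u, n_k = n_k, lambdas = as.numeric(lambdas),
         temperature = temperature),
    class = "reduced_potentials"
  )
}

#' @export
print.reduced_potentials <- function(x, ...) {
  cat(sprintf("Reduced-potential set: %d states, %d samples (T = %g K)\n",
              nrow(x$u), ncol(x$u), x$temperature))
  cat("  lambda schedule:", paste(format(x$lambdas), collapse = " "), "\n")
  cat("  samples/state:  ", paste(x$n_k, collapse = " "), "\n")
  invisible(x)
}

#' Per-state free energies with covariance
#'
#' Dimensionless free energies `f_k`, anchored at `f_1 = 0`, together with the
#' covariance matrix of the anchored values (zero row/column for the anchor).
#'
#' @param f numeric vector of free energies in kT, first element 0.
#' @param covariance K x K covariance matrix of the anchored `f` (kT^2);
#'   symmetric positive semidefinite with zero anchor row/column.
#' @param temperature temperature in kelvin for unit conversion.
#' @return An object of class `"free_energy_set"`.
#' @export
free_energy_set <- function(f, covariance = NULL, temperature = 300) {
  f <- as.numeric(f)
  if (length(f) < 1L || !all(is.finite(f))) {
    stop("'f' must be finite", call. = FALSE)
  }
  if (abs(f[1L]) > 1e-12) stop("free energies must be anchored at f[1] = 0", call. = FALSE)
  k <- length(f)
  if (is.null(covariance)) covariance <- matrix(0, k, k)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == k)) stop("covariance dimension mismatch", call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  stop_if_not_scalar_positive(temperature, "temperature")
  structure(list(f = f, covariance = covariance, temperature = temperature),
            class = "free_energy_set")
}

#' @export
print.free_energy_set <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  cat(sprintf("Free energies (kT, anchored at state 1; T = %g K):\n", x$temperature))
  print(data.frame(state = seq_along(x$f), f_kT = x$f, se_kT = se,
                   f_kjmol = kt_to_kjmol(x$f, x$temperature)),
        row.names = FALSE, digits = 4)
  invisible(x)
}
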