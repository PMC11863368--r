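# Prediction-quality metrics against experimental relative affinities:
# MAD, maximum error, bidirectional R^2, Kendall rank concordance (tau_r and
# the significance-filtered tau_r90), with parametric-bootstrap uncertainties.

#' Build a prediction set
#'
#' Pairs calculated relative binding free energies (with their ensemble SEs)
#' with experimental references for the same transformations. Experimental
#' values flagged as lower bounds are used at face value by the metrics but
#' the flag is carried into reports.
#'
#' @param transformation character ids, unique.
#' @param calc,calc_se calculated values and standard errors (kJ/mol,
#'   `calc_se >= 0`).
#' @param exp experimental values (kJ/mol).
#' @param exp_bound `"none"` or `"lower"` per transformation (default none).
#' @param exp_sigma optional experimental sigmas (kJ/mol); `NA` when unknown.
#' @return A `prediction_set` data frame.
#' @export
prediction_set <- function(transformation, calc, calc_se, exp,
                           exp_bound = NULL, exp_sigma = NULL) {
  n <- length(transformation)
  if (anyDuplicated(transformation)) stop("transformation ids must be unique", call. = FALSE)
  if (length(calc) != n || length(calc_se) != n || length(exp) != n) {
    stop("all columns must have one entry per transformation", call. = FALSE)
  }
  if (any(!is.finite(calc)) || any(!is.finite(exp))) {
    stop("calculated and experimental values must be finite", call. = FALSE)
  }
  if (any(!is.finite(calc_se)) || any(calc_se < 0)) {
    stop("'calc_se' must be finite and >= 0", call. = FALSE)
  }
  if (is.null(exp_bound)) exp_bound <- rep("none", n)
  if (!all(exp_bound %in% c("none", "lower"))) {
    stop("'exp_bound' entries must be 'none' or 'lower'", call. = FALSE)
  }
  if (is.null(exp_sigma)) exp_sigma <- rep(NA_real_, n)
  if (any(!is.na(exp_sigma) & exp_sigma < 0)) {
    stop("'exp_sigma' must be >= 0 where given", call. = FALSE)
  }
  out <- data.frame(transformation = as.character(transformation),
                    calc = as.numeric(calc), calc_se = as.numeric(calc_se),
                    exp = as.numeric(exp), exp_bound = as.character(exp_bound),
                    exp_sigma = as.numeric(exp_sigma),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Signed errors against experiment
#'
#' `error = calculated - experimental`, per transformation. Reversing a
#' transformation's direction flips the error's sign.
#'
#' @param p a [prediction_set()].
#' @return Named numeric vector of signed errors (kJ/mol).
#' @export
signed_errors <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  if (any(is.na(p$exp))) stop("experimental values are required", call. = FALSE)
  stats::setNames(p$calc - p$exp, p$transformation)
}

#' Mean and maximum absolute deviation
#'
#' @param errors numeric vector of signed errors (at least one).
#' @return `c(mad = mean(|e|), max = max(|e|))`.
#' @export
mad_max <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 1L) stop("at least one error is required", call. = FALSE)
  c(mad = mean(abs(errors)), max = max(abs(errors)))
}

#' Bidirectional squared correlation
#'
#' The direction of a relative transformation (L1 -> L2 versus L2 -> L1) is
#' arbitrary, and the plain Pearson R^2 depends on it. The bidirectional R^2
#' removes that arbitrariness by augmenting the point set with the
#' sign-mirrored point of every transformation; the augmented set has exact
#' zero means, so R^2 reduces to `(sum xy)^2 / (sum x^2 * sum y^2)`.
#'
#' @param p a [prediction_set()] with at least two transformations.
#' @return R^2 in `[0, 1]`.
#' @export
r2_bidirectional <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  if (nrow(p) < 2L) stop("at least two transformations are required", call. = FALSE)
  .r2_bidir(p$calc, p$exp)
}

.r2_bidir <- function(x, y) {
  sxx <- sum(x^2); syy <- sum(y^2)
  if (sxx == 0 || syy == 0) {
    stop("zero variance in the calculated or experimental values", call. = FALSE)
  }
  sum(x * y)^2 / (sxx * syy)
}

#' Kendall rank concordance over the studied transformations
#'
#' Counts concordant and discordant pairs of (calculated, experimental)
#' values over all pairs of transformations that were explicitly studied --
#' not over all ligand pairs derivable by chaining. Two tie conventions are
#' supported and never mixed silently: `"count"` (tau_a style) keeps tied
#' pairs in the denominator, `"drop"` removes them entirely.
#'
#' @param p a [prediction_set()] with at least two transformations.
#' @param ties `"count"` (default) or `"drop"`.
#' @return Kendall tau in `[-1, 1]`.
#' @export
kendall_tau_r <- function(p, ties = c("count", "drop")) {
  stopifnot(inherits(p, "prediction_set"))
  if (nrow(p) < 2L) stop("at least two transformations are required", call. = FALSE)
  .kendall(p$calc, p$exp, match.arg(ties))$tau
}

.kendall <- function(x, y, ties) {
  n <- length(x)
  conc <- 0L; disc <- 0L; tied <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L
      else if (s < 0) disc <- disc + 1L
      else tied <- tied + 1L
    }
  }
  denom <- if (ties == "count") conc + disc + tied else conc + disc
  list(tau = if (denom > 0) (conc - disc) / denom else NA_real_,
       concordant = conc, discordant = disc, tied = tied)
}

#' Significance-filtered Kendall concordance (tau_r90)
#'
#' Kendall concordance restricted to transformations whose values differ from
#' zero at the 90% level: a transformation is kept only if `|calc| >= z *
#' calc_se` (and, when an experimental sigma is available, `|exp| >= z *
#' exp_sigma`). The default multiplier `z = 1.645` is the two-sided normal
#' 90% quantile. Pairs with exactly tied experimental values follow the
#' `ties` convention of [kendall_tau_r()].
#'
#' @param p a [prediction_set()].
#' @param z significance multiplier (default 1.645).
#' @param ties `"count"` or `"drop"`.
#' @return List of class `"tau_r90"`: `tau` (`NA` when fewer than two
#'   transformations survive -- undefined, not an error), `retained`,
#'   `excluded`, `z`, `ties`.
#' @export
tau_r90 <- function(p, z = 1.645, ties = c("count", "drop")) {
  stopifnot(inherits(p, "prediction_set"))
  ties <- match.arg(ties)
  keep <- abs(p$calc) >= z * p$calc_se
  has_sigma <- !is.na(p$exp_sigma)
  keep[has_sigma] <- keep[has_sigma] &
    abs(p$exp[has_sigma]) >= z * p$exp_sigma[has_sigma]
  kept <- p[keep, , drop = FALSE]
  tau <- if (nrow(kept) >= 2L) .kendall(kept$calc, kept$exp, ties)$tau else NA_real_
  structure(list(tau = tau,
                 retained = kept$transformation,
                 excluded = p$transformation[!keep],
                 z = z, ties = ties),
            class = "tau_r90")
}

#' @export
print.tau_r90 <- function(x, ...) {
  cat(sprintf("tau_r90 (z = %.3f, ties = %s): %s\n", x$z, x$ties,
              if (is.na(x$tau)) "undefined (fewer than two significant transformations)"
              else sprintf("%.3f", x$tau)))
  if (length(x$excluded)) {
    cat("  excluded as not significant:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

# All four (five counting tau_r) point metrics for a numeric calc/exp pair.
.quality_point <- function(calc, se, expv, exp_sigma, z, ties) {
  err <- calc - expv
  mm <- mad_max(err)
  keep <- abs(calc) >= z * se
  has_sigma <- !is.na(exp_sigma)
  keep[has_sigma] <- keep[has_sigma] & abs(expv[has_sigma]) >= z * exp_sigma[has_sigma]
  t90 <- if (sum(keep) >= 2L) .kendall(calc[keep], expv[keep], ties)$tau else NA_real_
  c(mad = unname(mm["mad"]), max = unname(mm["max"]),
    r2 = .r2_bidir(calc, expv),
    tau_r = .kendall(calc, expv, ties)$tau,
    tau_r90 = t90)
}

#' Quality report with parametric-bootstrap uncertainties
#'
#' Computes the five quality measures (MAD, maximum error, bidirectional
#' R^2, tau_r, tau_r90) for a prediction set, and attaches a parametric
#' bootstrap uncertainty to each: for every bootstrap set each calculated
#' value is perturbed by Gaussian noise with its standard error (and each
#' experimental value with its sigma, where one is provided), the metrics are
#' recomputed, and the standard deviation over the sets is reported. The
#' central values are the unperturbed point estimates.
#'
#' @param p a [prediction_set()].
#' @param sets number of bootstrap sets (>= 2, default 1000).
#' @param seed integer seed, echoed in the report.
#' @param z,ties passed to the tau metrics.
#' @return Object of class `"quality_report"`: `estimates`, `sd`, `sets`,
#'   `seed`, `n_undefined_tau90` (bootstrap sets where tau_r90 was
#'   undefined), plus the flags of any lower-bound experimental values.
#' @examples
#' fx <- fep_fixture("lysozyme")
#' s <- aggregate_replicates(fx$replicates)
#' vis <- s[s$condition == "VIS", ]
#' p <- prediction_set(vis$transformation, vis$mean_kjmol, vis$se_kjmol,
#'                     fx$experimental$ddg_exp_kjmol[match(vis$transformation,
#'                       fx$experimental$transformation)])
#' quality_report(p, sets = 200, seed = 1)
#' @export
quality_report <- function(p, sets = 1000, seed = 1, z = 1.645,
                           ties = c("count", "drop")) {
  stopifnot(inherits(p, "prediction_set"))
  ties <- match.arg(ties)
  sets <- as.integer(sets)
  if (sets < 2L) stop("'sets' must be >= 2", call. = FALSE)
  point <- .quality_point(p$calc, p$calc_se, p$exp, p$exp_sigma, z, ties)
  sig_exp <- ifelse(is.na(p$exp_sigma), 0, p$exp_sigma)
  draws <- with_seed(seed, {
    vapply(seq_len(sets), function(s) {
      calc_s <- stats::rnorm(nrow(p), p$calc, p$calc_se)
      exp_s <- stats::rnorm(nrow(p), p$exp, sig_exp)
      .quality_point(calc_s, p$calc_se, exp_s, p$exp_sigma, z, ties)
    }, numeric(5))
  })
  sds <- apply(draws, 1L, stats::sd, na.rm = TRUE)
  structure(
    list(estimates = point, sd = sds, sets = sets, seed = seed,
         z = z, ties = ties,
         n_undefined_tau90 = sum(is.na(draws["tau_r90", ])),
         lower_bounds = p$transformation[p$exp_bound == "lower"]),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Prediction quality (%d bootstrap sets, seed %s, ties = %s):\n",
              x$sets, format(x$seed), x$ties))
  tab <- data.frame(metric = c("MAD (kJ/mol)", "Max (kJ/mol)", "R2",
                               "tau_r", "tau_r90"),
                    estimate = round(unname(x$estimates), 3),
                    bootstrap_sd = round(unname(x$sd), 3))
  print(tab, row.names = FALSE)
  if (length(x$lower_bounds)) {
    cat("  note: experimental lower bound(s) used at face value for:",
        paste(x$lower_bounds, collapse = ", "), "\n")
  }
  if (x$n_undefined_tau90 > 0) {
    cat(sprintf("  note: tau_r90 undefined in %d bootstrap set(s)\n",
                x$n_undefined_tau90))
  }
  invisible(x)
}
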