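# Gaussian-null test for a difference between two replicate-generation
# conditions (e.g. velocity-induced vs solvent-induced replicas).

#' Test whether two replicate conditions differ
#'
#' Given the replicate values of one transformation under two conditions, the
#' observed statistic is the difference of the condition means (with standard
#' error `sqrt(SE_A^2 + SE_B^2)`). Under the null hypothesis the two
#' conditions share one Gaussian distribution whose mean and standard
#' deviation are taken from the pooled replicate values (sample sd of the
#' combined values, n - 1 denominator). The Monte-Carlo p-value is the
#' fraction of seeded repetitions in which two synthetic groups of the
#' original sizes give an absolute mean difference at least as large as
#' observed; the analytic p-value is the two-sided Gaussian tail of the
#' observed difference against `sd * sqrt(1/n_A + 1/n_B)`.
#'
#' @param a,b numeric replicate values for the two conditions (at least two
#'   each), or data frames carrying a `ddg_kjmol` column.
#' @param repetitions Monte-Carlo repetitions (default 1e6; below 1000 a
#'   warning is issued).
#' @param seed integer seed for the Monte-Carlo draw, echoed in the output.
#' @param labels length-2 character labels for the conditions.
#' @return Object of class `"condition_comparison"`: observed `difference`
#'   and `se_difference`, `null_mean`, `null_sd`, `p_mc`, `p_analytic`,
#'   `repetitions`, `seed`, group sizes.
#' @examples
#' fx <- fep_fixture("lysozyme")$replicates
#' et <- fx[fx$transformation == "Eth->Tol", ]
#' compare_conditions(et[et$condition == "VIS", ], et[et$condition == "SIS", ],
#'                    repetitions = 1e4, seed = 1)
#' @export
compare_conditions <- function(a, b, repetitions = 1e6, seed = 1,
                               labels = c("A", "B")) {
  if (is.data.frame(a)) {
    if (!is.null(a$condition) && length(unique(a$condition)) == 1L) {
      labels[1L] <- a$condition[1L]
    }
    a <- a$ddg_kjmol
  }
  if (is.data.frame(b)) {
    if (!is.null(b$condition) && length(unique(b$condition)) == 1L) {
      labels[2L] <- b$condition[1L]
    }
    b <- b$ddg_kjmol
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each condition needs at least two replicates", call. = FALSE)
  }
  repetitions <- as.integer(round(repetitions))
  if (repetitions < 1L) stop("'repetitions' must be >= 1", call. = FALSE)
  if (repetitions < 1000L) {
    warning("fewer than 1000 Monte-Carlo repetitions; the p-value will be coarse")
  }
  na <- length(a); nb <- length(b)
  diff_obs <- mean(a) - mean(b)
  se_diff <- sqrt(stats::var(a) / na + stats::var(b) / nb)
  pooled <- c(a, b)
  mu0 <- mean(pooled)
  sd0 <- stats::sd(pooled)

  scale <- sd0 * sqrt(1 / na + 1 / nb)
  p_analytic <- if (scale > 0) 2 * stats::pnorm(-abs(diff_obs) / scale) else
    as.numeric(diff_obs == 0)

  hits <- with_seed(seed, {
    total <- 0
    left <- repetitions
    chunk <- 100000L
    while (left > 0L) {
      m <- min(chunk, left)
      ga <- matrix(stats::rnorm(na * m, mu0, sd0), nrow = na)
      gb <- matrix(stats::rnorm(nb * m, mu0, sd0), nrow = nb)
      total <- total + sum(abs(colMeans(ga) - colMeans(gb)) >= abs(diff_obs))
      left <- left - m
    }
    total
  })
  p_mc <- hits / repetitions

  structure(
    list(labels = labels, n = c(na, nb),
         mean_a = mean(a), mean_b = mean(b),
         difference = diff_obs, se_difference = se_diff,
         null_mean = mu0, null_sd = sd0,
         p_mc = p_mc, p_analytic = p_analytic,
         repetitions = repetitions, seed = seed),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison %s vs %s (n = %d, %d):\n",
              x$labels[1L], x$labels[2L], x$n[1L], x$n[2L]))
  cat(sprintf("  difference of means: %.2f +/- %.2f kJ/mol\n",
              x$difference, x$se_difference))
  cat(sprintf("  Gaussian null: mean %.2f, sd %.2f kJ/mol\n", x$null_mean, x$null_sd))
  cat(sprintf("  p (Monte Carlo, %g reps, seed %s): %.3g%%; p (analytic): %.3g%%\n",
              x$repetitions, format(x$seed), 100 * x$p_mc, 100 * x$p_analytic))
  invisible(x)
}
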