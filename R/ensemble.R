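# Replicate-ensemble analysis: aggregation of independent FEP replicas,
# precision ratios and leg combination.

.replicate_cols <- c("transformation", "condition", "replicate",
                     "ddg_kjmol", "sigma_kjmol")

validate_replicates <- function(records) {
  if (!is.data.frame(records)) stop("replicate records must be a data frame", call. = FALSE)
  missing <- setdiff(.replicate_cols, names(records))
  if (length(missing)) {
    stop("replicate table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$ddg_kjmol))) stop("non-finite ddg values", call. = FALSE)
  if (any(!is.finite(records$sigma_kjmol)) || any(records$sigma_kjmol < 0)) {
    stop("per-replicate sigma values must be finite and >= 0", call. = FALSE)
  }
  key <- paste(records$transformation, records$condition, records$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (transformation, condition, replicate) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  invisible(records)
}

#' Aggregate independent replicates into ensemble estimates
#'
#' For each (transformation, condition) group the ensemble estimate is the
#' mean over replicates; its uncertainty is the ensemble standard error, i.e.
#' the sample standard deviation (n - 1 denominator) divided by `sqrt(n)`.
#' The mean per-replicate estimator sigma and the precision ratio (ensemble
#' SE over mean estimator sigma) are carried alongside: ratios above 1 mean a
#' single simulation's internal uncertainty understates the true replicate
#' spread.
#'
#' @param records replicate table with columns `transformation`, `condition`,
#'   `replicate`, `ddg_kjmol`, `sigma_kjmol` (one row per replicate).
#' @return A `transformation_summary` data frame with one row per
#'   (transformation, condition): `n`, `mean_kjmol`, `se_kjmol`,
#'   `mean_sigma_kjmol`, `precision_ratio`.
#' @examples
#' recs <- fep_fixture("brd4")$replicates
#' aggregate_replicates(recs)
#' @export
aggregate_replicates <- function(records) {
  validate_replicates(records)
  groups <- split(records,
                  list(records$transformation, records$condition),
                  drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2L) {
      stop(sprintf("transformation %s (%s) has %d replicate(s); at least 2 are required",
                   g$transformation[1L], g$condition[1L], nrow(g)), call. = FALSE)
    }
    mean_sigma <- mean(g$sigma_kjmol)
    se <- stats::sd(g$ddg_kjmol) / sqrt(nrow(g))
    data.frame(
      transformation = g$transformation[1L],
      condition = g$condition[1L],
      n = nrow(g),
      mean_kjmol = mean(g$ddg_kjmol),
      se_kjmol = se,
      mean_sigma_kjmol = mean_sigma,
      precision_ratio = if (mean_sigma > 0) se / mean_sigma else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transformation, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transformation_summary", "data.frame")
  out
}

#' @export
print.transformation_summary <- function(x, ...) {
  cat("Ensemble summaries (kJ/mol):\n")
  y <- as.data.frame(x)
  y$mean_kjmol <- round(y$mean_kjmol, 2)
  y$se_kjmol <- round(y$se_kjmol, 2)
  y$mean_sigma_kjmol <- round(y$mean_sigma_kjmol, 3)
  y$precision_ratio <- round(y$precision_ratio, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Precision ratio of an ensemble estimate
#'
#' Ratio of the ensemble standard error over the mean per-replicate estimator
#' sigma. A ratio above 1 quantifies how much a single simulation's reported
#' precision overstates the real reproducibility.
#'
#' @param se ensemble standard error (kJ/mol), or a one-row
#'   `transformation_summary`.
#' @param mean_sigma mean per-replicate estimator sigma (kJ/mol, > 0);
#'   ignored when `se` is a summary row.
#' @return The ratio.
#' @export
precision_ratio <- function(se, mean_sigma = NULL) {
  if (inherits(se, "transformation_summary") || is.data.frame(se)) {
    if (nrow(se) != 1L) stop("supply a single summary row", call. = FALSE)
    mean_sigma <- se$mean_sigma_kjmol
    se <- se$se_kjmol
  }
  if (is.null(mean_sigma) || !is.finite(mean_sigma) || mean_sigma <= 0) {
    stop("the mean estimator sigma must be positive", call. = FALSE)
  }
  if (se < 0) stop("'se' must be >= 0", call. = FALSE)
  se / mean_sigma
}

#' Combine bound and free legs into a relative binding free energy
#'
#' The relative binding free energy of two ligands is the free-energy
#' difference of the transformation carried out with the ligand bound to the
#' protein minus the same transformation in water:
#' `ddG_bind = dG_bound - dG_free`, with uncertainties added in quadrature.
#'
#' @param bound,free numeric of length 2, `c(value, sigma)`, in the same
#'   units.
#' @return Named numeric `c(ddg, se)`.
#' @examples
#' combine_legs(c(10, 0.3), c(2, 0.4))  # 8.0 +/- 0.5
#' @export
combine_legs <- function(bound, free) {
  stopifnot(length(bound) == 2L, length(free) == 2L,
            all(is.finite(c(bound, free))))
  if (bound[2L] < 0 || free[2L] < 0) stop("leg sigmas must be >= 0", call. = FALSE)
  c(ddg = unname(bound[1L] - free[1L]),
    se = unname(sqrt(bound[2L]^2 + free[2L]^2)))
}

#' Reverse the stored direction of transformations
#'
#' A transformation id `"A->B"` traversed backwards becomes `"B->A"`; its
#' free-energy values flip sign and the sigmas are unchanged.
#'
#' @param records replicate table (or any data frame with `transformation`
#'   and `ddg_kjmol` columns).
#' @return The table with ids reversed and values negated.
#' @export
reverse_transformation <- function(records) {
  parts <- parse_transformation(records$transformation)
  records$transformation <- paste0(parts$to, "->", parts$from)
  records$ddg_kjmol <- -records$ddg_kjmol
  records
}

parse_transformation <- function(id) {
  parts <- strsplit(as.character(id), "->", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("transformation ids must look like 'A->B'; offending: ",
         paste(unique(id[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(from = trimws(vapply(parts, `[`, character(1), 1L)),
             to = trimws(vapply(parts, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}
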