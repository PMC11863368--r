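# End-to-end study driver: aggregate replicates, close cycles, compare the
# replicate-generation conditions and score against experiment.

#' Run the full ensemble analysis of a replicate study
#'
#' Chains the analysis stages over a replicate table: per
#' (transformation, condition) ensemble summaries with precision ratios; per
#' cycle and condition the closure statistics over all replicate
#' combinations; per condition a quality report against experiment (when an
#' experimental table is supplied); and per transformation a Gaussian
#' Monte-Carlo comparison of the two conditions (when exactly two conditions
#' are present). All randomness flows from the single `seed`, expanded
#' deterministically per stage; every stage seed is recorded in the output.
#'
#' @param replicates replicate table (see [read_replicates()]) or a path to
#'   one.
#' @param experimental optional experimental table (see
#'   [read_experimental()]) or a path.
#' @param cycles optional list of [cycle_definition()] (or a JSON path); an
#'   empty list simply omits the cycle section.
#' @param seed top-level seed (default 1).
#' @param mc_repetitions Monte-Carlo repetitions per condition comparison.
#' @param bootstrap_sets bootstrap sets per quality report.
#' @param z,ties tau_r90 parameters, passed through.
#' @return Object of class `"fep_study"` with components `summaries`,
#'   `cycles`, `comparisons`, `quality`, `predictions`, `seeds`.
#' @examples
#' fx <- fep_fixture("brd4")
#' st <- run_study(fx$replicates, fx$experimental, fx$cycles,
#'                 mc_repetitions = 1e4, bootstrap_sets = 200)
#' print(st)
#' @export
run_study <- function(replicates, experimental = NULL, cycles = NULL,
                      seed = 1, mc_repetitions = 1e6, bootstrap_sets = 1000,
                      z = 1.645, ties = c("count", "drop")) {
  ties <- match.arg(ties)
  if (is.character(replicates)) replicates <- read_replicates(replicates)
  validate_replicates(replicates)
  if (is.character(experimental)) experimental <- read_experimental(experimental)
  if (is.character(cycles)) cycles <- read_cycles(cycles)
  if (inherits(cycles, "cycle_definition")) cycles <- list(cycles)

  seeds <- list(compare = derive_seed(seed, 1L), bootstrap = derive_seed(seed, 2L))
  conditions <- sort(unique(replicates$condition))

  summaries <- aggregate_replicates(replicates)

  cycle_results <- list()
  if (length(cycles)) {
    for (cond in conditions) {
      sub <- replicates[replicates$condition == cond, , drop = FALSE]
      for (cy in cycles) {
        res <- cycle_closure(cy, sub)
        label <- paste0(if (!is.null(cy$name)) cy$name else
          paste(cy$transformations, collapse = "|"), ".", cond)
        cycle_results[[label]] <- res
      }
    }
  }

  comparisons <- list()
  if (length(conditions) == 2L) {
    for (tr in unique(replicates$transformation)) {
      a <- replicates[replicates$transformation == tr &
                        replicates$condition == conditions[1L], , drop = FALSE]
      b <- replicates[replicates$transformation == tr &
                        replicates$condition == conditions[2L], , drop = FALSE]
      if (nrow(a) >= 2L && nrow(b) >= 2L) {
        comparisons[[tr]] <- compare_conditions(
          a, b, repetitions = mc_repetitions,
          seed = derive_seed(seeds$compare, match(tr, unique(replicates$transformation)))
        )
      }
    }
  }

  quality <- list()
  predictions <- list()
  if (!is.null(experimental)) {
    for (cond in conditions) {
      s <- summaries[summaries$condition == cond, , drop = FALSE]
      m <- match(s$transformation, experimental$transformation)
      if (any(is.na(m))) {
        stop("no experimental value for transformation(s): ",
             paste(s$transformation[is.na(m)], collapse = ", "), call. = FALSE)
      }
      p <- prediction_set(s$transformation, s$mean_kjmol, s$se_kjmol,
                          experimental$ddg_exp_kjmol[m],
                          exp_bound = experimental$bound[m],
                          exp_sigma = experimental$sigma_exp_kjmol[m])
      predictions[[cond]] <- p
      quality[[cond]] <- quality_report(p, sets = bootstrap_sets,
                                        seed = derive_seed(seeds$bootstrap,
                                                           match(cond, conditions)),
                                        z = z, ties = ties)
    }
  }

  structure(
    list(summaries = summaries, cycles = cycle_results,
         comparisons = comparisons, quality = quality,
         predictions = predictions,
         seeds = c(list(top = seed), seeds),
         options = list(mc_repetitions = mc_repetitions,
                        bootstrap_sets = bootstrap_sets, z = z, ties = ties)),
    class = "fep_study"
  )
}

#' @export
print.fep_study <- function(x, ...) {
  print(x$summaries)
  if (length(x$cycles)) {
    cat("\n")
    for (cc in x$cycles) print(cc)
  }
  if (length(x$comparisons)) {
    cat("\nCondition differences (mean A - mean B, analytic p):\n")
    tab <- data.frame(
      transformation = names(x$comparisons),
      difference = round(vapply(x$comparisons, `[[`, numeric(1), "difference"), 2),
      se = round(vapply(x$comparisons, `[[`, numeric(1), "se_difference"), 2),
      p_mc_pct = signif(100 * vapply(x$comparisons, `[[`, numeric(1), "p_mc"), 3),
      p_analytic_pct = signif(100 * vapply(x$comparisons, `[[`, numeric(1), "p_analytic"), 3)
    )
    print(tab, row.names = FALSE)
  }
  if (length(x$quality)) {
    for (cond in names(x$quality)) {
      cat("\n[", cond, "] ", sep = "")
      print(x$quality[[cond]])
    }
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the full report as one JSON file plus CSV tables (summaries,
#' comparisons). Every number in the CSVs also appears in the JSON; the
#' rendered output holds no format-only values.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "fep_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(study$summaries),
                   file.path(dir, "summaries.csv"), row.names = FALSE)
  if (length(study$comparisons)) {
    comp <- do.call(rbind, lapply(names(study$comparisons), function(tr) {
      cc <- study$comparisons[[tr]]
      data.frame(transformation = tr, difference = cc$difference,
                 se_difference = cc$se_difference, null_mean = cc$null_mean,
                 null_sd = cc$null_sd, p_mc = cc$p_mc,
                 p_analytic = cc$p_analytic, repetitions = cc$repetitions,
                 seed = cc$seed)
    }))
    utils::write.csv(comp, file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  report <- list(
    summaries = as.data.frame(study$summaries),
    cycles = lapply(study$cycles, function(cc) {
      list(cycle = paste(c(cc$cycle$ligands, cc$cycle$ligands[1L]),
                         collapse = "->"),
           condition = cc$condition, n_combinations = cc$n_combinations,
           mean = cc$mean, min = cc$min, max = cc$max, se = cc$se,
           sd_sums = cc$sd_sums)
    }),
    comparisons = lapply(study$comparisons, function(cc) {
      cc[c("labels", "n", "difference", "se_difference", "null_mean",
           "null_sd", "p_mc", "p_analytic", "repetitions", "seed")]
    }),
    quality = lapply(study$quality, function(q) {
      list(estimates = as.list(q$estimates), sd = as.list(q$sd),
           sets = q$sets, seed = q$seed, ties = q$ties,
           lower_bounds = q$lower_bounds)
    }),
    seeds = study$seeds,
    options = study$options
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
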