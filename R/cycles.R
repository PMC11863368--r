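# Thermodynamic-cycle closure over all replicate combinations.

#' Define a thermodynamic cycle
#'
#' An ordered, signed list of transformations whose free energies must sum to
#' zero around the loop. A step with sign -1 traverses its transformation
#' against the stored direction. The ligand path is validated: each signed
#' step must start where the previous one ended and the last must return to
#' the first.
#'
#' @param transformations character vector of ids like `"L3->L2"`.
#' @param signs integer vector of +1/-1, one per step.
#' @param name optional label.
#' @return Object of class `"cycle_definition"`.
#' @examples
#' cycle_definition(c("L3->L2", "L4->L2", "L3->L4"), c(1, -1, -1))
#' @export
cycle_definition <- function(transformations, signs, name = NULL) {
  transformations <- as.character(transformations)
  signs <- as.integer(signs)
  if (length(signs) != length(transformations) || !all(signs %in% c(-1L, 1L))) {
    stop("'signs' must be +1/-1, one per transformation", call. = FALSE)
  }
  if (length(transformations) < 2L) stop("a cycle needs at least two steps", call. = FALSE)
  parts <- parse_transformation(transformations)
  start <- ifelse(signs == 1L, parts$from, parts$to)
  end <- ifelse(signs == 1L, parts$to, parts$from)
  nxt <- c(start[-1L], start[1L])
  broken <- which(end != nxt)
  if (length(broken)) {
    i <- broken[1L]
    stop(sprintf("cycle does not close: step %d (%s, sign %+d) ends at '%s' but the next step starts at '%s'",
                 i, transformations[i], signs[i], end[i], nxt[i]), call. = FALSE)
  }
  structure(list(transformations = transformations, signs = signs,
                 ligands = start, name = name),
            class = "cycle_definition")
}

#' @export
print.cycle_definition <- function(x, ...) {
  cat("Thermodynamic cycle", if (!is.null(x$name)) paste0("'", x$name, "'"), ":",
      paste(c(x$ligands, x$ligands[1L]), collapse = " -> "), "\n")
  invisible(x)
}

#' Cycle-closure statistics over all replicate combinations
#'
#' Enumerates the full Cartesian product of replicate choices (lexicographic
#' in replicate indices) for the transformations of a cycle and forms every
#' signed sum. Around a closed cycle the free energies should vanish; the
#' spread of the sums measures the self-consistency of the ensemble. The
#' reported `se` is the quadrature sum of the per-transformation ensemble
#' standard errors (the uncertainty of the mean closure); `sd_sums` is the
#' standard deviation over all combinations.
#'
#' @param cycle a [cycle_definition()].
#' @param records replicate table restricted to one condition.
#' @return Object of class `"cycle_closure"`: `n_combinations`, `mean`,
#'   `min`, `max`, `se`, `sd_sums`, and the per-step replicate counts.
#' @examples
#' fx <- fep_fixture("brd4")
#' vis <- fx$replicates[fx$replicates$condition == "VIS", ]
#' cycle_closure(fx$cycles[[1]], vis)
#' @export
cycle_closure <- function(cycle, records) {
  stopifnot(inherits(cycle, "cycle_definition"))
  validate_replicates(records)
  if (length(unique(records$condition)) > 1L) {
    stop("restrict 'records' to a single condition before closing a cycle",
         call. = FALSE)
  }
  values <- lapply(seq_along(cycle$transformations), function(i) {
    id <- cycle$transformations[i]
    g <- records[records$transformation == id, , drop = FALSE]
    if (nrow(g) == 0L) {
      stop(sprintf("no replicates for cycle transformation '%s'", id), call. = FALSE)
    }
    g <- g[order(g$replicate), , drop = FALSE]
    cycle$signs[i] * g$ddg_kjmol
  })
  counts <- vapply(values, length, integer(1))
  # Cartesian product, lexicographic in replicate indices (first step fastest).
  idx <- expand.grid(lapply(counts, seq_len))
  sums <- as.vector(Reduce(`+`, Map(function(v, j) v[j], values, idx)))
  ses <- vapply(values, function(v) {
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  structure(
    list(cycle = cycle,
         condition = if (nrow(records)) records$condition[1L] else NA_character_,
         n_combinations = prod(counts),
         replicates_per_step = counts,
         mean = mean(sums), min = min(sums), max = max(sums),
         se = sqrt(sum(ses^2)),
         sd_sums = if (length(sums) > 1L) stats::sd(sums) else 0),
    class = "cycle_closure"
  )
}

#' @export
print.cycle_closure <- function(x, ...) {
  cat(sprintf("Cycle closure (%s, %s): %d combinations\n",
              paste(c(x$cycle$ligands, x$cycle$ligands[1L]), collapse = "->"),
              x$condition, x$n_combinations))
  cat(sprintf("  mean %.2f +/- %.2f kJ/mol, range %.2f to %.2f (sd over sums %.2f)\n",
              x$mean, x$se, x$min, x$max, x$sd_sums))
  invisible(x)
}
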