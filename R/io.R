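# File formats: replicate tables, experimental references, reduced-potential
# (u_nk) tables and cycle configurations.
#
# Replicate CSV schema (one row per replicate):
#   transformation,condition,replicate,ddg_kjmol,sigma_kjmol
# Experimental CSV schema:
#   transformation,ddg_exp_kjmol,bound,sigma_exp_kjmol   (bound: none|lower)
# u_nk CSV layout (one row per sample):
#   state,lambda_<l1>,lambda_<l2>,...   -- `state` is the 1-based index of the
#   lambda state the sample was drawn from; the remaining columns hold the
#   sample's reduced potential evaluated at every lambda, in schedule order.

#' Read a replicate table
#'
#' Validates the schema and every row; malformed rows are reported with their
#' line numbers. A header-only file yields an empty table with a warning.
#'
#' @param path CSV file in the replicate schema.
#' @return Validated replicate data frame.
#' @export
read_replicates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.replicate_cols, names(tab))
  if (length(missing)) {
    stop("replicate file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("replicate file ", path, " contains a header only")
    return(tab)
  }
  line <- seq_len(nrow(tab)) + 1L   # header is line 1
  problems <- character(0)
  bad_num <- !is.finite(tab$ddg_kjmol)
  if (any(bad_num)) {
    problems <- c(problems, sprintf("line %d: non-numeric or missing ddg_kjmol",
                                    line[bad_num]))
  }
  bad_sig <- !is.finite(tab$sigma_kjmol) | tab$sigma_kjmol < 0
  if (any(bad_sig)) {
    problems <- c(problems, sprintf("line %d: sigma_kjmol must be a number >= 0",
                                    line[bad_sig]))
  }
  key <- paste(tab$transformation, tab$condition, tab$replicate)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems, sprintf("line %d: duplicate (transformation, condition, replicate)",
                                    line[dup]))
  }
  if (length(problems)) {
    stop("invalid replicate rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  parse_transformation(tab$transformation)  # id syntax check
  tab
}

#' Write a replicate table
#'
#' @param records replicate data frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(records, path) {
  validate_replicates(records)
  utils::write.csv(records[, .replicate_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an experimental reference table
#'
#' @param path CSV with columns `transformation`, `ddg_exp_kjmol`, and
#'   optionally `bound` (`none`/`lower`) and `sigma_exp_kjmol`.
#' @return Data frame with all four columns filled in.
#' @export
read_experimental <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transformation", "ddg_exp_kjmol")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("experimental file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$ddg_exp_kjmol))) {
    stop("experimental values must be numeric", call. = FALSE)
  }
  if (is.null(tab$bound)) tab$bound <- "none"
  tab$bound[is.na(tab$bound) | tab$bound == ""] <- "none"
  if (!all(tab$bound %in% c("none", "lower"))) {
    stop("'bound' entries must be 'none' or 'lower'", call. = FALSE)
  }
  if (is.null(tab$sigma_exp_kjmol)) tab$sigma_exp_kjmol <- NA_real_
  tab
}

#' Write a reduced-potential set in the u_nk CSV layout
#'
#' @param data a [reduced_potentials()] object.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_u_nk <- function(data, path) {
  stopifnot(inherits(data, "reduced_potentials"))
  state <- rep(seq_along(data$n_k), data$n_k)
  tab <- cbind(data.frame(state = state), as.data.frame(t(data$u)))
  names(tab)[-1L] <- paste0("lambda_", format(data$lambdas, trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reduced-potential set from the u_nk CSV layout
#'
#' @param path CSV written by [write_u_nk()] (or an equivalent exporter):
#'   a `state` column of 1-based sampling-state indices followed by one
#'   column per lambda value named `lambda_<value>`.
#' @param temperature temperature in kelvin for the container.
#' @return A [reduced_potentials()] object. Samples are re-ordered by
#'   sampling state; lambda values are parsed from the header and must be
#'   strictly increasing.
#' @export
read_u_nk <- function(path, temperature = 300) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"state" %in% names(tab)) {
    stop("u_nk file must have a 'state' column", call. = FALSE)
  }
  lam_cols <- grep("^lambda_", names(tab), value = TRUE)
  if (length(lam_cols) < 1L) {
    stop("u_nk file must have lambda_<value> columns", call. = FALSE)
  }
  lambdas <- as.numeric(sub("^lambda_", "", lam_cols))
  if (any(is.na(lambdas))) stop("unparseable lambda column names", call. = FALSE)
  k <- length(lambdas)
  state <- as.integer(tab$state)
  bad <- which(is.na(state) | state < 1L | state > k)
  if (length(bad)) {
    stop("invalid sampling-state index on line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  u_raw <- as.matrix(tab[lam_cols])
  if (any(!is.finite(u_raw))) {
    stop("non-finite reduced potentials on line(s) ",
         paste(which(rowSums(!is.finite(u_raw)) > 0) + 1L, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(state)
  n_k <- tabulate(state, nbins = k)
  reduced_potentials(t(u_raw[ord, , drop = FALSE]), n_k, lambdas = lambdas,
                     temperature = temperature)
}

#' Read a cycle configuration
#'
#' JSON list of cycles, each `{"name": ..., "transformations": [...],
#' "signs": [...]}`.
#'
#' @param path JSON file.
#' @return List of [cycle_definition()] objects.
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(cc) {
    cycle_definition(unlist(cc$transformations), unlist(cc$signs),
                     name = if (!is.null(cc$name)) cc$name else NULL)
  })
}
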