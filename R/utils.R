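# Internal numerical helpers shared across the estimators.

# Gas constant in kJ/(mol K).
.RGAS <- 8.31446261815324e-3

#' Convert dimensionless free energies (kT) to kJ/mol
#'
#' @param x numeric, free energies in units of kT.
#' @param temperature temperature in kelvin (default 300).
#' @return `x * R * T` in kJ/mol.
#' @export
kt_to_kjmol <- function(x, temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  x * .RGAS * temperature
}

# Overflow-safe log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or an Inf dominates)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix (K x N): returns length-N vector.
col_logsumexp <- function(a) {
  if (nrow(a) == 1L) return(as.vector(a))
  m <- apply(a, 2L, max)
  m + log(colSums(exp(sweep(a, 2L, m, "-"))))
}

# log(1 + exp(x)) without overflow.
log1pexp <- function(x) {
  out <- x
  small <- x <= 35
  out[small] <- log1p(exp(x[small]))
  out
}

# Evaluate `code` under a fixed, named RNG (Mersenne-Twister / inversion),
# restoring the caller's RNG state afterwards. All package randomness flows
# through this helper so results are bit-reproducible under a fixed seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Derive a stage seed from a top-level seed; double arithmetic (exact below
# 2^53) keeps the result a valid integer seed < 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stage)) %% 2147483647)
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
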