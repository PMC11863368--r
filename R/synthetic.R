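# Synthetic ground-truth systems: every downstream stage of the package can be
# validated against these analytically tractable generators without any MD
# engine.

#' Default synthetic lambda ladders
#'
#' Even 11-point ladder (0, 0.1, ..., 1) and the 13-point variant that adds
#' 0.05 and 0.95 near the end points, mirroring common alchemical window
#' designs.
#'
#' @param n either 11 or 13.
#' @return numeric lambda schedule.
#' @export
default_lambdas <- function(n = 11) {
  if (n == 11) return(seq(0, 1, by = 0.1))
  if (n == 13) return(sort(c(seq(0, 1, by = 0.1), 0.05, 0.95)))
  stop("supported ladders have 11 or 13 points", call. = FALSE)
}

#' Generate an exactly solvable harmonic alchemical system
#'
#' Each lambda state `k` is a one-dimensional harmonic potential
#' `u_k(x) = stiffness_k / 2 * (x - offset_k)^2` (dimensionless, i.e. in units
#' of kT). Its configurational partition function is `sqrt(2 * pi /
#' stiffness_k)`, so the exact dimensionless free energy of state `k` relative
#' to state 1 is `log(stiffness_k / stiffness_1) / 2`, independent of the
#' offsets. The generator draws the requested number of independent samples
#' from each state's Boltzmann distribution (a Gaussian with sd
#' `1/sqrt(stiffness_k)`) and evaluates every sample's reduced potential at
#' every state -- exactly the input MBAR expects, with a known answer.
#'
#' @param stiffness positive numeric vector, one force constant per state.
#' @param offset numeric vector of state centres (default all 0).
#' @param n_samples samples per state: scalar or vector, all >= 1.
#' @param seed integer seed; the draw is bit-reproducible.
#' @param lambdas optional lambda schedule (default: even grid).
#' @param temperature temperature in kelvin carried into the container.
#' @return A list with components `potentials` (a [reduced_potentials()] set),
#'   `exact` (a [free_energy_set()] with the closed-form free energies),
#'   `samples` (the raw coordinates) and `seed`.
#' @examples
#' sys <- gen_harmonic_alchemy(c(1, 4), n_samples = 2000, seed = 1)
#' sys$exact$f[2]  # log(4)/2
#' @export
gen_harmonic_alchemy <- function(stiffness, offset = NULL, n_samples = 1000,
                                 seed = 1, lambdas = NULL, temperature = 300) {
  stiffness <- as.numeric(stiffness)
  k <- length(stiffness)
  if (k < 1L || any(!is.finite(stiffness)) || any(stiffness <= 0)) {
    stop("all stiffness values must be positive and finite", call. = FALSE)
  }
  if (is.null(offset)) offset <- numeric(k)
  offset <- as.numeric(offset)
  if (length(offset) != k) {
    stop("'offset' must have one entry per state", call. = FALSE)
  }
  n_samples <- as.integer(round(n_samples))
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, k)
  if (length(n_samples) != k || any(n_samples < 1L)) {
    stop("'n_samples' must give a positive sample count per state", call. = FALSE)
  }

  x <- with_seed(seed, {
    unlist(lapply(seq_len(k), function(i) {
      stats::rnorm(n_samples[i], mean = offset[i], sd = 1 / sqrt(stiffness[i]))
    }))
  })
  # u[k, n]: reduced potential of every pooled sample in every state.
  u <- vapply(seq_along(x), function(n) stiffness / 2 * (x[n] - offset)^2,
              numeric(k))
  u <- matrix(u, nrow = k)

  exact <- free_energy_set(0.5 * log(stiffness / stiffness[1L]),
                           temperature = temperature)
  list(
    potentials = reduced_potentials(u, n_samples, lambdas = lambdas,
                                    temperature = temperature),
    exact = exact,
    samples = x,
    seed = seed
  )
}

#' Generate a synthetic replicate study
#'
#' Emulates a replicate-ensemble FEP study: for each transformation and each
#' condition, replicate relative free energies are independent Gaussian draws
#' centred at the true value (plus an optional systematic offset applied to
#' one condition, emulating a protocol that genuinely shifts the result) with
#' replicate scatter `sigma_rep`. Each replicate also carries a nominal
#' per-replicate estimator uncertainty `sigma_mbar`, typically smaller than
#' the replicate scatter.
#'
#' @param truth named numeric vector: true relative free energy (kJ/mol) per
#'   transformation; names are transformation ids like `"L1->L2"`.
#' @param sigma_rep replicate scatter sd in kJ/mol (>= 0).
#' @param sigma_mbar reported per-replicate estimator sigma in kJ/mol (>= 0).
#' @param n_replicates replicates per condition (>= 2).
#' @param conditions character vector of condition tags (default VIS and SIS).
#' @param offset systematic shift in kJ/mol added to `offset_condition`.
#' @param offset_condition condition receiving the offset.
#' @param seed integer seed.
#' @return List with `records` (a replicate table: transformation, condition,
#'   replicate, ddg_kjmol, sigma_kjmol), `truth` (data frame of true values)
#'   and `seed`.
#' @export
gen_replicate_study <- function(truth, sigma_rep = 0.39, sigma_mbar = 0.1,
                                n_replicates = 5,
                                conditions = c("VIS", "SIS"),
                                offset = 0, offset_condition = "SIS",
                                seed = 1) {
  truth <- unlist(truth)
  if (is.null(names(truth)) || any(!nzchar(names(truth)))) {
    stop("'truth' must be a named vector of transformation ids", call. = FALSE)
  }
  if (anyDuplicated(names(truth))) stop("duplicate transformation ids", call. = FALSE)
  if (!is.numeric(sigma_rep) || sigma_rep < 0) stop("'sigma_rep' must be >= 0", call. = FALSE)
  if (!is.numeric(sigma_mbar) || sigma_mbar < 0) stop("'sigma_mbar' must be >= 0", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) {
    stop("'n_replicates' must be >= 2 (the ensemble SE is undefined otherwise)",
         call. = FALSE)
  }
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("duplicate condition tags", call. = FALSE)

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      condition = conditions,
                      transformation = names(truth),
                      stringsAsFactors = FALSE)
  mu <- truth[grid$transformation] +
    ifelse(grid$condition == offset_condition, offset, 0)
  ddg <- with_seed(seed, stats::rnorm(nrow(grid), mean = mu, sd = sigma_rep))
  records <- data.frame(
    transformation = grid$transformation,
    condition = grid$condition,
    replicate = grid$replicate,
    ddg_kjmol = ddg,
    sigma_kjmol = rep(sigma_mbar, nrow(grid)),
    stringsAsFactors = FALSE
  )
  records <- records[order(records$transformation, records$condition,
                           records$replicate), , drop = FALSE]
  rownames(records) <- NULL
  list(
    records = records,
    truth = data.frame(transformation = names(truth),
                       ddg_true_kjmol = as.numeric(truth),
                       stringsAsFactors = FALSE),
    offset = offset, offset_condition = offset_condition, seed = seed
  )
}

# Rigid three-site water geometry (O-H 0.9572 A, H-O-H 104.52 deg), O at the
# origin, molecule in the xz plane.
.water_template <- function() {
  r <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c(r * sin(half), 0, r * cos(half)),
        H2 = c(-r * sin(half), 0, r * cos(half)))
}

# Uniform random rotation matrix via the quaternion method (Shoemake).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a geometric stand-in for an equilibrated water-box snapshot
#'
#' Places rigid three-site waters on a jittered cubic lattice with random
#' orientations inside a cubic box. The box is a geometric stand-in for a
#' snapshot of an equilibrated pure-water simulation: it has roughly the right
#' density and no atomic clashes, but no physical water-water structure.
#'
#' @param edge cubic box edge length in angstrom.
#' @param count number of waters; must be placeable on the lattice with an
#'   oxygen-oxygen spacing of at least 2.4 A.
#' @param jitter uniform per-axis displacement amplitude of the oxygens in
#'   angstrom (default 0.15; kept small so lattice neighbours cannot clash).
#' @param seed integer seed.
#' @param id snapshot identifier recorded in the output.
#' @return Object of class `"water_box"`: `atoms` (data frame with water
#'   index, atom name, element, x, y, z), `edge`, `n_waters`, `id`, `seed`.
#' @export
gen_water_box <- function(edge, count, jitter = 0.15, seed = 1, id = 1L) {
  stop_if_not_scalar_positive(edge, "edge")
  count <- as.integer(count)
  if (count < 1L) stop("'count' must be positive", call. = FALSE)
  if (jitter < 0) stop("'jitter' must be >= 0", call. = FALSE)
  per_side <- ceiling(count^(1 / 3) - 1e-9)
  spacing <- edge / per_side
  if (spacing < 2.4) {
    stop(sprintf(paste0("requested density implies an oxygen lattice spacing of ",
                        "%.2f A (< 2.4 A): reduce 'count' or enlarge 'edge'"),
                 spacing), call. = FALSE)
  }
  grid <- expand.grid(i = seq_len(per_side), j = seq_len(per_side),
                      k = seq_len(per_side))
  grid <- grid[seq_len(count), , drop = FALSE]
  lattice <- (as.matrix(grid) - 0.5) * spacing

  coords <- with_seed(seed, {
    tmpl <- .water_template()
    out <- matrix(0, nrow = 3L * count, ncol = 3L)
    for (w in seq_len(count)) {
      disp <- if (jitter > 0) stats::runif(3, -jitter, jitter) else numeric(3)
      o <- lattice[w, ] + disp
      # keep the oxygen inside the box (wrap on the lattice period)
      o <- o %% edge
      rot <- random_rotation()
      out[(3 * w - 2):(3 * w), ] <- sweep(tmpl %*% t(rot), 2L, o, "+")
    }
    out
  })

  atoms <- data.frame(
    water = rep(seq_len(count), each = 3L),
    name = rep(c("O", "H1", "H2"), count),
    element = rep(c("O", "H", "H"), count),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, edge = edge, n_waters = count,
                 id = id, seed = seed, jitter = jitter),
            class = "water_box")
}

#' @export
print.water_box <- function(x, ...) {
  mass_g <- x$n_waters * 18.01528 / 6.02214076e23
  dens <- mass_g / (x$edge * 1e-8)^3
  cat(sprintf("Water box %s: %d waters, edge %.2f A, density %.3f g/cm^3 (seed %s)\n",
              format(x$id), x$n_waters, x$edge, dens, format(x$seed)))
  invisible(x)
}
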