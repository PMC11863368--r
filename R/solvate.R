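# Solvent-induced replica construction: overlay a solute with an equilibrated
# water-box snapshot under a seeded rigid transform, tile to the target box,
# and cull clashing waters (whole molecules only).

#' Solvate a solute with a water-box snapshot
#'
#' Implements the standard overlay solvation step with its randomness made
#' explicit and reproducible. The target box is the solute bounding box
#' extended by `margin` on every axis and cubified (edge = largest extended
#' axis); for an empty solute the target box is exactly one image of the
#' snapshot. The snapshot is rigidly rotated about its centre (uniform
#' rotation via the quaternion method) and translated by a uniform shift
#' within one box period, both drawn from the seeded generator; each water is
#' then wrapped whole (by its oxygen, minimum-image on the snapshot's cubic
#' period) and the box is tiled periodically to cover the target box. A water
#' is deleted when any of its atoms lies within `cutoff` of any solute atom;
#' molecules are never split. Distinct snapshots or seeds give distinct
#' solvated systems -- exactly the randomness that solvent-induced replicas
#' exploit.
#'
#' @param solute atom-set data frame (see [read_solute_pdb()]); may have zero
#'   rows for a pure solvent box.
#' @param box a `"water_box"` snapshot.
#' @param margin minimum solute-box distance per axis in angstrom (> 0,
#'   default 12).
#' @param cutoff clash cutoff in angstrom on any solute-water atom pair
#'   (> 0, default 2.4, an approximate heavy-atom van der Waals contact).
#' @param seed integer seed for the rigid transform.
#' @param transform `"random"` (default) or `"identity"` (no rotation or
#'   translation; useful for regression tests).
#' @return Object of class `"solvated_system"`: `solute`, `waters` (retained
#'   water atoms), `box_edge`, `origin`, `n_waters`, `n_removed`, and
#'   `provenance` (snapshot id, seed, transform, cutoff, margin).
#' @examples
#' box <- gen_water_box(18.6, 216, seed = 3)
#' solute <- data.frame(name = "C1", resid = "LIG", resno = 1L, element = "C",
#'                      x = 9.3, y = 9.3, z = 9.3)
#' solvate(solute, box, margin = 6, cutoff = 2.4, seed = 1)
#' @export
solvate <- function(solute, box, margin = 12, cutoff = 2.4, seed = 1,
                    transform = c("random", "identity")) {
  stopifnot(inherits(box, "water_box"))
  transform <- match.arg(transform)
  stop_if_not_scalar_positive(margin, "margin")
  stop_if_not_scalar_positive(cutoff, "cutoff")
  if (cutoff >= margin) {
    warning("clash cutoff >= margin: culling will reach the box boundary")
  }
  if (box$n_waters < 1L) stop("the water box is empty", call. = FALSE)
  if (is.null(solute)) {
    solute <- data.frame(name = character(0), resid = character(0),
                         resno = integer(0), element = character(0),
                         x = numeric(0), y = numeric(0), z = numeric(0))
  }
  has_solute <- nrow(solute) > 0L
  if (has_solute && any(!is.finite(as.matrix(solute[, c("x", "y", "z")])))) {
    stop("solute coordinates must be finite", call. = FALSE)
  }

  edge <- box$edge
  if (has_solute) {
    sxyz <- as.matrix(solute[, c("x", "y", "z")])
    lo <- apply(sxyz, 2L, min)
    hi <- apply(sxyz, 2L, max)
    target <- max(hi - lo) + 2 * margin
    centre <- (lo + hi) / 2
    origin <- centre - target / 2
  } else {
    target <- edge
    origin <- c(0, 0, 0)
  }

  wxyz <- as.matrix(box$atoms[, c("x", "y", "z")])
  n_w <- box$n_waters
  if (transform == "random") {
    tr <- with_seed(seed, list(rotation = random_rotation(),
                               translation = stats::runif(3, 0, edge)))
    bc <- rep(edge / 2, 3)
    wxyz <- sweep(sweep(wxyz, 2L, bc, "-") %*% t(tr$rotation), 2L,
                  bc + tr$translation, "+")
  } else {
    tr <- list(rotation = diag(3), translation = c(0, 0, 0))
  }

  # wrap each molecule whole, by its oxygen, into [0, edge)^3
  o_idx <- seq(1L, 3L * n_w, by = 3L)
  shift <- -floor(wxyz[o_idx, , drop = FALSE] / edge) * edge
  wxyz <- wxyz + shift[rep(seq_len(n_w), each = 3L), , drop = FALSE]

  # tile images to cover the target box
  n_img <- ceiling(target / edge - 1e-9)
  images <- as.matrix(expand.grid(x = 0:(n_img - 1), y = 0:(n_img - 1),
                                  z = 0:(n_img - 1))) * edge
  tiles <- lapply(seq_len(nrow(images)), function(i) {
    sweep(wxyz, 2L, origin + images[i, ], "+")
  })
  all_xyz <- do.call(rbind, tiles)
  water_id <- rep(seq_len(n_w * nrow(images)), each = 3L)

  # keep waters whose oxygen falls inside the target box
  o_all <- all_xyz[seq(1L, nrow(all_xyz), by = 3L), , drop = FALSE]
  inside <- o_all[, 1L] >= origin[1L] & o_all[, 1L] < origin[1L] + target &
    o_all[, 2L] >= origin[2L] & o_all[, 2L] < origin[2L] + target &
    o_all[, 3L] >= origin[3L] & o_all[, 3L] < origin[3L] + target
  keep_rows <- inside[water_id]
  all_xyz <- all_xyz[keep_rows, , drop = FALSE]
  water_id <- water_id[keep_rows]
  n_kept0 <- length(unique(water_id))

  # cull whole waters with any atom within cutoff of any solute atom
  if (has_solute && nrow(all_xyz)) {
    min_d2 <- rep(Inf, nrow(all_xyz))
    for (i in seq_len(nrow(sxyz))) {
      d2 <- (all_xyz[, 1L] - sxyz[i, 1L])^2 + (all_xyz[, 2L] - sxyz[i, 2L])^2 +
        (all_xyz[, 3L] - sxyz[i, 3L])^2
      min_d2 <- pmin(min_d2, d2)
    }
    clash_water <- unique(water_id[min_d2 < cutoff^2])
    drop_rows <- water_id %in% clash_water
    all_xyz <- all_xyz[!drop_rows, , drop = FALSE]
    water_id <- water_id[!drop_rows]
  }
  n_final <- length(unique(water_id))

  waters <- data.frame(
    water = match(water_id, unique(water_id)),
    name = rep(c("O", "H1", "H2"), length.out = nrow(all_xyz)),
    element = rep(c("O", "H", "H"), length.out = nrow(all_xyz)),
    x = all_xyz[, 1L], y = all_xyz[, 2L], z = all_xyz[, 3L],
    stringsAsFactors = FALSE
  )

  structure(
    list(solute = solute, waters = waters,
         box_edge = target, origin = origin,
         n_waters = n_final, n_removed = n_kept0 - n_final,
         provenance = list(snapshot_id = box$id, seed = seed,
                           transform = tr, transform_kind = transform,
                           cutoff = cutoff, margin = margin)),
    class = "solvated_system"
  )
}

#' @export
print.solvated_system <- function(x, ...) {
  cat(sprintf("Solvated system: %d solute atoms, %d waters (%d culled)\n",
              nrow(x$solute), x$n_waters, x$n_removed))
  cat(sprintf("  cubic box edge %.2f A (snapshot %s, seed %s, cutoff %.2f A, margin %.1f A)\n",
              x$box_edge, format(x$provenance$snapshot_id),
              format(x$provenance$seed), x$provenance$cutoff,
              x$provenance$margin))
  invisible(x)
}

#' Minimum solute-water distance of a solvated system
#'
#' Exhaustive scan over all solute-water atom pairs; used to verify the
#' clash invariant.
#'
#' @param system a [solvate()] result with a non-empty solute.
#' @return Minimum interatomic distance in angstrom (`Inf` when either set
#'   is empty).
#' @export
min_solute_water_distance <- function(system) {
  stopifnot(inherits(system, "solvated_system"))
  if (!nrow(system$solute) || !nrow(system$waters)) return(Inf)
  s <- as.matrix(system$solute[, c("x", "y", "z")])
  w <- as.matrix(system$waters[, c("x", "y", "z")])
  best <- Inf
  for (i in seq_len(nrow(s))) {
    d2 <- (w[, 1L] - s[i, 1L])^2 + (w[, 2L] - s[i, 2L])^2 + (w[, 3L] - s[i, 3L])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Replica manifest for an independent-simulation ensemble
#'
#' Describes how an ensemble of independent replicas is generated. In VIS
#' (velocity-induced) mode all replicas share one solvated structure and
#' differ only in the starting-velocity seed; in SIS (solvent-induced) mode
#' each replica has its own water-box snapshot (ids must be distinct) and a
#' fresh velocity seed as well. Every seed and snapshot id is recorded.
#'
#' @param mode `"VIS"` or `"SIS"`.
#' @param n_replicates number of replicas (>= 1).
#' @param snapshot_ids water-box snapshot ids; required (length
#'   `n_replicates`, unique) in SIS mode, a single reference id in VIS mode.
#' @param velocity_seeds optional integer seeds (length `n_replicates`);
#'   derived from `seed` when missing.
#' @param seed base seed used to derive missing velocity seeds.
#' @param net_charge net system charge recorded as metadata (counterion
#'   placement is out of scope).
#' @return Object of class `"fep_manifest"`: one row per replica with
#'   condition, replicate index, snapshot id and velocity seed.
#' @export
ensemble_manifest <- function(mode = c("VIS", "SIS"), n_replicates,
                              snapshot_ids = NULL, velocity_seeds = NULL,
                              seed = 1, net_charge = 0) {
  mode <- match.arg(mode)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (is.null(velocity_seeds)) {
    velocity_seeds <- vapply(seq_len(n_replicates),
                             function(i) derive_seed(seed, i), numeric(1))
  }
  if (length(velocity_seeds) != n_replicates) {
    stop("one velocity seed per replica is required", call. = FALSE)
  }
  if (mode == "SIS") {
    if (is.null(snapshot_ids) || length(snapshot_ids) != n_replicates) {
      stop("SIS mode requires one snapshot id per replica", call. = FALSE)
    }
    if (anyDuplicated(snapshot_ids)) {
      stop("duplicate snapshot ids in SIS mode", call. = FALSE)
    }
    snaps <- snapshot_ids
  } else {
    if (is.null(snapshot_ids)) snapshot_ids <- 1L
    snaps <- rep(snapshot_ids[1L], n_replicates)
  }
  entries <- data.frame(condition = mode,
                        replicate = seq_len(n_replicates),
                        snapshot_id = snaps,
                        velocity_seed = velocity_seeds,
                        stringsAsFactors = FALSE)
  structure(list(mode = mode, entries = entries,
                 n_structures = length(unique(snaps)),
                 net_charge = net_charge, seed = seed),
            class = "fep_manifest")
}

#' @export
print.fep_manifest <- function(x, ...) {
  cat(sprintf("%s ensemble manifest: %d replicas, %d distinct structure(s)\n",
              x$mode, nrow(x$entries), x$n_structures))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Write a manifest as JSON
#'
#' @param manifest an [ensemble_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  stopifnot(inherits(manifest, "fep_manifest"))
  jsonlite::write_json(
    list(mode = manifest$mode, n_structures = manifest$n_structures,
         net_charge = manifest$net_charge, seed = manifest$seed,
         replicas = manifest$entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
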