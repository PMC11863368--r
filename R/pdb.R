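# PDB input/output. Atom records go through bio3d; the CRYST1 box record,
# which bio3d::write.pdb does not emit, is handled by a thin wrapper.

#' Read a solute structure from PDB
#'
#' @param path PDB file with ATOM/HETATM records.
#' @return An atom-set data frame: `name`, `resid`, `resno`, `element`,
#'   `x`, `y`, `z` (angstrom), with the box edge from a CRYST1 record (if
#'   any) as attribute `"box_edge"`.
#' @export
read_solute_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  out <- data.frame(name = a$elety, resid = a$resid, resno = a$resno,
                    element = ifelse(is.na(a$elesy) | a$elesy == "",
                                     substr(trimws(a$elety), 1L, 1L), a$elesy),
                    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst)) {
    attr(out, "box_edge") <- as.numeric(substr(cryst[1L], 7L, 15L))
  }
  out
}

# Write atom records plus an optional cubic CRYST1 record.
.write_pdb_atoms <- function(path, xyz, elety, resid, resno, elesy,
                             type = "HETATM", box_edge = NULL) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(xyz)),
                   type = rep(type, length.out = nrow(xyz)),
                   resno = resno, resid = resid,
                   eleno = seq_len(nrow(xyz)), elety = elety,
                   elesy = elesy)
  body <- readLines(tmp, warn = FALSE)
  header <- if (!is.null(box_edge)) {
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            box_edge, box_edge, box_edge, 90, 90, 90)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a water box as PDB
#'
#' Waters are written as HETATM records (residue WAT, one residue per
#' molecule) with a CRYST1 record carrying the cubic box.
#'
#' @param box a [gen_water_box()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_water_box_pdb <- function(box, path) {
  stopifnot(inherits(box, "water_box"))
  a <- box$atoms
  .write_pdb_atoms(path,
                   xyz = as.matrix(a[, c("x", "y", "z")]),
                   elety = ifelse(a$name == "O", "O", sub("H", "H", a$name)),
                   resid = rep("WAT", nrow(a)), resno = a$water,
                   elesy = a$element, type = "HETATM", box_edge = box$edge)
}

#' Read a water box from PDB
#'
#' Expects three-site waters (O, H, H per residue) and a CRYST1 record for
#' the cubic box edge.
#'
#' @param path PDB file.
#' @param id snapshot id to record (default: the file name).
#' @return A `"water_box"` object.
#' @export
read_water_box_pdb <- function(path, id = NULL) {
  atoms <- read_solute_pdb(path)
  edge <- attr(atoms, "box_edge")
  if (is.null(edge) || !is.finite(edge)) {
    stop("water-box PDB must carry a CRYST1 record", call. = FALSE)
  }
  if (nrow(atoms) %% 3L != 0L) {
    stop("expected three atoms (O, H, H) per water", call. = FALSE)
  }
  n <- nrow(atoms) %/% 3L
  out <- data.frame(
    water = rep(seq_len(n), each = 3L),
    name = rep(c("O", "H1", "H2"), n),
    element = rep(c("O", "H", "H"), n),
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = out, edge = edge, n_waters = n,
                 id = if (is.null(id)) basename(path) else id,
                 seed = NA, jitter = NA),
            class = "water_box")
}

#' Write a solvated system as PDB
#'
#' Solute atoms first (ATOM records), then the retained waters (HETATM,
#' residue WAT), with the final cubic box in CRYST1.
#'
#' @param system a [solvate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solvated_pdb <- function(system, path) {
  stopifnot(inherits(system, "solvated_system"))
  s <- system$solute
  w <- system$waters
  n_s <- if (is.null(s)) 0L else nrow(s)
  xyz <- rbind(if (n_s) as.matrix(s[, c("x", "y", "z")]),
               as.matrix(w[, c("x", "y", "z")]))
  resno_w <- if (nrow(w)) max(if (n_s) s$resno else 0L, 0L) +
    as.integer(factor(w$water)) else integer(0)
  .write_pdb_atoms(
    path, xyz = xyz,
    elety = c(if (n_s) s$name, w$name),
    resid = c(if (n_s) s$resid, rep("WAT", nrow(w))),
    resno = c(if (n_s) s$resno, resno_w),
    elesy = c(if (n_s) s$element, w$element),
    type = c(rep("ATOM", n_s), rep("HETATM", nrow(w))),
    box_edge = system$box_edge
  )
}
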