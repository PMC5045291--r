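# Bondi van der Waals radii (angstrom) by element; hydrogens are expected
# to be absent from the models this package handles
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73)

#' Atomic structure container
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z` and optionally `radius`
#'   (van der Waals, angstrom). Missing radii are assigned from a standard
#'   (Bondi) element table.
#' @param title Optional provenance string.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, title = "") {
  req <- c("chain", "resno", "atom_name", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stop("empty model")
  if (!"resname" %in% names(atoms)) atoms$resname <- NA_character_
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (!"radius" %in% names(atoms) || anyNA(atoms$radius)) {
    r <- .vdw_radii[toupper(atoms$element)]
    if (anyNA(r))
      stop("no van der Waals radius for element(s): ",
           paste(unique(atoms$element[is.na(r)]), collapse = ", "))
    if (!"radius" %in% names(atoms)) atoms$radius <- unname(r)
    else atoms$radius[is.na(atoms$radius)] <- unname(r[is.na(atoms$radius)])
  }
  if (any(atoms$radius <= 0)) stop("radii must be positive")
  key <- paste(atoms$chain, atoms$resno, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) key: ", key[duplicated(key)][1])
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              x$title, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Wraps `bio3d::read.pdb`: keeps protein/hetero ATOM records, drops waters,
#' resolves alternate locations to the highest-occupancy conformer, and
#' assigns standard van der Waals radii by element.
#'
#' @param path Path to a PDB file.
#' @param keep_hetero Keep non-water HETATM records (default `FALSE`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, keep_hetero = FALSE) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no atoms in ", path)
  # altloc: keep highest occupancy per (chain, resno, atom) key
  key <- paste(at$chain, at$resno, at$elety)
  occ <- if (!is.null(at$o)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(elem)) || anyNA(elem))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  structure_model(
    data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
               atom_name = at$elety, element = elem,
               x = at$x, y = at$y, z = at$z),
    title = basename(path))
}

# deterministic Fibonacci sphere lattice: n approximately evenly spaced
# unit vectors
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's accessible sphere (radius + probe) is
#' sampled on a deterministic Fibonacci lattice and a point is accessible
#' if outside every neighboring atom's expanded sphere. Per-atom area is
#' the accessible point fraction times the sphere area.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius in angstrom (default 1.4, water).
#' @param n_points Lattice points per atom (default 960).
#' @return List with `total` (angstrom^2), `per_atom` (numeric vector), and
#'   the parameters used.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$radius + probe
  pts <- .fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  # neighbor lists via cutoff on pairwise distances (chunked for memory)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < rad[i] + rad[nb]]
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      # points exactly on a neighbor's expanded sphere (coincident atoms)
      # are occluded only by earlier-indexed atoms, so a duplicated surface
      # is counted once rather than twice or not at all
      tol <- 1e-9 * rad[j]^2
      buried <- if (j < i) dj2 < rad[j]^2 + tol else dj2 < rad[j]^2 - tol
      accessible <- accessible & !buried
      if (!any(accessible)) break
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * mean(accessible)
  }
  list(total = sum(per_atom), per_atom = per_atom,
       probe = probe, n_points = n_points)
}

#' Buried surface area of a binary interface
#'
#' `delta_total = SASA(a) + SASA(b) - SASA(a + b)`: the solvent-accessible
#' area lost when the two bodies associate. Both the total and the
#' per-interface half (`delta_total / 2`) are reported, since both
#' conventions are in use.
#'
#' @param a,b [structure_model()] objects (chains may overlap in naming;
#'   they are disambiguated internally).
#' @param probe,n_points Passed to [sasa()].
#' @return List with `delta_total`, `delta_half` (angstrom^2), component
#'   totals, and the SASA parameters used.
#' @export
buried_surface_area <- function(a, b, probe = 1.4, n_points = 960) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  aa <- a$atoms; ba <- b$atoms
  aa$chain <- paste0("A_", aa$chain)
  ba$chain <- paste0("B_", ba$chain)
  ab <- structure_model(rbind(aa, ba), title = "complex")
  sa <- sasa(structure_model(aa), probe, n_points)
  sb <- sasa(structure_model(ba), probe, n_points)
  sab <- sasa(ab, probe, n_points)
  delta <- sa$total + sb$total - sab$total
  list(delta_total = delta, delta_half = delta / 2,
       sasa_a = sa$total, sasa_b = sb$total, sasa_complex = sab$total,
       probe = probe, n_points = n_points)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1
#'   (checked to 1e-9).
#' @param translation Length-3 translation vector (angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)))
    stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  if (length(translation) != 3) stop("translation must have length 3")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a structure
#'
#' Maps every coordinate `x` to `R x + t`; all other fields are preserved.
#'
#' @param model A [structure_model()].
#' @param transform A [rigid_transform()].
#' @return The transformed [structure_model()].
#' @export
apply_transform <- function(model, transform) {
  stopifnot(inherits(model, "structure_model"),
            inherits(transform, "rigid_transform"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(transform$rotation)
  new <- sweep(new, 2, transform$translation, "+")
  out <- model
  out$atoms$x <- new[, 1]; out$atoms$y <- new[, 2]; out$atoms$z <- new[, 3]
  out
}

#' Crystallographic symmetry mate
#'
#' Applies an explicit fractional-space symmetry operator (3x3 matrix plus
#' translation, as printed in space-group tables) to a model given the unit
#' cell, returning the symmetry-related copy in Cartesian coordinates.
#' No space-group expansion is performed; the operator is supplied by the
#' caller.
#'
#' @param model A [structure_model()].
#' @param rot_frac 3x3 operator matrix in fractional coordinates.
#' @param trans_frac Length-3 fractional translation.
#' @param cell Unit cell: `c(a, b, c, alpha, beta, gamma)` (angstrom,
#'   degrees).
#' @return The symmetry-related [structure_model()].
#' @export
symmetry_mate <- function(model, rot_frac, trans_frac, cell) {
  stopifnot(inherits(model, "structure_model"), length(cell) == 6)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  # standard orthogonalization (PDB convention)
  M <- matrix(c(a, b * cos(ga), cc * cos(be),
                0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
                0, 0, cc * v / sin(ga)),
              nrow = 3, byrow = TRUE)
  Minv <- solve(M)
  xyz <- t(as.matrix(model$atoms[, c("x", "y", "z")]))
  frac <- Minv %*% xyz
  frac2 <- as.matrix(rot_frac) %*% frac + as.numeric(trans_frac)
  new <- t(M %*% frac2)
  out <- model
  out$atoms$x <- new[, 1]; out$atoms$y <- new[, 2]; out$atoms$z <- new[, 3]
  out$title <- paste0(model$title, " (symmetry mate)")
  out
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Matches atoms between two models by `(chain, residue number, atom name)`
#' intersection -- after applying an optional residue-number offset to `b`
#' and an optional chain map -- then computes the optimal rotation
#' (reflections excluded, determinant +1) and translation superposing `b`
#' onto `a`, and the RMSD over the matched atoms.
#'
#' @param a,b [structure_model()] objects.
#' @param offset Residue-number offset added to `b`'s numbering before
#'   matching (default 0).
#' @param chain_map Optional named character vector mapping `b` chains to
#'   `a` chains (default: match chain identifiers as-is; use
#'   `ignore_chain = TRUE` to match on residue number + atom name only).
#' @param ignore_chain Match only on (residue number, atom name)
#'   (default `FALSE`); requires unambiguous keys.
#' @return List with `rmsd` (angstrom), `transform`
#'   (a [rigid_transform()] mapping `b` onto `a`), and `n_atoms`.
#' @export
superpose_rmsd <- function(a, b, offset = 0, chain_map = NULL,
                           ignore_chain = FALSE) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  ba <- b$atoms
  ba$resno <- ba$resno + offset
  if (!is.null(chain_map)) {
    mapped <- chain_map[ba$chain]
    ba$chain <- ifelse(is.na(mapped), ba$chain, mapped)
  }
  key_a <- if (ignore_chain) paste(a$atoms$resno, a$atoms$atom_name)
           else paste(a$atoms$chain, a$atoms$resno, a$atoms$atom_name)
  key_b <- if (ignore_chain) paste(ba$resno, ba$atom_name)
           else paste(ba$chain, ba$resno, ba$atom_name)
  if (ignore_chain && (anyDuplicated(key_a) || anyDuplicated(key_b)))
    stop("ambiguous atom keys with ignore_chain = TRUE")
  common <- intersect(key_a, key_b)
  if (length(common) < 3) stop("fewer than 3 matched atoms")
  P <- as.matrix(a$atoms[match(common, key_a), c("x", "y", "z")])
  Q <- as.matrix(ba[match(common, key_b), c("x", "y", "z")])
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  s <- svd(crossprod(Q0, P0))  # H = Q0' P0; R = V D U' maps Q -> P
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2)
    stop("degenerate (collinear) atom set")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qr - P0)^2)))
  trans <- pc - as.numeric(R %*% qc)
  list(rmsd = rmsd,
       transform = rigid_transform(R, trans),
       n_atoms = length(common))
}
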