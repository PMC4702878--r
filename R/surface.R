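# Solvent-accessible surface area by the Shrake-Rupley rolling-probe
# method: each heavy atom's sphere (van der Waals radius + probe radius)
# is sampled with a deterministic quasi-uniform point set; points not
# buried inside any neighboring sphere contribute area.

#' Default van der Waals radii (Angstrom) by element
#' @format Named numeric vector.
#' @export
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, SE = 1.9)

#' Maximum residue solvent accessibility (Angstrom^2)
#'
#' Theoretical Gly-X-Gly maxima of Tien et al. (2013, PLoS ONE 8:e80635),
#' used as denominators for relative accessibility.
#'
#' @format Named numeric vector, 1-letter codes.
#' @export
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci lattice) construction: deterministic for a
#' given \code{n} and approximately uniform, which is what the
#' Shrake-Rupley quadrature needs.
#'
#' @param n Number of points (>= 1).
#' @return \code{n x 3} matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-atom SASA for all heavy atoms of the model (polymer and
#' ligand atoms occlude each other; hydrogens are ignored), sums per
#' residue, and derives relative accessibility against per-residue
#' maxima ([MAX_SASA]).
#'
#' @param model A [read_pdb()] model, or a data frame of atoms with
#'   columns \code{x, y, z, element} (and optionally \code{chain, resno,
#'   insert, resid, elety}).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii_table Element-to-radius lookup overriding [VDW_RADII].
#' @param default_radius Radius for unknown elements (with a warning).
#' @return Object of class \code{"SasaResult"}: list with \code{per_atom}
#'   (data frame with an \code{sasa} column, Angstrom^2),
#'   \code{per_residue} (chain, resno, insert, resid, sasa, relative) and
#'   the parameters used. Relative values above 1.2 are flagged via the
#'   \code{relative_flag} column.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         radii_table = VDW_RADII, default_radius = 1.7) {
  atoms <- if (inherits(model, "StructureModel")) {
    rbind_atom_tables(model$atoms, model$ligands)
  } else {
    as.data.frame(model)
  }
  stopifnot(all(c("x", "y", "z", "element") %in% names(atoms)))
  el <- toupper(trimws(atoms$element))
  atoms <- atoms[el != "H" & el != "D", , drop = FALSE]
  el <- el[el != "H" & el != "D"]
  n <- nrow(atoms)
  if (!n) stop("no heavy atoms to compute SASA for")

  r <- unname(radii_table[el])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using default radius ", default_radius, " Angstrom")
    r[is.na(r)] <- default_radius
  }
  R <- r + probe
  pts <- sphere_points(n_points)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)

  sasa <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    # candidate occluders: spheres that can reach atom i's surface
    dx <- xyz[, 1] - xyz[i, 1]
    dy <- xyz[, 2] - xyz[i, 2]
    dz <- xyz[, 3] - xyz[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    surf <- pts * R[i]
    surf <- sweep(surf, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      ddx <- surf[acc, 1] - xyz[j, 1]
      ddy <- surf[acc, 2] - xyz[j, 2]
      ddz <- surf[acc, 3] - xyz[j, 3]
      acc[acc] <- ddx * ddx + ddy * ddy + ddz * ddz > R[j]^2
    }
    sasa[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }

  atoms$sasa <- sasa
  per_res <- NULL
  if (all(c("chain", "resno", "resid") %in% names(atoms))) {
    if (!"insert" %in% names(atoms)) atoms$insert <- ""
    key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
    first <- !duplicated(key)
    per_res <- data.frame(
      chain = atoms$chain[first], resno = atoms$resno[first],
      insert = atoms$insert[first], resid = atoms$resid[first],
      sasa = as.numeric(tapply(atoms$sasa, key, sum)[key[first]]),
      stringsAsFactors = FALSE)
    letter <- AA_321[per_res$resid]
    per_res$relative <- per_res$sasa / unname(MAX_SASA[letter])
    per_res$relative_flag <- !is.na(per_res$relative) & per_res$relative > 1.2
  }
  out <- list(per_atom = atoms, per_residue = per_res,
              probe = probe, n_points = n_points)
  class(out) <- "SasaResult"
  out
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult: %d atoms, total %.1f Angstrom^2 (probe %.1f, %d points)\n",
              nrow(x$per_atom), sum(x$per_atom$sasa), x$probe, x$n_points))
  invisible(x)
}

rbind_atom_tables <- function(a, b) {
  common <- intersect(names(a), names(b))
  rbind(a[common], b[common])
}
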