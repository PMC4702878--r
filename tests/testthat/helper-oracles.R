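# Independent brute-force oracles and small geometric utilities shared
# across tests. These deliberately avoid the package's own fast paths.

# all-pairs neighbor scan: residues whose CA is within `cutoff` of the
# reference point, straight from the atom table
brute_neighbor_set <- function(model, ref_point, cutoff, exclude_resno) {
  a <- model$atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  keep <- logical(nrow(ca))
  for (i in seq_len(nrow(ca))) {
    d <- sqrt(sum((c(ca$x[i], ca$y[i], ca$z[i]) - ref_point)^2))
    keep[i] <- d <= cutoff && ca$resno[i] != exclude_resno
  }
  sort(ca$resno[keep])
}

# per-radius amino-acid recount from raw coordinates
brute_radial_counts <- function(model, ref_point, radii, exclude_resno,
                                aa321) {
  a <- model$atoms
  ca <- a[a$elety == "CA" & a$resno != exclude_resno, , drop = FALSE]
  d <- sqrt((ca$x - ref_point[1])^2 + (ca$y - ref_point[2])^2 +
              (ca$z - ref_point[3])^2)
  sapply(radii, function(r) {
    tb <- table(factor(aa321[ca$resid[d <= r]],
                       levels = sort(unname(aa321))))
    as.integer(tb)
  })
}

# random rotation matrix via QR of a Gaussian matrix, det forced to +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform to every coordinate of a StructureModel
rigid_transform <- function(model, R, t) {
  for (tab in c("atoms", "ligands")) {
    xyz <- as.matrix(model[[tab]][, c("x", "y", "z")])
    if (nrow(xyz)) {
      new <- xyz %*% t(R)
      model[[tab]]$x <- new[, 1] + t[1]
      model[[tab]]$y <- new[, 2] + t[2]
      model[[tab]]$z <- new[, 3] + t[3]
    }
  }
  model
}

# numeric spherical-quadrature SASA for a two-sphere system: area of
# sphere 1 (radius R1 centred at c1) outside sphere 2 (R2 at c2),
# computed on a fine lat-long grid with exact area weights
quadrature_sasa_two_spheres <- function(c1, R1, c2, R2, n_theta = 400,
                                        n_phi = 800) {
  mu <- seq(-1 + 1 / n_theta, 1 - 1 / n_theta, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-1]
  area_cell <- (2 / n_theta) * (2 * pi / n_phi) * R1^2
  total <- 0
  for (m in mu) {
    s <- sqrt(1 - m^2)
    px <- c1[1] + R1 * s * cos(phi)
    py <- c1[2] + R1 * s * sin(phi)
    pz <- c1[3] + R1 * m
    out <- (px - c2[1])^2 + (py - c2[2])^2 + (pz - c2[3])^2 > R2^2
    total <- total + sum(out) * area_cell
  }
  total
}

aa_321_table <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# minimal hand-written PDB text for parser tests
write_tiny_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

# assemble an in-memory StructureModel from per-atom rows
# rows: list of list(type, chain, resno, resid, elety, element, x, y, z)
model_from_rows <- function(rows, resolution = 1.8) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(type = r$type %||% "ATOM", chain = r$chain %||% "A",
               resno = r$resno, insert = "", resid = r$resid,
               elety = r$elety, element = r$element %||%
                 substr(r$elety, 1, 1), alt = "",
               x = r$x, y = r$y, z = r$z, o = 1,
               stringsAsFactors = FALSE)))
  m <- list(pdb_id = "MANUAL", resolution = resolution,
            experiment = "X-RAY DIFFRACTION",
            atoms = df[df$type == "ATOM", setdiff(names(df), "type")],
            ligands = df[df$type == "HETATM", setdiff(names(df), "type")])
  class(m) <- "StructureModel"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
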