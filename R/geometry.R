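# Side-chain orientation geometry and spatial composition around PTM
# substrate sites.
#
# For a substrate residue p and a spatially neighboring residue k:
#   S_k = X_p(modified atom) - X_k(Calpha)   (substrate-direction vector)
#   V_k = X_k(functional atom) - X_k(Calpha) (side-chain vector)
#   theta_k = arccos( S_k . V_k / (|S_k| |V_k|) ), in degrees.
# A neighbor with theta_k < 80 degrees is classified as a functional
# residue for the substrate site.

#' Functional side-chain atom lookup table
#'
#' Designated terminal side-chain atom representing each residue type's
#' chemical business end (e.g. OG for Ser, NZ for Lys). Glycine has no
#' side chain and no entry. The table is the package default and can be
#' overridden via the \code{table} argument of [functional_atom()].
#'
#' @format Named character vector: 1-letter residue code to atom name.
#' @export
FUNCTIONAL_ATOMS <- c(
  S = "OG", T = "OG1", Y = "OH", C = "SG", K = "NZ", R = "CZ",
  N = "ND2", Q = "NE2", D = "CG", E = "CD", H = "NE2", W = "NE1",
  F = "CZ", M = "SD", L = "CG", I = "CD1", V = "CB", A = "CB", P = "CG"
)

# Side-chain atom name heuristic: anything beyond the backbone set.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

atom_coord <- function(res, name) {
  i <- match(name, res$atoms$elety)
  if (is.na(i)) return(NULL)
  c(res$atoms$x[i], res$atoms$y[i], res$atoms$z[i])
}

#' Designated functional atom of a residue
#'
#' Returns the residue's designated side-chain functional atom per a fixed
#' lookup table ([FUNCTIONAL_ATOMS]). When the designated atom is not
#' resolved, falls back to the outermost resolved side-chain atom (largest
#' distance from Calpha) and flags the fallback. Glycine, and residues
#' with no resolved side-chain atoms, yield \code{NULL}.
#'
#' @param res Residue as returned by [get_residue()].
#' @param table Lookup table overriding [FUNCTIONAL_ATOMS].
#' @return List with \code{name}, \code{coord} (3-vector, Angstrom) and
#'   \code{fallback} flag, or \code{NULL} when no side chain is resolved.
#' @export
functional_atom <- function(res, table = FUNCTIONAL_ATOMS) {
  letter <- AA_321[res$resid]
  want <- if (!is.na(letter)) table[letter] else NA_character_
  if (!is.na(want)) {
    xyz <- atom_coord(res, want)
    if (!is.null(xyz))
      return(list(name = unname(want), coord = xyz, fallback = FALSE))
  }
  if (!is.na(letter) && letter == "G") return(NULL)
  # fallback: outermost resolved side-chain atom
  sc <- res$atoms[!res$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (!nrow(sc)) {
    warning("no side-chain atoms resolved for ", res$resid, " ",
            res$chain, ":", res$resno)
    return(NULL)
  }
  ca <- atom_coord(res, "CA")
  d <- if (is.null(ca)) rep(0, nrow(sc)) else
    sqrt((sc$x - ca[1])^2 + (sc$y - ca[2])^2 + (sc$z - ca[3])^2)
  i <- which.max(d)
  list(name = sc$elety[i], coord = c(sc$x[i], sc$y[i], sc$z[i]),
       fallback = TRUE)
}

#' Substrate-direction vector S_k
#'
#' Vector from a neighbor's Calpha atom to the substrate residue's
#' modified atom (its functional atom), in Angstrom.
#'
#' @param site_res Substrate residue ([get_residue()]).
#' @param neighbor_res Neighboring residue.
#' @return Numeric 3-vector.
#' @export
substrate_vector <- function(site_res, neighbor_res) {
  fa <- functional_atom(site_res)
  if (is.null(fa)) stop("substrate residue has no modified (functional) atom")
  ca <- atom_coord(neighbor_res, "CA")
  if (is.null(ca)) stop("neighbor residue lacks a Calpha atom")
  fa$coord - ca
}

#' Side-chain vector V_k
#'
#' Vector from a residue's Calpha to its functional atom, in Angstrom.
#' Returns \code{NULL} for glycine or when no side chain is resolved.
#'
#' @param res Residue ([get_residue()]).
#' @return Numeric 3-vector, or \code{NULL}.
#' @export
sidechain_vector <- function(res) {
  fa <- functional_atom(res)
  if (is.null(fa)) return(NULL)
  ca <- atom_coord(res, "CA")
  if (is.null(ca)) stop("residue lacks a Calpha atom")
  v <- fa$coord - ca
  if (sqrt(sum(v^2)) < 1e-9)
    stop("degenerate side-chain vector: functional atom coincides with Calpha")
  v
}

#' Orientation angle between two vectors, in degrees
#'
#' \eqn{\theta = \arccos(S \cdot V / (\|S\| \|V\|))}, with the normalized
#' dot product clamped to \eqn{[-1, 1]} so numerically (anti)parallel
#' vectors never raise a domain error.
#'
#' @param S,V Numeric 3-vectors (nonzero).
#' @return Angle in degrees, in \eqn{[0, 180]}.
#' @export
orientation_angle <- function(S, V) {
  ns <- sqrt(sum(S^2)); nv <- sqrt(sum(V^2))
  if (ns == 0 || nv == 0) stop("zero vector has no orientation")
  cosv <- sum(S * V) / (ns * nv)
  acos(max(-1, min(1, cosv))) * 180 / pi
}

#' Classify a neighbor as a functional residue
#'
#' A spatially neighboring residue whose side-chain orientation angle is
#' strictly less than the threshold (default 80 degrees) is classed as
#' functional for the substrate site.
#'
#' @param theta_deg Angle in degrees, \eqn{[0, 180]}.
#' @param threshold Threshold in degrees (default 80).
#' @return Logical.
#' @export
classify_functional <- function(theta_deg, threshold = 80) {
  stopifnot(all(theta_deg >= 0 & theta_deg <= 180))
  theta_deg < threshold
}

# Reference point of a mapped site for distance measurements.
site_reference_point <- function(model, mapped,
                                 reference = c("functional_atom", "calpha",
                                               "any_sidechain_atom")) {
  reference <- match.arg(reference)
  res <- get_residue(model, mapped$chain_id, mapped$resno, mapped$insert)
  if (reference == "calpha") {
    ca <- atom_coord(res, "CA")
    if (is.null(ca)) stop("site residue lacks a Calpha atom; ",
                          "no reference point available")
    return(list(point = matrix(ca, 1L, 3L), res = res))
  }
  fa <- functional_atom(res)
  if (reference == "functional_atom") {
    if (is.null(fa))
      stop("site residue has no resolved functional atom; ",
           "try reference = \"calpha\"")
    return(list(point = matrix(fa$coord, 1L, 3L), res = res))
  }
  sc <- res$atoms[!res$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (!nrow(sc))
    stop("site residue has no side-chain atoms; try reference = \"calpha\"")
  list(point = cbind(sc$x, sc$y, sc$z), res = res)
}

# One row per polymer residue with its Calpha position; file order kept.
calpha_table <- function(model) {
  a <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  a[!duplicated(paste(a$chain, a$resno, a$insert, sep = "\r")), ,
    drop = FALSE]
}

#' Spatial neighbors of a mapped PTM site
#'
#' Finds every residue (excluding the site itself) whose Calpha lies
#' within \code{cutoff} of the site's reference point, and computes for
#' each the distance, the side-chain orientation angle theta relative to
#' the substrate's modified atom, and the functional-residue flag.
#' With \code{reference = "any_sidechain_atom"} the distance is the
#' minimum over the site's side-chain atoms.
#'
#' @param model A [read_pdb()] model.
#' @param mapped A \code{"MappedSite"}.
#' @param cutoff Distance cutoff in Angstrom (default 10; residues at
#'   exactly the cutoff are included).
#' @param reference Site reference point: the site's functional atom
#'   (default), its Calpha, or the nearest of its side-chain atoms.
#' @param threshold Functional-residue angle threshold, degrees.
#' @return Data frame sorted by ascending distance (ties by chain then
#'   residue number): \code{chain, resno, insert, resid, aa, distance,
#'   theta_deg, functional}. Theta is \code{NA} for glycine or unresolved
#'   side chains.
#' @export
spatial_neighbors <- function(model, mapped, cutoff = 10,
                              reference = c("functional_atom", "calpha",
                                            "any_sidechain_atom"),
                              threshold = 80) {
  reference <- match.arg(reference)
  ref <- site_reference_point(model, mapped, reference)
  cas <- calpha_table(model)
  self <- cas$chain == mapped$chain_id & cas$resno == mapped$resno &
    cas$insert == mapped$insert
  cas <- cas[!self, , drop = FALSE]
  if (!nrow(cas)) return(empty_neighbors())

  # min distance from reference point(s) to each neighbor Calpha
  d <- vapply(seq_len(nrow(cas)), function(i) {
    dx <- ref$point[, 1] - cas$x[i]
    dy <- ref$point[, 2] - cas$y[i]
    dz <- ref$point[, 3] - cas$z[i]
    min(sqrt(dx * dx + dy * dy + dz * dz))
  }, numeric(1L))
  keep <- d <= cutoff
  cas <- cas[keep, , drop = FALSE]
  d <- d[keep]
  if (!nrow(cas)) return(empty_neighbors())

  site_fa <- functional_atom(ref$res)
  theta <- rep(NA_real_, nrow(cas))
  for (i in seq_len(nrow(cas))) {
    nres <- get_residue(model, cas$chain[i], cas$resno[i], cas$insert[i])
    v <- tryCatch(sidechain_vector(nres), error = function(e) NULL)
    if (is.null(v) || is.null(site_fa)) next
    ca <- atom_coord(nres, "CA")
    theta[i] <- orientation_angle(site_fa$coord - ca, v)
  }
  aa <- AA_321[cas$resid]
  aa[is.na(aa)] <- "X"
  out <- data.frame(
    chain = cas$chain, resno = cas$resno, insert = cas$insert,
    resid = cas$resid, aa = unname(aa), distance = d, theta_deg = theta,
    functional = ifelse(is.na(theta), NA,
                        classify_functional(ifelse(is.na(theta), 0, theta),
                                            threshold)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance, out$chain, out$resno, out$insert), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_neighbors <- function() {
  data.frame(chain = character(), resno = integer(), insert = character(),
             resid = character(), aa = character(), distance = numeric(),
             theta_deg = numeric(), functional = logical(),
             stringsAsFactors = FALSE)
}

#' Sequential neighbors of a site on its protein sequence
#'
#' Up to \code{window} residues upstream (offsets -window..-1) and
#' downstream (+1..+window) of the site, truncated at the termini.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based site position.
#' @param window Flank width (default 6, matching the -6..+6 display
#'   convention).
#' @return Data frame: \code{seq_offset, position, aa}.
#' @export
sequential_neighbors <- function(sequence, position, window = 6) {
  n <- nchar(sequence)
  stopifnot(position >= 1L, position <= n)
  if (window < 1L)
    return(data.frame(seq_offset = integer(), position = integer(),
                      aa = character(), stringsAsFactors = FALSE))
  off <- setdiff(seq.int(-window, window), 0L)
  pos <- position + off
  keep <- pos >= 1L & pos <= n
  data.frame(
    seq_offset = off[keep], position = pos[keep],
    aa = substring(sequence, pos[keep], pos[keep]),
    stringsAsFactors = FALSE)
}

#' Radial cumulative amino-acid composition around a PTM site
#'
#' For each radius on the grid (default 2..10 Angstrom in 1 Angstrom
#' steps), counts neighbor residues (Calpha within the radius of the
#' site's reference point, site excluded) by 1-letter code and normalizes
#' to relative frequencies. Non-standard residues are excluded from the
#' 20-amino-acid vectors and tallied separately.
#'
#' @inheritParams spatial_neighbors
#' @param radii Radius grid in Angstrom.
#' @return Object of class \code{"RadialProfile"}: list with \code{radii},
#'   \code{cumulative_counts} (radius x 20 matrix),
#'   \code{cumulative_freqs} (rows \code{NA} when the shell is empty) and
#'   \code{nonstandard} (per-radius count of non-standard residues).
#' @export
radial_composition <- function(model, mapped, radii = 2:10,
                               reference = c("functional_atom", "calpha",
                                             "any_sidechain_atom")) {
  reference <- match.arg(reference)
  nb <- spatial_neighbors(model, mapped, cutoff = max(radii),
                         reference = reference)
  counts <- matrix(0L, length(radii), length(STANDARD_AA),
                   dimnames = list(radii, STANDARD_AA))
  nonstd <- integer(length(radii))
  freqs <- matrix(NA_real_, length(radii), length(STANDARD_AA),
                  dimnames = list(radii, STANDARD_AA))
  for (j in seq_along(radii)) {
    within <- nb[nb$distance <= radii[j], , drop = FALSE]
    std <- within$aa[within$aa %in% STANDARD_AA]
    tb <- table(factor(std, levels = STANDARD_AA))
    counts[j, ] <- as.integer(tb)
    nonstd[j] <- sum(!within$aa %in% STANDARD_AA)
    tot <- sum(counts[j, ])
    if (tot > 0) freqs[j, ] <- counts[j, ] / tot
  }
  out <- list(radii = radii, cumulative_counts = counts,
              cumulative_freqs = freqs, nonstandard = nonstd)
  class(out) <- "RadialProfile"
  out
}

#' @export
print.RadialProfile <- function(x, ...) {
  cat("RadialProfile over radii", paste(range(x$radii), collapse = "-"),
      "Angstrom\n")
  tot <- rowSums(x$cumulative_counts)
  cat("residues within max radius:", tot[length(tot)], "\n")
  if (tot[length(tot)] > 0) {
    f <- x$cumulative_freqs[nrow(x$cumulative_freqs), ]
    top <- sort(f, decreasing = TRUE)[1:3]
    cat("modal amino acids:",
        paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Modal amino acid of a radial profile at its outermost radius
#'
#' @param profile A [radial_composition()] result.
#' @return 1-letter code of the most abundant amino acid (ties broken
#'   alphabetically), or \code{NA} when the profile is empty.
#' @export
modal_amino_acid <- function(profile) {
  stopifnot(inherits(profile, "RadialProfile"))
  cnt <- profile$cumulative_counts[nrow(profile$cumulative_counts), ]
  if (sum(cnt) == 0) return(NA_character_)
  names(cnt)[which.max(cnt)]
}

#' Full structural report for one mapped site
#'
#' Convenience wrapper combining spatial neighbors, sequential neighbors
#' (when a protein sequence is supplied), the radial composition profile
#' and per-residue solvent accessibility of the site.
#'
#' @inheritParams spatial_neighbors
#' @param sequence Optional protein sequence for sequential context.
#' @param window Sequential flank width.
#' @param sasa Logical; also compute the site residue's solvent
#'   accessibility (slower for large structures).
#' @return List with components \code{site}, \code{spatial},
#'   \code{sequential}, \code{radial} and optionally \code{sasa_site}.
#' @export
analyze_site <- function(model, mapped, cutoff = 10,
                         reference = "functional_atom",
                         sequence = NULL, window = 6, sasa = FALSE) {
  spatial <- spatial_neighbors(model, mapped, cutoff, reference)
  radial <- radial_composition(model, mapped,
                               radii = 2:max(2, ceiling(cutoff)),
                               reference = reference)
  sequential <- NULL
  if (!is.null(sequence))
    sequential <- sequential_neighbors(sequence, mapped$site$position,
                                       window)
  out <- list(site = mapped, spatial = spatial, sequential = sequential,
              radial = radial)
  if (isTRUE(sasa)) {
    sr <- compute_sasa(model)
    pr <- sr$per_residue
    i <- pr$chain == mapped$chain_id & pr$resno == mapped$resno &
      pr$insert == mapped$insert
    out$sasa_site <- pr[i, , drop = FALSE]
  }
  out
}
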