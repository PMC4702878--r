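# Drug-binding-associated PTM screen: ligand extraction from HETATM
# groups and side-chain-to-ligand minimum-distance screening. A PTM site
# whose side chain lies within 10 Angstrom of a bound drug-like ligand is
# regarded as drug-binding associated.

#' Het codes excluded from ligand extraction by default
#'
#' Waters plus common crystallization ions, buffers and cryoprotectants.
#'
#' @format Character vector of 3-letter chemical component codes.
#' @export
EXCLUDED_HET <- c(
  "HOH", "DOD", "WAT",
  "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO", "CD",
  "BR", "IOD", "F",
  "SO4", "PO4", "NO3", "ACT", "FMT", "CIT", "TRS", "EPE", "MES",
  "GOL", "EDO", "PEG", "PGE", "PG4", "MPD", "DMS", "BME", "IPA", "EOH"
)

#' Extract ligand groups from a structure model
#'
#' Partitions HETATM records into ligand groups by (het code, chain,
#' residue number, insertion code), dropping waters and other excluded
#' codes. An optional annotation table (het code to drug label) attaches
#' user-supplied drug identities.
#'
#' @param model A [read_pdb()] model.
#' @param exclude Het codes to drop (default [EXCLUDED_HET]).
#' @param annotation Optional data frame with columns \code{het_code} and
#'   \code{label}.
#' @return List of ligand groups, each a list with \code{het_code},
#'   \code{chain}, \code{resno}, \code{insert}, \code{annotation} and
#'   \code{atoms} (data frame of heavy atoms).
#' @export
extract_ligands <- function(model, exclude = EXCLUDED_HET,
                            annotation = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  h <- model$ligands
  if (!nrow(h)) return(list())
  h <- h[!h$resid %in% exclude, , drop = FALSE]
  el <- toupper(trimws(h$element))
  h <- h[el != "H" & el != "D", , drop = FALSE]
  if (!nrow(h)) return(list())
  key <- paste(h$resid, h$chain, h$resno, h$insert, sep = "\r")
  lapply(split(seq_len(nrow(h)), factor(key, levels = unique(key))),
         function(idx) {
           g <- h[idx, , drop = FALSE]
           lab <- NA_character_
           if (!is.null(annotation)) {
             m <- match(g$resid[1L], annotation$het_code)
             if (!is.na(m)) lab <- annotation$label[m]
           }
           list(het_code = g$resid[1L], chain = g$chain[1L],
                resno = g$resno[1L], insert = g$insert[1L],
                annotation = lab, atoms = g)
         })
}

#' Screen a mapped PTM site for ligand proximity
#'
#' For every ligand group in the model, computes the minimum heavy-atom
#' distance from any side-chain atom of the site residue (Calpha fallback
#' for glycine or side-chain-free residues, flagged) and marks contacts
#' within the cutoff. Sites within 10 Angstrom of a bound ligand are the
#' drug-binding-associated PTM candidates.
#'
#' @param model A [read_pdb()] model.
#' @param mapped A \code{"MappedSite"}.
#' @param cutoff Distance cutoff in Angstrom (default 10; contacts at
#'   exactly the cutoff count as within it).
#' @param ligands Optional pre-extracted [extract_ligands()] list.
#' @param ... Passed to [extract_ligands()].
#' @return Data frame sorted by ascending \code{min_distance}:
#'   \code{het_code, chain, resno, insert, annotation, min_distance,
#'   within_cutoff, calpha_fallback}.
#' @export
screen_drug_proximity <- function(model, mapped, cutoff = 10,
                                  ligands = NULL, ...) {
  stopifnot(inherits(model, "StructureModel"))
  if (is.null(ligands)) ligands <- extract_ligands(model, ...)
  res <- get_residue(model, mapped$chain_id, mapped$resno, mapped$insert)
  sc <- res$atoms[!res$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  fallback <- FALSE
  if (!nrow(sc)) {
    sc <- res$atoms[res$atoms$elety == "CA", , drop = FALSE]
    fallback <- TRUE
    if (!nrow(sc)) stop("site residue has neither side-chain atoms nor Calpha")
  }
  sp <- cbind(sc$x, sc$y, sc$z)
  rows <- lapply(ligands, function(lig) {
    lp <- cbind(lig$atoms$x, lig$atoms$y, lig$atoms$z)
    dmin <- min(vapply(seq_len(nrow(lp)), function(i) {
      dx <- sp[, 1] - lp[i, 1]; dy <- sp[, 2] - lp[i, 2]
      dz <- sp[, 3] - lp[i, 3]
      min(dx * dx + dy * dy + dz * dz)
    }, numeric(1L)))
    data.frame(het_code = lig$het_code, chain = lig$chain,
               resno = lig$resno, insert = lig$insert,
               annotation = lig$annotation, min_distance = sqrt(dmin),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(het_code = character(), chain = character(),
               resno = integer(), insert = character(),
               annotation = character(), min_distance = numeric(),
               stringsAsFactors = FALSE)
  out$within_cutoff <- out$min_distance <= cutoff
  out$calpha_fallback <- rep(fallback, nrow(out))
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
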