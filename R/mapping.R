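# Localization of PTM peptides/sites on structure chains at 100% sequence
# identity.

#' Find all exact-match offsets of a peptide in a chain sequence
#'
#' No mismatches are tolerated: mapping requires 100\% identity.
#'
#' @param peptide Peptide string (length >= 1).
#' @param chain_seq Chain sequence string.
#' @return Integer vector of 0-based match offsets, ascending; empty when
#'   the peptide does not occur.
#' @export
locate_peptide <- function(peptide, chain_seq) {
  stopifnot(is.character(peptide), nchar(peptide) >= 1L)
  hits <- gregexpr(peptide, chain_seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Map a PTM site onto a structure chain
#'
#' Scans every chain of the model for an exact (100\% identity) occurrence
#' of the modified peptide and localizes the substrate residue. A unique,
#' unambiguous match is required; models whose crystallographic resolution
#' is not better than \code{max_resolution} are rejected, mirroring the
#' restriction to X-ray structures solved at better than 2.5 Angstrom.
#'
#' @param site One site record (list or single-row data frame with
#'   \code{accession}, \code{position}, \code{residue}, \code{ptm_type}).
#' @param peptide Peptide carrying the site.
#' @param offset_in_peptide 0-based index of the modified residue within
#'   the peptide.
#' @param model A [read_pdb()] model.
#' @param max_resolution Resolution cutoff in Angstrom (strict \code{<};
#'   default 2.5). Models without a recorded resolution fail the filter.
#'   Set \code{check_resolution = FALSE} to disable.
#' @param check_resolution Apply the resolution filter (default TRUE).
#' @return An object of class \code{"MappedSite"}: list with \code{site},
#'   \code{pdb_id}, \code{chain_id}, \code{resno}, \code{insert},
#'   \code{peptide_span} (0-based half-open on the chain sequence) and
#'   \code{peptide}.
#' @export
map_site <- function(site, peptide, offset_in_peptide, model,
                     max_resolution = 2.5, check_resolution = TRUE) {
  stopifnot(inherits(model, "StructureModel"))
  site <- as.list(site)
  if (offset_in_peptide < 0L || offset_in_peptide >= nchar(peptide))
    stop("offset_in_peptide outside the peptide")
  if (substr(peptide, offset_in_peptide + 1L, offset_in_peptide + 1L) !=
      site$residue)
    stop("peptide residue at offset does not match site record")
  if (check_resolution &&
      (is.na(model$resolution) || model$resolution >= max_resolution)) {
    stop("structure ", model$pdb_id, " rejected: resolution ",
         if (is.na(model$resolution)) "unknown" else model$resolution,
         " is not better than ", max_resolution, " Angstrom")
  }

  chains <- unique(model$atoms$chain)
  cand <- list()
  for (ch in chains) {
    cs <- chain_sequence(model, ch)
    for (off in locate_peptide(peptide, cs$sequence)) {
      idx <- off + offset_in_peptide + 1L   # 1-based chain-sequence index
      cand[[length(cand) + 1L]] <- list(
        chain_id = ch, offset = off, index = idx,
        resno = cs$map$resno[idx], insert = cs$map$insert[idx],
        resid = cs$map$resid[idx])
    }
  }
  if (!length(cand)) {
    stop("peptide not found at 100% identity in any chain of ",
         model$pdb_id)
  }
  if (length(cand) > 1L) {
    desc <- vapply(cand, function(c)
      sprintf("%s:%d%s", c$chain_id, c$resno, c$insert), "")
    stop("ambiguous mapping in ", model$pdb_id, ": candidates ",
         paste(desc, collapse = ", "))
  }
  hit <- cand[[1L]]
  expect1 <- AA_321[hit$resid]
  if (is.na(expect1) || expect1 != site$residue) {
    stop("residue type mismatch at mapped position: chain has ",
         hit$resid, ", site record says ", site$residue)
  }
  out <- list(
    site = site, pdb_id = model$pdb_id, chain_id = hit$chain_id,
    resno = hit$resno, insert = hit$insert,
    peptide_span = c(hit$offset, hit$offset + nchar(peptide)),
    peptide = peptide)
  class(out) <- "MappedSite"
  out
}

#' @export
print.MappedSite <- function(x, ...) {
  cat(sprintf("MappedSite: %s pos %d (%s, %s) -> %s chain %s resno %d%s\n",
              x$site$accession, x$site$position, x$site$residue,
              x$site$ptm_type, x$pdb_id, x$chain_id, x$resno, x$insert))
  invisible(x)
}

# Convenience constructor for analyses starting from a known structure
# residue rather than a peptide mapping.
#' Build a MappedSite directly from a structure residue
#'
#' Useful when the substrate residue on the structure is already known
#' (e.g. interactive analysis of one site).
#'
#' @param model A [read_pdb()] model.
#' @param chain_id Chain label.
#' @param resno Author residue number.
#' @param insert Insertion code.
#' @param ptm_type PTM label attached to the synthesized site record.
#' @return A \code{"MappedSite"} object.
#' @export
site_at_residue <- function(model, chain_id, resno, insert = "",
                            ptm_type = "unspecified") {
  res <- get_residue(model, chain_id, resno, insert)
  cs <- chain_sequence(model, chain_id)
  idx <- which(cs$map$resno == resno & cs$map$insert == insert)
  letter <- AA_321[res$resid]
  if (is.na(letter)) letter <- "X"
  out <- list(
    site = list(accession = model$pdb_id, position = idx,
                residue = letter, ptm_type = ptm_type),
    pdb_id = model$pdb_id, chain_id = chain_id, resno = resno,
    insert = insert,
    peptide_span = c(idx - 1L, idx), peptide = letter)
  class(out) <- "MappedSite"
  out
}
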