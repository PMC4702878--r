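# Structure I/O: PDB parsing into a flat atom-table model, chain sequences,
# FASTA and PTM site tables.

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (first model only) into a flat atom table.
#' Polymer (ATOM) records populate the chain store; HETATM records,
#' including waters, are routed to the ligand store. Alternate locations
#' are resolved per \code{altloc_policy} so that no residue retains two
#' atoms with the same name. The crystallographic resolution is read from
#' the \code{REMARK   2} header when present.
#'
#' @param path Path to a PDB-format text file.
#' @param altloc_policy \code{"occupancy"} (default) keeps, for each
#'   duplicated atom name within a residue, the conformer with the highest
#'   occupancy (ties broken by alphabetically first altloc code);
#'   \code{"first"} keeps the first record in file order.
#' @return An object of class \code{"StructureModel"}: a list with
#'   \code{pdb_id}, \code{resolution} (Angstrom, \code{NA} when absent),
#'   \code{experiment}, \code{atoms} (polymer atom data frame) and
#'   \code{ligands} (HETATM data frame). Atom tables carry columns
#'   \code{chain, resno, insert, resid, elety, element, alt, x, y, z, o}.
#' @seealso [chain_sequence()], [get_residue()]
#' @export
read_pdb <- function(path, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)

  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # validate coordinate fields before parsing so errors carry line numbers
  coord_txt <- substr(lines[is_atom], 31, 54)
  bad <- grepl("[^0-9. +-]", coord_txt) | nchar(trimws(coord_txt)) == 0L
  if (any(bad)) {
    stop("malformed coordinate field at line ",
         which(is_atom)[which(bad)[1L]], " of ", path)
  }

  # first model only
  model_ends <- which(rec == "ENDMDL")
  keep_upto <- if (length(model_ends)) model_ends[1L] else length(lines)

  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$elesy[is.na(a$elesy)] <- ""
  df <- data.frame(
    type = a$type, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = a$insert, resid = a$resid,
    elety = a$elety, element = trimws(a$elesy), alt = a$alt,
    x = a$x, y = a$y, z = a$z, o = a$o,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in ", path)
  if (length(model_ends)) {
    nmod1 <- sum(is_atom[seq_len(keep_upto)])
    df <- df[seq_len(min(nmod1, nrow(df))), , drop = FALSE]
  }

  df <- resolve_altloc(df, altloc_policy)

  model <- list(
    pdb_id = sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
    resolution = parse_resolution(lines),
    experiment = parse_expdta(lines),
    atoms = df[df$type == "ATOM", setdiff(names(df), "type"), drop = FALSE],
    ligands = df[df$type == "HETATM", setdiff(names(df), "type"), drop = FALSE]
  )
  rownames(model$atoms) <- NULL
  rownames(model$ligands) <- NULL
  class(model) <- "StructureModel"
  model
}

parse_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1L], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)",
                                  rl[1L], perl = TRUE))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

parse_expdta <- function(lines) {
  el <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(el)) return(NA_character_)
  trimws(substr(el[1L], 11, nchar(el[1L])))
}

# Keep one conformer per (residue, atom name): highest occupancy, ties by
# alphabetically first altloc code.
resolve_altloc <- function(df, policy) {
  key <- paste(df$type, df$chain, df$resno, df$insert, df$elety, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  ord <- if (policy == "occupancy") {
    order(key, -df$o, df$alt)
  } else {
    order(key, seq_len(nrow(df)))
  }
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$type, df$chain, df$resno, df$insert,
                             df$elety, sep = "\r")), , drop = FALSE]
  # restore file order of the survivors
  df[order(as.integer(rownames(df))), , drop = FALSE]
}

#' @export
print.StructureModel <- function(x, ...) {
  nres <- nrow(unique(x$atoms[c("chain", "resno", "insert")]))
  cat(sprintf(
    "StructureModel %s: %d chain(s), %d residues, %d atoms, %d HETATM atoms\n",
    x$pdb_id, length(unique(x$atoms$chain)), nres, nrow(x$atoms),
    nrow(x$ligands)))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f Angstrom\n", x$resolution))
  invisible(x)
}

#' Derive a chain's one-letter sequence and residue-number map
#'
#' The sequence comes from ATOM-record residues in file order (resolved
#' residues only); non-standard residues render as \code{"X"}. The map links
#' each 1-based sequence index to the author residue number and insertion
#' code, which is the coordinate space reported to users.
#'
#' @param model A [read_pdb()] model.
#' @param chain_id Chain label.
#' @return A list with \code{sequence} (character scalar) and \code{map}
#'   (data frame: \code{index, resno, insert, resid}).
#' @export
chain_sequence <- function(model, chain_id) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(a)) stop("unknown chain: ", chain_id)
  key <- paste(a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  map <- data.frame(
    index = seq_len(sum(first)),
    resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], stringsAsFactors = FALSE
  )
  letters1 <- AA_321[map$resid]
  letters1[is.na(letters1)] <- "X"
  list(sequence = paste(letters1, collapse = ""), map = map)
}

#' Extract one residue (with its atoms) from a structure model
#'
#' @param model A [read_pdb()] model.
#' @param chain_id Chain label.
#' @param resno Author residue number.
#' @param insert Insertion code (default none).
#' @return List with \code{chain, resno, insert, resid} and \code{atoms}
#'   (data frame of the residue's atoms).
#' @export
get_residue <- function(model, chain_id, resno, insert = "") {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms[model$atoms$chain == chain_id &
                     model$atoms$resno == resno &
                     model$atoms$insert == insert, , drop = FALSE]
  if (!nrow(a)) {
    stop("no residue ", chain_id, ":", resno, insert, " in ", model$pdb_id)
  }
  list(chain = chain_id, resno = resno, insert = insert,
       resid = a$resid[1L], atoms = a)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read and validate a PTM site table
#'
#' Expects a TSV with header columns \code{accession}, \code{position}
#' (1-based), \code{residue} (1-letter), \code{ptm_type} and optionally
#' \code{pubmed_ids} (semicolon-separated). Duplicate
#' (accession, position, ptm_type) rows are collapsed with a warning.
#' When \code{sequences} is supplied, rows whose residue letter disagrees
#' with the sequence at that position are rejected; rejected row numbers
#' are reported and attached as attribute \code{"rejected"}.
#'
#' @param path TSV file.
#' @param sequences Optional named character vector (accession to sequence)
#'   used for residue validation.
#' @return Data frame of validated site records.
#' @export
read_site_table <- function(path, sequences = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "position", "residue", "ptm_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"pubmed_ids" %in% names(df)) df$pubmed_ids <- ""
  df$position <- as.integer(df$position)
  if (anyNA(df$position) || any(df$position < 1L))
    stop("site positions must be integers >= 1")
  key <- paste(df$accession, df$position, df$ptm_type, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (accession, position, ptm_type) row(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rejected <- df[0, , drop = FALSE]
  if (!is.null(sequences)) {
    ok <- vapply(seq_len(nrow(df)), function(i) {
      s <- sequences[[df$accession[i]]]
      !is.null(s) && df$position[i] <= nchar(s) &&
        substr(s, df$position[i], df$position[i]) == df$residue[i]
    }, logical(1L))
    if (any(!ok)) {
      warning("rejected ", sum(!ok), " site row(s) not matching the ",
              "supplied sequences (rows ",
              paste(which(!ok), collapse = ", "), ")")
      rejected <- df[!ok, , drop = FALSE]
      df <- df[ok, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

#' Write a PTM site table
#'
#' @param sites Data frame as returned by [read_site_table()].
#' @param path Output TSV path.
#' @export
write_site_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixed-column PDB writer used by the fixture generator and round-trip
# tests. `atoms` needs: type, chain, resno, insert, resid, elety, element,
# x, y, z, o.
write_pdb_atoms <- function(atoms, path, resolution = NULL,
                            pdb_id = "XXXX") {
  hdr <- sprintf("HEADER    SYNTHETIC FIXTURE%41s%s", "", pdb_id)
  lines <- c(hdr, "EXPDTA    X-RAY DIFFRACTION")
  if (!is.null(resolution) && !is.na(resolution)) {
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  }
  # PDB atom-name convention: 1-3 character names start in column 14
  fmt_name <- ifelse(nchar(atoms$elety) < 4L,
                     sprintf(" %-3s", atoms$elety),
                     atoms$elety)
  body <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$type, seq_len(nrow(atoms)), fmt_name, "", atoms$resid,
    atoms$chain, atoms$resno, atoms$insert, atoms$x, atoms$y, atoms$z,
    atoms$o, 0, atoms$element)
  writeLines(c(lines, body, "END"), path)
  invisible(path)
}
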