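# Deterministic synthetic-data generator. Every planted quantity
# (neighbor distance, orientation angle, ligand distance, fragment
# duplicate) is recoverable by the corresponding analysis operation, so
# fixtures double as construction-inverse oracles. A single integer seed
# governs all randomness; the global RNG state is restored on exit.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) v / sqrt(sum(v^2))

perpendicular <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(c(v[2] * a[3] - v[3] * a[2],
         v[3] * a[1] - v[1] * a[3],
         v[1] * a[2] - v[2] * a[1]))
}

#' Build a synthetic structure with planted geometry
#'
#' Writes a valid PDB file containing a central serine "site" residue
#' plus neighbor residues whose Calpha distances from the site's
#' functional atom (OG) and side-chain orientation angles realize the
#' planted values exactly, and optional single-atom ligand groups at
#' planted minimum distances from the site side chain. Ground truth is
#' returned (and written as TSV) so analyses can be checked against the
#' construction.
#'
#' @param spec List with elements:
#'   \describe{
#'     \item{seed}{integer (default 1); governs neighbor directions}
#'     \item{neighbors}{data frame with columns \code{distance}
#'       (Angstrom), \code{theta_deg} (degrees, \eqn{[0, 180]}) and
#'       optionally \code{aa} (1-letter code, default S)}
#'     \item{ligand_distances}{numeric vector of planted minimum
#'       side-chain-to-ligand distances}
#'     \item{resolution}{REMARK 2 resolution, Angstrom (default 1.8);
#'       \code{NA} omits the record}
#'   }
#' @param dir Output directory (created if needed).
#' @return List with \code{pdb} (file path), \code{model} (the same
#'   structure as an in-memory \code{"StructureModel"} with
#'   full-precision coordinates; the file is limited to the PDB format's
#'   3 decimals), \code{truth} (data frame), \code{truth_path} and
#'   \code{site} (chain/resno of the site residue).
#' @export
make_toy_structure <- function(spec = list(), dir = tempfile("toystruct")) {
  seed <- spec$seed %||% 1L
  nb <- spec$neighbors %||%
    data.frame(distance = numeric(), theta_deg = numeric())
  if (is.null(nb$aa)) nb$aa <- rep("S", nrow(nb))
  ligd <- spec$ligand_distances %||% numeric(0)
  resolution <- if ("resolution" %in% names(spec)) spec$resolution else 1.8
  stopifnot(all(nb$distance > 0), all(ligd > 0),
            all(nb$theta_deg >= 0 & nb$theta_deg <= 180))

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # site residue: SER, chain A, resno 100; CA at origin, CB and OG on +x
  site_ca <- c(0, 0, 0)
  site_cb <- c(1.5, 0, 0)
  site_og <- c(2.4, 0, 0)
  rows <- list(
    atom_row("ATOM", "A", 100L, "SER", "N",  "N", site_ca + c(-1.2, 0.8, 0)),
    atom_row("ATOM", "A", 100L, "SER", "CA", "C", site_ca),
    atom_row("ATOM", "A", 100L, "SER", "C",  "C", site_ca + c(-0.6, -1.3, 0.2)),
    atom_row("ATOM", "A", 100L, "SER", "O",  "O", site_ca + c(-0.5, -2.2, 0.9)),
    atom_row("ATOM", "A", 100L, "SER", "CB", "C", site_cb),
    atom_row("ATOM", "A", 100L, "SER", "OG", "O", site_og))

  truth <- list()
  dirs <- with_seed(seed, {
    # quasi-uniform, seed-jittered directions for neighbor placement
    base <- sphere_points(max(2L, nrow(nb)) + 2L)
    jit <- matrix(rnorm(length(base), sd = 0.05), ncol = 3L)
    t(apply(base + jit, 1L, unit))
  })
  for (i in seq_len(nrow(nb))) {
    u <- dirs[i, ]
    ca <- site_og + nb$distance[i] * u
    s_hat <- unit(site_og - ca)
    w <- perpendicular(s_hat)
    th <- nb$theta_deg[i] * pi / 180
    v_hat <- cos(th) * s_hat + sin(th) * w
    aa <- nb$aa[i]
    res3 <- AA_123[aa]
    if (is.na(res3)) stop("unknown amino acid code: ", aa)
    fname <- if (aa == "G") NA_character_ else
      unname(FUNCTIONAL_ATOMS[aa])
    resno <- 10L + i
    rows <- c(rows, list(
      atom_row("ATOM", "A", resno, res3, "N", "N", ca - 1.5 * w),
      atom_row("ATOM", "A", resno, res3, "CA", "C", ca)))
    if (!is.na(fname)) {
      rows <- c(rows, list(
        atom_row("ATOM", "A", resno, res3, "CB", "C", ca + 0.8 * v_hat),
        if (fname != "CB")
          atom_row("ATOM", "A", resno, res3, fname,
                   substr(fname, 1, 1), ca + 1.8 * v_hat)))
      rows <- Filter(Negate(is.null), rows)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "neighbor", chain = "A", resno = resno, aa = aa,
      distance = nb$distance[i], theta_deg = nb$theta_deg[i],
      stringsAsFactors = FALSE)
  }

  # ligands: single carbon atoms in the +x hemisphere so the site's OG
  # (not CB) is always the nearest side-chain atom
  if (length(ligd)) {
    ldirs <- sphere_points(length(ligd) + 2L)
    ldirs[, 1] <- abs(ldirs[, 1]) + 0.3
    ldirs <- t(apply(ldirs, 1L, unit))
    for (i in seq_along(ligd)) {
      pos <- site_og + ligd[i] * ldirs[i, ]
      resno <- 500L + i
      rows <- c(rows, list(
        atom_row("HETATM", "B", resno, "LIG", "C1", "C", pos)))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "ligand", chain = "B", resno = resno, aa = NA_character_,
        distance = ligd[i], theta_deg = NA_real_, stringsAsFactors = FALSE)
    }
  }
  # a few waters so extraction must filter them
  for (i in 1:3) {
    rows <- c(rows, list(
      atom_row("HETATM", "W", 900L + i, "HOH", "O", "O",
               c(25 + 3 * i, 25, 25))))
  }

  atoms <- do.call(rbind, rows)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.5)
    stop("infeasible geometry: planted atoms overlap (min separation ",
         round(dmin, 3), " Angstrom)")

  pdb_path <- file.path(dir, "toy.pdb")
  write_pdb_atoms(atoms, pdb_path, resolution = resolution,
                  pdb_id = "TOY1")
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), chain = character(), resno = integer(),
               aa = character(), distance = numeric(),
               theta_deg = numeric(), stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # in-memory model keeps full-precision coordinates (the PDB file is
  # limited to the format's 3 decimals)
  model <- list(
    pdb_id = "TOY1", resolution = resolution,
    experiment = "X-RAY DIFFRACTION",
    atoms = atoms[atoms$type == "ATOM", setdiff(names(atoms), "type")],
    ligands = atoms[atoms$type == "HETATM",
                    setdiff(names(atoms), "type")])
  rownames(model$atoms) <- NULL
  rownames(model$ligands) <- NULL
  class(model) <- "StructureModel"
  list(pdb = pdb_path, model = model, truth = truth_df,
       truth_path = truth_path, site = list(chain = "A", resno = 100L))
}

atom_row <- function(type, chain, resno, resid, elety, element, xyz) {
  data.frame(type = type, chain = chain, resno = resno, insert = "",
             resid = resid, elety = elety, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], o = 1,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a random in-memory structure for oracle cross-checks
#'
#' Serine-only chain with Calpha positions uniform in a cubic box and a
#' short side chain in a random direction; useful for brute-force
#' neighbor/composition oracles at sizes where writing files would be
#' wasteful. Residue types are drawn uniformly from the 20 standard
#' amino acids for composition tests, but every residue carries CB/OG
#' style pseudo-atoms named per its functional-atom convention.
#'
#' @param n_residues Number of residues.
#' @param seed Integer seed.
#' @param box Box edge length, Angstrom.
#' @return A \code{"StructureModel"} (no file written).
#' @export
make_random_structure <- function(n_residues, seed = 1L, box = 40) {
  with_seed(seed, {
    aa <- sample(names(FUNCTIONAL_ATOMS), n_residues, replace = TRUE)
    ca <- matrix(runif(3 * n_residues, 0, box), ncol = 3L)
    vdir <- matrix(rnorm(3 * n_residues), ncol = 3L)
    vdir <- vdir / sqrt(rowSums(vdir^2))
    fname <- unname(FUNCTIONAL_ATOMS[aa])
    res3 <- unname(AA_123[aa])
    mk <- function(elety, coords, keep = rep(TRUE, n_residues)) {
      data.frame(chain = "A", resno = seq_len(n_residues)[keep],
                 insert = "", resid = res3[keep], elety = elety[keep],
                 element = substr(elety[keep], 1, 1), alt = "",
                 x = coords[keep, 1], y = coords[keep, 2],
                 z = coords[keep, 3], o = 1, stringsAsFactors = FALSE)
    }
    atoms <- rbind(
      mk(rep("CA", n_residues), ca),
      mk(rep("CB", n_residues), ca + 0.9 * vdir, fname != "CB"),
      mk(fname, ca + 1.9 * vdir))
    atoms$element[atoms$elety == "CA"] <- "C"
    model <- list(pdb_id = sprintf("RND%d", seed), resolution = 1.5,
                  experiment = "X-RAY DIFFRACTION",
                  atoms = atoms, ligands = atoms[0, ])
    class(model) <- "StructureModel"
    model
  })
}

#' Generate a synthetic proteome with planted PTM sites
#'
#' Writes a FASTA of random protein sequences, a TSV of planted
#' modification sites on a subset of the proteins, and a JSON manifest of
#' expected benchmark counts. Exact-duplicate fragment windows can be
#' injected: duplicate positives (two annotated sites sharing one window,
#' collapsed by within-set clustering) and duplicate negatives (an
#' unannotated window identical to a positive window, removed by the
#' cross-set purge).
#'
#' Expected counts in the manifest are derived by direct scanning and
#' string set operations on the final sequences — never by running the
#' clustering pipeline — so they are an independent oracle. Because
#' random windows are pairwise far below the 50\% identity threshold with
#' overwhelming probability, expected survivor counts equal the distinct
#' window counts; the generator verifies this property by an all-pairs
#' scan and redraws from a derived seed in the (vanishingly rare) case it
#' fails.
#'
#' @param spec List with elements (all optional): \code{seed} (default 1),
#'   \code{n_proteins} (30), \code{length_range} (c(150, 300)),
#'   \code{target_residue} ("K"), \code{target_freq} (0.08),
#'   \code{n_modified} (20 proteins carrying sites), \code{n_sites} (40),
#'   \code{n_dup_positives} (0), \code{n_dup_negatives} (0),
#'   \code{window_n} (10).
#' @param dir Output directory.
#' @return List with \code{fasta}, \code{sites} (paths),
#'   \code{manifest} (list) and \code{manifest_path}.
#' @export
make_synthetic_proteome <- function(spec = list(),
                                    dir = tempfile("proteome")) {
  seed <- spec$seed %||% 1L
  n_prot <- spec$n_proteins %||% 30L
  lrange <- spec$length_range %||% c(150L, 300L)
  target <- spec$target_residue %||% "K"
  tfreq <- spec$target_freq %||% 0.08
  n_mod <- min(spec$n_modified %||% 20L, n_prot)
  n_sites <- spec$n_sites %||% 40L
  n_dup_pos <- spec$n_dup_positives %||% 0L
  n_dup_neg <- spec$n_dup_negatives %||% 0L
  wn <- spec$window_n %||% 10L

  for (attempt in 0:19) {
    out <- with_seed(seed + 1000L * attempt,
                     draw_proteome(n_prot, lrange, target, tfreq, n_mod,
                                   n_sites, n_dup_pos, n_dup_neg, wn))
    if (!is.null(out)) break
  }
  if (is.null(out)) stop("could not realize the proteome spec")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteome.fasta")
  write_fasta(out$seqs, fasta)
  sites_path <- file.path(dir, "sites.tsv")
  write_site_table(out$sites, sites_path)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(out$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  list(fasta = fasta, sites = sites_path, manifest = out$manifest,
       manifest_path = manifest_path)
}

draw_proteome <- function(n_prot, lrange, target, tfreq, n_mod, n_sites,
                          n_dup_pos, n_dup_neg, wn) {
  aas <- sort(unname(AA_321))
  probs <- setNames(rep((1 - tfreq) / 19, 20L), aas)
  probs[target] <- tfreq
  lens <- sample(lrange[1L]:lrange[2L], n_prot, replace = TRUE)
  accs <- sprintf("SYNP%03d", seq_len(n_prot))
  seqs <- setNames(vapply(lens, function(L)
    paste(sample(aas, L, replace = TRUE, prob = probs), collapse = ""),
    ""), accs)

  modified <- accs[seq_len(n_mod)]
  # interior target-residue occurrences eligible as sites
  occ_in <- lapply(seqs[modified], function(s) {
    p <- gregexpr(target, s, fixed = TRUE)[[1L]]
    p <- if (p[1L] == -1L) integer(0) else as.integer(p)
    p[p > wn & p <= nchar(s) - wn]
  })
  pool <- do.call(rbind, lapply(modified, function(acc) {
    if (!length(occ_in[[acc]])) return(NULL)
    data.frame(accession = acc, position = occ_in[[acc]],
               stringsAsFactors = FALSE)
  }))
  if (n_sites > 0L && (is.null(pool) || nrow(pool) < n_sites))
    return(NULL)
  pick <- if (n_sites > 0L) {
    p <- pool[sample(nrow(pool), n_sites), , drop = FALSE]
    p[order(p$accession, p$position), , drop = FALSE]
  } else {
    data.frame(accession = character(), position = integer(),
               stringsAsFactors = FALSE)
  }

  win <- function(acc, p) substr(seqs[[acc]], p - wn, p + wn)

  # Duplicate injections live on dedicated carrier proteins whose flanks
  # are free of the target residue. Copying a window in place inside an
  # existing protein would create partially overlapping negatives that
  # share > 50% identity with their source-side counterparts; carriers
  # keep every duplicate exact and everything else in general position.
  # Sources are restricted to sites whose window holds a single target
  # residue (the center) so carriers contribute no stray occurrences.
  clean <- vapply(seq_len(nrow(pick)), function(i) {
    w <- strsplit(win(pick$accession[i], pick$position[i]), "")[[1L]]
    sum(w == target) == 1L
  }, logical(1L))
  clean_sites <- pick[clean, , drop = FALSE]
  if ((n_dup_pos + n_dup_neg) > 0L && nrow(clean_sites) == 0L)
    return(NULL)
  aa_not <- setdiff(aas, target)
  flank <- function(L) paste(sample(aa_not, L, replace = TRUE),
                             collapse = "")
  extra_sites <- list()
  carriers <- character(0)
  for (i in seq_len(n_dup_pos)) {
    src <- clean_sites[sample(nrow(clean_sites), 1L), ]
    acc <- sprintf("SYNDUPP%02d", i)
    seqs[acc] <- paste0(flank(20L), win(src$accession, src$position),
                        flank(20L))
    extra_sites[[length(extra_sites) + 1L]] <- data.frame(
      accession = acc, position = 20L + wn + 1L, stringsAsFactors = FALSE)
    carriers <- c(carriers, acc)
  }
  for (i in seq_len(n_dup_neg)) {
    src <- clean_sites[sample(nrow(clean_sites), 1L), ]
    acc <- sprintf("SYNDUPN%02d", i)
    # unannotated copy of the source window (the cross-set duplicate)
    # plus a fresh annotated site so the carrier counts as modified
    fresh <- paste0(flank(wn), target, flank(wn))
    seqs[acc] <- paste0(flank(20L), win(src$accession, src$position),
                        flank(20L), fresh, flank(20L))
    extra_sites[[length(extra_sites) + 1L]] <- data.frame(
      accession = acc, position = 20L + (2L * wn + 1L) + 20L + wn + 1L,
      stringsAsFactors = FALSE)
    carriers <- c(carriers, acc)
  }
  modified <- c(modified, carriers)

  all_sites <- rbind(pick, do.call(rbind, extra_sites))
  all_sites <- all_sites[order(all_sites$accession, all_sites$position), ,
                         drop = FALSE]
  nsite <- nrow(all_sites)
  sites <- data.frame(
    accession = all_sites$accession, position = all_sites$position,
    residue = rep(target, nsite),
    ptm_type = rep("Ubiquitylation", nsite),
    pubmed_ids = rep("10000001", nsite), stringsAsFactors = FALSE)

  # ---- independent expected-count bookkeeping (direct scanning) ----
  pos_key <- paste(sites$accession, sites$position)
  pos_windows <- as.character(mapply(win, sites$accession,
                                     sites$position))
  modified <- unique(sites$accession)   # proteins actually carrying sites
  neg_windows <- unlist(lapply(modified, function(acc) {
    p <- gregexpr(target, seqs[[acc]], fixed = TRUE)[[1L]]
    p <- if (p[1L] == -1L) integer(0) else as.integer(p)
    p <- p[!paste(acc, p) %in% pos_key]
    vapply(p, function(q) extract_window(seqs[[acc]], q, wn), "")
  }))

  # general-position check: all distinct windows pairwise below 50%
  distinct_pos <- unique(pos_windows)
  distinct_neg <- unique(neg_windows)
  if (max_pair_identity(distinct_pos) >= 0.5) return(NULL)
  if (max_pair_identity(distinct_neg) >= 0.5) return(NULL)

  surviving_neg <- setdiff(distinct_neg, distinct_pos)
  manifest <- list(
    seed_note = "expected counts from direct scans and string set ops",
    target_residue = target, window_n = wn,
    n_proteins = n_prot, n_modified = length(modified),
    n_sites = nrow(sites),
    n_dup_positives = n_dup_pos,
    n_dup_negatives = n_dup_neg,
    expected_positives_raw = length(pos_windows),
    expected_negatives_raw = length(neg_windows),
    expected_positives_final = length(distinct_pos),
    expected_negatives_after_cluster = length(distinct_neg),
    expected_negatives_final = length(surviving_neg),
    expected_cross_purged = length(distinct_neg) - length(surviving_neg))
  list(seqs = seqs, sites = sites, manifest = manifest)
}

# maximum pairwise identity within a set of equal-length windows
max_pair_identity <- function(ws, pad = "-") {
  n <- length(ws)
  if (n < 2L) return(0)
  m <- 0
  for (i in seq_len(n - 1L)) {
    m <- max(m, max(identity_to_many(ws[i], ws[(i + 1L):n], pad)))
    if (m >= 0.5) return(m)
  }
  m
}
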