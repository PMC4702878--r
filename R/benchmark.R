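# Non-homologous benchmark dataset construction and predictor evaluation.
#
# Positive fragments: 2n+1 windows centered at experimentally verified
# PTM sites of the target residue type. Negative fragments: windows
# centered at every other occurrence of that residue type in the same
# (modified) proteins. Redundancy is removed by greedy incremental
# clustering at a within-set identity threshold (default 50%), then
# negatives identical to positives (cross-set identity 100%) are purged.

#' Extract a fixed-width sequence window around a site
#'
#' @param sequence Protein sequence string.
#' @param position 1-based site position.
#' @param n Flank width; the window is 2n+1 characters (default 10,
#'   giving 21-mers).
#' @param pad Terminus padding character (default \code{"-"}).
#' @return Character scalar of length 2n+1 with the site residue at the
#'   center.
#' @export
extract_window <- function(sequence, position, n = 10, pad = "-") {
  L <- nchar(sequence)
  if (position < 1L || position > L) stop("position out of range")
  lo <- position - n
  hi <- position + n
  core <- substr(sequence, max(1L, lo), min(L, hi))
  paste0(strrep(pad, max(0L, 1L - lo)), core, strrep(pad, max(0L, hi - L)))
}

#' Build positive and negative fragment sets
#'
#' Positives are windows at the annotated sites of the target residue;
#' negatives are windows at every other occurrence of that residue in the
#' same modified proteins. Proteins with no annotated site contribute
#' nothing. Sites whose residue differs from \code{target_residue} are
#' skipped with a warning.
#'
#' @param proteins Named character vector, accession to sequence.
#' @param sites Site table ([read_site_table()]).
#' @param target_residue 1-letter code of the residue type under study.
#' @param n Flank width (default 10).
#' @param pad Padding character.
#' @return List with \code{positives} and \code{negatives}, data frames
#'   with columns \code{accession, position, seq, label}.
#' @export
build_sets <- function(proteins, sites, target_residue, n = 10,
                       pad = "-") {
  wrong <- sites$residue != target_residue
  if (any(wrong)) {
    warning("skipping ", sum(wrong), " site(s) whose residue is not ",
            target_residue)
    sites <- sites[!wrong, , drop = FALSE]
  }
  sites <- sites[sites$accession %in% names(proteins), , drop = FALSE]
  pos_rows <- list(); neg_rows <- list()
  for (acc in unique(sites$accession)) {
    seqs <- proteins[[acc]]
    site_pos <- sort(unique(sites$position[sites$accession == acc]))
    occ <- gregexpr(target_residue, seqs, fixed = TRUE)[[1L]]
    occ <- if (occ[1L] == -1L) integer(0) else as.integer(occ)
    for (p in site_pos) {
      pos_rows[[length(pos_rows) + 1L]] <- data.frame(
        accession = acc, position = p,
        seq = extract_window(seqs, p, n, pad), label = "positive",
        stringsAsFactors = FALSE)
    }
    for (p in setdiff(occ, site_pos)) {
      neg_rows[[length(neg_rows) + 1L]] <- data.frame(
        accession = acc, position = p,
        seq = extract_window(seqs, p, n, pad), label = "negative",
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(accession = character(), position = integer(),
                      seq = character(), label = character(),
                      stringsAsFactors = FALSE)
  list(positives = if (length(pos_rows)) do.call(rbind, pos_rows) else empty,
       negatives = if (length(neg_rows)) do.call(rbind, neg_rows) else empty)
}

#' Pairwise identity of two equal-length fragments
#'
#' Fraction of positions carrying identical non-pad characters, with the
#' full window length as denominator (terminus pads count as mismatches).
#'
#' @param a,b Fragment strings of equal length.
#' @param pad Padding character.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
fragment_identity <- function(a, b, pad = "-") {
  if (nchar(a) != nchar(b)) stop("fragments differ in length")
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  sum(ca == cb & ca != pad) / length(ca)
}

# Vectorized identity of one fragment vs many (all equal length).
identity_to_many <- function(a, bs, pad = "-") {
  if (!length(bs)) return(numeric(0))
  L <- nchar(a)
  ca <- strsplit(a, "")[[1L]]
  m <- matrix(unlist(strsplit(bs, "")), nrow = L)
  colSums(m == ca & ca != pad) / L
}

#' Greedy incremental redundancy clustering
#'
#' Fragments are scanned in input order; each joins the first existing
#' cluster whose representative (founder) it matches at or above the
#' identity threshold, otherwise it founds a new cluster. Cluster
#' founders are the retained representatives, so no two representatives
#' match at the threshold or above. Deterministic for a fixed input
#' order.
#'
#' @param fragments Character vector of equal-length fragment strings, or
#'   a data frame with a \code{seq} column.
#' @param threshold Identity threshold (default 0.5).
#' @param pad Padding character.
#' @return Integer vector of representative indices into the input (in
#'   input order). For a data frame input, subset it with the result.
#' @export
greedy_cluster <- function(fragments, threshold = 0.5, pad = "-") {
  seqs <- if (is.data.frame(fragments)) fragments$seq else fragments
  if (!length(seqs)) return(integer(0))
  stopifnot(length(unique(nchar(seqs))) == 1L)
  reps <- 1L
  for (i in seq_along(seqs)[-1L]) {
    ids <- identity_to_many(seqs[i], seqs[reps], pad)
    if (!any(ids >= threshold)) reps <- c(reps, i)
  }
  reps
}

#' Purge negatives matching positives across sets
#'
#' Removes every negative whose identity to any positive reaches the
#' cross-set threshold. At the default threshold of 1.0 this removes
#' negatives that are exactly identical to a positive.
#'
#' @param positives,negatives Data frames with a \code{seq} column.
#' @param identity Cross-set identity threshold (default 1.0).
#' @param pad Padding character.
#' @return The purged negatives data frame.
#' @export
cross_purge <- function(positives, negatives, identity = 1.0, pad = "-") {
  if (!nrow(negatives) || !nrow(positives)) return(negatives)
  drop <- vapply(negatives$seq, function(s) {
    any(identity_to_many(s, positives$seq, pad) >= identity)
  }, logical(1L), USE.NAMES = FALSE)
  out <- negatives[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a complete non-homologous benchmark dataset
#'
#' Runs the full pipeline: window extraction, greedy within-set
#' redundancy reduction at \code{identity_threshold}, and cross-set
#' purging of negatives identical to positives.
#'
#' @inheritParams build_sets
#' @param ptm_type Label stored in the dataset.
#' @param identity_threshold Within-set identity threshold (default 0.5).
#' @param cross_identity Cross-set purge threshold (default 1.0).
#' @return Object of class \code{"BenchmarkDataset"}: list with
#'   \code{positives}, \code{negatives} (post-pipeline data frames with a
#'   \code{fragment_id} column \code{accession|position|label}),
#'   \code{target_residue}, \code{ptm_type}, \code{window_n},
#'   \code{identity_threshold}, \code{cross_identity} and \code{raw}
#'   (pre-clustering counts).
#' @export
build_benchmark <- function(proteins, sites, target_residue,
                            ptm_type = "unspecified", n = 10,
                            identity_threshold = 0.5,
                            cross_identity = 1.0, pad = "-") {
  sets <- build_sets(proteins, sites, target_residue, n, pad)
  raw <- c(positives = nrow(sets$positives),
           negatives = nrow(sets$negatives))
  pos <- sets$positives[greedy_cluster(sets$positives, identity_threshold,
                                       pad), , drop = FALSE]
  neg <- sets$negatives[greedy_cluster(sets$negatives, identity_threshold,
                                       pad), , drop = FALSE]
  neg <- cross_purge(pos, neg, cross_identity, pad)
  pos$fragment_id <- paste(pos$accession, pos$position, pos$label,
                           sep = "|")
  if (nrow(neg)) {
    neg$fragment_id <- paste(neg$accession, neg$position, neg$label,
                             sep = "|")
  } else neg$fragment_id <- character(0)
  rownames(pos) <- NULL; rownames(neg) <- NULL
  out <- list(positives = pos, negatives = neg,
              target_residue = target_residue, ptm_type = ptm_type,
              window_n = n, identity_threshold = identity_threshold,
              cross_identity = cross_identity, raw = raw)
  class(out) <- "BenchmarkDataset"
  out
}

#' @export
print.BenchmarkDataset <- function(x, ...) {
  cat(sprintf(
    "BenchmarkDataset (%s on %s, 2n+1 = %d): %d positives, %d negatives\n",
    x$ptm_type, x$target_residue, 2 * x$window_n + 1,
    nrow(x$positives), nrow(x$negatives)))
  cat(sprintf("  raw windows %d/%d; within-set identity < %.0f%%, no cross-set duplicates at %.0f%%\n",
              x$raw["positives"], x$raw["negatives"],
              100 * x$identity_threshold, 100 * x$cross_identity))
  invisible(x)
}

#' Write a benchmark dataset to disk
#'
#' Emits \code{positives.fasta} and \code{negatives.fasta} (headers
#' \code{accession|position|label}) plus a \code{manifest.json} recording
#' the parameters and counts.
#'
#' @param dataset A \code{"BenchmarkDataset"}.
#' @param dir Output directory (created if absent).
#' @export
write_benchmark <- function(dataset, dir) {
  stopifnot(inherits(dataset, "BenchmarkDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in c("positives", "negatives")) {
    df <- dataset[[set]]
    seqs <- setNames(as.character(df$seq), df$fragment_id)
    write_fasta(seqs, file.path(dir, paste0(set, ".fasta")))
  }
  manifest <- list(
    target_residue = dataset$target_residue, ptm_type = dataset$ptm_type,
    window_n = dataset$window_n,
    identity_threshold = dataset$identity_threshold,
    cross_identity = dataset$cross_identity,
    n_positives = nrow(dataset$positives),
    n_negatives = nrow(dataset$negatives),
    raw = as.list(dataset$raw))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Evaluate predictor output against a benchmark dataset
#'
#' Computes the confusion counts and the standard rates:
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and the Matthews
#' correlation coefficient. When an MCC denominator term is zero, MCC is
#' reported as 0 with \code{mcc_undefined = TRUE}.
#'
#' @param dataset A \code{"BenchmarkDataset"}.
#' @param predictions Named logical vector: fragment id (as in the
#'   dataset's \code{fragment_id} columns) to predicted-positive call.
#' @param missing Policy for fragments without a prediction:
#'   \code{"error"} (default) or \code{"negative"} (count as a negative
#'   call).
#' @return List with \code{TP, FP, TN, FN, Sn, Sp, Acc, MCC,
#'   mcc_undefined}.
#' @export
evaluate_predictions <- function(dataset, predictions,
                                 missing = c("error", "negative")) {
  stopifnot(inherits(dataset, "BenchmarkDataset"))
  missing <- match.arg(missing)
  ids <- c(dataset$positives$fragment_id, dataset$negatives$fragment_id)
  truth <- rep(c(TRUE, FALSE),
               c(nrow(dataset$positives), nrow(dataset$negatives)))
  unknown <- setdiff(names(predictions), ids)
  if (length(unknown)) {
    stop("predictions for unknown fragment(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  pred <- predictions[ids]
  if (anyNA(pred)) {
    if (missing == "error") {
      stop(sum(is.na(pred)), " fragment(s) lack a prediction")
    }
    pred[is.na(pred)] <- FALSE
  }
  TP <- sum(pred & truth); FP <- sum(pred & !truth)
  TN <- sum(!pred & !truth); FN <- sum(!pred & truth)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  undefined <- denom == 0
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       Acc = (TP + TN) / length(pred),
       MCC = if (undefined) 0 else
         (TP * TN - FP * FN) / denom,
       mcc_undefined = undefined)
}
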