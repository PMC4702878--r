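# Benchmark dataset construction and predictor evaluation.

test_that("window extraction centers the site and pads termini", {
  s <- paste(rep("ACDEFGHIKL", 5), collapse = "")   # length 50
  w <- extract_window(s, 25, n = 10)
  expect_equal(nchar(w), 21L)
  expect_equal(substr(w, 11, 11), substr(s, 25, 25))
  expect_equal(w, substr(s, 15, 35))
  w1 <- extract_window(s, 1, n = 10)
  expect_equal(w1, paste0(strrep("-", 10), substr(s, 1, 11)))
  expect_equal(extract_window(s, 7, n = 0), substr(s, 7, 7))
  expect_error(extract_window(s, 0), "out of range")
  expect_error(extract_window(s, 51), "out of range")
})

test_that("positives and negatives partition target occurrences in modified proteins", {
  proteins <- c(P1 = "KAKAK", P2 = "AAKAA")
  sites <- data.frame(accession = "P1", position = 1L, residue = "K",
                      ptm_type = "Ubiquitylation",
                      stringsAsFactors = FALSE)
  sets <- build_sets(proteins, sites, "K", n = 2)
  expect_equal(nrow(sets$positives), 1L)
  expect_equal(nrow(sets$negatives), 2L)       # K at 3 and 5
  expect_equal(sets$positives$seq, "--KAK")
  # P2 has no annotated site: contributes nothing
  expect_false("P2" %in% c(sets$positives$accession,
                           sets$negatives$accession))
  # conservation: positives + negatives = all K in modified proteins
  expect_equal(nrow(sets$positives) + nrow(sets$negatives),
               lengths(regmatches("KAKAK", gregexpr("K", "KAKAK"))))
})

test_that("sites of the wrong residue type are skipped with a warning", {
  proteins <- c(P1 = "KASAK")
  sites <- data.frame(accession = c("P1", "P1"), position = c(1L, 3L),
                      residue = c("K", "S"), ptm_type = "x",
                      stringsAsFactors = FALSE)
  expect_warning(sets <- build_sets(proteins, sites, "K", n = 1),
                 "skipping 1")
  expect_equal(nrow(sets$positives), 1L)
})

test_that("fragment identity counts matching non-pad positions over full length", {
  a <- strrep("A", 21)
  expect_equal(fragment_identity(a, a), 1.0)
  expect_equal(fragment_identity(a, strrep("C", 21)), 0.0)
  half <- paste0(strrep("A", 10), strrep("C", 11))
  expect_equal(fragment_identity(a, half), 10 / 21)
  # pads never count as matches
  p <- paste0("----------", strrep("A", 11))
  expect_equal(fragment_identity(p, p), 11 / 21)
  expect_error(fragment_identity("AAA", "AAAA"), "length")
})

test_that("greedy clustering collapses redundant fragments in input order", {
  frags <- rep(strrep("A", 21), 5)
  expect_equal(greedy_cluster(frags), 1L)
  two <- c(paste0(strrep("A", 8), strrep("C", 13)),
           paste0(strrep("A", 8), strrep("D", 13)))   # 8/21 < 0.5
  expect_equal(greedy_cluster(two, threshold = 0.5), c(1L, 2L))
  # representatives are pairwise below threshold (all-pairs oracle)
  set.seed(15)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pool <- vapply(1:120, function(i)
    paste(sample(aas, 21, replace = TRUE), collapse = ""), "")
  # inject redundancy: 30 mutated copies sharing >= 11 positions
  copies <- vapply(sample(120, 30, replace = TRUE), function(i) {
    x <- strsplit(pool[i], "")[[1]]
    idx <- sample(21, 8)
    x[idx] <- sample(aas, 8, replace = TRUE)
    paste(x, collapse = "")
  }, "")
  all <- c(pool, copies)
  reps <- greedy_cluster(all, threshold = 0.5)
  kept <- all[reps]
  for (i in seq_along(kept)[-1]) {
    for (j in 1:(i - 1)) {
      expect_lt(fragment_identity(kept[i], kept[j]), 0.5)
    }
  }
})

test_that("cross purge removes only negatives meeting the identity threshold", {
  pos <- data.frame(seq = c(strrep("A", 21), strrep("C", 21)),
                    stringsAsFactors = FALSE)
  near <- paste0(strrep("A", 20), "C")               # 20/21 ~ 95%
  neg <- data.frame(seq = c(strrep("A", 21), near, strrep("D", 21)),
                    stringsAsFactors = FALSE)
  purged <- cross_purge(pos, neg, identity = 1.0)
  expect_equal(purged$seq, c(near, strrep("D", 21)))
  # lower threshold also removes the 95% twin
  purged2 <- cross_purge(pos, neg, identity = 0.9)
  expect_equal(purged2$seq, strrep("D", 21))
})

test_that("the full pipeline reproduces the generator manifest exactly", {
  px <- make_synthetic_proteome(list(seed = 101, n_dup_positives = 4,
                                     n_dup_negatives = 10))
  seqs <- read_fasta(px$fasta)
  sites <- read_site_table(px$sites, seqs)
  expect_equal(nrow(attr(sites, "rejected")), 0L)
  bm <- build_benchmark(seqs, sites, "K", ptm_type = "Ubiquitylation")
  mf <- px$manifest
  expect_equal(unname(bm$raw["positives"]), mf$expected_positives_raw)
  expect_equal(unname(bm$raw["negatives"]), mf$expected_negatives_raw)
  expect_equal(nrow(bm$positives), mf$expected_positives_final)
  expect_equal(nrow(bm$negatives), mf$expected_negatives_final)
  # post-hoc all-pairs scans: non-homology within sets, no cross twins
  for (set in list(bm$positives$seq, bm$negatives$seq)) {
    n <- length(set)
    for (i in seq_len(n - 1)) {
      ids <- vapply(set[(i + 1):n], fragment_identity, 0, a = set[i])
      expect_true(all(ids < 0.5))
    }
  }
  expect_length(intersect(bm$positives$seq, bm$negatives$seq), 0L)
})

test_that("benchmark datasets round-trip through the on-disk format", {
  px <- make_synthetic_proteome(list(seed = 7))
  seqs <- read_fasta(px$fasta)
  sites <- read_site_table(px$sites, seqs)
  bm <- build_benchmark(seqs, sites, "K")
  dir <- tempfile("bmds")
  write_benchmark(bm, dir)
  pos <- read_fasta(file.path(dir, "positives.fasta"))
  expect_equal(unname(pos), bm$positives$seq)
  expect_equal(names(pos), bm$positives$fragment_id)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$n_positives, nrow(bm$positives))
})

test_that("a perfect predictor scores Sn = Sp = Acc = MCC = 1", {
  px <- make_synthetic_proteome(list(seed = 23))
  seqs <- read_fasta(px$fasta)
  bm <- build_benchmark(seqs, read_site_table(px$sites, seqs), "K")
  preds <- setNames(
    rep(c(TRUE, FALSE), c(nrow(bm$positives), nrow(bm$negatives))),
    c(bm$positives$fragment_id, bm$negatives$fragment_id))
  m <- evaluate_predictions(bm, preds)
  expect_equal(m$Sn, 1); expect_equal(m$Sp, 1)
  expect_equal(m$Acc, 1); expect_equal(m$MCC, 1)
  expect_false(m$mcc_undefined)
})

test_that("an all-positive predictor has Sn 1, Sp 0, undefined MCC flagged", {
  px <- make_synthetic_proteome(list(seed = 29))
  seqs <- read_fasta(px$fasta)
  bm <- build_benchmark(seqs, read_site_table(px$sites, seqs), "K")
  ids <- c(bm$positives$fragment_id, bm$negatives$fragment_id)
  m <- evaluate_predictions(bm, setNames(rep(TRUE, length(ids)), ids))
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 0)
  expect_equal(m$MCC, 0)
  expect_true(m$mcc_undefined)
})

test_that("a random predictor on a large balanced set has MCC near zero", {
  # synthesized fragment ids suffice: evaluation only joins on ids
  n <- 5000L
  ds <- list(
    positives = data.frame(fragment_id = sprintf("P|%d|positive", 1:n),
                           stringsAsFactors = FALSE),
    negatives = data.frame(fragment_id = sprintf("N|%d|negative", 1:n),
                           stringsAsFactors = FALSE))
  class(ds) <- "BenchmarkDataset"
  set.seed(37)
  ids <- c(ds$positives$fragment_id, ds$negatives$fragment_id)
  m <- evaluate_predictions(ds, setNames(sample(c(TRUE, FALSE), 2 * n,
                                                replace = TRUE), ids))
  expect_lt(abs(m$MCC), 0.05)
})

test_that("unknown fragments and missing predictions follow the policy", {
  px <- make_synthetic_proteome(list(seed = 41, n_proteins = 10L,
                                     n_modified = 6L, n_sites = 8L))
  seqs <- read_fasta(px$fasta)
  bm <- build_benchmark(seqs, read_site_table(px$sites, seqs), "K")
  ids <- c(bm$positives$fragment_id, bm$negatives$fragment_id)
  expect_error(
    evaluate_predictions(bm, setNames(TRUE, "bogus|1|positive")),
    "unknown")
  partial <- setNames(rep(TRUE, nrow(bm$positives)),
                      bm$positives$fragment_id)
  expect_error(evaluate_predictions(bm, partial), "lack a prediction")
  m <- evaluate_predictions(bm, partial, missing = "negative")
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 1)   # all missing negatives counted as negative calls
})
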