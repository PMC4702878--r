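# Side-chain orientation math, neighbor detection and radial composition.

res_from <- function(resid, atoms) {
  # atoms: named list elety -> coord
  df <- do.call(rbind, lapply(names(atoms), function(nm)
    data.frame(chain = "A", resno = 1L, insert = "", resid = resid,
               elety = nm, element = substr(nm, 1, 1), alt = "",
               x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
               o = 1, stringsAsFactors = FALSE)))
  list(chain = "A", resno = 1L, insert = "", resid = resid, atoms = df)
}

test_that("functional atoms follow the lookup table with fallback", {
  ser <- res_from("SER", list(N = c(0, 1, 0), CA = c(0, 0, 0),
                              CB = c(1.5, 0, 0), OG = c(2.4, 0, 0)))
  fa <- functional_atom(ser)
  expect_equal(fa$name, "OG")
  expect_false(fa$fallback)
  gly <- res_from("GLY", list(CA = c(0, 0, 0), N = c(1, 0, 0)))
  expect_null(functional_atom(gly))
  # LYS missing NZ: outermost resolved side-chain atom with a flag
  lys <- res_from("LYS", list(CA = c(0, 0, 0), CB = c(1.5, 0, 0),
                              CG = c(2.5, 0, 0), CD = c(3.5, 0, 0),
                              CE = c(4.5, 0, 0)))
  fa2 <- functional_atom(lys)
  expect_equal(fa2$name, "CE")
  expect_true(fa2$fallback)
})

test_that("substrate and side-chain vectors are plain coordinate differences", {
  site <- res_from("SER", list(CA = c(0.5, 0.5, 0.5), CB = c(1, 0, 0),
                               OG = c(1, 0, 0)))
  nb <- res_from("ALA", list(CA = c(0, 0, 0), CB = c(0, 0, 1)))
  expect_equal(substrate_vector(site, nb), c(1, 0, 0))
  # translation invariance of the difference
  shift <- c(3, -2, 7)
  site2 <- res_from("SER", list(CA = c(0.5, 0.5, 0.5) + shift,
                                CB = c(1, 0, 0) + shift,
                                OG = c(1, 0, 0) + shift))
  nb2 <- res_from("ALA", list(CA = shift, CB = c(0, 0, 1) + shift))
  expect_equal(substrate_vector(site2, nb2), c(1, 0, 0))
  ser <- res_from("SER", list(CA = c(0, 0, 0), CB = c(0, 0, 1),
                              OG = c(0, 0, 2)))
  expect_equal(sidechain_vector(ser), c(0, 0, 2))
  # degenerate: functional atom on top of CA
  bad <- res_from("SER", list(CA = c(0, 0, 0), CB = c(1, 0, 0),
                              OG = c(0, 0, 0)))
  expect_error(sidechain_vector(bad), "degenerate")
})

test_that("orientation angle handles parallel, orthogonal and clamped cases", {
  expect_equal(orientation_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(orientation_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(orientation_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(orientation_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
  # near-parallel vectors whose naive cosine exceeds 1
  v <- c(1, 1e-9, 0)
  expect_true(is.finite(orientation_angle(v, v)))
})

test_that("functional classification is strict at the 80 degree boundary", {
  expect_true(classify_functional(27.9))
  expect_false(classify_functional(80.0))
  expect_false(classify_functional(179.9))
  expect_true(classify_functional(79.999))
})

test_that("theta is invariant under rigid transforms and positive scaling", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    S <- rnorm(3); V <- rnorm(3)
    th <- orientation_angle(S, V)
    R <- random_rotation(); tvec <- rnorm(3, sd = 10)
    # vectors transform without translation; scaling leaves theta fixed
    th2 <- orientation_angle(as.vector(R %*% S), as.vector(R %*% V))
    th3 <- orientation_angle(runif(1, 0.1, 10) * S,
                             runif(1, 0.1, 10) * V)
    worst <- max(worst, abs(th - th2), abs(th - th3))
  }
  expect_lt(worst, 1e-9)
})

test_that("angle(S, V) + angle(S, -V) is always 180 degrees", {
  set.seed(7)
  for (i in 1:200) {
    S <- rnorm(3); V <- rnorm(3)
    expect_equal(orientation_angle(S, V) + orientation_angle(S, -V), 180,
                 tolerance = 1e-9)
  }
})

test_that("the 10 Angstrom neighbor boundary is inclusive", {
  fx <- make_toy_structure(list(seed = 5,
    neighbors = data.frame(distance = c(9.9, 10.1),
                           theta_deg = c(30, 90))))
  ms <- site_at_residue(fx$model, "A", 100)
  nb <- spatial_neighbors(fx$model, ms, cutoff = 10)
  expect_equal(nb$distance, 9.9, tolerance = 1e-9)
  # a neighbor at exactly the cutoff is included (binary-exact coords)
  m <- model_from_rows(list(
    list(resno = 1L, resid = "SER", elety = "CA", x = 0, y = 0, z = 0),
    list(resno = 1L, resid = "SER", elety = "CB", x = 1.5, y = 0, z = 0),
    list(resno = 1L, resid = "SER", elety = "OG", x = 2.5, y = 0, z = 0),
    list(resno = 2L, resid = "ALA", elety = "CA", x = 12.5, y = 0, z = 0),
    list(resno = 2L, resid = "ALA", elety = "CB", x = 13.5, y = 0, z = 0)))
  ms2 <- site_at_residue(m, "A", 1L)
  nb2 <- spatial_neighbors(m, ms2, cutoff = 10)
  expect_equal(nb2$distance, 10)
})

test_that("planted neighbors come back sorted with exact geometry", {
  fx <- make_toy_structure(list(seed = 6,
    neighbors = data.frame(distance = c(7.2, 3.1, 5.5),
                           theta_deg = c(150, 27.9, 80),
                           aa = c("R", "S", "N"))))
  ms <- site_at_residue(fx$model, "A", 100)
  nb <- spatial_neighbors(fx$model, ms)
  expect_equal(nb$distance, c(3.1, 5.5, 7.2), tolerance = 1e-9)
  expect_equal(nb$aa, c("S", "N", "R"))
  expect_equal(nb$theta_deg, c(27.9, 80, 150), tolerance = 1e-9)
  expect_equal(nb$functional, c(TRUE, FALSE, FALSE))
})

test_that("glycine neighbors get a distance but no orientation", {
  fx <- make_toy_structure(list(seed = 8,
    neighbors = data.frame(distance = c(4, 6), theta_deg = c(40, 0),
                           aa = c("G", "K"))))
  ms <- site_at_residue(fx$model, "A", 100)
  nb <- spatial_neighbors(fx$model, ms)
  expect_true(is.na(nb$theta_deg[nb$aa == "G"]))
  expect_true(is.na(nb$functional[nb$aa == "G"]))
  expect_false(is.na(nb$theta_deg[nb$aa == "K"]))
})

test_that("spatial neighbors match the all-pairs oracle on random structures", {
  for (seed in 1:8) {
    n <- c(60, 120, 250, 400, 80, 150, 300, 100)[seed]
    m <- make_random_structure(n, seed = seed)
    ms <- site_at_residue(m, "A", 1L)
    ref <- functional_atom(get_residue(m, "A", 1L))$coord
    nb <- spatial_neighbors(m, ms, cutoff = 10)
    expect_equal(sort(nb$resno),
                 brute_neighbor_set(m, ref, 10, 1L))
  }
})

test_that("sequential neighbors window, truncation and empty cases", {
  s <- "MKTAYIAKQRQISFVKSHFSRQ"
  mid <- sequential_neighbors(s, 10, window = 6)
  expect_equal(nrow(mid), 12L)
  expect_equal(mid$seq_offset, c(-6:-1, 1:6))
  expect_equal(mid$aa, strsplit(substr(s, 4, 16), "")[[1]][-7])
  first <- sequential_neighbors(s, 1, window = 6)
  expect_equal(nrow(first), 6L)
  expect_true(all(first$seq_offset > 0))
  expect_equal(nrow(sequential_neighbors(s, 10, window = 0)), 0L)
})

test_that("radial composition: single neighbor, empty shells, cumulation", {
  fx <- make_toy_structure(list(seed = 9,
    neighbors = data.frame(distance = 5, theta_deg = 45, aa = "A")))
  ms <- site_at_residue(fx$model, "A", 100)
  rp <- radial_composition(fx$model, ms, radii = 2:10)
  expect_s3_class(rp, "RadialProfile")
  # empty below 5 Angstrom: frequency undefined
  expect_true(all(is.na(rp$cumulative_freqs["4", ])))
  expect_equal(sum(rp$cumulative_counts["4", ]), 0L)
  # at 6 Angstrom the lone Ala dominates
  expect_equal(rp$cumulative_freqs["6", "A"], 1.0)
  expect_equal(sum(rp$cumulative_freqs["6", ]), 1.0)
  # counts monotone non-decreasing in radius
  expect_true(all(diff(rowSums(rp$cumulative_counts)) >= 0))
  expect_equal(modal_amino_acid(rp), "A")
})

test_that("radial counts equal a brute-force recount on random structures", {
  for (seed in c(3, 14)) {
    m <- make_random_structure(300, seed = seed)
    ms <- site_at_residue(m, "A", 1L)
    ref <- functional_atom(get_residue(m, "A", 1L))$coord
    rp <- radial_composition(m, ms, radii = 2:10)
    brute <- brute_radial_counts(m, ref, 2:10, 1L, aa_321_table)
    expect_equal(unname(t(rp$cumulative_counts)), unname(brute))
    tot <- rowSums(rp$cumulative_counts)
    nonempty <- tot > 0
    expect_equal(rowSums(rp$cumulative_freqs[nonempty, , drop = FALSE]),
                 setNames(rep(1, sum(nonempty)),
                          rownames(rp$cumulative_counts)[nonempty]))
  }
})

test_that("analyze_site bundles spatial, sequential and radial context", {
  fx <- make_toy_structure(list(seed = 10,
    neighbors = data.frame(distance = c(4, 8), theta_deg = c(30, 120),
                           aa = c("N", "R"))))
  ms <- site_at_residue(fx$model, "A", 100)
  rep <- analyze_site(fx$model, ms, sequence = "AAAASAAAA", sasa = TRUE)
  expect_equal(nrow(rep$spatial), 2L)
  expect_s3_class(rep$radial, "RadialProfile")
  expect_equal(nrow(rep$sasa_site), 1L)
  expect_gt(rep$sasa_site$sasa, 0)
})
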