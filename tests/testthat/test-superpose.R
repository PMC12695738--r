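# Rigid superposition, subunit shifts and cofactor site matching.

two_chain_model <- function() {
  build_toy_model(protein_chains = list(
    list(chain_id = "X", n = 60),
    list(chain_id = "Y", n = 40, start = c(25, 0, 0), axis = c(1, 0, 0))),
    model_id = "twochain")
}

test_that("pair_atoms pairs Calphas, reports unpaired, honours offsets", {
  m <- two_chain_model()
  p <- pair_atoms(m, m)
  expect_equal(nrow(p), 100)
  expect_equal(nrow(attr(p, "unpaired")), 0)

  # B missing 5 residues -> reported unpaired
  mb <- m
  mb$atoms <- mb$atoms[!(mb$atoms$chain_id == "X" &
                           mb$atoms$seq_id %in% 1:5), ]
  p2 <- pair_atoms(m, mb)
  expect_equal(nrow(p2), 95)
  un <- attr(p2, "unpaired")
  expect_equal(sort(un$seq_id[un$model == "A"]), 1:5)

  # declared residue-number offset shifts the pairing
  mo <- m
  mo$atoms$seq_id <- mo$atoms$seq_id + 100L
  p3 <- pair_atoms(m, mo, seq_offset = c(X = 100, Y = 100))
  expect_equal(nrow(p3), 100)
  expect_equal(p3$seq_b, p3$seq_a + 100)
  expect_equal(p3[, c("xa", "ya", "za")], p3[, c("xb", "yb", "zb")],
               ignore_attr = TRUE)

  expect_error(pair_atoms(m, mo), "fewer than 3")
})

test_that("superpose recovers planted transforms exactly", {
  m <- two_chain_model()
  sp0 <- superpose(pair_atoms(m, m))
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_about(30 * pi / 180)
  mb <- transformed_copy(m, R, c(5, 0, 0))
  sp <- superpose(pair_atoms(m, mb))
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # recovered transform is the inverse of the planted one
  expect_equal(sp$rotation %*% R, diag(3), tolerance = 1e-9)
  # and maps B's coordinates back onto A's
  xyz_b <- as.matrix(mb$atoms[, c("x", "y", "z")])
  back <- apply_superposition(sp, xyz_b)
  expect_lt(max(abs(back - as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-9)
})

test_that("superposition rmsd of a noisy copy matches sigma*sqrt(3)", {
  m <- build_toy_model(protein_chains = list(list(chain_id = "X", n = 600)))
  sigma <- 0.2
  mb <- transformed_copy(m, rotation_about(0.4, "x"), c(1, -2, 3),
                         noise_sigma = sigma, seed = 99)
  sp <- superpose(pair_atoms(m, mb))
  expect_equal(sp$rmsd, sigma * sqrt(3), tolerance = 0.10)
})

test_that("superposition rmsd is invariant under rigid pre-transforms", {
  m <- two_chain_model()
  set.seed(31)
  mb <- transformed_copy(m, random_rotation(), c(3, 1, -4),
                         noise_sigma = 0.3, seed = 5)
  r0 <- superpose(pair_atoms(m, mb))$rmsd
  ma2 <- transformed_copy(m, random_rotation(), c(-8, 12, 2))
  mb2 <- transformed_copy(mb, random_rotation(), c(7, 7, 7))
  expect_equal(superpose(pair_atoms(ma2, mb))$rmsd, r0, tolerance = 1e-9)
  expect_equal(superpose(pair_atoms(m, mb2))$rmsd, r0, tolerance = 1e-9)
})

test_that("superpose agrees with the bio3d reference fit", {
  m <- two_chain_model()
  set.seed(17)
  mb <- transformed_copy(m, random_rotation(), c(2, -1, 6),
                         noise_sigma = 0.5, seed = 8)
  pairing <- pair_atoms(m, mb)
  sp <- superpose(pairing)
  fixed <- as.numeric(t(as.matrix(pairing[, c("xa", "ya", "za")])))
  mobile <- as.numeric(t(as.matrix(pairing[, c("xb", "yb", "zb")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed, mobile))
  ref_rmsd <- sqrt(mean(colSums(
    (matrix(fixed, 3) - matrix(as.numeric(fitted), 3))^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("collinear pairings are rejected", {
  xyz <- cbind(seq_len(10), 0, 0)
  pairing <- data.frame(xa = xyz[, 1], ya = xyz[, 2], za = xyz[, 3],
                        xb = xyz[, 1], yb = xyz[, 2], zb = xyz[, 3])
  expect_error(superpose(pairing), "collinear|degenerate")
})

test_that("subunit_shift recovers a planted translation", {
  m <- two_chain_model()
  # identical models: zero shift
  ss0 <- subunit_shift(m, m, core_map = c(X = "X"),
                       subunit_map = c(Y = "Y"))
  expect_equal(ss0$centroid_shift, 0, tolerance = 1e-9)

  # chain Y translated 3.0 A after a global transform; core X anchors
  mb <- transformed_copy(m, rotation_about(0.7, "y"), c(10, 3, -2),
                         chain_offsets = list(Y = c(3, 0, 0)))
  ss <- subunit_shift(m, mb, core_map = c(X = "X"),
                      subunit_map = c(Y = "Y"))
  expect_equal(ss$centroid_shift, 3.0, tolerance = 1e-6)
  expect_equal(ss$per_atom_rmsd, 3.0, tolerance = 1e-6)
  expect_equal(ss$n_atoms, 40)

  # with core noise sigma the recovery error stays within 3*sigma/sqrt(n)
  sigma <- 0.2
  mbn <- transformed_copy(m, rotation_about(0.7, "y"), c(10, 3, -2),
                          chain_offsets = list(Y = c(3, 0, 0)),
                          noise_sigma = sigma, seed = 12)
  ssn <- subunit_shift(m, mbn, core_map = c(X = "X"),
                       subunit_map = c(Y = "Y"))
  expect_lt(abs(ssn$centroid_shift - 3.0), 3 * sigma / sqrt(40) + sigma)

  expect_error(subunit_shift(m, mb, core_map = c(X = "X"),
                             subunit_map = c(X = "X")),
               "excluded from the core")
  expect_error(subunit_shift(m, mb, core_map = c(X = "X"),
                             subunit_map = c(Z = "Z")), "absent")
})

test_that("match_cofactor_sites is a perfect matching on identical models", {
  m <- random_chl_model(8, seed = 23)
  tab <- match_cofactor_sites(m, m)
  expect_equal(nrow(tab$matched), 8)
  expect_true(all(tab$matched$distance < 1e-9))
  expect_true(all(tab$matched$same_category))
  expect_equal(nrow(tab$only_in_A), 0)
  expect_equal(nrow(tab$only_in_B), 0)

  # residue order must not matter
  ms <- m
  set.seed(3); ms$atoms <- ms$atoms[sample(nrow(ms$atoms)), ]
  tab2 <- match_cofactor_sites(m, ms)
  expect_equal(nrow(tab2$matched), 8)
  expect_true(all(tab2$matched$site_a == tab2$matched$site_b))
})

test_that("site deletions and type switches are reported", {
  m <- random_chl_model(6, seed = 29)
  mb <- m
  # delete one chlorophyll in B
  mb$atoms <- mb$atoms[mb$atoms$seq_id != 301, ]
  tab <- match_cofactor_sites(m, mb)
  expect_equal(nrow(tab$only_in_A), 1)
  expect_equal(tab$only_in_A$seq_id, 301)

  # switch one comp_id CLA -> KC2 at identical coordinates
  mc <- m
  sel <- mc$atoms$seq_id == 302
  mc$atoms$comp_id[sel] <- "KC2"
  mc <- classify_cofactors(mc)
  tab2 <- match_cofactor_sites(m, mc)
  row <- tab2$matched[tab2$matched$site_a == "P:302", ]
  expect_false(row$same_category)
  expect_equal(row$category_b, "chl_c")
})

test_that("greedy matching equals optimal assignment on well-separated sites", {
  radius <- 3
  for (seed in 1:5) {
    set.seed(seed)
    # <= 6 sites, all inter-site distances > 2 * radius
    n <- sample(3:6, 1)
    pts <- matrix(stats::runif(3 * n, 0, 60), ncol = 3)
    while (min(stats::dist(pts)) <= 2 * radius) {
      pts <- matrix(stats::runif(3 * n, 0, 60), ncol = 3)
    }
    jitter <- matrix(stats::runif(3 * n, -1, 1), ncol = 3)
    pts_b <- pts + jitter
    greedy <- chlnet:::.greedy_match(pts, pts_b, radius,
                                     seq_len(n), seq_len(n))
    oracle <- brute_force_assignment(pts, pts_b, radius)
    expect_equal(nrow(greedy), oracle$n)
    expect_equal(sum(greedy[, "dist"]), oracle$total, tolerance = 1e-9)
  }
})
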