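# Point-dipole FRET rates, the orientation factor and network assembly.

chl_at <- function(mg, u, kind = "chl_a") {
  u <- u / sqrt(sum(u^2))
  chlorophyll(mg, mg - 2.05 * u, mg + 2.05 * u, kind = kind)
}

test_that("kappa squared reproduces the canonical geometries", {
  d <- chl_at(c(0, 0, 0), c(0, 0, 1))
  a <- chl_at(c(10, 0, 0), c(0, 0, 1))
  expect_equal(kappa_squared(d, a), 1)                 # (1 - 0)^2
  a2 <- chl_at(c(10, 0, 0), c(1, 0, 0))
  d2 <- chl_at(c(0, 0, 0), c(1, 0, 0))
  expect_equal(kappa_squared(d2, a2), 4)               # (1 - 3)^2
  a3 <- chl_at(c(10, 0, 0), c(0, 1, 0))
  expect_equal(kappa_squared(d2, a3), 0)               # (0 - 0)^2
  expect_error(kappa_squared(d, d), "coincident")
})

test_that("kappa squared is bounded, flip- and exchange-invariant, isotropic mean 2/3", {
  set.seed(42)
  n <- 10000
  ud <- random_unit_vectors(n)
  ua <- random_unit_vectors(n)
  sep <- random_unit_vectors(n) * 12
  k2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- chl_at(c(0, 0, 0), ud[i, ])
    a <- chl_at(sep[i, ], ua[i, ])
    k2[i] <- kappa_squared(d, a)
    if (i <= 200) {
      # sign flip of either dipole and donor/acceptor exchange
      expect_equal(kappa_squared(chl_at(c(0, 0, 0), -ud[i, ]), a), k2[i])
      expect_equal(kappa_squared(d, chl_at(sep[i, ], -ua[i, ])), k2[i])
      expect_equal(kappa_squared(a, d), k2[i])
    }
  }
  expect_gte(min(k2), 0)
  expect_lte(max(k2), 4)
  expect_equal(mean(k2), 2 / 3, tolerance = 0.05)  # Monte-Carlo error
})

test_that("worked rate arithmetic: kappa^2=1, R=2 nm, C=32.26, n=1.55", {
  d <- chl_at(c(0, 0, 0), c(0, 0, 1))
  a <- chl_at(c(20, 0, 0), c(0, 0, 1))
  # independent hand arithmetic: 1.55^4 = 5.77200625, 2^6 = 64
  expect_equal(fret_rate(d, a), 32.26 / (5.77200625 * 64),
               tolerance = 1e-12)
  expect_equal(fret_rate(d, a), 0.0873, tolerance = 1e-3)
})

test_that("rate follows the R^-6 law and vanishes with kappa^2", {
  d <- chl_at(c(0, 0, 0), c(0, 0, 1))
  a1 <- chl_at(c(8, 0, 0), c(0, 0, 1))
  a2 <- chl_at(c(16, 0, 0), c(0, 0, 1))
  expect_equal(fret_rate(d, a1) / fret_rate(d, a2), 64, tolerance = 1e-9)
  d3 <- chl_at(c(0, 0, 0), c(1, 0, 0))
  a3 <- chl_at(c(10, 0, 0), c(0, 1, 0))
  expect_equal(fret_rate(d3, a3), 0)
})

test_that("pairs excluded by the pair rule give an explicit NA, not zero", {
  d <- chl_at(c(0, 0, 0), c(0, 0, 1))
  c_ <- chl_at(c(10, 0, 0), c(0, 0, 1), kind = "chl_c")
  expect_identical(fret_rate(d, c_), NA_real_)
  expect_identical(fret_rate(c_, d), NA_real_)
})

test_that("rate is invariant under global rigid transforms", {
  set.seed(11)
  d <- chl_at(c(1, 2, 3), c(0.3, -0.5, 0.8))
  a <- chl_at(c(12, -3, 7), c(-0.7, 0.1, 0.7))
  r0 <- fret_rate(d, a)
  for (rep in 1:20) {
    R <- random_rotation()
    t_ <- stats::rnorm(3, sd = 10)
    tf <- function(ch) chl_at(as.numeric(R %*% ch$mg + t_),
                              as.numeric(R %*% ch$dipole))
    expect_equal(fret_rate(tf(d), tf(a)), r0, tolerance = 1e-9)
  }
})

test_that("cutoff is inclusive and the pair rule disconnects chl c", {
  expect_equal(nrow(build_network(parallel_pair_model(19))$edges), 1)
  expect_equal(nrow(build_network(parallel_pair_model(21))$edges), 0)
  expect_equal(nrow(build_network(parallel_pair_model(20))$edges), 1)

  mixed <- build_toy_model(chlorophylls = list(
    placement_for(c(0, 0, 0), c(0, 0, 1)),
    placement_for(c(10, 0, 0), c(0, 0, 1), kind = "chl_c")))
  net <- build_network(mixed)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 2)   # chl c listed as a node
})

test_that("a fully connected clique has n(n-1)/2 edges", {
  n <- 7
  m <- build_toy_model(chlorophylls = lapply(seq_len(n), function(i)
    placement_for(c(5 * cos(2 * pi * i / n), 5 * sin(2 * pi * i / n), 0),
                  c(0, 0, 1))))
  expect_equal(nrow(build_network(m)$edges), n * (n - 1) / 2)
})

test_that("build_network equals the brute-force pair oracle on 50 random pigments", {
  m <- random_chl_model(50, box = 60, seed = 9)
  chl <- extract_chlorophylls(m)
  got <- build_network(m)$edges
  want <- brute_force_edges(chl)
  expect_equal(nrow(got), nrow(want))
  rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("network edges are invariant under rigid transforms of the model", {
  m <- random_chl_model(20, seed = 13)
  net0 <- build_network(m)
  set.seed(14)
  mt <- transformed_copy(m, random_rotation(), c(30, -10, 5))
  net1 <- build_network(mt)
  expect_equal(net1$edges$separation, net0$edges$separation,
               tolerance = 1e-9)
  expect_equal(net1$edges$kappa_sq, net0$edges$kappa_sq, tolerance = 1e-9)
  expect_equal(net1$edges$rate, net0$edges$rate, tolerance = 1e-9)
})

test_that("compare_networks matches, classifies and partitions edges", {
  m <- random_chl_model(12, seed = 21)
  net <- build_network(m)
  expect_gt(nrow(net$edges), 0)

  # identical networks under the identity mapping: all matched, all equal
  cmp <- compare_networks(net, net)
  expect_equal(nrow(cmp$matched), nrow(net$edges))
  expect_true(all(cmp$matched$status == "equal"))
  expect_equal(nrow(cmp$only_in_A), 0)
  expect_equal(nrow(cmp$only_in_B), 0)

  # B missing one edge: that edge lands in only_in_A with status absent
  netB <- net
  netB$edges <- netB$edges[-1, ]
  cmp2 <- compare_networks(net, netB)
  expect_equal(nrow(cmp2$only_in_A), 1)
  expect_equal(cmp2$only_in_A$status, "absent")
  expect_equal(nrow(cmp2$matched), nrow(net$edges) - 1)
})

test_that("scaling one pair's separation by 2^(1/6) halves the matched rate", {
  mA <- parallel_pair_model(10)
  mB <- parallel_pair_model(10 * 2^(1 / 6))
  cmp <- compare_networks(build_network(mA), build_network(mB))
  expect_equal(nrow(cmp$matched), 1)
  expect_equal(cmp$matched$rate_ratio, 0.5, tolerance = 1e-9)
  expect_equal(cmp$matched$status, "decreased")
})

test_that("non-injective correspondences are rejected", {
  net <- build_network(parallel_pair_model(10))
  corr <- data.frame(chain_a = c("P", "P"), seq_a = c(301, 302),
                     chain_b = c("P", "P"), seq_b = c(301, 301))
  expect_error(compare_networks(net, net, corr), "injective")
})

test_that("edge CSV and GraphML exports are written and deterministic", {
  net <- build_network(random_chl_model(8, seed = 2))
  csv1 <- tempfile(fileext = ".csv"); csv2 <- tempfile(fileext = ".csv")
  write_edges_csv(net, csv1); write_edges_csv(net, csv2)
  expect_identical(readLines(csv1), readLines(csv2))
  expect_equal(nrow(utils::read.csv(csv1)), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
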