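# Shared fixtures and independent oracles. All fixtures are built in code.

# a chl_placement with a valid orthogonal frame for an arbitrary dipole
placement_for <- function(center, u, kind = "chl_a") {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * u) * u
  w <- w / sqrt(sum(w^2))
  chl_placement(center, u, w, kind = kind)
}

# n chlorophylls at random centers/orientations inside a box (chl_a)
random_chl_model <- function(n, box = 30, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
  dirs <- random_unit_vectors(n)
  build_toy_model(
    chlorophylls = lapply(seq_len(n), function(i)
      placement_for(centers[i, ], dirs[i, ])),
    model_id = sprintf("rand%d_%d", n, seed))
}

# Oracle: brute-force double loop over all chl_a pairs with the scalar
# per-pair functions; independent of build_network's vectorised path.
brute_force_edges <- function(chl, p = fret_parameters()) {
  n <- nrow(chl)
  out <- list()
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (chl$kind[i] != "chl_a" || chl$kind[j] != "chl_a") next
      ci <- chlorophyll(chl[i, ]); cj <- chlorophyll(chl[j, ])
      sep <- mg_distance(ci, cj)
      if (sep > p$cutoff) next
      out[[length(out) + 1]] <- data.frame(
        donor_chain = chl$chain_id[i], donor_seq = chl$seq_id[i],
        acceptor_chain = chl$chain_id[j], acceptor_seq = chl$seq_id[j],
        separation = sep, kappa_sq = kappa_squared(ci, cj),
        rate = fret_rate(ci, cj, p))
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$donor_chain, df$donor_seq, df$acceptor_chain,
           df$acceptor_seq), ]
}

# Oracle: optimal one-to-one assignment by enumeration over permutations
# (feasible for <= 6 points). Minimises total distance over pairs within
# `radius`; returns the matched pair count and total distance.
brute_force_assignment <- function(xyz_a, xyz_b, radius) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  dmat <- as.matrix(stats::dist(rbind(xyz_a, xyz_b)))[seq_len(na),
                                                      na + seq_len(nb),
                                                      drop = FALSE]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- list(n = -1, total = Inf, pairs = NULL)
  idx_b <- seq_len(nb)
  for (pm in perms(idx_b)) {
    n_m <- 0; tot <- 0; pairs <- NULL
    for (i in seq_len(min(na, nb))) {
      d <- dmat[i, pm[i]]
      if (d <= radius) {
        n_m <- n_m + 1; tot <- tot + d
        pairs <- rbind(pairs, c(i, pm[i]))
      }
    }
    if (n_m > best$n || (n_m == best$n && tot < best$total)) {
      best <- list(n = n_m, total = tot, pairs = pairs)
    }
  }
  best
}

# hand-rolled fixed-width PDB serialisation of a structure_model's atom
# table (fixture construction only; parsing stays with the package)
write_fixture_pdb <- function(model, path) {
  a <- model$atoms
  name4 <- ifelse(nchar(a$atom) >= 4, a$atom,
                  sprintf(" %-3s", a$atom))
  rec <- ifelse(a$category == "protein", "ATOM  ", "HETATM")
  lines <- sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), name4,
    ifelse(a$alt_id == "", " ", a$alt_id),
    a$comp_id, a$chain_id, a$seq_id, a$x, a$y, a$z, a$occupancy, 0,
    a$element)
  writeLines(c(lines, "END"), path)
  path
}

# standard two-chlorophyll geometry: parallel dipoles along z, separation
# `sep` along x => kappa^2 = 1
parallel_pair_model <- function(sep) {
  build_toy_model(chlorophylls = list(
    chl_placement(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
    chl_placement(c(sep, 0, 0), c(0, 0, 1), c(1, 0, 0))),
    model_id = sprintf("pair%.3f", sep))
}
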