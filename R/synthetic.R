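#' Chlorophyll placement for the synthetic generator
#'
#' Describes an idealised chlorophyll coordination frame: the central Mg
#' at `center` and the four pyrrole nitrogens at 2.05 angstrom in the ring
#' plane, with the NB->ND axis along `dipole_direction`.
#'
#' @param center Numeric 3-vector, angstrom.
#' @param dipole_direction 3-vector; normalised internally.
#' @param plane_normal 3-vector orthogonal to `dipole_direction`
#'   (tolerance 1e-9 after normalisation); normalised internally.
#' @param kind `"chl_a"` or `"chl_c"`.
#' @return An object of class `chl_placement`.
#' @export
chl_placement <- function(center, dipole_direction = c(1, 0, 0),
                          plane_normal = c(0, 0, 1),
                          kind = c("chl_a", "chl_c")) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3, all(is.finite(center)))
  u <- dipole_direction / sqrt(sum(dipole_direction^2))
  w <- plane_normal / sqrt(sum(plane_normal^2))
  if (abs(sum(u * w)) > 1e-9) {
    stop("plane_normal must be orthogonal to dipole_direction")
  }
  structure(list(center = as.numeric(center), dipole_direction = u,
                 plane_normal = w, kind = kind),
            class = "chl_placement")
}

# Mg-N coordination distance of the idealised frame, angstrom
.CHL_MG_N <- 2.05

#' Emit the atoms of one idealised chlorophyll frame
#'
#' MG sits at the placement center; NB and ND sit at -/+ 2.05 angstrom
#' along the dipole direction so that `ND - NB` is parallel to it; NA and
#' NC complete the square in the ring plane. The component code is `CLA`
#' for chl a and `KC2` for chl c.
#'
#' @param p A [chl_placement].
#' @param chain_id,seq_id Author identifiers for the emitted residue.
#' @return Atom data.frame in [structure_model] column layout.
#' @export
make_chlorophyll_frame <- function(p, chain_id = "A", seq_id = 301L) {
  stopifnot(inherits(p, "chl_placement"))
  u <- p$dipole_direction
  v <- c(p$plane_normal[2] * u[3] - p$plane_normal[3] * u[2],
         p$plane_normal[3] * u[1] - p$plane_normal[1] * u[3],
         p$plane_normal[1] * u[2] - p$plane_normal[2] * u[1])
  comp <- if (p$kind == "chl_a") "CLA" else "KC2"
  pos <- rbind(MG = p$center,
               `NA` = p$center + .CHL_MG_N * v,
               NB = p$center - .CHL_MG_N * u,
               NC = p$center - .CHL_MG_N * v,
               ND = p$center + .CHL_MG_N * u)
  data.frame(chain_id = chain_id, seq_id = as.integer(seq_id),
             comp_id = comp, atom = rownames(pos),
             element = c("MG", "N", "N", "N", "N"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occupancy = 1, alt_id = "",
             category = p$kind, stringsAsFactors = FALSE)
}

#' Emit an idealised Fe4S4 cubane cluster (component SF4)
#'
#' Four Fe and four S on alternating vertices of a cube with 2.3 angstrom
#' Fe-S edges, centred at `center`.
#'
#' @param center Numeric 3-vector, angstrom.
#' @param chain_id,seq_id Author identifiers.
#' @return Atom data.frame in [structure_model] column layout.
#' @export
make_fes_cluster <- function(center, chain_id = "A", seq_id = 401L) {
  h <- 2.3 / 2
  sgn <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  parity <- (sgn[, 1] > 0) + (sgn[, 2] > 0) + (sgn[, 3] > 0)
  fe <- sgn[parity %% 2 == 0, ]
  s <- sgn[parity %% 2 == 1, ]
  pos <- rbind(fe, s)
  data.frame(chain_id = chain_id, seq_id = as.integer(seq_id),
             comp_id = "SF4",
             atom = c(paste0("FE", 1:4), paste0("S", 1:4)),
             element = c(rep("FE", 4), rep("S", 4)),
             x = pos[, 1] + center[1], y = pos[, 2] + center[2],
             z = pos[, 3] + center[3],
             occupancy = 1, alt_id = "",
             category = "fes_cluster", stringsAsFactors = FALSE)
}

.make_water <- function(center, chain_id = "W", seq_id = 1L) {
  data.frame(chain_id = chain_id, seq_id = as.integer(seq_id),
             comp_id = "HOH", atom = "O", element = "O",
             x = center[1], y = center[2], z = center[3],
             occupancy = 1, alt_id = "", category = "water",
             stringsAsFactors = FALSE)
}

# helical Calpha trace: standard alpha-helix geometry (2.3 A radius,
# 1.5 A rise, 100 degrees per residue), ALA residues
.make_helix <- function(n, chain_id = "X", start = c(0, 0, 0),
                        axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  pos <- outer(2.3 * cos(th), e1) + outer(2.3 * sin(th), e2) +
    outer(1.5 * i, axis)
  pos <- sweep(pos, 2, start, `+`)
  data.frame(chain_id = chain_id, seq_id = as.integer(seq_len(n)),
             comp_id = "ALA", atom = "CA", element = "C",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occupancy = 1, alt_id = "", category = "protein",
             stringsAsFactors = FALSE)
}

#' Build a synthetic structure model with planted ground truth
#'
#' Assembles chlorophyll frames, Fe4S4 clusters, waters and helical
#' Calpha-only protein chains into a [structure_model] whose geometry is
#' known exactly, so every downstream operation can be validated against
#' closed forms. Deterministic: the same spec always yields the same
#' model, and [write_mmcif()] of it is byte-identical.
#'
#' @param chlorophylls List of [chl_placement]s; residues are numbered
#'   301, 302, ... on chain `"P"` unless a placement carries `chain_id` /
#'   `seq_id` attributes.
#' @param clusters List of 3-vector centers (chain `"C"`, 401, 402, ...).
#' @param waters List of entries: either a 3-vector position, or
#'   `list(cluster = i, radius = r, direction = v)` planting a water whose
#'   nearest-atom distance to cluster `i` is exactly `r`, offset along `v`
#'   (chain `"W"`, 1, 2, ...).
#' @param protein_chains List of `list(chain_id =, n =, start =, axis =)`
#'   helical traces, or `list(chain_id =, xyz = matrix)` explicit traces.
#' @param model_id Identifier for the assembled model.
#' @return A [structure_model].
#' @export
build_toy_model <- function(chlorophylls = list(), clusters = list(),
                            waters = list(), protein_chains = list(),
                            model_id = "toy") {
  parts <- list()
  if (length(chlorophylls)) {
    parts <- c(parts, lapply(seq_along(chlorophylls), function(i) {
      p <- chlorophylls[[i]]
      ch <- attr(p, "chain_id"); sq <- attr(p, "seq_id")
      make_chlorophyll_frame(p,
                             chain_id = if (is.null(ch)) "P" else ch,
                             seq_id = if (is.null(sq)) 300L + i else sq)
    }))
  }
  cluster_atoms <- lapply(seq_along(clusters), function(i) {
    make_fes_cluster(clusters[[i]], chain_id = "C", seq_id = 400L + i)
  })
  parts <- c(parts, cluster_atoms)
  if (length(waters)) {
    parts <- c(parts, lapply(seq_along(waters), function(i) {
      w <- waters[[i]]
      if (is.numeric(w)) return(.make_water(w, seq_id = i))
      stopifnot(is.list(w), !is.null(w$cluster), !is.null(w$radius))
      cl <- cluster_atoms[[w$cluster]]
      xyz <- as.matrix(cl[, c("x", "y", "z")])
      v <- if (is.null(w$direction)) c(1, 0, 0) else w$direction
      v <- v / sqrt(sum(v^2))
      # place the water at radius r beyond the cluster atom that extends
      # furthest along v: its distance to that atom is exactly r, and to
      # every other atom at least r (projection bound), so the planted
      # nearest-atom distance is exact
      a_star <- xyz[which.max(xyz %*% v), ]
      .make_water(a_star + w$radius * v, seq_id = i)
    }))
  }
  if (length(protein_chains)) {
    parts <- c(parts, lapply(protein_chains, function(pc) {
      if (!is.null(pc$xyz)) {
        xyz <- as.matrix(pc$xyz)
        data.frame(chain_id = pc$chain_id,
                   seq_id = as.integer(seq_len(nrow(xyz))),
                   comp_id = "ALA", atom = "CA", element = "C",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, alt_id = "", category = "protein",
                   stringsAsFactors = FALSE)
      } else {
        .make_helix(pc$n, chain_id = pc$chain_id,
                    start = if (is.null(pc$start)) c(0, 0, 0) else pc$start,
                    axis = if (is.null(pc$axis)) c(0, 0, 1) else pc$axis)
      }
    }))
  }
  if (!length(parts)) stop("empty spec: nothing to build")
  atoms <- do.call(rbind, parts)
  key <- unique(atoms[, c("chain_id", "seq_id")])
  if (anyDuplicated(paste(key$chain_id, key$seq_id)) ||
      anyDuplicated(paste(atoms$chain_id, atoms$seq_id, atoms$atom))) {
    stop("duplicate (chain, seq) placement in spec")
  }
  structure_model(atoms, model_id = model_id, source_format = "synthetic")
}

#' Rigid-transformed (optionally noisy) copy of a model
#'
#' Applies `x -> R x + t` to all coordinates, then adds per-chain
#' translations (planting known subunit shifts) and optional i.i.d.
#' Gaussian coordinate noise under a fixed seed.
#'
#' @param model A [structure_model].
#' @param rotation 3x3 proper rotation (det = +1 within 1e-9).
#' @param translation Numeric 3-vector, angstrom.
#' @param chain_offsets Named list/vector of 3-vectors keyed by chain_id,
#'   added after the global transform.
#' @param noise_sigma Standard deviation of the added Gaussian noise per
#'   coordinate, angstrom (default 0).
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @param model_id Identifier of the copy.
#' @return The transformed [structure_model].
#' @export
transformed_copy <- function(model, rotation = diag(3),
                             translation = c(0, 0, 0),
                             chain_offsets = NULL, noise_sigma = 0,
                             seed = 1L, model_id = NULL) {
  stopifnot(inherits(model, "structure_model"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      abs(det(rotation) - 1) > 1e-9 ||
      max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9) {
    stop("rotation must be a proper orthogonal 3x3 matrix")
  }
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  if (!is.null(chain_offsets)) {
    for (ch in names(chain_offsets)) {
      idx <- a$chain_id == ch
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2,
                          chain_offsets[[ch]], `+`)
    }
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                        ncol = 3)
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  model$atoms <- a
  model$model_id <- if (is.null(model_id))
    paste0(model$model_id, "_copy") else model_id
  model
}

#' Rotation matrix about a coordinate axis
#'
#' Convenience for building planted transforms in tests and simulations.
#'
#' @param angle Angle in radians.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about <- function(angle, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE),
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE))
}

#' Uniformly random unit vectors and rotations
#'
#' `random_unit_vectors` draws directions uniformly on the sphere;
#' `random_rotation` draws a rotation uniformly from SO(3) (QR of a
#' Gaussian matrix with sign correction).
#'
#' @param n Number of vectors.
#' @return `random_unit_vectors`: n x 3 matrix; `random_rotation`: 3x3
#'   proper rotation.
#' @export
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' @rdname random_unit_vectors
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}
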