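#' Pair atoms between two models for superposition
#'
#' Pairs atoms (Calpha by default) with equal residue number under a chain
#' correspondence. Species differ in chain naming, so the correspondence is
#' user-supplied: a named character vector mapping chains of A to chains of
#' B, with an optional per-chain residue-number offset
#' (`seq_b = seq_a + offset`). Residues present on one side only are
#' reported in the `unpaired` attribute.
#'
#' @param modelA,modelB [structure_model]s.
#' @param chain_map Named character vector, `names = chains in A`,
#'   `values = chains in B`. Default: identity over the chains shared by
#'   both models.
#' @param seq_offset Named numeric vector of per-A-chain offsets
#'   (default 0).
#' @param atom_name Atom to pair (default `"CA"`).
#' @param categories Residue categories eligible for pairing (default
#'   `"protein"`).
#' @return data.frame of class `atom_pairing` with columns `chain_a`,
#'   `seq_a`, `chain_b`, `seq_b`, `xa`, `ya`, `za`, `xb`, `yb`, `zb`;
#'   attribute `unpaired` lists residues without a partner.
#' @export
pair_atoms <- function(modelA, modelB, chain_map = NULL, seq_offset = NULL,
                       atom_name = "CA", categories = "protein") {
  stopifnot(inherits(modelA, "structure_model"),
            inherits(modelB, "structure_model"))
  sel <- function(m) {
    a <- m$atoms
    a[a$atom == atom_name & a$category %in% categories, , drop = FALSE]
  }
  aa <- sel(modelA); bb <- sel(modelB)
  if (is.null(chain_map)) {
    shared <- intersect(unique(aa$chain_id), unique(bb$chain_id))
    chain_map <- stats::setNames(shared, shared)
  }
  rows <- list(); unpaired <- list()
  for (ca in names(chain_map)) {
    cb <- chain_map[[ca]]
    off <- if (!is.null(seq_offset) && ca %in% names(seq_offset))
      seq_offset[[ca]] else 0
    sa <- aa[aa$chain_id == ca, , drop = FALSE]
    sb <- bb[bb$chain_id == cb, , drop = FALSE]
    idx <- match(sa$seq_id + off, sb$seq_id)
    ok <- !is.na(idx)
    if (any(ok)) {
      rows[[ca]] <- data.frame(
        chain_a = ca, seq_a = sa$seq_id[ok],
        chain_b = cb, seq_b = sb$seq_id[idx[ok]],
        xa = sa$x[ok], ya = sa$y[ok], za = sa$z[ok],
        xb = sb$x[idx[ok]], yb = sb$y[idx[ok]], zb = sb$z[idx[ok]],
        stringsAsFactors = FALSE)
    }
    un_a <- sa[!ok, c("chain_id", "seq_id"), drop = FALSE]
    un_b <- sb[!(sb$seq_id %in% (sa$seq_id + off)),
               c("chain_id", "seq_id"), drop = FALSE]
    if (nrow(un_a)) unpaired[[paste0(ca, ".A")]] <-
        cbind(model = "A", un_a)
    if (nrow(un_b)) unpaired[[paste0(ca, ".B")]] <-
        cbind(model = "B", un_b)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_a = character(), seq_a = integer(),
               chain_b = character(), seq_b = integer(),
               xa = numeric(), ya = numeric(), za = numeric(),
               xb = numeric(), yb = numeric(), zb = numeric())
  rownames(out) <- NULL
  if (nrow(out) < 3) stop("fewer than 3 atom pairs: cannot superpose")
  attr(out, "unpaired") <- if (length(unpaired))
    do.call(rbind, c(unpaired, make.row.names = FALSE)) else
      data.frame(model = character(), chain_id = character(),
                 seq_id = integer())
  class(out) <- c("atom_pairing", "data.frame")
  out
}

# Kabsch closed form: proper rotation R and translation t minimising
# sum |xa - (R xb + t)|^2. Sign-corrected SVD guarantees det(R) = +1.
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_ <- ca - as.numeric(R %*% cb)
  list(rotation = R, translation = t_)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping model B's paired
#' atoms onto model A's in the least-squares sense, via the closed-form
#' singular-value decomposition with determinant sign correction.
#'
#' @param pairing An [pair_atoms()] result, or any data.frame with the
#'   same coordinate columns.
#' @return An object of class `superposition`: list with `rotation`
#'   (3x3, det = +1), `translation` (3-vector, angstrom), `rmsd`
#'   (angstrom over the pairing), `n_pairs`, `pairing`.
#' @export
superpose <- function(pairing) {
  A <- as.matrix(pairing[, c("xa", "ya", "za")])
  B <- as.matrix(pairing[, c("xb", "yb", "zb")])
  if (nrow(A) < 3) stop("fewer than 3 pairs: cannot superpose")
  # collinearity check: centered B must span at least 2 dimensions
  sv <- svd(sweep(B, 2, colMeans(B)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate (collinear) atom pairing: superposition ill-defined")
  }
  k <- .kabsch(A, B)
  Bt <- sweep(B %*% t(k$rotation), 2, k$translation, `+`)
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = rmsd, n_pairs = nrow(A), pairing = pairing),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates or a model
#'
#' Transforms points from the B frame into the A frame
#' (`x -> R x + t`).
#'
#' @param sp A [superpose()] result.
#' @param x An n x 3 matrix, or a [structure_model].
#' @return The transformed matrix or model.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "superposition"))
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- apply_superposition(sp, xyz)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  x <- matrix(as.numeric(x), ncol = 3)
  sweep(x %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Core-anchored displacement of an antenna subunit
#'
#' Fits the rigid transform on reference-core chains only (the subunit
#' under test is excluded from the fit), applies it to model B, then
#' measures how far the subunit moved: the distance between the Calpha
#' centroids of the subunit in A and in transformed B, plus the per-atom
#' RMSD over the paired subunit Calphas.
#'
#' @param modelA,modelB [structure_model]s.
#' @param core_map Named character vector mapping A's core chains to B's
#'   (e.g. PsaA/PsaB for PSI, D1/D2/CP43/CP47 for PSII).
#' @param subunit_map Length-1 named character vector mapping the subunit
#'   chain in A to its chain in B.
#' @param seq_offset Optional named offsets as in [pair_atoms()].
#' @return An object of class `subunit_shift`: list with `subunit`,
#'   `centroid_shift` (angstrom), `per_atom_rmsd`, `n_atoms`,
#'   `core_superposition`.
#' @export
subunit_shift <- function(modelA, modelB, core_map, subunit_map,
                          seq_offset = NULL) {
  stopifnot(length(subunit_map) == 1, !is.null(names(subunit_map)))
  if (names(subunit_map) %in% names(core_map)) {
    stop("subunit chain must be excluded from the core fit")
  }
  core_pairing <- pair_atoms(modelA, modelB, chain_map = core_map,
                             seq_offset = seq_offset)
  sp <- superpose(core_pairing)
  sub_pairing <- tryCatch(
    pair_atoms(modelA, modelB, chain_map = subunit_map,
               seq_offset = seq_offset),
    error = function(e) stop("subunit absent or too short in one model: ",
                             conditionMessage(e), call. = FALSE))
  A <- as.matrix(sub_pairing[, c("xa", "ya", "za")])
  B <- apply_superposition(sp, as.matrix(sub_pairing[, c("xb", "yb", "zb")]))
  centroid_shift <- sqrt(sum((colMeans(A) - colMeans(B))^2))
  per_atom_rmsd <- sqrt(mean(rowSums((A - B)^2)))
  structure(list(subunit = subunit_map, centroid_shift = centroid_shift,
                 per_atom_rmsd = per_atom_rmsd, n_atoms = nrow(A),
                 core_superposition = sp),
            class = "subunit_shift")
}

#' @export
print.subunit_shift <- function(x, ...) {
  cat(sprintf(
    "subunit_shift %s->%s: centroid %.2f A, per-atom rmsd %.2f A (n=%d; core rmsd %.2f A)\n",
    names(x$subunit), x$subunit, x$centroid_shift, x$per_atom_rmsd,
    x$n_atoms, x$core_superposition$rmsd))
  invisible(x)
}

# representative center of a cofactor residue: Mg for chlorophylls,
# geometric center of non-hydrogen atoms otherwise
.cofactor_centers <- function(model, categories) {
  a <- model$atoms
  a <- a[a$category %in% categories & !(a$element %in% c("H", "D")), ,
         drop = FALSE]
  sites <- unique(a[, c("chain_id", "seq_id", "comp_id", "category")])
  if (!nrow(sites)) {
    return(cbind(sites, data.frame(x = numeric(), y = numeric(),
                                   z = numeric())))
  }
  centers <- t(vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    ra <- a[a$chain_id == s$chain_id & a$seq_id == s$seq_id &
              a$comp_id == s$comp_id, , drop = FALSE]
    if (s$category %in% c("chl_a", "chl_c") && any(ra$atom == "MG")) {
      ra <- ra[ra$atom == "MG", , drop = FALSE]
    }
    c(mean(ra$x), mean(ra$y), mean(ra$z))
  }, numeric(3)))
  sites$x <- centers[, 1]; sites$y <- centers[, 2]; sites$z <- centers[, 3]
  rownames(sites) <- NULL
  sites
}

# Greedy nearest-first one-to-one matching between two point sets within
# `radius`. Deterministic tie-break: smaller distance, then A-side chain
# and residue number, then B-side. Returns integer index pairs.
.greedy_match <- function(xyz_a, xyz_b, radius, order_a, order_b) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  if (!na || !nb) return(cbind(i = integer(), j = integer(),
                               dist = numeric()))
  dmat <- as.matrix(stats::dist(rbind(xyz_a, xyz_b)))[seq_len(na),
                                                      na + seq_len(nb),
                                                      drop = FALSE]
  cand <- which(dmat <= radius, arr.ind = TRUE)
  if (!nrow(cand)) return(cbind(i = integer(), j = integer(),
                                dist = numeric()))
  dd <- dmat[cand]
  ord <- order(dd, order_a[cand[, 1]], order_b[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]; dd <- dd[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cbind(i = cand[keep, 1], j = cand[keep, 2], dist = dd[keep])
}

#' Match cofactor binding sites across two superposed structures
#'
#' After transforming model B into A's frame, representative centers
#' (chlorophylls: the Mg atom; other cofactors: the geometric center) are
#' matched one-to-one by greedy nearest-first assignment within
#' `match_radius`. A matched pair whose categories differ (e.g. chl a in
#' one structure, chl c in the other) is flagged as a type change.
#'
#' @param modelA,modelB Classified [structure_model]s.
#' @param sp [superpose()] result mapping B onto A (or `NULL` if already
#'   in the same frame).
#' @param match_radius Maximum center-center distance in angstrom
#'   (default 3.0: below inter-pigment spacing, above modelling jitter).
#' @param categories Cofactor categories to match (default pigments,
#'   lipids and Fe-S clusters).
#' @return An object of class `site_match_table`: list with `matched`
#'   (data.frame `site_a`, `site_b`, `comp_a`, `comp_b`, `category_a`,
#'   `category_b`, `distance`, `same_category`), `only_in_A`,
#'   `only_in_B`.
#' @export
match_cofactor_sites <- function(modelA, modelB, sp = NULL,
                                 match_radius = 3.0,
                                 categories = c("chl_a", "chl_c",
                                                "carotenoid", "lipid",
                                                "fes_cluster")) {
  ca <- .cofactor_centers(modelA, categories)
  cb <- .cofactor_centers(modelB, categories)
  if (nrow(cb) && !is.null(sp)) {
    xyz <- apply_superposition(sp, as.matrix(cb[, c("x", "y", "z")]))
    cb$x <- xyz[, 1]; cb$y <- xyz[, 2]; cb$z <- xyz[, 3]
  }
  m <- .greedy_match(as.matrix(ca[, c("x", "y", "z")]),
                     as.matrix(cb[, c("x", "y", "z")]),
                     match_radius,
                     order(order(ca$chain_id, ca$seq_id)),
                     order(order(cb$chain_id, cb$seq_id)))
  matched <- data.frame(
    site_a = .site_key(ca$chain_id[m[, "i"]], ca$seq_id[m[, "i"]]),
    site_b = .site_key(cb$chain_id[m[, "j"]], cb$seq_id[m[, "j"]]),
    comp_a = ca$comp_id[m[, "i"]], comp_b = cb$comp_id[m[, "j"]],
    category_a = ca$category[m[, "i"]], category_b = cb$category[m[, "j"]],
    distance = m[, "dist"],
    same_category = ca$category[m[, "i"]] == cb$category[m[, "j"]],
    stringsAsFactors = FALSE)
  only_a <- ca[!(seq_len(nrow(ca)) %in% m[, "i"]), , drop = FALSE]
  only_b <- cb[!(seq_len(nrow(cb)) %in% m[, "j"]), , drop = FALSE]
  rownames(only_a) <- rownames(only_b) <- NULL
  structure(list(matched = matched, only_in_A = only_a,
                 only_in_B = only_b, match_radius = match_radius),
            class = "site_match_table")
}

#' @export
print.site_match_table <- function(x, ...) {
  cat("site_match_table: ", nrow(x$matched), " matched (",
      sum(!x$matched$same_category), " type changes), ",
      nrow(x$only_in_A), " only in A, ", nrow(x$only_in_B),
      " only in B (radius ", x$match_radius, " A)\n", sep = "")
  invisible(x)
}
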