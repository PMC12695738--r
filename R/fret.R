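#' Parameters of the point-dipole FRET rate model
#'
#' The pairwise rate between chlorophylls is
#' \deqn{K_{DA} = C \, \kappa^2 / (n^4 R^6)}
#' with \eqn{\kappa^2} the transition-dipole orientation factor, `n` the
#' refractive index of the protein medium and `R` the Mg--Mg separation.
#' Under the convention adopted here `R` enters in nanometres and the rate
#' comes out in 1/ns; the overlap constant `C = 32.26` is the literature
#' value for chlorophyll a to chlorophyll a transfer in that convention.
#' Only chl a -> chl a pairs are connected by default because the overlap
#' constant involving chlorophyll c is not established.
#'
#' @param c_factor Spectral-overlap constant (default 32.26).
#' @param refractive_index Medium refractive index `n` (default 1.55).
#' @param cutoff Mg--Mg center-to-center cutoff in angstrom, inclusive
#'   (default 20).
#' @param pair_rule Currently `"chl_a_only"`.
#' @return An object of class `fret_parameters`.
#' @export
fret_parameters <- function(c_factor = 32.26, refractive_index = 1.55,
                            cutoff = 20, pair_rule = "chl_a_only") {
  stopifnot(c_factor > 0, refractive_index >= 1, cutoff > 0)
  pair_rule <- match.arg(pair_rule, "chl_a_only")
  structure(list(c_factor = c_factor, refractive_index = refractive_index,
                 cutoff = cutoff, pair_rule = pair_rule),
            class = "fret_parameters")
}

.as_chl <- function(x) {
  if (inherits(x, "chlorophyll")) x else chlorophyll(x)
}

#' Mg--Mg separation between two chlorophylls
#'
#' @param a,b [chlorophyll] objects (or one-row `chl_set` slices).
#' @return Euclidean distance in angstrom.
#' @export
mg_distance <- function(a, b) {
  a <- .as_chl(a); b <- .as_chl(b)
  d <- sqrt(sum((a$mg - b$mg)^2))
  if (d < 1e-6) stop("identical Mg positions: not a pigment pair")
  d
}

#' Transition-dipole orientation factor kappa squared
#'
#' \deqn{\kappa^2 = [\hat u_D\cdot\hat u_A -
#'   3(\hat u_D\cdot\hat R)(\hat u_A\cdot\hat R)]^2}
#' with \eqn{\hat R} the unit vector along the donor-to-acceptor Mg--Mg
#' axis. Bounded in [0, 4]; invariant under a sign flip of either dipole
#' and under donor/acceptor exchange.
#'
#' @param d,a Donor and acceptor [chlorophyll] objects.
#' @return Dimensionless value in [0, 4].
#' @export
kappa_squared <- function(d, a) {
  d <- .as_chl(d); a <- .as_chl(a)
  r <- a$mg - d$mg
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6) stop("coincident Mg positions: orientation factor undefined")
  rhat <- r / nr
  ud <- d$dipole; ua <- a$dipole
  (sum(ud * ua) - 3 * sum(ud * rhat) * sum(ua * rhat))^2
}

#' Pairwise FRET rate
#'
#' Returns `NA_real_` (an explicit "pair excluded" result, never a silent
#' zero) when the pair violates the active pair rule, i.e. when either
#' pigment is not chlorophyll a under `"chl_a_only"`.
#'
#' @param d,a Donor and acceptor [chlorophyll] objects.
#' @param p [fret_parameters].
#' @return Rate in 1/ns, or `NA_real_` for an excluded pair.
#' @export
fret_rate <- function(d, a, p = fret_parameters()) {
  d <- .as_chl(d); a <- .as_chl(a)
  if (p$pair_rule == "chl_a_only" &&
      (d$kind != "chl_a" || a$kind != "chl_a")) {
    return(NA_real_)
  }
  r_nm <- mg_distance(d, a) / 10
  p$c_factor * kappa_squared(d, a) / (p$refractive_index^4 * r_nm^6)
}

#' Build the chlorophyll energy-transfer network of a model
#'
#' Nodes are all extracted chlorophylls; one undirected edge connects each
#' chlorophyll-a pair whose Mg--Mg separation is at or below the cutoff
#' (inclusive boundary, so edge membership is deterministic). Under the
#' default pair rule chlorophyll-c nodes are listed but unconnected. The
#' rate is symmetric because the overlap constant is direction-independent
#' for a-to-a transfer.
#'
#' @param model A classified [structure_model], or a `chl_set` from
#'   [extract_chlorophylls()].
#' @param p [fret_parameters].
#' @return An object of class `fret_network`: list with `model_id`,
#'   `params`, `nodes` (the `chl_set`) and `edges` (data.frame
#'   `donor_chain`, `donor_seq`, `acceptor_chain`, `acceptor_seq`,
#'   `separation`, `kappa_sq`, `rate`).
#' @export
build_network <- function(model, p = fret_parameters()) {
  chl <- if (inherits(model, "chl_set")) model else
    extract_chlorophylls(model)
  n <- nrow(chl)
  mg <- as.matrix(chl[, c("mg_x", "mg_y", "mg_z")])
  u <- as.matrix(chl[, c("ux", "uy", "uz")])
  is_a <- chl$kind == "chl_a"
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (!is_a[i]) next
      for (j in seq((i + 1), n)) {
        if (!is_a[j]) next
        dv <- mg[j, ] - mg[i, ]
        sep <- sqrt(sum(dv^2))
        if (sep > p$cutoff || sep < 1e-6) next
        rhat <- dv / sep
        k2 <- (sum(u[i, ] * u[j, ]) -
                 3 * sum(u[i, ] * rhat) * sum(u[j, ] * rhat))^2
        rate <- p$c_factor * k2 /
          (p$refractive_index^4 * (sep / 10)^6)
        edges[[length(edges) + 1]] <- data.frame(
          donor_chain = chl$chain_id[i], donor_seq = chl$seq_id[i],
          acceptor_chain = chl$chain_id[j], acceptor_seq = chl$seq_id[j],
          separation = sep, kappa_sq = k2, rate = rate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(donor_chain = character(), donor_seq = integer(),
               acceptor_chain = character(), acceptor_seq = integer(),
               separation = numeric(), kappa_sq = numeric(),
               rate = numeric())
  # canonical edge order: donor site then acceptor site
  edges <- edges[order(edges$donor_chain, edges$donor_seq,
                       edges$acceptor_chain, edges$acceptor_seq), ]
  rownames(edges) <- NULL
  structure(list(model_id = attr(chl, "model_id"), params = p,
                 nodes = chl, edges = edges),
            class = "fret_network")
}

#' @export
print.fret_network <- function(x, ...) {
  cat("fret_network '", x$model_id, "': ", nrow(x$nodes), " chlorophylls (",
      sum(x$nodes$kind == "chl_a"), " chl a), ", nrow(x$edges),
      " edges within ", x$params$cutoff, " A\n", sep = "")
  invisible(x)
}

.edge_keys <- function(edges) {
  paste(.site_key(edges$donor_chain, edges$donor_seq),
        .site_key(edges$acceptor_chain, edges$acceptor_seq), sep = "--")
}

# unordered edge key: endpoints sorted so A--B == B--A
.edge_keys_unordered <- function(d, a) {
  lo <- pmin(d, a); hi <- pmax(d, a)
  paste(lo, hi, sep = "--")
}

#' Compare two energy-transfer networks under a site correspondence
#'
#' Maps each edge of network A through an injective site correspondence;
#' edges whose mapped endpoints are joined in B are matched and classified
#' by the rate ratio `rate_B / rate_A` (`equal` when within `rel_tol` of
#' 1, else `increased` / `decreased`); A-edges without a counterpart go to
#' `only_in_A` (status `unmapped` when an endpoint has no correspondence,
#' `absent` when mapped but B lacks the edge), and unconsumed B-edges to
#' `only_in_B`.
#'
#' @param netA,netB [build_network()] results.
#' @param correspondence data.frame with columns `chain_a`, `seq_a`,
#'   `chain_b`, `seq_b`; must be injective. Defaults to the identity on
#'   A's nodes.
#' @param rel_tol Relative tolerance for the `equal` call (default 0.05,
#'   below the rate jitter induced by coordinate precision at typical
#'   model resolutions).
#' @return An object of class `edge_comparison`: list with `matched`
#'   (edge pair table incl. `rate_ratio`, `status`), `only_in_A`,
#'   `only_in_B`.
#' @export
compare_networks <- function(netA, netB, correspondence = NULL,
                             rel_tol = 0.05) {
  stopifnot(inherits(netA, "fret_network"), inherits(netB, "fret_network"))
  if (is.null(correspondence)) {
    correspondence <- data.frame(
      chain_a = netA$nodes$chain_id, seq_a = netA$nodes$seq_id,
      chain_b = netA$nodes$chain_id, seq_b = netA$nodes$seq_id,
      stringsAsFactors = FALSE)
  }
  ka <- .site_key(correspondence$chain_a, correspondence$seq_a)
  kb <- .site_key(correspondence$chain_b, correspondence$seq_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("correspondence must be injective (duplicate site on one side)")
  }
  map <- stats::setNames(kb, ka)

  ea <- netA$edges; eb <- netB$edges
  akey_d <- .site_key(ea$donor_chain, ea$donor_seq)
  akey_a <- .site_key(ea$acceptor_chain, ea$acceptor_seq)
  mapped_d <- unname(map[akey_d]); mapped_a <- unname(map[akey_a])
  bkeys <- .edge_keys_unordered(.site_key(eb$donor_chain, eb$donor_seq),
                                .site_key(eb$acceptor_chain, eb$acceptor_seq))
  want <- .edge_keys_unordered(mapped_d, mapped_a)
  hit <- !is.na(mapped_d) & !is.na(mapped_a) & want %in% bkeys

  matched <- NULL
  if (any(hit)) {
    idx_b <- match(want[hit], bkeys)
    ratio <- eb$rate[idx_b] / ea$rate[hit]
    # two vanishing rates (kappa^2 = 0 on both sides) are equal, not 0/0
    ratio[ea$rate[hit] == 0 & eb$rate[idx_b] == 0] <- 1
    status <- ifelse(abs(ratio - 1) <= rel_tol, "equal",
                     ifelse(ratio > 1, "increased", "decreased"))
    matched <- data.frame(
      edge_a = .edge_keys(ea)[hit], edge_b = bkeys[idx_b],
      rate_a = ea$rate[hit], rate_b = eb$rate[idx_b],
      rate_ratio = ratio, status = status, stringsAsFactors = FALSE)
  } else {
    matched <- data.frame(edge_a = character(), edge_b = character(),
                          rate_a = numeric(), rate_b = numeric(),
                          rate_ratio = numeric(), status = character())
  }
  only_a <- ea[!hit, , drop = FALSE]
  only_a$status <- ifelse(is.na(mapped_d[!hit]) | is.na(mapped_a[!hit]),
                          "unmapped", "absent")
  rownames(only_a) <- NULL
  only_b <- eb[!(bkeys %in% want[hit]), , drop = FALSE]
  rownames(only_b) <- NULL
  structure(list(matched = matched, only_in_A = only_a, only_in_B = only_b,
                 rel_tol = rel_tol),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat("edge_comparison: ", nrow(x$matched), " matched (",
      sum(x$matched$status == "equal"), " equal, ",
      sum(x$matched$status == "increased"), " increased, ",
      sum(x$matched$status == "decreased"), " decreased), ",
      nrow(x$only_in_A), " only in A, ", nrow(x$only_in_B),
      " only in B\n", sep = "")
  invisible(x)
}

#' Write a network edge list as CSV
#'
#' Columns: model_id, donor_chain, donor_seq, acceptor_chain, acceptor_seq,
#' separation_A, kappa_sq, rate_ns.
#'
#' @param net A [fret_network].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(net, path) {
  e <- net$edges
  utils::write.csv(
    data.frame(model_id = rep(net$model_id, nrow(e)),
               donor_chain = e$donor_chain, donor_seq = e$donor_seq,
               acceptor_chain = e$acceptor_chain,
               acceptor_seq = e$acceptor_seq,
               separation_A = e$separation, kappa_sq = e$kappa_sq,
               rate_ns = e$rate),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry `kind`; edges carry `separation`, `kappa_sq` and `rate`.
#'
#' @param net A [fret_network].
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  nodes <- data.frame(
    name = .site_key(net$nodes$chain_id, net$nodes$seq_id),
    kind = net$nodes$kind, stringsAsFactors = FALSE)
  e <- net$edges
  edges <- data.frame(
    from = .site_key(e$donor_chain, e$donor_seq),
    to = .site_key(e$acceptor_chain, e$acceptor_seq),
    separation = e$separation, kappa_sq = e$kappa_sq, rate = e$rate,
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
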