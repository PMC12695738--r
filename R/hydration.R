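#' Parameters for water-shell and conservation analysis
#'
#' @param shell_radius Shell radius in angstrom around the target
#'   cofactors (default 8.0, the vicinity radius used for the Fe-S
#'   cluster shell of the PSI core).
#' @param match_radius Maximum water-oxygen distance in angstrom for two
#'   superposed structures to count a water as conserved (default 1.2,
#'   around the positional uncertainty of ordered waters at ~2 angstrom
#'   resolution).
#' @param distance_reference `"any_cluster_atom"` (default): a water is in
#'   the shell when its oxygen lies within `shell_radius` of any atom of
#'   any target residue; `"cluster_centroid"`: distance to the target's
#'   geometric center instead.
#' @return An object of class `hydration_parameters`.
#' @export
hydration_parameters <- function(shell_radius = 8.0, match_radius = 1.2,
                                 distance_reference = c("any_cluster_atom",
                                                        "cluster_centroid")) {
  stopifnot(shell_radius > 0, match_radius > 0)
  distance_reference <- match.arg(distance_reference)
  structure(list(shell_radius = shell_radius, match_radius = match_radius,
                 distance_reference = distance_reference),
            class = "hydration_parameters")
}

# water oxygen table: one row per water residue (the O atom)
.water_oxygens <- function(model) {
  a <- model$atoms
  w <- a[a$category == "water" & (a$element == "O" | a$atom == "O"), ,
         drop = FALSE]
  w <- w[!duplicated(paste(w$chain_id, w$seq_id)), , drop = FALSE]
  rownames(w) <- NULL
  w
}

# resolve a targets argument into target atom coordinates: either a
# comp_id string (e.g. "SF4" -> all residues with that code) or a
# data.frame(chain_id, seq_id)
.target_atoms <- function(model, targets) {
  a <- model$atoms
  if (is.character(targets)) {
    t_at <- a[a$comp_id %in% targets, , drop = FALSE]
  } else {
    stopifnot(is.data.frame(targets),
              all(c("chain_id", "seq_id") %in% names(targets)))
    key <- paste(a$chain_id, a$seq_id)
    t_at <- a[key %in% paste(targets$chain_id, targets$seq_id), ,
              drop = FALSE]
  }
  if (!nrow(t_at)) stop("no target residues found in model")
  t_at
}

#' Water shell around target cofactors
#'
#' Collects the waters whose oxygen lies within `shell_radius` (inclusive
#' boundary) of the targets -- by default of any atom of any target
#' residue, e.g. the three Fe4S4 clusters of the PSI electron-transfer
#' chain. Waters are returned sorted by their minimum distance to the
#' targets.
#'
#' @param model A classified [structure_model].
#' @param targets Either a component code (character, e.g. `"SF4"`) or a
#'   data.frame with `chain_id`, `seq_id` rows naming target residues.
#' @param p [hydration_parameters].
#' @return An object of class `water_shell`: list with `model_id`,
#'   `targets` (site table), `waters` (data.frame `chain_id`, `seq_id`,
#'   `x`, `y`, `z`, `min_dist`), `params`.
#' @export
water_shell <- function(model, targets = "SF4",
                        p = hydration_parameters()) {
  stopifnot(inherits(model, "structure_model"))
  t_at <- .target_atoms(model, targets)
  if (p$distance_reference == "cluster_centroid") {
    key <- paste(t_at$chain_id, t_at$seq_id)
    ref <- do.call(rbind, lapply(split(seq_len(nrow(t_at)), key),
                                 function(i) colMeans(
                                   as.matrix(t_at[i, c("x", "y", "z")]))))
  } else {
    ref <- as.matrix(t_at[, c("x", "y", "z")])
  }
  w <- .water_oxygens(model)
  if (!nrow(w)) {
    waters <- data.frame(chain_id = character(), seq_id = integer(),
                         x = numeric(), y = numeric(), z = numeric(),
                         min_dist = numeric())
  } else {
    wxyz <- as.matrix(w[, c("x", "y", "z")])
    nd <- vapply(seq_len(nrow(wxyz)), function(i) {
      sqrt(min(rowSums(sweep(ref, 2, wxyz[i, ])^2)))
    }, numeric(1))
    # inclusive boundary, with 1e-9 slack so that a water deposited at
    # exactly the shell radius survives coordinate serialisation rounding
    keep <- nd <= p$shell_radius + 1e-9
    waters <- data.frame(chain_id = w$chain_id[keep],
                         seq_id = w$seq_id[keep],
                         x = w$x[keep], y = w$y[keep], z = w$z[keep],
                         min_dist = nd[keep], stringsAsFactors = FALSE)
    waters <- waters[order(waters$min_dist, waters$chain_id,
                           waters$seq_id), ]
    rownames(waters) <- NULL
  }
  structure(list(model_id = model$model_id,
                 targets = unique(t_at[, c("chain_id", "seq_id",
                                           "comp_id")]),
                 waters = waters, params = p),
            class = "water_shell")
}

#' @export
print.water_shell <- function(x, ...) {
  cat("water_shell '", x$model_id, "': ", nrow(x$waters),
      " waters within ", x$params$shell_radius, " A of ",
      nrow(x$targets), " target residue(s)\n", sep = "")
  invisible(x)
}

#' Conservation of shell waters in another structure
#'
#' Transforms the comparison model into the reference frame, then assigns
#' each reference shell water its nearest comparison-water oxygen by
#' greedy nearest-first one-to-one matching (each comparison water usable
#' at most once; deterministic tie-break by chain then residue number). A
#' reference water is conserved when its match lies within
#' `p$match_radius`.
#'
#' @param shell_ref A [water_shell()] on the reference model.
#' @param other Comparison [structure_model].
#' @param sp [superpose()] result mapping `other` onto the reference
#'   frame, or `NULL` if frames already agree.
#' @param p [hydration_parameters].
#' @return data.frame of class `conservation_records`: `ref_water`
#'   (site key), `comparison_model`, `conserved`, `nearest_water`,
#'   `nearest_dist`.
#' @export
conserved_waters <- function(shell_ref, other, sp = NULL,
                             p = hydration_parameters()) {
  stopifnot(inherits(shell_ref, "water_shell"),
            inherits(other, "structure_model"))
  rw <- shell_ref$waters
  ow <- .water_oxygens(other)
  out <- data.frame(
    ref_water = .site_key(rw$chain_id, rw$seq_id),
    comparison_model = other$model_id,
    conserved = FALSE, nearest_water = NA_character_,
    nearest_dist = NA_real_, stringsAsFactors = FALSE)
  if (!nrow(ow)) {
    warning("comparison model '", other$model_id,
            "' contains no waters", call. = FALSE)
    class(out) <- c("conservation_records", "data.frame")
    return(out)
  }
  oxyz <- as.matrix(ow[, c("x", "y", "z")])
  if (!is.null(sp)) oxyz <- apply_superposition(sp, oxyz)
  m <- .greedy_match(as.matrix(rw[, c("x", "y", "z")]), oxyz,
                     p$match_radius,
                     order(order(rw$chain_id, rw$seq_id)),
                     order(order(ow$chain_id, ow$seq_id)))
  if (nrow(m)) {
    out$conserved[m[, "i"]] <- TRUE
    out$nearest_water[m[, "i"]] <- .site_key(ow$chain_id[m[, "j"]],
                                             ow$seq_id[m[, "j"]])
    out$nearest_dist[m[, "i"]] <- m[, "dist"]
  }
  # for unmatched reference waters report the nearest oxygen anyway
  un <- which(!out$conserved)
  if (length(un)) {
    rxyz <- as.matrix(rw[un, c("x", "y", "z"), drop = FALSE])
    for (k in seq_along(un)) {
      dd <- sqrt(rowSums(sweep(oxyz, 2, rxyz[k, ])^2))
      j <- which.min(dd)
      out$nearest_water[un[k]] <- .site_key(ow$chain_id[j], ow$seq_id[j])
      out$nearest_dist[un[k]] <- dd[j]
    }
  }
  class(out) <- c("conservation_records", "data.frame")
  out
}

#' Summarise conservation records over several comparison models
#'
#' @param records A `conservation_records` data.frame or a list of them
#'   (one per comparison model).
#' @return list with `per_model` (data.frame `comparison_model`,
#'   `n_conserved`, `n_waters`) and `per_water` (data.frame `ref_water`,
#'   `n_models_conserved`).
#' @export
conservation_summary <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  if (!length(records)) {
    return(list(per_model = data.frame(comparison_model = character(),
                                       n_conserved = integer(),
                                       n_waters = integer()),
                per_water = data.frame(ref_water = character(),
                                       n_models_conserved = integer())))
  }
  all <- do.call(rbind, records)
  per_model <- do.call(rbind, lapply(
    split(all, all$comparison_model), function(d) {
      data.frame(comparison_model = d$comparison_model[1],
                 n_conserved = sum(d$conserved), n_waters = nrow(d))
    }))
  rownames(per_model) <- NULL
  per_water <- do.call(rbind, lapply(
    split(all, all$ref_water), function(d) {
      data.frame(ref_water = d$ref_water[1],
                 n_models_conserved = sum(d$conserved))
    }))
  per_water <- per_water[order(-per_water$n_models_conserved,
                               per_water$ref_water), ]
  rownames(per_water) <- NULL
  list(per_model = per_model, per_water = per_water)
}

#' Write water-shell and conservation CSV reports
#'
#' @param shell A [water_shell()] result (or `NULL`).
#' @param records `conservation_records` or list thereof (or `NULL`).
#' @param shell_path,conservation_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_hydration_csv <- function(shell = NULL, records = NULL,
                                shell_path = NULL,
                                conservation_path = NULL) {
  if (!is.null(shell) && !is.null(shell_path)) {
    w <- shell$waters
    utils::write.csv(data.frame(model_id = shell$model_id,
                                water_chain = w$chain_id,
                                water_seq = w$seq_id,
                                min_dist_A = w$min_dist),
                     shell_path, row.names = FALSE)
  }
  if (!is.null(records) && !is.null(conservation_path)) {
    if (is.data.frame(records)) records <- list(records)
    utils::write.csv(do.call(rbind, records), conservation_path,
                     row.names = FALSE)
  }
  invisible(list(shell = shell_path, conservation = conservation_path))
}
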