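#' Run configuration for the command-line pipeline
#'
#' Bundles inputs and parameters for the `run_*` pipeline commands and the
#' `chlnet` shell front-end. Defaults reproduce the published analysis
#' settings: C = 32.26, n = 1.55, 20 angstrom chlorophyll cutoff, and the
#' 8 angstrom Fe-S water shell. The configuration is serialised (with a
#' hash) next to every output for provenance.
#'
#' @param input Path of the primary coordinate file.
#' @param comparison Optional path of a second coordinate file (for
#'   `run_compare` / `run_waters` conservation).
#' @param format `"auto"`, `"mmcif"` or `"pdb"`.
#' @param component_map Optional YAML component-map path.
#' @param fret [fret_parameters()].
#' @param hydration [hydration_parameters()].
#' @param chain_map Optional YAML chain-map path, or a named character
#'   vector (A chain -> B chain).
#' @param core_chains Character vector of A-side chains anchoring the
#'   core fit in `run_compare` (default `NULL`: all mapped chains).
#' @param subunit Optional A-side chain whose shift to report.
#' @param targets Target selector for `run_waters` (component code or
#'   site data.frame; default `"SF4"`).
#' @param out Output directory.
#' @param seed Integer seed for any randomised option.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, comparison = NULL,
                       format = "auto", component_map = NULL,
                       fret = fret_parameters(),
                       hydration = hydration_parameters(),
                       chain_map = NULL, core_chains = NULL,
                       subunit = NULL, targets = "SF4",
                       out = ".", seed = 1L, log_level = "info") {
  structure(list(input = input, comparison = comparison, format = format,
                 component_map = component_map, fret = fret,
                 hydration = hydration, chain_map = chain_map,
                 core_chains = core_chains, subunit = subunit,
                 targets = targets, out = out, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

.log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

.cfg_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))),
             collapse = "\n")
  # small deterministic content hash (djb2) for provenance stamping
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

# serialise the config (with hash) next to the outputs
.write_provenance <- function(cfg, outdir) {
  lst <- unclass(cfg)
  lst$fret <- unclass(lst$fret)
  lst$hydration <- unclass(lst$hydration)
  lst$config_hash <- .cfg_hash(cfg)
  jsonlite::write_json(lst, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  lst$config_hash
}

.load_input <- function(cfg, which = c("input", "comparison")) {
  which <- match.arg(which)
  path <- cfg[[which]]
  if (is.null(path) || !file.exists(path)) {
    stop("input file missing: ", if (is.null(path)) "(not set)" else path,
         call. = FALSE)
  }
  cmap <- if (is.null(cfg$component_map)) default_component_map() else
    read_component_map(cfg$component_map)
  read_structure(path, format = cfg$format, cmap = cmap)
}

.chain_map_vec <- function(cfg) {
  cm <- cfg$chain_map
  if (is.null(cm)) return(NULL)
  if (is.character(cm) && length(cm) == 1 && file.exists(cm)) {
    y <- yaml::read_yaml(cm)
    return(stats::setNames(vapply(y, as.character, character(1)),
                           names(y)))
  }
  cm
}

#' Pipeline command: cofactor inventory
#'
#' Reads, classifies and inventories the input model; writes
#' `inventory_counts.csv` and `inventory_sites.csv` under `cfg$out`.
#'
#' @param cfg A [run_config].
#' @return The [inventory()] result, invisibly.
#' @export
run_inventory <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  model <- .load_input(cfg)
  inv <- inventory(model)
  write_inventory_csv(inv,
                      counts_path = file.path(cfg$out,
                                              "inventory_counts.csv"),
                      sites_path = file.path(cfg$out,
                                             "inventory_sites.csv"))
  h <- .write_provenance(cfg, cfg$out)
  .log(cfg, "inventory of '", model$model_id, "' written (config ", h, ")")
  invisible(inv)
}

#' Pipeline command: FRET network
#'
#' Builds the chlorophyll-a energy-transfer network and writes
#' `fret_edges.csv` and `fret_network.graphml` under `cfg$out`. Rerunning
#' with the same config and input yields byte-identical outputs.
#'
#' @param cfg A [run_config].
#' @return The [build_network()] result, invisibly.
#' @export
run_fret <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  model <- .load_input(cfg)
  net <- build_network(model, cfg$fret)
  write_edges_csv(net, file.path(cfg$out, "fret_edges.csv"))
  write_graphml(net, file.path(cfg$out, "fret_network.graphml"))
  h <- .write_provenance(cfg, cfg$out)
  .log(cfg, nrow(net$edges), " edges written (config ", h, ")")
  invisible(net)
}

#' Pipeline command: structural comparison
#'
#' Superposes the comparison model onto the input model (core-anchored
#' when `core_chains` is given), writes the subunit-shift report
#' (`subunit_shifts.csv`), the cofactor site-match table
#' (`site_matches.csv`) and, when both models yield networks, the
#' network comparison (`network_comparison.csv`).
#'
#' @param cfg A [run_config] with `comparison` set.
#' @return list with `superposition`, `shifts`, `sites`, `networks`,
#'   invisibly.
#' @export
run_compare <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  ma <- .load_input(cfg, "input")
  mb <- .load_input(cfg, "comparison")
  cm <- .chain_map_vec(cfg)
  if (is.null(cm)) {
    shared <- intersect(unique(ma$atoms$chain_id),
                        unique(mb$atoms$chain_id))
    cm <- stats::setNames(shared, shared)
  }
  core <- if (is.null(cfg$core_chains)) cm else
    cm[names(cm) %in% cfg$core_chains]
  sp <- superpose(pair_atoms(ma, mb, chain_map = core))

  subunits <- if (is.null(cfg$subunit))
    setdiff(names(cm), names(core)) else cfg$subunit
  shifts <- lapply(subunits, function(su) {
    subunit_shift(ma, mb, core_map = core, subunit_map = cm[su])
  })
  shift_df <- if (length(shifts)) data.frame(
    subunit = vapply(shifts, function(s) names(s$subunit), character(1)),
    centroid_shift_A = vapply(shifts, `[[`, numeric(1), "centroid_shift"),
    per_atom_rmsd_A = vapply(shifts, `[[`, numeric(1), "per_atom_rmsd"),
    n_atoms = vapply(shifts, `[[`, integer(1), "n_atoms")
  ) else data.frame(subunit = character(), centroid_shift_A = numeric(),
                    per_atom_rmsd_A = numeric(), n_atoms = integer())
  utils::write.csv(shift_df, file.path(cfg$out, "subunit_shifts.csv"),
                   row.names = FALSE)

  sites <- match_cofactor_sites(ma, mb, sp)
  st <- rbind(
    data.frame(site_a = sites$matched$site_a,
               site_b = sites$matched$site_b,
               distance = sites$matched$distance,
               category_a = sites$matched$category_a,
               category_b = sites$matched$category_b,
               status = ifelse(sites$matched$same_category, "matched",
                               "type_change")),
    if (nrow(sites$only_in_A)) data.frame(
      site_a = .site_key(sites$only_in_A$chain_id,
                         sites$only_in_A$seq_id),
      site_b = NA, distance = NA,
      category_a = sites$only_in_A$category, category_b = NA,
      status = "only_A"),
    if (nrow(sites$only_in_B)) data.frame(
      site_a = NA,
      site_b = .site_key(sites$only_in_B$chain_id,
                         sites$only_in_B$seq_id),
      distance = NA, category_a = NA,
      category_b = sites$only_in_B$category, status = "only_B"))
  utils::write.csv(st, file.path(cfg$out, "site_matches.csv"),
                   row.names = FALSE)

  networks <- NULL
  chl_a_count <- function(m) sum(inventory(m)$counts["chl_a"])
  if (chl_a_count(ma) >= 2 && chl_a_count(mb) >= 2) {
    na_ <- build_network(ma, cfg$fret)
    nb_ <- build_network(mb, cfg$fret)
    # spatial correspondence from the matched chlorophyll sites
    chl_m <- sites$matched[sites$matched$category_a == "chl_a" &
                             sites$matched$category_b == "chl_a", ,
                           drop = FALSE]
    corr <- if (nrow(chl_m)) {
      sa <- strsplit(chl_m$site_a, ":", fixed = TRUE)
      sb <- strsplit(chl_m$site_b, ":", fixed = TRUE)
      data.frame(chain_a = vapply(sa, `[`, "", 1),
                 seq_a = as.integer(vapply(sa, `[`, "", 2)),
                 chain_b = vapply(sb, `[`, "", 1),
                 seq_b = as.integer(vapply(sb, `[`, "", 2)))
    } else NULL
    networks <- compare_networks(na_, nb_, corr)
    comp_df <- rbind(
      data.frame(pathway = networks$matched$edge_a,
                 status = networks$matched$status,
                 rate_A = networks$matched$rate_a,
                 rate_B = networks$matched$rate_b),
      if (nrow(networks$only_in_A)) data.frame(
        pathway = .edge_keys(networks$only_in_A), status = "absent_in_B",
        rate_A = networks$only_in_A$rate, rate_B = NA),
      if (nrow(networks$only_in_B)) data.frame(
        pathway = .edge_keys(networks$only_in_B), status = "new_in_B",
        rate_A = NA, rate_B = networks$only_in_B$rate))
    utils::write.csv(comp_df,
                     file.path(cfg$out, "network_comparison.csv"),
                     row.names = FALSE)
  }
  h <- .write_provenance(cfg, cfg$out)
  .log(cfg, "comparison written (core rmsd ",
       sprintf("%.2f", sp$rmsd), " A; config ", h, ")")
  invisible(list(superposition = sp, shifts = shifts, sites = sites,
                 networks = networks))
}

#' Pipeline command: water shells and conservation
#'
#' Extracts the water shell around the target cofactors and, when a
#' comparison model is configured, its conservation records. With
#' `radius_sweep`, one shell row per swept radius is appended to
#' `shell_sweep.csv`.
#'
#' @param cfg A [run_config].
#' @param radius_sweep Optional numeric vector of shell radii to sweep.
#' @param match_sweep Optional numeric vector of conservation match radii
#'   to sweep.
#' @return list with `shell`, `records` (or `NULL`), `sweep`, invisibly.
#' @export
run_waters <- function(cfg, radius_sweep = NULL, match_sweep = NULL) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  model <- .load_input(cfg)
  shell <- water_shell(model, targets = cfg$targets, p = cfg$hydration)
  records <- NULL
  if (!is.null(cfg$comparison)) {
    other <- .load_input(cfg, "comparison")
    cm <- .chain_map_vec(cfg)
    sp <- tryCatch(superpose(pair_atoms(model, other, chain_map = cm)),
                   error = function(e) NULL)
    records <- conserved_waters(shell, other, sp, cfg$hydration)
    if (!is.null(match_sweep)) {
      sweep_df <- do.call(rbind, lapply(match_sweep, function(r) {
        p2 <- cfg$hydration; p2$match_radius <- r
        rec <- conserved_waters(shell, other, sp, p2)
        data.frame(match_radius = r, n_conserved = sum(rec$conserved))
      }))
      utils::write.csv(sweep_df,
                       file.path(cfg$out, "conservation_sweep.csv"),
                       row.names = FALSE)
    }
  }
  sweep <- NULL
  if (!is.null(radius_sweep)) {
    sweep <- do.call(rbind, lapply(radius_sweep, function(r) {
      p2 <- cfg$hydration; p2$shell_radius <- r
      data.frame(shell_radius = r,
                 n_waters = nrow(water_shell(model, cfg$targets,
                                             p2)$waters))
    }))
    utils::write.csv(sweep, file.path(cfg$out, "shell_sweep.csv"),
                     row.names = FALSE)
  }
  write_hydration_csv(shell, records,
                      shell_path = file.path(cfg$out, "water_shell.csv"),
                      conservation_path = if (!is.null(records))
                        file.path(cfg$out, "water_conservation.csv"))
  h <- .write_provenance(cfg, cfg$out)
  .log(cfg, nrow(shell$waters), " shell waters written (config ", h, ")")
  invisible(list(shell = shell, records = records, sweep = sweep))
}

#' Pipeline command: emit a demonstration synthetic model
#'
#' Writes a deterministic toy supercomplex (chlorophyll pair grid, one
#' Fe4S4 cluster with planted waters, two helical chains) as mmCIF under
#' `cfg$out`, for exercising the other commands without any downloads.
#'
#' @param cfg A [run_config] (`seed` controls the randomised dipoles).
#' @return The path of the written file, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  dirs <- random_unit_vectors(8)
  chl <- lapply(seq_len(8), function(i) {
    u <- dirs[i, ]
    # any normal orthogonal to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- ref - sum(ref * u) * u; w <- w / sqrt(sum(w^2))
    chl_placement(center = c(12 * ((i - 1) %% 4), 14 * ((i - 1) %/% 4), 0),
                  dipole_direction = u, plane_normal = w,
                  kind = if (i %% 4 == 0) "chl_c" else "chl_a")
  })
  model <- build_toy_model(
    chlorophylls = chl,
    clusters = list(c(0, -20, 0)),
    waters = list(list(cluster = 1, radius = 5, direction = c(1, 0, 0)),
                  list(cluster = 1, radius = 8, direction = c(0, 1, 0)),
                  list(cluster = 1, radius = 11, direction = c(0, 0, 1))),
    protein_chains = list(list(chain_id = "X", n = 40),
                          list(chain_id = "Y", n = 30,
                               start = c(20, 0, 0))),
    model_id = sprintf("sim_seed%d", cfg$seed))
  path <- file.path(cfg$out, paste0(model$model_id, ".cif"))
  write_mmcif(model, path)
  .write_provenance(cfg, cfg$out)
  .log(cfg, "synthetic model written to ", path)
  invisible(path)
}
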