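#' Structure model container
#'
#' A parsed coordinate model. The canonical representation is a flat atom
#' table (one row per atom after alternate-location resolution) using
#' *author* chain identifiers and residue numbers, because published site
#' names (e.g. "a306/i") follow author-style labels.
#'
#' Columns of `atoms`: `chain_id`, `seq_id`, `comp_id`, `atom` (atom name),
#' `element`, `x`, `y`, `z` (angstrom), `occupancy`, `alt_id` (`""` when
#' none), `category` (see [COFACTOR_CATEGORIES]).
#'
#' @param atoms Atom data.frame as described above.
#' @param model_id Free identifier string (e.g. a PDB accession).
#' @param source_format `"mmcif"`, `"pdb"` or `"synthetic"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model",
                            source_format = "synthetic") {
  need <- c("chain_id", "seq_id", "comp_id", "atom", "element",
            "x", "y", "z", "occupancy", "alt_id", "category")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty model: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    stop("occupancy outside [0, 1]")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = model_id,
                 source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  res <- unique(a[, c("chain_id", "seq_id", "comp_id")])
  cat("structure_model '", x$model_id, "' (", x$source_format, "): ",
      nrow(a), " atoms, ", nrow(res), " residues, ",
      length(unique(a$chain_id)), " chains\n", sep = "")
  invisible(x)
}

# residue-level site key used throughout: "chain:seq"
.site_key <- function(chain_id, seq_id) paste(chain_id, seq_id, sep = ":")

# Resolve alternate locations: keep the highest-occupancy conformer per
# (chain, seq, comp, atom); ties break to the lexicographically first
# alt_id. Atoms with occupancy zero are discarded first.
.resolve_altloc <- function(atoms) {
  atoms <- atoms[atoms$occupancy > 0, , drop = FALSE]
  key <- paste(atoms$chain_id, atoms$seq_id, atoms$comp_id, atoms$atom,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$alt_id)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

.detect_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  ext <- tools::file_ext(p)
  switch(ext,
         cif = "mmcif", mmcif = "mmcif",
         pdb = "pdb", ent = "pdb",
         stop("cannot auto-detect format of '", path,
              "'; pass format explicitly"))
}

#' Read a coordinate file into a structure model
#'
#' Parses mmCIF (PDBx) or legacy PDB (gzip-transparent) via bio3d, keeps
#' atoms with nonzero occupancy, resolves alternate locations to the
#' highest-occupancy conformer (ties to the alphabetically first alt_id)
#' and classifies every residue through `cmap`. Hydrogens are retained in
#' the table; distance-based operations ignore them unless asked.
#'
#' @param path File path (`.cif`, `.pdb`, optionally `.gz`).
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @param model_id Identifier; default the file base name.
#' @param cmap [component_map] used for classification, or `NULL` to leave
#'   all categories `"unknown"` for a later [classify_cofactors()] call.
#' @return A [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           model_id = NULL,
                           cmap = default_component_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detect_format(path)
  if (is.null(model_id)) {
    model_id <- sub("\\.(cif|pdb|ent)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE)
  }

  src <- path
  if (format == "pdb" && grepl("\\.gz$", path)) {
    # bio3d::read.pdb does not take connections; inflate to a temp file
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src), add = TRUE)
    writeLines(readLines(gzfile(path)), src)
  }

  parsed <- tryCatch(
    suppressWarnings(
      if (format == "mmcif") bio3d::read.cif(src, rm.alt = FALSE)
      else bio3d::read.pdb(src, rm.alt = FALSE)
    ),
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) stop("empty model: ", path)

  atoms <- data.frame(
    chain_id = as.character(at$chain),
    seq_id = as.integer(at$resno),
    comp_id = as.character(at$resid),
    atom = as.character(at$elety),
    element = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    alt_id = ifelse(is.na(at$alt), "", as.character(at$alt)),
    category = "unknown",
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)
  model <- structure_model(atoms, model_id = model_id,
                           source_format = format)
  if (!is.null(cmap)) model <- classify_cofactors(model, cmap)
  model
}

#' Write a structure model as mmCIF
#'
#' Emits a minimal PDBx `atom_site` loop (coordinates to 0.001 angstrom)
#' that round-trips through [read_structure()]. Output is deterministic:
#' equal models give byte-identical files.
#'
#' @param model A [structure_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  grp <- ifelse(a$category == "protein", "ATOM", "HETATM")
  alt <- ifelse(a$alt_id == "", ".", a$alt_id)
  ele <- ifelse(a$element == "", "X", a$element)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$model_id)),
    "#",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            grp, seq_len(nrow(a)), ele, a$atom, alt, a$comp_id,
            a$chain_id, a$seq_id, a$x, a$y, a$z, a$occupancy,
            a$seq_id, a$comp_id, a$chain_id, a$atom),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Residue-level cofactor inventory
#'
#' Counts residues (waters count once per residue, not per atom) in each
#' cofactor category and lists every site.
#'
#' @param model A classified [structure_model].
#' @return An object of class `cofactor_inventory`: list with `counts`
#'   (named integer over [COFACTOR_CATEGORIES]) and `by_site`
#'   (data.frame `chain_id`, `seq_id`, `comp_id`, `category`, sorted by
#'   chain then residue number).
#' @export
inventory <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  by_site <- unique(a[, c("chain_id", "seq_id", "comp_id", "category")])
  by_site <- by_site[order(by_site$chain_id, by_site$seq_id), ]
  rownames(by_site) <- NULL
  counts <- table(factor(by_site$category, levels = COFACTOR_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(model_id = model$model_id, counts = counts,
                 by_site = by_site),
            class = "cofactor_inventory")
}

#' @export
print.cofactor_inventory <- function(x, ...) {
  cat("cofactor_inventory for '", x$model_id, "':\n", sep = "")
  nz <- x$counts[x$counts > 0]
  for (k in names(nz)) cat(sprintf("  %-12s %d\n", k, nz[[k]]))
  invisible(x)
}

#' Write inventory tables as CSV
#'
#' @param inv A [cofactor_inventory].
#' @param counts_path,sites_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
write_inventory_csv <- function(inv, counts_path = NULL, sites_path = NULL) {
  stopifnot(inherits(inv, "cofactor_inventory"))
  if (!is.null(counts_path)) {
    utils::write.csv(data.frame(model_id = inv$model_id,
                                category = names(inv$counts),
                                count = unname(inv$counts)),
                     counts_path, row.names = FALSE)
  }
  if (!is.null(sites_path)) {
    utils::write.csv(inv$by_site, sites_path, row.names = FALSE)
  }
  invisible(list(counts = counts_path, sites = sites_path))
}

#' Extract chlorophyll cofactors with transition-dipole frames
#'
#' One entry per chl_a / chl_c residue carrying the central Mg position and
#' the NB and ND pyrrole nitrogen positions; the Qy transition dipole is
#' the unit vector from NB toward ND. Residues missing any of MG/NB/ND (or
#' with |ND - NB| < 0.1 angstrom, leaving the dipole undefined) are
#' excluded and reported in the `excluded` attribute.
#'
#' @param model A classified [structure_model].
#' @return A data.frame of class `chl_set` with columns `chain_id`,
#'   `seq_id`, `comp_id`, `kind`, `mg_x..mg_z`, `nb_*`, `nd_*`,
#'   `ux`, `uy`, `uz` (unit dipole), plus attribute `excluded`
#'   (data.frame of skipped sites with a reason).
#' @export
extract_chlorophylls <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  chl <- a[a$category %in% c("chl_a", "chl_c"), , drop = FALSE]
  sites <- unique(chl[, c("chain_id", "seq_id", "comp_id", "category")])
  rows <- vector("list", nrow(sites))
  excl <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    ra <- chl[chl$chain_id == s$chain_id & chl$seq_id == s$seq_id &
                chl$comp_id == s$comp_id, , drop = FALSE]
    pick <- function(name) {
      m <- ra[ra$atom == name, c("x", "y", "z"), drop = FALSE]
      if (nrow(m) != 1) NULL else as.numeric(m[1, ])
    }
    mg <- pick("MG"); nb <- pick("NB"); nd <- pick("ND")
    if (is.null(mg) || is.null(nb) || is.null(nd)) {
      excl[[length(excl) + 1]] <- data.frame(
        s[, 1:3], reason = "missing MG/NB/ND atom")
      next
    }
    v <- nd - nb
    nv <- sqrt(sum(v^2))
    if (nv < 0.1) {
      excl[[length(excl) + 1]] <- data.frame(
        s[, 1:3], reason = "degenerate NB-ND axis")
      next
    }
    u <- v / nv
    rows[[i]] <- data.frame(
      chain_id = s$chain_id, seq_id = s$seq_id, comp_id = s$comp_id,
      kind = s$category,
      mg_x = mg[1], mg_y = mg[2], mg_z = mg[3],
      nb_x = nb[1], nb_y = nb[2], nb_z = nb[3],
      nd_x = nd[1], nd_y = nd[2], nd_z = nd[3],
      ux = u[1], uy = u[2], uz = u[3],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chain_id = character(), seq_id = integer(),
                      comp_id = character(), kind = character(),
                      mg_x = numeric(), mg_y = numeric(), mg_z = numeric(),
                      nb_x = numeric(), nb_y = numeric(), nb_z = numeric(),
                      nd_x = numeric(), nd_y = numeric(), nd_z = numeric(),
                      ux = numeric(), uy = numeric(), uz = numeric())
  }
  rownames(out) <- NULL
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(chain_id = character(), seq_id = integer(),
               comp_id = character(), reason = character())
  attr(out, "excluded") <- excl
  attr(out, "model_id") <- model$model_id
  class(out) <- c("chl_set", "data.frame")
  out
}

#' Single-chlorophyll accessor
#'
#' Builds the scalar chlorophyll object used by [mg_distance()],
#' [kappa_squared()] and [fret_rate()] from one row of a `chl_set` (or
#' directly from coordinates).
#'
#' @param mg,nb,nd Numeric 3-vectors (angstrom), or `mg` may be a one-row
#'   `chl_set` slice from which everything is taken.
#' @param kind `"chl_a"` or `"chl_c"`.
#' @param site_id Optional identifier list/character.
#' @return An object of class `chlorophyll`: list with `mg`, `nb`, `nd`,
#'   unit `dipole`, `kind`, `site_id`.
#' @export
chlorophyll <- function(mg, nb = NULL, nd = NULL, kind = "chl_a",
                        site_id = NULL) {
  if (is.data.frame(mg)) {
    r <- mg
    stopifnot(nrow(r) == 1)
    return(chlorophyll(c(r$mg_x, r$mg_y, r$mg_z),
                       c(r$nb_x, r$nb_y, r$nb_z),
                       c(r$nd_x, r$nd_y, r$nd_z),
                       kind = r$kind,
                       site_id = .site_key(r$chain_id, r$seq_id)))
  }
  stopifnot(length(mg) == 3, length(nb) == 3, length(nd) == 3)
  v <- nd - nb
  nv <- sqrt(sum(v^2))
  if (nv < 0.1) stop("dipole undefined: |ND - NB| < 0.1 angstrom")
  structure(list(mg = as.numeric(mg), nb = as.numeric(nb),
                 nd = as.numeric(nd), dipole = v / nv,
                 kind = kind, site_id = site_id),
            class = "chlorophyll")
}
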