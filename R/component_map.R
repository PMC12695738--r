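#' Cofactor categories recognised by chlnet
#'
#' Every residue in a parsed model is assigned exactly one of these
#' categories through a [component_map]. Codes absent from the active map
#' fall back to `"unknown"` and are never dropped.
#'
#' @format Character vector of category names.
#' @export
COFACTOR_CATEGORIES <- c(
  "protein", "chl_a", "chl_c", "carotenoid", "lipid", "water",
  "fes_cluster", "ion", "detergent", "unknown"
)

# Standard amino-acid three-letter codes (incl. MSE selenomethionine).
.AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)

#' Chemical-component map
#'
#' Maps chemical component codes (`comp_id`) to cofactor categories and
#' display names. Deposited code vocabularies vary between entries (the
#' carotenoid codes used for alloxanthin, crocoxanthin and monadoxanthin
#' differ across depositions), so the map is data, not code: the built-in
#' defaults can be extended or overridden per key from a YAML file.
#'
#' @param entries Named list; each element is `list(category, display_name)`.
#'   Names are component codes.
#' @param provenance `"builtin-default"` or the path of the user file.
#' @return An object of class `component_map`.
#' @seealso [default_component_map()], [read_component_map()]
#' @export
component_map <- function(entries, provenance = "builtin-default") {
  stopifnot(is.list(entries), !is.null(names(entries)))
  bad <- vapply(entries, function(e) {
    !is.list(e) || !e$category %in% COFACTOR_CATEGORIES
  }, logical(1))
  if (any(bad)) {
    stop("invalid component_map entries for: ",
         paste(names(entries)[bad], collapse = ", "))
  }
  structure(list(entries = entries, provenance = provenance),
            class = "component_map")
}

#' Built-in default component map
#'
#' Covers the codes found in cryptophyte photosystem depositions:
#' chlorophyll a (CLA), chlorophylls c1/c2 (KC1, KC2), common carotenoid
#' codes, the four thylakoid lipid classes (PG, MGDG, DGDG, SQDG), the
#' Fe4S4 cluster (SF4), waters, maltoside detergents and common ions. All
#' twenty standard amino acids map to `protein`.
#'
#' @return A [component_map].
#' @export
default_component_map <- function() {
  e <- list()
  for (aa in .AMINO_ACIDS) e[[aa]] <- list(category = "protein",
                                           display_name = aa)
  e$CLA <- list(category = "chl_a", display_name = "Chl a")
  e$KC1 <- list(category = "chl_c", display_name = "Chl c1")
  e$KC2 <- list(category = "chl_c", display_name = "Chl c2")
  for (code in c("BCR", "ECH", "LUT", "XAT", "NEX")) {
    e[[code]] <- list(category = "carotenoid", display_name = code)
  }
  e$LHG <- list(category = "lipid", display_name = "PG")
  e$PG  <- list(category = "lipid", display_name = "PG")
  e$LMG <- list(category = "lipid", display_name = "MGDG")
  e$DGD <- list(category = "lipid", display_name = "DGDG")
  e$SQD <- list(category = "lipid", display_name = "SQDG")
  e$SF4 <- list(category = "fes_cluster", display_name = "Fe4S4")
  e$HOH <- list(category = "water", display_name = "water")
  e$LMT <- list(category = "detergent", display_name = "DDM")
  e$LMU <- list(category = "detergent", display_name = "DDM")
  for (code in c("MG", "CA", "CL", "NA", "K", "MN", "FE", "ZN")) {
    e[[code]] <- list(category = "ion", display_name = code)
  }
  component_map(e, provenance = "builtin-default")
}

#' Read a component map from YAML
#'
#' The file maps component codes to `category` or `category:display_name`,
#' e.g. `A86: carotenoid:Alx`. User entries override the built-in defaults
#' per key; codes not mentioned keep their default category.
#'
#' @param path YAML file path.
#' @param base Map to override; defaults to [default_component_map()].
#' @return A [component_map] with `provenance = path`.
#' @export
read_component_map <- function(path, base = default_component_map()) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) return(base)
  ent <- base$entries
  for (code in names(raw)) {
    parts <- strsplit(as.character(raw[[code]]), ":", fixed = TRUE)[[1]]
    cat_ <- parts[1]
    if (!cat_ %in% COFACTOR_CATEGORIES) {
      stop("unknown category '", cat_, "' for code ", code, " in ", path)
    }
    ent[[code]] <- list(category = cat_,
                        display_name = if (length(parts) > 1) parts[2] else code)
  }
  component_map(ent, provenance = path)
}

#' @export
print.component_map <- function(x, ...) {
  cats <- vapply(x$entries, `[[`, character(1), "category")
  cat("component_map (", x$provenance, "): ", length(x$entries),
      " codes\n", sep = "")
  print(table(factor(cats, levels = COFACTOR_CATEGORIES)))
  invisible(x)
}

#' Assign cofactor categories to every residue of a model
#'
#' Classification is a pure function of `comp_id` through the map; codes
#' absent from the map are categorised `unknown` (reported via a warning,
#' never dropped).
#'
#' @param model A [structure_model].
#' @param cmap A [component_map]; default the built-in map.
#' @return The model with the `category` column of its atom table filled.
#' @export
classify_cofactors <- function(model, cmap = default_component_map()) {
  stopifnot(inherits(model, "structure_model"))
  comp <- model$atoms$comp_id
  cats <- vapply(comp, function(code) {
    e <- cmap$entries[[code]]
    if (is.null(e)) "unknown" else e$category
  }, character(1), USE.NAMES = FALSE)
  model$atoms$category <- cats
  unknown <- sort(unique(comp[cats == "unknown"]))
  if (length(unknown)) {
    warning("component codes not in map, categorised 'unknown': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  model$component_map <- cmap$provenance
  model
}
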