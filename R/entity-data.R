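# Embedded property tables for the supported metal cations and solvent media.
# Shipped as commented TSV under inst/extdata so they are diffable; loaded
# lazily and cached for the session.

metal_property_names <- c(
  "atomic_number", "outer_shell_electrons",
  "ionization_energy_1", "ionization_energy_2", "ionization_energy_3",
  "electron_affinity", "atomic_radius", "covalent_radius", "ionic_radius",
  "electronegativity_pauling", "melting_point", "boiling_point",
  "density", "standard_entropy")

medium_property_names <- c("density", "molar_mass", "melting_point")

read_extdata_tsv <- function(fname) {
  path <- system.file("extdata", fname, package = "lanbind")
  if (!nzchar(path)) path <- file.path("inst", "extdata", fname)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Table of supported lanthanide cations
#'
#' Returns the embedded table of the 15 supported cations (the trivalent
#' series Ce--Lu plus Ce(4+)) with 14 elemental/ionic properties used as
#' model features.
#'
#' @return A data.frame with columns `symbol`, `charge` and the 14 properties
#'   named in `metal_property_names`.
#' @export
lan_metals <- function() {
  if (is.null(.lanbind_env$metals)) {
    tab <- read_extdata_tsv("metals.tsv")
    stopifnot(nrow(tab) == 15L,
              all(c("symbol", "charge", metal_property_names) %in% names(tab)))
    .lanbind_env$metals <- tab
  }
  .lanbind_env$metals
}

#' Table of supported solvent media
#'
#' Returns the embedded table of the 8 supported background media, each
#' represented by a single compound whose density, molar mass and melting
#' point serve as medium features.
#'
#' @return A data.frame with columns `name`, `representative_compound` and the
#'   3 properties named in `medium_property_names`.
#' @export
lan_media <- function() {
  if (is.null(.lanbind_env$media)) {
    tab <- read_extdata_tsv("media.tsv")
    stopifnot(nrow(tab) == 8L,
              all(c("name", medium_property_names) %in% names(tab)))
    .lanbind_env$media <- tab
  }
  .lanbind_env$media
}

#' Look up a supported metal cation
#'
#' @param symbol Element symbol, e.g. `"Eu"`.
#' @param charge Integer oxidation state (3 for all entries, 4 for one Ce
#'   entry).
#' @return A list with `symbol`, `charge` and `properties`, an ordered named
#'   14-vector of elemental/ionic properties.
#' @examples
#' lookup_metal("Eu", 3)$properties[["atomic_number"]]  # 63
#' @export
lookup_metal <- function(symbol, charge) {
  tab <- lan_metals()
  hit <- tab$symbol == symbol & tab$charge == as.integer(charge)
  if (sum(hit) != 1L) {
    lan_abort(sprintf("unsupported cation: %s%+d (supported: %s)",
                      symbol, as.integer(charge),
                      paste0(tab$symbol, tab$charge, collapse = ", ")),
              "lanbind_unsupported_cation")
  }
  row <- tab[hit, , drop = FALSE]
  props <- as.numeric(row[1, metal_property_names])
  names(props) <- metal_property_names
  list(symbol = symbol, charge = as.integer(charge), properties = props)
}

#' Look up a supported solvent medium
#'
#' @param name Medium name, one of `alcohol`, `dioxane`, `KCl`, `KNO3`,
#'   `NaCl`, `NaClO4`, `NaNO3`, `R4NX` (case-insensitive).
#' @return A list with `name`, `representative_compound` and `properties`, an
#'   ordered named 3-vector (density, molar mass, melting point).
#' @examples
#' lookup_medium("NaClO4")$properties[["molar_mass"]]  # 122.44
#' @export
lookup_medium <- function(name) {
  tab <- lan_media()
  hit <- tolower(tab$name) == tolower(name)
  if (sum(hit) != 1L) {
    lan_abort(sprintf("unsupported medium: %s (supported: %s)",
                      name, paste(tab$name, collapse = ", ")),
              "lanbind_unsupported_medium")
  }
  row <- tab[hit, , drop = FALSE]
  props <- as.numeric(row[1, medium_property_names])
  names(props) <- medium_property_names
  list(name = row$name[1], representative_compound = row$representative_compound[1],
       properties = props)
}
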