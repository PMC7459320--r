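# Feature-vector assembly: 83 molecular descriptors (frozen configuration)
# + 14 metal properties + 3 medium properties + temperature and ionic
# strength = 102 features in a fixed block order.

N_MOLECULAR_DESCRIPTORS <- 83L

#' The frozen molecular-descriptor layout
#'
#' Returns the 83 descriptor names of the default configuration, in their
#' canonical (alphabetical) order. The list is shipped as a plain JSON config
#' and loaded once; it is never recomputed implicitly, so feature columns are
#' stable across runs. Users fitting their own corpus can regenerate a layout
#' with [freeze_descriptor_config()].
#'
#' @param config_path Optional path to an alternative JSON config.
#' @return Character vector of 83 descriptor names.
#' @export
default_descriptor_names <- function(config_path = NULL) {
  if (is.null(config_path)) {
    if (!is.null(.lanbind_env$desc_config)) return(.lanbind_env$desc_config)
    config_path <- system.file("extdata", "descriptor_config.json",
                               package = "lanbind")
    if (!nzchar(config_path))
      config_path <- file.path("inst", "extdata", "descriptor_config.json")
    cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    .lanbind_env$desc_config <- cfg$descriptors
    return(.lanbind_env$desc_config)
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  cfg$descriptors
}

#' Prune the candidate descriptor set
#'
#' Applies the three screening rules to a candidate descriptor matrix:
#' (a) fragment-count descriptors (`fr_` prefix) are dropped, (b) descriptors
#' that are null/zero for more than `null_frac` of the molecules are dropped,
#' (c) of any group of exactly identical columns only the alphabetically
#' first survives. The result is alphabetically sorted so the layout is
#' stable.
#'
#' @param matrix Numeric matrix of candidate descriptors (columns named) over
#'   the training molecules.
#' @param null_frac Maximum tolerated fraction of zero/missing values
#'   (default 0.95).
#' @return Ordered character vector of surviving descriptor names.
#' @export
prune_descriptor_set <- function(matrix, null_frac = 0.95) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0)
    lan_abort("empty descriptor matrix", "lanbind_config_error")
  keep <- colnames(matrix)
  keep <- keep[!startsWith(keep, "fr_")]
  nullish <- vapply(keep, function(nm) {
    col <- matrix[, nm]
    mean(!is.finite(col) | col == 0) > null_frac
  }, TRUE)
  keep <- keep[!nullish]
  keep <- sort(keep)
  # exact duplicate columns: first name (alphabetical) survives
  sig <- vapply(keep, function(nm) paste(matrix[, nm], collapse = ","), "")
  keep <- keep[!duplicated(sig)]
  sort(keep)
}

#' Freeze a descriptor configuration
#'
#' Runs [prune_descriptor_set()] on a reference molecule set and freezes the
#' survivors to a JSON config. When more than `n_keep` descriptors survive,
#' the lowest-variance survivors are dropped so the canonical 102-column
#' feature layout is preserved.
#'
#' @param mols List of `lan_mol` reference molecules.
#' @param path Output JSON path.
#' @param n_keep Number of descriptors to freeze (default 83).
#' @param null_frac Passed to [prune_descriptor_set()].
#' @return Invisibly, the frozen name vector.
#' @export
freeze_descriptor_config <- function(mols, path, n_keep = N_MOLECULAR_DESCRIPTORS,
                                     null_frac = 0.95) {
  dm <- descriptor_matrix(mols, all_descriptor_names())
  keep <- prune_descriptor_set(dm$matrix, null_frac = null_frac)
  if (length(keep) < n_keep) {
    lan_abort(sprintf("only %d descriptors survive pruning; %d required",
                      length(keep), n_keep), "lanbind_config_error")
  }
  if (length(keep) > n_keep) {
    vars <- apply(dm$matrix[, keep, drop = FALSE], 2, var)
    keep <- sort(keep[order(-vars)][seq_len(n_keep)])
  }
  jsonlite::write_json(list(descriptors = keep, n = length(keep)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(keep)
}

#' Names of the full 102-feature layout
#'
#' @param descriptor_names The molecular-descriptor block (default frozen
#'   layout).
#' @return Character vector of 102 feature names: descriptors, `metal_*`,
#'   `medium_*`, `temperature_K`, `ionic_strength_M`.
#' @export
feature_names <- function(descriptor_names = default_descriptor_names()) {
  c(descriptor_names,
    paste0("metal_", metal_property_names),
    paste0("medium_", medium_property_names),
    "temperature_K", "ionic_strength_M")
}

#' Assemble the full feature vector
#'
#' Concatenates the molecular-descriptor block with metal and medium
#' properties and the experimental conditions, in the fixed block order.
#'
#' @param desc Named numeric descriptor vector in the frozen 83-name layout.
#' @param metal A metal record from [lookup_metal()].
#' @param medium A medium record from [lookup_medium()].
#' @param temperature_K Temperature in kelvin (> 0).
#' @param ionic_strength_M Ionic strength in mol/L (>= 0).
#' @return Named numeric vector of length 102.
#' @export
assemble_features <- function(desc, metal, medium, temperature_K,
                              ionic_strength_M) {
  layout <- default_descriptor_names()
  if (length(desc) != length(layout) || !identical(names(desc), layout)) {
    lan_abort(sprintf(
      "feature-layout mismatch: expected the frozen %d-descriptor layout",
      length(layout)), "lanbind_feature_layout_error")
  }
  stopifnot(temperature_K > 0, ionic_strength_M >= 0)
  out <- c(unname(desc), unname(metal$properties), unname(medium$properties),
           temperature_K, ionic_strength_M)
  names(out) <- feature_names(layout)
  out
}

#' Featurize curated binding records into a model-ready matrix
#'
#' Computes the descriptor block once per distinct ligand and joins it with
#' the per-record metal, medium and condition features.
#'
#' @param records Data.frame of curated binding records (see
#'   [load_binding_table()]).
#' @param mols Named list of `lan_mol` objects covering `records$ligand_id`.
#' @return List with `X` (numeric matrix, 102 columns), `y` (logK1 vector),
#'   `records` (rows actually featurized) and `rejects`.
#' @export
featurize_records <- function(records, mols) {
  layout <- default_descriptor_names()
  dm <- descriptor_matrix(mols[unique(records$ligand_id)], layout)
  ok <- records$ligand_id %in% rownames(dm$matrix)
  rec <- records[ok, , drop = FALSE]
  n <- nrow(rec)
  X <- matrix(NA_real_, n, length(feature_names(layout)),
              dimnames = list(NULL, feature_names(layout)))
  for (r in seq_len(n)) {
    desc <- dm$matrix[rec$ligand_id[r], ]
    names(desc) <- layout
    X[r, ] <- assemble_features(desc,
                                lookup_metal(rec$cation_symbol[r], rec$cation_charge[r]),
                                lookup_medium(rec$medium[r]),
                                rec$temperature_K[r], rec$ionic_strength_M[r])
  }
  list(X = X, y = rec$logK1, records = rec, rejects = dm$rejects)
}
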