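# Synthetic fixture generator: seeded ligand structures and binding tables
# with known ground truth, emulating the statistical shape of curated
# stability-constant compilations (thousands of rows, 15 cations with one
# rare cation, logK1 in [-1.4, 30.7] with most mass between 0 and 10).
# It is not a statistical emulator of lanthanide chemistry; it only matches
# the dataset's shape so that recovery and pipeline properties are testable.

LOGK1_RANGE <- c(-1.4, 30.7)

SYNTH_SCAFFOLDS <- c("para_benzene", "pyridine", "chain", "tri_benzene")

SYNTH_SUBSTITUENTS <- c(
  "C(=O)O", "CC(=O)O", "CCC(=O)O", "N", "CN", "NCC", "O", "OC", "C", "CC",
  "CCC", "P(=O)(O)O", "CP(=O)(O)O", "C#N", "Cl", "F", "C(=O)N", "CO",
  "OCC(=O)O", "N(CC(=O)O)CC(=O)O")

#' Generate synthetic ligand structures
#'
#' Assembles neutral, single-fragment, valence-valid SMILES by seeded
#' sampling of carboxylate / amine / phosphonate / aromatic substituents on
#' a small scaffold set, echoing typical chelator chemistry.
#'
#' @param n Number of ligands.
#' @param seed Integer seed.
#' @return Data.frame with `id` and `smiles`, deterministic per seed.
#' @export
generate_ligands <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withr_seed(seed, {
    scaf <- sample(SYNTH_SCAFFOLDS, n, replace = TRUE)
    s1 <- sample(SYNTH_SUBSTITUENTS, n, replace = TRUE)
    s2 <- sample(SYNTH_SUBSTITUENTS, n, replace = TRUE)
    s3 <- sample(SYNTH_SUBSTITUENTS, n, replace = TRUE)
  })
  smiles <- character(n)
  for (i in seq_len(n)) {
    smiles[i] <- switch(scaf[i],
      para_benzene = sprintf("c1ccc(%s)cc1%s", s1[i], s2[i]),
      pyridine = sprintf("c1cc(%s)cnc1%s", s1[i], s2[i]),
      # a leading nitrile fragment must attach through its carbon
      chain = paste0(if (s1[i] == "C#N") "N#C" else s1[i], "CC", s2[i]),
      tri_benzene = sprintf("c1cc(%s)cc(%s)c1%s", s1[i], s2[i], s3[i]))
  }
  data.frame(id = sprintf("synth_%04d", seq_len(n)), smiles = smiles,
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic binding table
#'
#' @param n_rows Number of measurements (default 2000).
#' @param n_ligands Number of distinct ligands (default 120).
#' @param cations Character vector `"Sym:charge"`; default all 15.
#' @param media Medium names; default all 8.
#' @param noise_sd Gaussian noise on logK1 (default 0.5).
#' @param coefficients Named weights over informative molecular descriptors
#'   (default: a 5-descriptor sparse ground truth).
#' @param seed Integer seed.
#' @return A `lan_synth_spec` list.
#' @export
synthetic_spec <- function(n_rows = 2000L, n_ligands = 120L, cations = NULL,
                           media = NULL, noise_sd = 0.5, coefficients = NULL,
                           seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (is.null(cations)) {
    mt <- lan_metals()
    cations <- paste0(mt$symbol, ":", mt$charge)
  }
  if (is.null(media)) media <- lan_media()$name
  if (is.null(coefficients))
    coefficients <- c(NumHAcceptors = 2.0, TPSA = 1.3, BalabanJ = 1.0,
                      MolWt = 0.8, NumAromaticRings = 0.5)
  structure(list(n_rows = as.integer(n_rows), n_ligands = as.integer(n_ligands),
                 cations = cations, media = media, noise_sd = noise_sd,
                 coefficients = coefficients, seed = as.integer(seed)),
            class = "lan_synth_spec")
}

#' Generate a synthetic binding table with known ground truth
#'
#' logK1 is a clipped affine-plus-smooth function of standardized informative
#' descriptors, the metal ionic radius and the experimental conditions, plus
#' Gaussian noise. Per-cation counts are skewed, with Pm drawn at the rate of
#' a rare cation (about 0.3% of rows). Values are clipped to the empirical
#' range [-1.4, 30.7].
#'
#' @param spec A `lan_synth_spec` from [synthetic_spec()].
#' @return List with `records` (canonical binding-record data.frame),
#'   `ligands` (id/smiles), `mols` (named `lan_mol` list) and `truth`
#'   (coefficients and noise level).
#' @export
generate_binding_table <- function(spec) {
  stopifnot(inherits(spec, "lan_synth_spec"))
  lig <- generate_ligands(spec$n_ligands, seed = spec$seed)
  parsed <- read_smiles(lig$smiles, lig$id)
  if (nrow(parsed$rejects) > 0)
    warning(sprintf("%d synthetic ligand(s) failed to parse", nrow(parsed$rejects)))
  mols <- parsed$mols
  lig <- lig[lig$id %in% names(mols), , drop = FALSE]
  dm <- descriptor_matrix(mols, names(spec$coefficients))
  D <- dm$matrix
  # standardize informative descriptors over the ligand set
  Z <- scale(D)
  Z[!is.finite(Z)] <- 0
  mt <- lan_metals()
  cat_keys <- paste0(mt$symbol, ":", mt$charge)
  cat_keys <- intersect(cat_keys, spec$cations)
  w <- rep((1 - 0.0032) / max(length(cat_keys) - 1, 1), length(cat_keys))
  pm <- grepl("^Pm:", cat_keys)
  if (any(pm) && length(cat_keys) > 1) w[pm] <- 0.0032
  w <- w / sum(w)
  n <- spec$n_rows
  draws <- withr_seed(spec$seed + 1L, list(
    lig_i = sample(nrow(lig), n, replace = TRUE),
    cat_i = sample(length(cat_keys), n, replace = TRUE, prob = w),
    med = sample(spec$media, n, replace = TRUE),
    temp = sample(c(293.15, 298.15, 303.15, 310.15), n, replace = TRUE,
                  prob = c(0.15, 0.6, 0.15, 0.1)),
    ionic = sample(c(0.1, 0.5, 1.0, 2.0, 3.0), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.12, 0.08, 0.05)),
    noise = rnorm(n, 0, spec$noise_sd)))
  cat_parsed <- parse_cation(cat_keys)
  ionic_radius <- vapply(seq_len(nrow(cat_parsed)), function(i)
    lookup_metal(cat_parsed$symbol[i], cat_parsed$charge[i])$properties[["ionic_radius"]],
    0)
  zrow <- Z[draws$lig_i, , drop = FALSE]
  lin <- as.numeric(zrow %*% spec$coefficients)
  r_i <- ionic_radius[draws$cat_i]
  y <- 4.5 + lin +
    0.8 * tanh(zrow[, 1]) +
    1.5 * pmax(rowSums(zrow[, seq_len(min(2, ncol(zrow))), drop = FALSE]) - 2, 0)^2 +
    0.15 * (95 - r_i) -
    0.8 * sqrt(draws$ionic) +
    0.05 * (draws$temp - 298.15) / 10 +
    draws$noise
  y <- pmin(pmax(y, LOGK1_RANGE[1]), LOGK1_RANGE[2])
  records <- data.frame(
    ligand_id = lig$id[draws$lig_i],
    cation_symbol = cat_parsed$symbol[draws$cat_i],
    cation_charge = cat_parsed$charge[draws$cat_i],
    medium = draws$med,
    temperature_K = draws$temp,
    ionic_strength_M = draws$ionic,
    logK1 = y,
    row = seq_len(n),
    stringsAsFactors = FALSE)
  list(records = records, ligands = lig, mols = mols,
       truth = list(coefficients = spec$coefficients,
                    noise_sd = spec$noise_sd))
}

#' Write a binding table in the canonical TSV schema
#'
#' The written file round-trips through [load_binding_table()] and
#' [curate()] losslessly. A sidecar JSON with the true coefficients is
#' written alongside when `truth` is supplied.
#'
#' @param records Binding records (canonical columns).
#' @param path Output TSV path.
#' @param truth Optional ground-truth list to write as `<path>.truth.json`.
#' @export
write_binding_table <- function(records, path, truth = NULL) {
  out <- data.frame(
    ligand = records$ligand_id,
    cation = paste0(records$cation_symbol, records$cation_charge, "+"),
    medium = records$medium,
    temperature = records$temperature_K,
    ionic_strength = records$ionic_strength_M,
    logK1 = records$logK1)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}
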