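# Binding-constant table ingestion, curation and splitting. The canonical
# record schema is one row per measurement: ligand id, cation, medium,
# temperature (K), ionic strength (mol/L) and logK1 (decadic log of
# K1 = [ML]/([M][L])).

CANONICAL_COLUMNS <- c("ligand_id", "cation", "medium", "temperature",
                       "ionic_strength", "logK1")

DEFAULT_COLUMN_ALIASES <- list(
  ligand_id = c("ligand_id", "ligand", "molecule", "compound", "id"),
  cation = c("cation", "metal", "metal_ion", "ion"),
  medium = c("medium", "solvent", "background", "electrolyte"),
  temperature = c("temperature", "temp", "temperature_k", "t_k", "t"),
  ionic_strength = c("ionic_strength", "ionic_strength_m", "ionic_concentration",
                     "i", "ionic"),
  logk1 = c("logk1", "log_k1", "logk", "log_k"))

#' Parse a cation notation
#'
#' Accepts notations like `"Eu3+"`, `"Eu(III)"`, `"Eu^3+^"`, `"Eu:3"` or
#' plain `"Eu"` (defaulting to +3).
#'
#' @param x Character vector of cation labels.
#' @return Data.frame with `symbol` and `charge`.
#' @export
parse_cation <- function(x) {
  x <- trimws(as.character(x))
  sym <- sub("^([A-Z][a-z]?).*$", "\\1", x)
  charge <- rep(3L, length(x))
  num <- regmatches(x, regexpr("[0-9]+", x))
  has_num <- grepl("[0-9]", x)
  charge[has_num] <- as.integer(unlist(num))
  roman <- regmatches(x, regexpr("\\((I+V?|IV)\\)", x))
  has_rom <- grepl("\\(I+V?\\)|\\(IV\\)", x)
  if (any(has_rom)) {
    rmap <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
    charge[has_rom] <- rmap[gsub("[()]", "", unlist(roman))]
  }
  data.frame(symbol = sym, charge = charge, stringsAsFactors = FALSE)
}

#' Load a binding-constant table
#'
#' Reads a delimited text file (TSV/CSV) or an `.xlsx` workbook whose header
#' names (case-insensitive, alias-mapped) cover ligand id, cation, medium,
#' temperature, ionic strength and logK1. Temperatures may be given in
#' Celsius with `temperature_unit = "C"`.
#'
#' @param path Input file.
#' @param aliases Optional alias list overriding `DEFAULT_COLUMN_ALIASES`.
#' @param temperature_unit `"K"` (default) or `"C"`.
#' @return Data.frame of binding records with canonical columns
#'   `ligand_id`, `cation_symbol`, `cation_charge`, `medium`,
#'   `temperature_K`, `ionic_strength_M`, `logK1` and `row` (source row).
#' @export
load_binding_table <- function(path, aliases = NULL, temperature_unit = c("K", "C")) {
  temperature_unit <- match.arg(temperature_unit)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      lan_abort("reading .xlsx requires the readxl package", "lanbind_schema_error")
    tab <- as.data.frame(readxl::read_excel(path))
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "#")
  }
  al <- DEFAULT_COLUMN_ALIASES
  if (!is.null(aliases)) al[names(aliases)] <- aliases
  lower <- tolower(trimws(names(tab)))
  pick <- function(field) {
    hit <- which(lower %in% tolower(al[[field]]))
    if (length(hit) == 0)
      lan_abort(sprintf("missing mandatory column: %s (aliases tried: %s)",
                        field, paste(al[[field]], collapse = ", ")),
                "lanbind_schema_error")
    hit[1]
  }
  cols <- vapply(c("ligand_id", "cation", "medium", "temperature",
                   "ionic_strength", "logk1"), pick, 1L)
  cat <- parse_cation(tab[[cols["cation"]]])
  temp <- suppressWarnings(as.numeric(tab[[cols["temperature"]]]))
  if (temperature_unit == "C") temp <- temp + 273.15
  out <- data.frame(
    ligand_id = as.character(tab[[cols["ligand_id"]]]),
    cation_symbol = cat$symbol,
    cation_charge = cat$charge,
    medium = as.character(tab[[cols["medium"]]]),
    temperature_K = temp,
    ionic_strength_M = suppressWarnings(as.numeric(tab[[cols["ionic_strength"]]])),
    logK1 = suppressWarnings(as.numeric(tab[[cols["logk1"]]])),
    row = seq_len(nrow(tab)),
    stringsAsFactors = FALSE)
  out
}

#' Curate binding records
#'
#' Drops rows with any missing condition field, an unsupported cation or an
#' unsupported medium, reporting per-reason drop counts. Surviving rows are
#' returned unchanged, so curation is idempotent.
#'
#' @param records Data.frame from [load_binding_table()].
#' @param quiet Suppress the per-reason drop report (default FALSE).
#' @return The curated data.frame.
#' @export
curate <- function(records, quiet = FALSE) {
  metals <- lan_metals()
  media <- tolower(lan_media()$name)
  supported_cation <- paste(records$cation_symbol, records$cation_charge) %in%
    paste(metals$symbol, metals$charge)
  reasons <- list(
    "missing temperature" = !is.finite(records$temperature_K),
    "missing ionic strength" = !is.finite(records$ionic_strength_M),
    "missing medium" = is.na(records$medium) | !nzchar(records$medium),
    "missing logK1" = !is.finite(records$logK1),
    "unsupported cation" = !supported_cation,
    "unsupported medium" = !(tolower(records$medium) %in% media))
  drop <- Reduce(`|`, reasons)
  if (!quiet) {
    for (nm in names(reasons)) {
      n <- sum(reasons[[nm]], na.rm = TRUE)
      if (n > 0) message(sprintf("curate: dropped %d row(s): %s", n, nm))
    }
  }
  out <- records[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("curation produced an empty table")
  out
}

#' Random train/test split
#'
#' Uniform random partition of record ids, reproducible for a fixed seed and
#' invariant to the input row order (ids are sorted before sampling).
#'
#' @param records Curated records data.frame (uses the `row` column as id) or
#'   a vector of ids.
#' @param fraction Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `seed`, `fraction`.
#' @export
split_train_test <- function(records, fraction = 0.2, seed = 1L) {
  ids <- if (is.data.frame(records)) records$row else records
  if (length(ids) < 2) lan_abort("need at least 2 records", "lanbind_split_error")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    lan_abort("fraction must lie in (0, 1)", "lanbind_split_error")
  ids <- sort(ids)
  n_test <- round(fraction * length(ids))
  test <- withr_seed(seed, sort(sample(ids, n_test)))
  list(train_ids = setdiff(ids, test), test_ids = test,
       seed = as.integer(seed), fraction = fraction)
}

#' k-fold partition
#'
#' @param records Records data.frame or id vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of k split objects (`train_ids`, `test_ids`); every id
#'   appears in exactly one test fold and fold sizes differ by at most one.
#' @export
kfold <- function(records, k = 10L, seed = 1L) {
  ids <- if (is.data.frame(records)) records$row else records
  n <- length(ids)
  if (k > n) lan_abort("k exceeds the number of records", "lanbind_split_error")
  ids <- sort(ids)
  perm <- withr_seed(seed, sample(ids))
  # contiguous blocks of the seeded permutation; sizes differ by at most one
  fold_of <- sort(rep(seq_len(k), length.out = n))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- sort(perm[fold_of == f])
    folds[[f]] <- list(train_ids = setdiff(ids, test), test_ids = test,
                       fold = f, seed = as.integer(seed))
  }
  folds
}

#' Write a split manifest as JSON
#' @param split A split object from [split_train_test()].
#' @param path Output path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
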