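# Molecule ingestion. All structure parsing, 2D layout, explicit-hydrogen
# addition, canonicalization and force-field minimization go through
# ChemmineR/ChemmineOB (OpenBabel). Internally a molecule is a light graph
# record ("lan_mol") extracted from the kekulized V2000 block: elements,
# bonds with orders, formal charges and coordinates.

ob_options <- function(names, args = rep("", length(names))) {
  data.frame(names = names, args = args, stringsAsFactors = FALSE)
}

ob_convert <- function(from, to, text, names = character(), args = rep("", length(names))) {
  if (length(names) == 0L) {
    ChemmineOB::convertFormat(from, to, text)
  } else {
    ChemmineOB::convertFormat(from, to, text, options = ob_options(names, args))
  }
}

# V2000 old-style charge codes -> formal charge
charge_from_code <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

split_sdf_records <- function(lines) {
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0L) return(list(lines))
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  Filter(function(r) any(nzchar(r)), recs)
}

#' @rdname read_smiles
#' @export
is_lan_mol <- function(x) inherits(x, "lan_mol")

# Build lan_mol objects from an SDF text block (one or more records).
mols_from_sdf_lines <- function(lines, fallback_ids = NULL) {
  recs <- split_sdf_records(lines)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(unlist(lapply(recs, c, "$$$$"))))
  ok <- ChemmineR::validSDF(sdfset)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    if (!ok[i]) next
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    id <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if ((is.null(id) || !nzchar(id) || grepl("^CMP", id)) && !is.null(fallback_ids)) {
      id <- fallback_ids[i]
    }
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    charges <- if ("C6" %in% colnames(ab)) charge_from_code(ab[, "C6"]) else
      rep(0L, nrow(ab))
    # M CHG property lines override the atom-block codes when present
    chg_lines <- grep("^M  CHG", recs[[i]], value = TRUE)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charges[f[2 * k]] <- f[2 * k + 1]
    }
    bonds <- if (nrow(bb) > 0) {
      cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
            order = as.integer(bb[, 3]))
    } else {
      matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
    }
    out[[i]] <- structure(list(
      id = as.character(id), elements = elements, bonds = bonds,
      charges = as.integer(charges), coords = coords,
      lines = recs[[i]], source = "sdf"), class = "lan_mol")
  }
  out
}

#' Read molecules from SMILES strings
#'
#' Parses SMILES, generates a deterministic rule-based 2D layout and adds
#' explicit hydrogens. Unparsable entries are returned in a rejects table
#' rather than silently dropped.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional stable identifiers (default `mol_1, ...`).
#' @return A list with `mols` (list of `lan_mol`) and `rejects` (data.frame of
#'   id and reason).
#' @export
read_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  txt <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- tryCatch(ob_convert("SMI", "SDF", txt, c("gen2D", "h")),
                  error = function(e) "")
  mols <- if (nzchar(out)) mols_from_sdf_lines(strsplit(out, "\n", fixed = TRUE)[[1]]) else list()
  mols <- Filter(Negate(is.null), mols)
  got <- vapply(mols, function(m) m$id, "")
  names(mols) <- got
  missing <- setdiff(ids, got)
  rejects <- data.frame(id = missing,
                        reason = rep("unparsable SMILES", length(missing)),
                        stringsAsFactors = FALSE)
  mols <- mols[intersect(ids, got)]
  list(mols = mols, rejects = rejects)
}

#' Read molecules from an SDF/MOL file
#'
#' Reads a (multi-record V2000) SDF or single MOL file and adds explicit
#' hydrogens. Gzip-compressed files are handled transparently.
#'
#' @param path File path.
#' @param add_hydrogens Add explicit hydrogens (default TRUE; descriptor
#'   computation expects them).
#' @return A list with `mols` and `rejects` as in [read_smiles()].
#' @export
read_sdf <- function(path, add_hydrogens = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!any(grepl("^\\${4}", lines))) lines <- c(lines, "$$$$")
  sdf_lines_to_mols(lines, add_hydrogens)
}

sdf_lines_to_mols <- function(lines, add_hydrogens = TRUE) {
  recs <- split_sdf_records(lines)
  orig_ids <- vapply(recs, function(r) trimws(r[1]), "")
  orig_ids[!nzchar(orig_ids)] <- paste0("rec_", which(!nzchar(orig_ids)))
  if (add_hydrogens) {
    txt <- paste0(paste(unlist(lapply(recs, c, "$$$$")), collapse = "\n"), "\n")
    out <- tryCatch(ob_convert("SDF", "SDF", txt, "h"), error = function(e) "")
    lines2 <- if (nzchar(out)) strsplit(out, "\n", fixed = TRUE)[[1]] else character(0)
    mols <- mols_from_sdf_lines(lines2)
  } else {
    mols <- mols_from_sdf_lines(lines)
  }
  mols <- Filter(Negate(is.null), mols)
  got <- vapply(mols, function(m) m$id, "")
  names(mols) <- got
  missing <- setdiff(orig_ids, got)
  list(mols = mols,
       rejects = data.frame(id = missing,
                            reason = rep("unparsable SDF record", length(missing)),
                            stringsAsFactors = FALSE))
}

#' Canonical structure keys
#'
#' Canonical SMILES (OpenBabel canonical order) used as the deduplication key
#' during library screening.
#'
#' @param mols List of `lan_mol` objects.
#' @return Named character vector of canonical SMILES (NA where conversion
#'   failed).
#' @export
canonical_keys <- function(mols) {
  if (length(mols) == 0L) return(character(0))
  txt <- paste0(unlist(lapply(mols, function(m) c(m$lines, "$$$$"))), collapse = "\n")
  out <- tryCatch(ob_convert("SDF", "CAN", paste0(txt, "\n")), error = function(e) "")
  keys <- rep(NA_character_, length(mols))
  names(keys) <- vapply(mols, function(m) m$id, "")
  if (nzchar(out)) {
    for (ln in strsplit(out, "\n", fixed = TRUE)[[1]]) {
      if (!nzchar(ln)) next
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) >= 2 && parts[2] %in% names(keys)) keys[parts[2]] <- parts[1]
    }
  }
  keys
}

#' Net formal charge of a molecule
#' @param mol A `lan_mol`.
#' @return Integer net formal charge (sum of atomic formal charges).
#' @export
formal_charge <- function(mol) sum(mol$charges)

format_atom_line <- function(xyz, rest) {
  paste0(sprintf("%10.4f%10.4f%10.4f", xyz[1], xyz[2], xyz[3]), rest)
}

#' Embed a molecule in 3D and refine with the UFF force field
#'
#' Builds a deterministic starting geometry from the rule-based 2D layout
#' plus a seeded out-of-plane perturbation, then relaxes it by steepest
#' descent under the general-purpose UFF force field. One conformer per
#' molecule; identical seed gives identical coordinates.
#'
#' @param mol A `lan_mol` with explicit hydrogens.
#' @param seed Integer seed for the starting perturbation (default 42).
#' @param steps Maximum minimization steps (default 1500).
#' @return The molecule with refined 3D coordinates.
#' @export
embed_and_refine <- function(mol, seed = 42L, steps = 1500L) {
  stopifnot(is_lan_mol(mol))
  n <- length(mol$elements)
  if (n == 0L) {
    lan_abort(sprintf("featurization failure for '%s': empty structure", mol$id),
              "lanbind_featurization_failure")
  }
  lines <- mol$lines
  atom_rows <- seq_len(n) + 4L
  jitter <- withr_seed(seed, matrix(rnorm(3L * n, 0, 0.25), ncol = 3))
  for (k in seq_len(n)) {
    i <- atom_rows[k]
    xyz <- mol$coords[k, ] + jitter[k, ]
    lines[i] <- format_atom_line(xyz, substr(lines[i], 31L, nchar(lines[i])))
  }
  txt <- paste0(paste(c(lines, "$$$$"), collapse = "\n"), "\n")
  out <- tryCatch(
    ob_convert("SDF", "SDF", txt, c("minimize", "ff", "steps", "sd"),
               c("", "UFF", as.character(steps), "")),
    error = function(e) "")
  refined <- if (nzchar(out))
    mols_from_sdf_lines(strsplit(out, "\n", fixed = TRUE)[[1]]) else list()
  refined <- Filter(Negate(is.null), refined)
  if (length(refined) != 1L || length(refined[[1]]$elements) != n) {
    lan_abort(sprintf("featurization failure for '%s': 3D refinement failed", mol$id),
              "lanbind_featurization_failure")
  }
  res <- refined[[1]]
  res$id <- mol$id
  res$source <- mol$source
  res
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
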