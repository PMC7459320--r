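# Applicability domain (per-descriptor bounding box over the training
# molecules) and streaming compound-library screening under standard
# conditions (298 K, 0.1 M, perchlorate medium).

STANDARD_CONDITIONS <- list(temperature_K = 298, ionic_strength_M = 0.1,
                            medium = "NaClO4")

#' Build the bounding-box applicability domain
#'
#' Tabulates the columnwise minimum and maximum of every molecular
#' descriptor over the training set. Bounds are closed intervals, so every
#' training molecule is in-domain by construction.
#'
#' @param train_descriptors Numeric matrix (rows = training molecules,
#'   columns = the frozen descriptor layout).
#' @return A `lan_domain_box` with `min`, `max`, `descriptor_names` and a
#'   fingerprint hash of the training matrix.
#' @export
build_domain <- function(train_descriptors) {
  X <- as.matrix(train_descriptors)
  if (nrow(X) == 0) lan_abort("empty training descriptor matrix",
                              "lanbind_domain_error")
  if (any(!is.finite(X))) lan_abort("non-finite entries in training descriptors",
                                    "lanbind_domain_error")
  structure(list(
    descriptor_names = colnames(X),
    min = apply(X, 2, min),
    max = apply(X, 2, max),
    n_train = nrow(X),
    fingerprint = sprintf("%d:%.8g", nrow(X), sum(X))), class = "lan_domain_box")
}

#' Test whether a descriptor vector lies inside the applicability domain
#'
#' @param desc Named numeric descriptor vector (or matrix of rows).
#' @param box A `lan_domain_box`.
#' @return Logical: TRUE iff every descriptor lies within its closed
#'   interval.
#' @export
in_domain <- function(desc, box) {
  if (is.matrix(desc)) {
    if (ncol(desc) != length(box$min))
      lan_abort("descriptor layout does not match the domain box",
                "lanbind_feature_layout_error")
    return(apply(desc, 1, function(r) all(r >= box$min & r <= box$max)))
  }
  if (length(desc) != length(box$min) ||
      (!is.null(names(desc)) && !is.null(box$descriptor_names) &&
       !identical(names(desc), box$descriptor_names)))
    lan_abort("descriptor layout does not match the domain box",
              "lanbind_feature_layout_error")
  all(desc >= box$min & desc <= box$max)
}

#' Serialize / restore a domain box
#' @param box A `lan_domain_box`.
#' @param path JSON path.
#' @export
write_domain <- function(box, path) {
  jsonlite::write_json(unclass(box), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$min <- setNames(as.numeric(obj$min), obj$descriptor_names)
  obj$max <- setNames(as.numeric(obj$max), obj$descriptor_names)
  structure(obj, class = "lan_domain_box")
}

#' Screen a compound library
#'
#' Streams a (possibly gzipped) multi-record SDF in chunks: deduplicates by
#' canonical structure key, drops molecules with nonzero net formal charge,
#' featurizes, filters by the applicability domain and predicts logK1 for
#' every requested cation under the given conditions. Memory use is bounded
#' by the chunk size; the library is never materialized wholesale.
#'
#' @param sdf_path Input SDF (`.sdf` or `.sdf.gz`).
#' @param model A trained `lan_model` on the 102-feature layout.
#' @param box A `lan_domain_box` over the molecular-descriptor block.
#' @param cations Character vector like `"Eu:3"`, or `"all"` for the full
#'   15-cation table.
#' @param conditions List with `temperature_K`, `ionic_strength_M`,
#'   `medium` (default `STANDARD_CONDITIONS`).
#' @param out Optional TSV output path (molecule id, cation, predicted
#'   logK1); when NULL predictions are returned in memory.
#' @param chunk_size Records per chunk (default 200).
#' @return List with `predictions` (data.frame; NULL if streamed to `out`)
#'   and `counters` (read, duplicate, charged, featurization_failed,
#'   out_of_domain, predicted).
#' @export
screen_library <- function(sdf_path, model, box, cations = "all",
                           conditions = STANDARD_CONDITIONS, out = NULL,
                           chunk_size = 200L) {
  if (identical(cations, "all")) {
    mt <- lan_metals()
    cations <- paste0(mt$symbol, ":", mt$charge)
  }
  cat_tab <- do.call(rbind, lapply(strsplit(cations, ":"), function(p)
    data.frame(symbol = p[1], charge = as.integer(p[2] %||% "3"),
               stringsAsFactors = FALSE)))
  metals <- lapply(seq_len(nrow(cat_tab)), function(i)
    lookup_metal(cat_tab$symbol[i], cat_tab$charge[i]))
  medium <- lookup_medium(conditions$medium)
  layout <- box$descriptor_names
  counters <- c(read = 0L, duplicate = 0L, charged = 0L,
                featurization_failed = 0L, out_of_domain = 0L, predicted = 0L)
  seen <- new.env(parent = emptyenv())
  preds <- list()
  out_con <- NULL
  if (!is.null(out)) {
    out_con <- file(out, "wt")
    writeLines("molecule_id\tcation\tlogK1_predicted", out_con)
    on.exit(close(out_con), add = TRUE)
  }
  con <- if (grepl("\\.gz$", sdf_path)) gzfile(sdf_path, "rt") else
    file(sdf_path, "rt")
  on.exit(close(con), add = TRUE)

  process_chunk <- function(lines) {
    parsed <- tryCatch(sdf_lines_to_mols(lines),
                       error = function(e) list(mols = list(),
                                                rejects = data.frame()))
    counters["featurization_failed"] <<- counters["featurization_failed"] +
      nrow(parsed$rejects)
    mols <- parsed$mols
    if (length(mols) == 0) return(invisible())
    keys <- canonical_keys(mols)
    keep <- list()
    for (m in mols) {
      key <- keys[[m$id]]
      if (is.na(key)) {
        counters["featurization_failed"] <<- counters["featurization_failed"] + 1L
        next
      }
      if (!is.null(seen[[key]])) {
        counters["duplicate"] <<- counters["duplicate"] + 1L
        next
      }
      assign(key, TRUE, envir = seen)
      if (formal_charge(m) != 0L) {
        counters["charged"] <<- counters["charged"] + 1L
        next
      }
      keep[[m$id]] <- m
    }
    if (length(keep) == 0) return(invisible())
    dm <- suppressWarnings(descriptor_matrix(keep, layout))
    counters["featurization_failed"] <<- counters["featurization_failed"] +
      nrow(dm$rejects)
    if (nrow(dm$matrix) == 0) return(invisible())
    inside <- in_domain(dm$matrix, box)
    counters["out_of_domain"] <<- counters["out_of_domain"] + sum(!inside)
    dm_in <- dm$matrix[inside, , drop = FALSE]
    if (nrow(dm_in) == 0) return(invisible())
    counters["predicted"] <<- counters["predicted"] + nrow(dm_in)
    for (ci in seq_along(metals)) {
      X <- matrix(NA_real_, nrow(dm_in), length(feature_names(layout)),
                  dimnames = list(NULL, feature_names(layout)))
      for (r in seq_len(nrow(dm_in))) {
        X[r, ] <- c(dm_in[r, ], unname(metals[[ci]]$properties),
                    unname(medium$properties), conditions$temperature_K,
                    conditions$ionic_strength_M)
      }
      p <- predict(model, X)
      df <- data.frame(molecule_id = rownames(dm_in),
                       cation = cations[ci], logK1_predicted = p,
                       stringsAsFactors = FALSE)
      if (!is.null(out_con)) {
        writeLines(sprintf("%s\t%s\t%.6g", df$molecule_id, df$cation,
                           df$logK1_predicted), out_con)
      } else {
        preds[[length(preds) + 1L]] <<- df
      }
    }
    invisible()
  }

  buffer <- character(0)
  n_in_buffer <- 0L
  repeat {
    batch <- readLines(con, n = 5000L, warn = FALSE)
    if (length(batch) == 0) break
    buffer <- c(buffer, batch)
    ends <- grep("^\\${4}", buffer)
    while (length(ends) >= chunk_size) {
      cut <- ends[chunk_size]
      counters["read"] <- counters["read"] + chunk_size
      process_chunk(buffer[seq_len(cut)])
      buffer <- buffer[-seq_len(cut)]
      ends <- grep("^\\${4}", buffer)
    }
  }
  ends <- grep("^\\${4}", buffer)
  if (length(ends) > 0) {
    counters["read"] <- counters["read"] + length(ends)
    process_chunk(buffer[seq_len(ends[length(ends)])])
  }
  list(predictions = if (is.null(out_con))
    (if (length(preds)) do.call(rbind, preds) else NULL) else NULL,
    counters = counters)
}
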