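# Cation-pair selectivity: matched-condition pairing of measurements for a
# ligand and two cations, and MAE/RMSE of predicted versus experimental
# selectivities (delta logK1).

#' Match records into selectivity pairs
#'
#' For a cation pair (A, B), finds every (ligand, conditions) combination
#' measured for both cations under the same medium (exact), temperature and
#' ionic strength (within tolerances). Replicate measurements within one
#' cell are averaged. The experimental selectivity is
#' delta = logK1(A) - logK1(B); swapping the cations negates it.
#'
#' @param records Curated binding records.
#' @param cation_a,cation_b Cation labels like `"Eu:3"` or `c("Eu", 3)`.
#' @param temp_tol Temperature tolerance in K (default 0.01).
#' @param ionic_tol Ionic-strength tolerance in mol/L (default 1e-6).
#' @return Data.frame of pairs: ligand_id, medium, temperature_K,
#'   ionic_strength_M, logK1_a, logK1_b, delta_exp. Empty (with a message)
#'   when no common conditions exist.
#' @export
match_pairs <- function(records, cation_a, cation_b, temp_tol = 0.01,
                        ionic_tol = 1e-6) {
  pa <- parse_cation(paste(cation_a, collapse = ""))
  pb <- parse_cation(paste(cation_b, collapse = ""))
  ra <- records[records$cation_symbol == pa$symbol &
                  records$cation_charge == pa$charge, , drop = FALSE]
  rb <- records[records$cation_symbol == pb$symbol &
                  records$cation_charge == pb$charge, , drop = FALSE]
  out <- list()
  if (nrow(ra) > 0 && nrow(rb) > 0) {
    for (i in seq_len(nrow(ra))) {
      hit <- rb$ligand_id == ra$ligand_id[i] &
        tolower(rb$medium) == tolower(ra$medium[i]) &
        abs(rb$temperature_K - ra$temperature_K[i]) <= temp_tol &
        abs(rb$ionic_strength_M - ra$ionic_strength_M[i]) <= ionic_tol
      if (!any(hit)) next
      key <- paste(ra$ligand_id[i], tolower(ra$medium[i]),
                   round(ra$temperature_K[i], 2),
                   signif(ra$ionic_strength_M[i], 6), sep = "|")
      cell <- out[[key]]
      if (is.null(cell)) {
        out[[key]] <- data.frame(
          ligand_id = ra$ligand_id[i], medium = ra$medium[i],
          temperature_K = ra$temperature_K[i],
          ionic_strength_M = ra$ionic_strength_M[i],
          logK1_a = ra$logK1[i], n_a = 1L,
          logK1_b = mean(rb$logK1[hit]), n_b = sum(hit),
          stringsAsFactors = FALSE)
      } else {
        # replicate measurement of cation A in the same cell: running mean
        cell$logK1_a <- (cell$logK1_a * cell$n_a + ra$logK1[i]) / (cell$n_a + 1L)
        cell$n_a <- cell$n_a + 1L
        out[[key]] <- cell
      }
    }
  }
  if (length(out) == 0) {
    message(sprintf("no common experimental conditions for %s and %s",
                    paste0(pa$symbol, pa$charge, "+"),
                    paste0(pb$symbol, pb$charge, "+")))
    return(data.frame(ligand_id = character(0), medium = character(0),
                      temperature_K = numeric(0), ionic_strength_M = numeric(0),
                      logK1_a = numeric(0), logK1_b = numeric(0),
                      delta_exp = numeric(0), stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  pairs$delta_exp <- pairs$logK1_a - pairs$logK1_b
  pairs$cation_a <- paste0(pa$symbol, ":", pa$charge)
  pairs$cation_b <- paste0(pb$symbol, ":", pb$charge)
  pairs[, c("ligand_id", "cation_a", "cation_b", "medium", "temperature_K",
            "ionic_strength_M", "logK1_a", "logK1_b", "delta_exp")]
}

#' Selectivity accuracy metrics
#'
#' Predicts logK1 for both cations of every pair under the pair's own
#' conditions and reports MAE/RMSE of (delta_pred - delta_exp). Symmetric
#' under swapping the cation order.
#'
#' @param pairs Data.frame from [match_pairs()].
#' @param model A trained `lan_model`.
#' @param mols Named list of `lan_mol` covering `pairs$ligand_id`.
#' @return List with `mae`, `rmse`, `n` and the augmented `pairs` table
#'   (delta_pred column); an explicit no-data result (`n = 0`, NA metrics)
#'   when `pairs` is empty.
#' @export
selectivity_metrics <- function(pairs, model, mols) {
  if (nrow(pairs) == 0)
    return(list(mae = NA_real_, rmse = NA_real_, n = 0L, pairs = pairs))
  layout <- default_descriptor_names()
  dm <- descriptor_matrix(mols[unique(pairs$ligand_id)], layout)
  medium_cache <- lapply(setNames(nm = unique(tolower(pairs$medium))),
                         lookup_medium)
  predict_one <- function(ligand, cation, row) {
    pc <- parse_cation(cation)
    metal <- lookup_metal(pc$symbol, pc$charge)
    med <- medium_cache[[tolower(row$medium)]]
    x <- c(dm$matrix[ligand, ], unname(metal$properties),
           unname(med$properties), row$temperature_K, row$ionic_strength_M)
    X <- matrix(x, 1, dimnames = list(NULL, feature_names(layout)))
    predict(model, X)
  }
  delta_pred <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    row <- pairs[i, ]
    delta_pred[i] <- predict_one(row$ligand_id, row$cation_a, row) -
      predict_one(row$ligand_id, row$cation_b, row)
  }
  pairs$delta_pred <- delta_pred
  err <- pairs$delta_pred - pairs$delta_exp
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), n = nrow(pairs),
       pairs = pairs)
}

#' Hand-computed selectivity error metrics
#'
#' Utility for reporting MAE/RMSE over explicit (delta_pred, delta_exp)
#' columns, e.g. from an external prediction table.
#'
#' @param delta_pred,delta_exp Numeric vectors of equal length.
#' @return List with `mae`, `rmse`, `n`.
#' @export
delta_metrics <- function(delta_pred, delta_exp) {
  stopifnot(length(delta_pred) == length(delta_exp))
  if (length(delta_pred) == 0)
    return(list(mae = NA_real_, rmse = NA_real_, n = 0L))
  err <- delta_pred - delta_exp
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), n = length(err))
}
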