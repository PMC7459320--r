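#' Out-of-sample validation table for nitrogen-donor ligands
#'
#' Bundled comparison of reference model predictions against experimental
#' logK1 values for 33 lanthanide complexes of six well-known nitrogen-donor
#' ligands (ADPTZ, MePhPTA, Phen, TERPY, Me-BTP, PDAM). Used as a worked
#' example of out-of-sample error arithmetic: the MAE between the two
#' columns summarizes model generalizability on chemistry outside the
#' training corpus.
#'
#' @return Data.frame with columns `ligand`, `cation`, `charge`,
#'   `logk1_predicted`, `logk1_experimental`.
#' @export
nitrogen_donor_validation <- function() {
  tab <- read_extdata_tsv("nitrogen_donor_logk1.tsv")
  stopifnot(nrow(tab) == 33L)
  tab
}
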