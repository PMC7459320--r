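# Shared fixtures, memoized for the test session. Everything is generated in
# code; no binary artifacts.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# A small panel of hand-picked molecules with known chemistry.
fx_mols <- function() {
  memo("mols", {
    smi <- c(eth = "CCO", benz = "c1ccccc1", water = "O", methane = "C",
             salicylic = "OC(=O)c1ccccc1O", glycine = "NCC(=O)O",
             pyridine = "c1ccncc1", acetate = "CC(=O)[O-]",
             edta_arm = "OC(=O)CN(CC(=O)O)CC(=O)O",
             phosphonate = "CP(=O)(O)O")
    read_smiles(unname(smi), names(smi))
  })
}

# Synthetic study-shaped binding table (the generator's defaults define the
# conditions: 2000 rows, noise_sd 0.5) plus its featurization and an 80/20
# split.
fx_synth <- function() {
  memo("synth", {
    tab <- generate_binding_table(
      synthetic_spec(n_rows = 2000L, n_ligands = 90L, seed = 101L))
    fz <- featurize_records(tab$records, tab$mols)
    sp <- split_train_test(fz$records, fraction = 0.2, seed = 7L)
    tr <- fz$records$row %in% sp$train_ids
    list(tab = tab, X = fz$X, y = fz$y, records = fz$records,
         train = tr, split = sp)
  })
}

fx_adaboost <- function() {
  memo("adaboost", {
    fx <- fx_synth()
    train_model("adaboost", fx$X[fx$train, ], fx$y[fx$train], seed = 5L)
  })
}

# Low-dimensional regression fixture for importance/curve tests: 3
# informative + 17 noise features.
fx_matrix <- function() {
  memo("matrix", {
    set.seed(42)
    n <- 600L; p <- 20L
    X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- 3 * X[, 1] + 2 * X[, 2] - 2 * X[, 3] + rnorm(n, 0, 0.1)
    list(X = X, y = y, informative = c("f1", "f2", "f3"))
  })
}
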