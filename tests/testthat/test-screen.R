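test_that("domain box equals a brute-force columnwise scan", {
  set.seed(31)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("d", 1:5)))
  box <- build_domain(X)
  for (j in 1:5) {
    lo <- Inf; hi <- -Inf
    for (i in 1:50) { lo <- min(lo, X[i, j]); hi <- max(hi, X[i, j]) }
    expect_equal(unname(box$min[j]), lo)
    expect_equal(unname(box$max[j]), hi)
  }
  # closure: every training row is in-domain; bounds are inclusive
  expect_true(all(in_domain(X, box)))
  expect_true(in_domain(box$min, box))
  expect_true(in_domain(box$max, box))
  one <- build_domain(X[1, , drop = FALSE])
  expect_equal(one$min, one$max)
  expect_true(in_domain(X[1, ], one))
  expect_error(build_domain(X[0, , drop = FALSE]), class = "lanbind_domain_error")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(build_domain(Xb), class = "lanbind_domain_error")
})

test_that("in_domain agrees with a per-coordinate loop oracle on 1000 vectors", {
  set.seed(32)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  box <- build_domain(X)
  V <- matrix(rnorm(1000 * 6, sd = 1.5), 1000, 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  fast <- in_domain(V, box)
  oracle <- logical(1000)
  for (i in 1:1000) {
    ok <- TRUE
    for (j in 1:6) {
      if (V[i, j] < box$min[j] || V[i, j] > box$max[j]) { ok <- FALSE; break }
    }
    oracle[i] <- ok
  }
  expect_identical(unname(fast), oracle)
  v <- X[3, ]; v[2] <- box$max[2] + 1e-9
  expect_false(in_domain(v, box))
  expect_error(in_domain(v[1:3], box), class = "lanbind_feature_layout_error")
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_domain(box, path)
  box2 <- read_domain(path)
  expect_identical(unname(in_domain(V, box2)), oracle)
})

screen_fixture <- function() {
  lig <- generate_ligands(12, seed = 77)
  parsed <- read_smiles(lig$smiles, lig$id)
  records <- data.frame(
    ligand_id = rep(names(parsed$mols), 2),
    cation_symbol = "Eu", cation_charge = 3L, medium = "NaClO4",
    temperature_K = 298, ionic_strength_M = 0.1,
    logK1 = rnorm(2 * length(parsed$mols), 5, 1),
    row = seq_len(2 * length(parsed$mols)), stringsAsFactors = FALSE)
  fz <- featurize_records(records, parsed$mols)
  model <- train_model(model_spec("knn", list(n_neighbours = 3L)), fz$X, fz$y,
                       seed = 1)
  box <- build_domain(fz$X[, default_descriptor_names(), drop = FALSE])
  list(mols = parsed$mols, model = model, box = box, smiles = lig$smiles)
}

write_sdf_file <- function(mols, path, extra_smiles = NULL, gz = FALSE) {
  lines <- unlist(lapply(mols, function(m) c(m$lines, "$$$$")))
  if (!is.null(extra_smiles)) {
    extra <- read_smiles(extra_smiles, paste0("extra_", seq_along(extra_smiles)))
    lines <- c(lines, unlist(lapply(extra$mols, function(m) c(m$lines, "$$$$"))))
  }
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

test_that("screening filters duplicates, charged molecules and out-of-domain", {
  fx <- screen_fixture()
  # library: the 12 training ligands + 2 duplicates + 1 cation + 1 exotic
  dup <- read_smiles(fx$smiles[1:2], c("dup_a", "dup_b"))$mols
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_file(c(fx$mols, dup), path,
                 extra_smiles = c("C[N+](C)(C)C", "FC(F)(F)C(F)(F)C(F)(F)F"))
  res <- screen_library(path, fx$model, fx$box, cations = c("Eu:3", "Gd:3"),
                        chunk_size = 5L)
  cnt <- res$counters
  expect_equal(unname(cnt["read"]), 16L)
  expect_equal(unname(cnt["duplicate"]), 2L)
  expect_equal(unname(cnt["charged"]), 1L)
  # counters conserve the record count
  expect_equal(unname(cnt["read"]),
               unname(cnt["predicted"] + cnt["duplicate"] + cnt["charged"] +
                        cnt["featurization_failed"] + cnt["out_of_domain"]))
  # training ligands screened against their own box: never out-of-domain
  expect_equal(unname(cnt["predicted"]), 12L + unname(cnt["out_of_domain"]) - 1L)
  # perfluorocarbon lies outside the training box
  expect_gte(unname(cnt["out_of_domain"]), 1L)
  # two cations requested per predicted molecule
  expect_equal(nrow(res$predictions), 2L * unname(cnt["predicted"]))
  expect_true(all(is.finite(res$predictions$logK1_predicted)))
})

test_that("screening the training ligands alone yields zero rejections", {
  fx <- screen_fixture()
  path <- withr::local_tempfile(fileext = ".sdf.gz")
  write_sdf_file(fx$mols, path, gz = TRUE)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- screen_library(path, fx$model, fx$box, cations = "Eu:3", out = out,
                        chunk_size = 4L)
  expect_equal(unname(res$counters["out_of_domain"]), 0L)
  expect_equal(unname(res$counters["predicted"]), length(fx$mols))
  tsv <- read.delim(out)
  expect_equal(nrow(tsv), length(fx$mols))
})

test_that("standard screening conditions are 298 K, 0.1 M, perchlorate", {
  expect_equal(lanbind:::STANDARD_CONDITIONS,
               list(temperature_K = 298, ionic_strength_M = 0.1,
                    medium = "NaClO4"))
})
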