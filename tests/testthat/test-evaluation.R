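test_that("PCA handles degenerate and hand-solvable fixtures", {
  # two identical columns, two samples: one direction carries everything
  ds <- as_spectra(matrix(c(1, 2, 1, 2), 2, 2), c(1000, 1010),
                   origin = c("A", "B"), variety = c("a", "b"))
  p <- run_pca(ds, 1)
  expect_equal(p$explained_pct[1], 100, tolerance = 1e-8)
  # 3 x 2 fixture: eigenvalues from the 2x2 covariance characteristic
  # polynomial
  m <- matrix(c(1, 2, 3, 1, 1, 4), 3, 2)
  ds2 <- as_spectra(m, c(1000, 1010), origin = rep("A", 3),
                    variety = rep("a", 3))
  p2 <- run_pca(ds2, 2)
  cv <- cov(m)
  tr <- sum(diag(cv)); dt <- det(cv)
  lam <- sort(c((tr + sqrt(tr^2 - 4 * dt)) / 2,
                (tr - sqrt(tr^2 - 4 * dt)) / 2), decreasing = TRUE)
  sv2 <- p2$explained_pct_all / 100 * sum(lam) # same normalisation
  expect_equal(sv2, lam / sum(lam) * sum(lam), tolerance = 1e-8)
  expect_error(run_pca(as_spectra(matrix(1, 3, 2), c(1, 2), rep("A", 3),
                                  rep("a", 3)), 1),
               "zero variance")
})

test_that("PCA explains 100% in total and reconstructs the data", {
  spec <- quick_spec(seed = 4, axis_step = 25)
  ds <- generate_spectra(spec)
  n_pc <- min(nrow(ds) - 1, length(wavenumbers(ds)))
  p <- run_pca(ds, n_pc)
  expect_equal(sum(p$explained_pct_all), 100, tolerance = 1e-6)
  expect_true(all(diff(p$explained_pct_all) <= 1e-8))
  # orthonormal loadings
  g <- crossprod(p$loadings)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8)
  # full reconstruction
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2, p$center, `+`)
  expect_equal(unname(rec), unname(spectra_matrix(ds)), tolerance = 1e-8)
  expect_s3_class(autoplot(p), "ggplot")
})

test_that("accuracy reporting follows the 2-decimal percent convention", {
  cm <- diag(c(13, 17, 14, 20)) # 64 of 66 correct
  cm[1, 2] <- 1; cm[3, 4] <- 1
  a <- accuracy(cm)
  expect_equal(a$overall, 96.97)
  cm2 <- diag(c(10, 16, 14, 18)); cm2[2, 1] <- 4; cm2[1, 3] <- 2
  cm2[4, 2] <- 2
  expect_equal(sum(cm2), 66); expect_equal(sum(diag(cm2)), 58)
  expect_equal(accuracy(cm2)$overall, 87.88)
  expect_equal(accuracy(matrix(c(0, 3, 2, 0), 2, 2))$overall, 0)
  # invariants: overall from trace, per-class from row sums
  expect_equal(a$overall, round(100 * sum(diag(cm)) / sum(cm), 2))
  expect_equal(unname(a$per_class),
               round(100 * diag(cm) / rowSums(cm), 2))
  expect_error(accuracy(matrix(numeric(0), 0, 0)), "empty")
})

test_that("run_task wires tasks, classes and refusals correctly", {
  spec <- quick_spec(seed = 5, axis_step = 16)
  ds <- denoise_spectra(generate_spectra(spec), wavelet_config())
  part <- stratified_split(ds, seed = 5)
  r1 <- run_task(ds, "origins", "full", "PLSDA", partition = part)
  expect_equal(nrow(r1$confusion), 4)
  r2 <- run_task(ds, "all_varieties", "full", "PLSDA", partition = part)
  expect_equal(nrow(r2$confusion), 10)
  # default half-up rounding of 2/3 gives 127 train / 65 test on this design
  expect_equal(sum(r2$confusion), 65)
  expect_error(run_task(ds, "origins", "full", "BPNN", partition = part),
               "not supported")
  expect_error(run_task(ds, "varieties_within", "full", "PLSDA",
                        partition = part),
               "`origin` required")
  r3 <- run_task(ds, "varieties_within", "full", "PLSDA", origin = "Yunnan",
                 partition = part)
  expect_equal(rownames(r3$confusion),
               sort(unique(ds$variety[ds$origin == "Yunnan"])))
  # overall accuracy is granular in steps of 100 / n_test
  expect_equal(r2$overall_acc,
               round(100 * sum(diag(r2$confusion)) / sum(r2$confusion), 2))
})

test_that("wavelength selection is fitted on the training rows only", {
  spec <- quick_spec(seed = 6, axis_step = 16)
  ds <- denoise_spectra(generate_spectra(spec), wavelet_config())
  part <- stratified_split(ds, seed = 6)
  rep <- run_task(ds, "origins", "uve_spa", "PLSDA", partition = part,
                  seed = 3,
                  selection_args = list(n_artificial = 100))
  train <- partition_rows(ds, part, "train")
  clean <- uve_spa_select(spectra_matrix(train), one_hot(train$origin),
                          pls_factor = min(12, nrow(train) - 2),
                          n_artificial = 100, seed = 3)
  leaky <- uve_spa_select(spectra_matrix(ds), one_hot(ds$origin),
                          pls_factor = min(12, nrow(ds) - 2),
                          n_artificial = 100, seed = 3)
  expect_identical(rep$selected_index, clean$selected_index)
  expect_false(identical(clean$selected_index, leaky$selected_index))
})

test_that("report tables order variable inputs and round-trip through CSV", {
  spec <- quick_spec(seed = 7, axis_step = 16)
  ds <- generate_spectra(spec)
  part <- stratified_split(ds, seed = 7)
  reps <- list(
    run_task(ds, "origins", "uve_spa", "PLSDA", partition = part,
             selection_args = list(n_artificial = 50)),
    run_task(ds, "origins", "full", "PLSDA", partition = part))
  tab <- build_report_tables(reps)
  expect_equal(tab$variable_input, c("full", "uve_spa"))
  expect_true(all(c("Yunnan", "Xinjiang", "Shaanxi", "Hebei", "overall")
                  %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_table(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$overall, tab$overall)
  expect_equal(nrow(build_report_tables(reps[[1]])), 1)
  md <- withr::local_tempfile(fileext = ".md")
  write_report_table(tab, md)
  expect_match(readLines(md)[1], "overall")
})
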