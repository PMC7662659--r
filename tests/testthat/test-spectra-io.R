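test_that("wide CSV round trip preserves absorbance at full precision", {
  ds <- tiny_spectra()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_identical(dim(back), dim(ds))
  expect_equal(spectra_matrix(back), spectra_matrix(ds), tolerance = 0)
  expect_identical(back$origin, ds$origin)
})

test_that("dataset validation rejects malformed inputs", {
  ds <- tiny_spectra()
  # duplicate sample id
  bad <- ds; bad$sample_id[2] <- bad$sample_id[1]
  expect_error(validate_spectra(bad), "duplicate sample_id")
  # variety under two origins
  bad <- ds; bad$origin[4] <- "A"
  expect_error(validate_spectra(bad), "nesting violated")
  # non-numeric absorbance cell reported with location
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  txt <- readLines(path)
  txt[3] <- sub("0.3", "oops", txt[3], fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_spectra(path), "non-numeric absorbance")
  # non-monotone axis
  m <- spectra_matrix(ds)
  expect_error(
    as_spectra(m, c(1000, 1020, 1010, 1030, 1040),
               ds$origin, ds$variety, ds$sample_id),
    "monotonic")
})

test_that("descending axes are stored ascending with columns reversed", {
  m <- matrix(1:6, 2, 3)
  ds <- as_spectra(m, c(900, 850, 800), origin = c("A", "A"),
                   variety = c("a", "a"))
  expect_equal(wavenumbers(ds), c(800, 850, 900))
  expect_equal(unname(spectra_matrix(ds)), m[, 3:1])
})

test_that("trim_range keeps the closed interval and is idempotent", {
  n <- 3601
  ds <- as_spectra(matrix(rnorm(2 * n), 2), seq(400, 4000, by = 1),
                   origin = c("A", "A"), variety = c("a", "a"))
  tr <- trim_range(ds, 700, 3450)
  expect_equal(length(wavenumbers(tr)), 2751)
  expect_identical(trim_range(tr, 700, 3450), tr)
  # trim to the full range is the identity
  expect_identical(trim_range(ds, 400, 4000), ds)
  # boundary inclusion
  ds2 <- as_spectra(matrix(1:4, 1), c(699.8, 700, 3450, 3450.2),
                    origin = "A", variety = "a")
  expect_equal(wavenumbers(trim_range(ds2, 700, 3450)), c(700, 3450))
  expect_error(trim_range(ds2, 6000, 5000), "`lo` must be smaller")
  expect_error(trim_range(ds2, 800, 900), "no variables in range")
})

test_that("stratified split honours per-variety counts and the 2/3 rule", {
  d <- walnut_design()
  expect_equal(sum(d$n), 192L)
  spec <- quick_spec(seed = 2)
  ds <- generate_spectra(spec)
  part <- stratified_split(ds, seed = 7,
                           n_train = stats::setNames(d$n_train, d$variety))
  counts <- dplyr::count(part, variety, role) |>
    tidyr::pivot_wider(names_from = "role", values_from = "n")
  counts <- counts[match(d$variety, counts$variety), ]
  expect_equal(counts$train, d$n_train)
  expect_equal(counts$train + counts$test, d$n)
  # default rounding: half-up of 2/3 n
  part2 <- stratified_split(ds, seed = 7)
  c2 <- table(part2$variety[part2$role == "train"])
  expect_equal(unname(c(c2[d$variety])), floor(2 / 3 * d$n + 0.5))
  expect_error(stratified_split(ds, frac_train = 1.2), "between 0 and 1")
})

test_that("splits are reproducible by seed and differ across seeds", {
  ds <- generate_spectra(quick_spec(seed = 3))
  p1 <- stratified_split(ds, seed = 10)
  p2 <- stratified_split(ds, seed = 10)
  expect_identical(p1$role, p2$role)
  others <- vapply(11:15, function(s) {
    identical(stratified_split(ds, seed = s)$role, p1$role)
  }, logical(1))
  # for a 16-sample variety alone there are C(16,11) admissible draws;
  # five independent seeds all colliding is essentially impossible
  expect_false(all(others))
})

test_that("partition JSON round trip preserves membership and seed", {
  ds <- tiny_spectra()
  part <- stratified_split(ds, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(attr(back, "seed"), 4L)
  expect_setequal(back$sample_id[back$role == "train"],
                  part$sample_id[part$role == "train"])
})

test_that("JCAMP-DX spectra are read and assembled via a manifest", {
  dir <- withr::local_tempdir()
  make_jcamp <- function(path, ys) {
    writeLines(c(
      "##TITLE=synthetic spectrum", "##JCAMP-DX=4.24",
      "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
      "##FIRSTX=1000", "##LASTX=1008", "##NPOINTS=5",
      "##XFACTOR=1", "##YFACTOR=0.001",
      "##XYDATA=(X++(Y..Y))",
      paste(c(1000, ys[1:3] * 1000), collapse = " "),
      paste(c(1006, ys[4:5] * 1000), collapse = " "),
      "##END="), path)
  }
  make_jcamp(file.path(dir, "a.jdx"), c(0.1, 0.2, 0.3, 0.4, 0.5))
  make_jcamp(file.path(dir, "b.jdx"), c(0.5, 0.4, 0.3, 0.2, 0.1))
  one <- read_jcamp(file.path(dir, "a.jdx"))
  expect_equal(one$wavenumber, seq(1000, 1008, by = 2))
  expect_equal(one$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5))
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(tibble::tibble(
    file = c("a.jdx", "b.jdx"), sample_id = c("s1", "s2"),
    origin = c("A", "A"), variety = c("a1", "a2")), manifest)
  ds <- read_spectra(manifest, format = "jcamp_dx")
  expect_equal(nrow(ds), 2)
  expect_equal(unname(spectra_matrix(ds)[2, ]), c(0.5, 0.4, 0.3, 0.2, 0.1))
})
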