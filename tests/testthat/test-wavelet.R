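# Reference level-1 db3 coefficients for x = 1..11, computed once with an
# independent reference DWT implementation (symmetric extension) and frozen.
ref_a_1_11 <- c(4.521112033849729, 1.5466694232059983, 2.5701933797908483,
                5.398620504537038, 8.227047629283229, 11.020248462143709,
                14.099105261003395, 15.481912378109303)
ref_absd_1_11 <- c(0.19112014953915538, 0.19112014953915507, 0, 0, 0,
                   0.33267055295008341, 0.29744426106437294,
                   0.035226291885709249)

# Independent single-level DWT oracle: explicit per-coefficient convolution
# loops over the symmetrically extended signal (no shared code with the
# package's strided implementation).
oracle_dwt <- function(x, lo, hi) {
  n <- length(x); f <- length(lo)
  xe <- function(i) { # 0-based virtual index with half-sample symmetry
    while (i < 0 || i >= n) {
      if (i < 0) i <- -i - 1
      if (i >= n) i <- 2 * n - i - 1
    }
    x[i + 1]
  }
  lc <- floor((n + f - 1) / 2)
  a <- d <- numeric(lc)
  for (k in seq_len(lc)) {
    for (j in seq_len(f)) {
      a[k] <- a[k] + lo[j] * xe(2 * (k - 1) + 1 - (j - 1))
      d[k] <- d[k] + hi[j] * xe(2 * (k - 1) + 1 - (j - 1))
    }
  }
  list(a = a, d = d)
}

test_that("db3 analysis matches the reference and the convolution oracle", {
  filt <- mirwalnut:::db_filters("db3")
  s <- mirwalnut:::dwt_step(1:11, filt)
  expect_equal(s$a, ref_a_1_11, tolerance = 1e-12)
  expect_equal(abs(s$d), ref_absd_1_11, tolerance = 1e-12)
  for (n in c(17, 32, 101)) {
    set.seed(n)
    x <- rnorm(n)
    o <- oracle_dwt(x, filt$dec_lo, filt$dec_hi)
    s <- mirwalnut:::dwt_step(x, filt)
    expect_equal(s$a, o$a, tolerance = 1e-12)
    expect_equal(s$d, o$d, tolerance = 1e-12)
  }
})

test_that("multilevel transform reconstructs perfectly at zero threshold", {
  cfg0 <- wavelet_config(threshold = 0)
  for (n in c(128, 311, 2751)) {
    set.seed(n)
    x <- cumsum(rnorm(n))
    rel <- max(abs(denoise_spectrum(x, cfg0) - x)) / max(abs(x))
    expect_lt(rel, 1e-10)
  }
  # deeper than admissible -> error naming the maximum level
  expect_error(wavedec(rnorm(40), "db3", 4), "max admissible 3")
})

test_that("constant spectra are invariant under any threshold", {
  x <- rep(2.5, 300)
  for (rule in c("universal_soft", "universal_hard")) {
    y <- denoise_spectrum(x, wavelet_config(threshold_rule = rule))
    expect_equal(y, x, tolerance = 1e-12)
  }
})

test_that("shrinkage never increases coefficient energy and is deterministic", {
  set.seed(8)
  x <- sin(seq_len(512) / 9) + rnorm(512, sd = 0.05)
  dec <- wavedec(x, "db3", 4)
  y1 <- denoise_spectrum(x)
  y2 <- denoise_spectrum(x)
  expect_identical(y1, y2)
  dec_thr <- wavedec(y1, "db3", 4)
  # thresholding shrinks detail magnitudes; compare total detail energy of
  # the raw decomposition against soft-thresholded coefficients directly
  sigma <- median(abs(dec$d[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  shrunk <- lapply(dec$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  e_before <- sum(unlist(dec$d)^2) + sum(dec$a^2)
  e_after <- sum(unlist(shrunk)^2) + sum(dec$a^2)
  expect_lte(e_after, e_before)
})

test_that("denoising a noisy sine at sigma 0.02 moves it toward the truth", {
  n <- 2048
  clean <- sin(2 * pi * seq_len(n) / 40)
  set.seed(123)
  noisy <- clean + rnorm(n, sd = 0.02)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  # a slow sine concentrates energy in the coarse detail bands, where the
  # constant bias of soft shrinkage is costly; hard thresholding removes
  # the noise without touching the large coefficients
  den <- denoise_spectrum(noisy,
                          wavelet_config(threshold_rule = "universal_hard"))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
})

test_that("dataset denoising is row-wise and reduces deviation from templates", {
  spec <- quick_spec(seed = 6, axis_step = 4, noise_sd = 0.02)
  ds <- generate_spectra(spec)
  cfg <- wavelet_config()
  dn <- denoise_spectra(ds, cfg)
  expect_identical(dn[c("sample_id", "origin", "variety")],
                   ds[c("sample_id", "origin", "variety")])
  # single-row consistency
  one <- ds[1, ]
  expect_equal(unname(spectra_matrix(denoise_spectra(one, cfg))[1, ]),
               denoise_spectrum(spectra_matrix(one)[1, ], cfg))
  # identical rows stay identical
  dup <- ds[c(1, 1), ]; dup$sample_id <- c("a", "b")
  mm <- spectra_matrix(denoise_spectra(dup, cfg))
  expect_equal(mm[1, ], mm[2, ])
  # closer to the noise-free templates than the raw draw
  tpl <- synthetic_templates(spec)[ds$variety, ]
  mad_raw <- mean(abs(spectra_matrix(ds) - tpl))
  mad_den <- mean(abs(spectra_matrix(dn) - tpl))
  expect_lt(mad_den, mad_raw)
})

test_that("class mean spectra equal a per-column loop oracle", {
  set.seed(21)
  m <- matrix(rnorm(20), 5, 4)
  ds <- as_spectra(m, c(1000, 1010, 1020, 1030),
                   origin = c("A", "A", "B", "B", "B"),
                   variety = c("a", "a", "b", "b", "b"))
  means <- class_mean_spectra(ds, by = "origin")
  oracle <- rbind(colMeans(m[1:2, ]), colMeans(m[3:5, ]))
  for (j in 1:4) {
    expect_equal(means[[j + 1]], oracle[, j])
  }
  # two identical samples: the mean is either of them
  ds2 <- ds[c(1, 1), ]; ds2$sample_id <- c("x", "y")
  expect_equal(unname(unlist(class_mean_spectra(ds2, "origin")[1, -1])),
               unname(m[1, ]))
})
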