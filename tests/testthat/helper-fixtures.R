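# Shared fixtures, all built in code.

# Minimal nested design: 4 varieties in 2 origins.
tiny_design <- function(n = 6L) {
  tibble::tibble(
    origin = rep(c("North", "South"), each = 2),
    variety = c("n1", "n2", "s1", "s2"),
    n = rep(as.integer(n), 4))
}

# A small, fast synthetic spec on a coarse axis.
quick_spec <- function(seed = 1L, axis_step = 10, ...) {
  synthetic_spec(axis_step = axis_step, seed = seed, ...)
}

# Easy, well-separated 4-class (one variety per origin) problem:
# 18 samples per class (12 train / 6 test at 2/3), high signal-to-noise.
easy_spec <- function(seed = 42L, snr = 20, axis_step = 8) {
  synthetic_spec(
    axis_step = axis_step,
    design = tibble::tibble(
      origin = c("A", "B", "C", "D"), variety = paste0("v", 1:4),
      n = rep(18L, 4), n_train = rep(12L, 4)),
    origin_effects = tibble::tibble(
      origin = c("A", "B", "C", "D"),
      amp_1740 = c(1.5, 0.6, 1.0, 1.2),
      amp_1160 = c(1.3, 1.0, 0.5, 1.5),
      amp_2925 = c(1.2, 1.4, 0.8, 1.0),
      shift_1740 = c(6, 0, 0, -6),
      shift_1160 = c(0, -6, 0, 6),
      shift_2925 = c(0, 0, 8, 0)),
    variety_effects = tibble::tibble(
      variety = paste0("v", 1:4),
      amp_1450 = c(1.15, 0.85, 1.1, 0.9),
      amp_1100 = c(0.9, 1.1, 0.85, 1.15)),
    snr = snr, seed = seed)
}

# Tiny handmade wide dataset: 4 samples, 5 wavenumbers, 2 origins.
tiny_spectra <- function() {
  as_spectra(
    matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,
             0.2, 0.3, 0.4, 0.5, 0.6,
             1.1, 1.2, 1.3, 1.4, 1.5,
             1.2, 1.3, 1.4, 1.5, 1.6), 4, 5, byrow = TRUE),
    wavenumbers = c(1000, 1010, 1020, 1030, 1040),
    origin = c("A", "A", "B", "B"),
    variety = c("a1", "a1", "b1", "b1"),
    sample_id = paste0("S", 1:4))
}

one_hot <- mirwalnut:::one_hot
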