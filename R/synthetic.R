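# Synthetic FT-MIR dataset generator.
#
# Emulates the study design the package targets: 10 walnut varieties nested
# in 4 geographic origins, 16-20 samples per variety, absorbance spectra on
# 700-3450 cm^-1 built from Gaussian/Lorentzian absorption bands at standard
# mid-IR assignments (O-H stretch ~3350, C-H stretch triplet 2800-3000, C=O
# 1740, C=C/N-H ~1630, aromatic C-C ~1450, C-O cluster 1000-1275). Origins
# perturb the amplitudes/centers of designated "origin bands"; varieties add
# smaller nested perturbations on separate "variety bands". Ground truth --
# which axis points are class-informative -- is exact by construction.

#' Study design: varieties nested in origins
#'
#' The default sampling design: 10 varieties in 4 origins, 192 samples
#' total, with the per-variety train/test partition of the emulated study
#' (train counts 13/13/13/13/13/13/13/10/12/13).
#'
#' @return tibble with columns `origin`, `variety`, `n`, `n_train`.
#' @export
walnut_design <- function() {
  tibble(
    origin = rep(c("Yunnan", "Xinjiang", "Shaanxi", "Hebei"),
                 c(2, 3, 2, 3)),
    variety = c("Yangbi Dapao", "Yangbi Caoguo",
                "Hetian 185", "Xinfeng", "Xinxin 2",
                "Liao 4", "Xiangling",
                "Qingxiang", "Liao 1", "Liao 8"),
    n = c(20L, 19L, 19L, 20L, 20L, 20L, 20L, 16L, 18L, 20L),
    n_train = c(13L, 13L, 13L, 13L, 13L, 13L, 13L, 10L, 12L, 13L))
}

#' Absorption band specification
#'
#' @param center band center in cm^-1.
#' @param width Gaussian sigma (or Lorentzian gamma) in cm^-1, > 0.
#' @param amplitude peak absorbance, >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return one-row tibble.
#' @export
band <- function(center, width, amplitude, shape = "gaussian") {
  if (width <= 0) abort("band `width` must be > 0")
  if (amplitude < 0) abort("band `amplitude` must be >= 0")
  if (!shape %in% c("gaussian", "lorentzian")) {
    abort("`shape` must be gaussian or lorentzian")
  }
  tibble(center = center, width = width, amplitude = amplitude,
         shape = shape)
}

default_bands <- function() {
  dplyr::bind_rows(
    band(3350, 120, 0.55), # O-H stretch, broad
    band(2855, 18, 0.45),  # C-H stretch triplet
    band(2925, 20, 0.60),
    band(2960, 15, 0.40),
    band(1740, 12, 0.70),  # C=O stretch, sharp
    band(1630, 35, 0.35),  # C=C / N-H
    band(1450, 28, 0.30),  # aromatic C-C
    band(1240, 25, 0.30),  # C-O cluster
    band(1160, 22, 0.45),
    band(1100, 25, 0.35),
    band(1050, 30, 0.40))
}

# Per-origin multipliers and center shifts on the designated origin bands
# (1740, 1160, 2925 cm^-1).
default_origin_effects <- function() {
  tibble(
    origin = c("Yunnan", "Xinjiang", "Shaanxi", "Hebei"),
    amp_1740 = c(1.30, 0.80, 1.00, 1.15),
    amp_1160 = c(1.15, 1.00, 0.70, 1.30),
    amp_2925 = c(1.10, 1.20, 0.85, 1.00),
    shift_1740 = c(4, 0, 0, -4),
    shift_1160 = c(0, -5, 0, 0),
    shift_2925 = c(0, 0, 6, 0))
}

# Nested per-variety multipliers on the variety bands (1450, 1100 cm^-1),
# roughly a third of the origin-effect spread.
default_variety_effects <- function() {
  d <- walnut_design()
  tibble(
    variety = d$variety,
    amp_1450 = c(1.12, 0.88, 1.10, 1.00, 0.90, 1.10, 0.90,
                 1.12, 1.00, 0.88),
    amp_1100 = c(0.92, 1.10, 0.90, 1.10, 1.00, 0.90, 1.10,
                 0.90, 1.08, 1.12))
}

#' Synthetic dataset specification
#'
#' The defaults define the package's reference conditions: the
#' [walnut_design()] sample sizes, a 1 cm^-1 axis over 700-3450 cm^-1 (2751
#' variables), the default band set with origin effects on 1740/1160/2925
#' cm^-1 and nested variety effects on 1450/1100 cm^-1, linear baseline
#' drift, and i.i.d. Gaussian noise. When `noise_sd` is `NULL` it is
#' calibrated so the class-effect signal-to-noise ratio -- RMS deviation of
#' the class templates from the grand template over the informative support,
#' divided by the noise sd -- equals `snr` (default 10).
#'
#' @param axis_lo,axis_hi,axis_step wavenumber axis in cm^-1.
#' @param design sampling design tibble (`origin`, `variety`, `n`, optional
#'   `n_train`).
#' @param shared_bands band tibble (see [band()]).
#' @param origin_effects,variety_effects effect tables; columns `amp_<c>` /
#'   `shift_<c>` act on the band centered at `<c>`.
#' @param noise_sd absorbance noise sd, or `NULL` to calibrate from `snr`.
#' @param snr target class-effect signal-to-noise ratio used when
#'   `noise_sd` is `NULL`.
#' @param baseline_offset,baseline_slope half-ranges of the uniform baseline
#'   offset (absorbance) and slope (absorbance per cm^-1) draws.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(axis_lo = 700, axis_hi = 3450, axis_step = 1,
                           design = walnut_design(),
                           shared_bands = default_bands(),
                           origin_effects = default_origin_effects(),
                           variety_effects = default_variety_effects(),
                           noise_sd = NULL, snr = 10,
                           baseline_offset = 0.02, baseline_slope = 1e-5,
                           seed = 1L) {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  axis <- synth_axis(spec)
  if (length(axis) < 50) {
    abort("axis step too coarse: fewer than 50 points")
  }
  if (anyDuplicated(design$variety)) abort("duplicate varieties in design")
  if (is.null(noise_sd)) {
    spec$noise_sd <- class_effect_rms(spec) / snr
  }
  spec
}

synth_axis <- function(spec) {
  seq(spec$axis_lo, spec$axis_hi, by = spec$axis_step)
}

band_profile <- function(axis, center, width, amplitude, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-(axis - center)^2 / (2 * width^2))
  } else {
    amplitude / (1 + ((axis - center) / width)^2)
  }
}

# Noise-free template spectrum of one variety.
variety_template <- function(spec, variety) {
  axis <- synth_axis(spec)
  d <- spec$design
  origin <- d$origin[match(variety, d$variety)]
  oe <- spec$origin_effects[spec$origin_effects$origin == origin, ,
                            drop = FALSE]
  ve <- spec$variety_effects[spec$variety_effects$variety == variety, ,
                             drop = FALSE]
  y <- numeric(length(axis))
  for (i in seq_len(nrow(spec$shared_bands))) {
    b <- spec$shared_bands[i, ]
    amp <- b$amplitude; ctr <- b$center
    for (eff in list(oe, ve)) {
      if (!nrow(eff)) next
      ac <- paste0("amp_", format_wn(b$center))
      sc <- paste0("shift_", format_wn(b$center))
      if (ac %in% names(eff)) amp <- amp * eff[[ac]]
      if (sc %in% names(eff)) ctr <- ctr + eff[[sc]]
    }
    y <- y + band_profile(axis, ctr, b$width, amp, b$shape)
  }
  y
}

#' Noise-free class templates of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return matrix, one row per variety (rownames = varieties).
#' @export
synthetic_templates <- function(spec) {
  out <- t(vapply(spec$design$variety, function(v) variety_template(spec, v),
                  numeric(length(synth_axis(spec)))))
  rownames(out) <- spec$design$variety
  out
}

# RMS deviation of the variety templates from the grand template over the
# informative support (used to calibrate the noise level).
class_effect_rms <- function(spec) {
  tpl <- synthetic_templates(spec)
  gt <- ground_truth(spec)
  dev <- sweep(tpl[, gt, drop = FALSE], 2,
               colMeans(tpl[, gt, drop = FALSE]))
  sqrt(mean(dev^2))
}

#' Generate a synthetic spectral dataset
#'
#' Each sample is its variety template plus a linear baseline draw plus
#' i.i.d. Gaussian noise; deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a spectral dataset tibble (see [as_spectra()]) with the design's
#'   sample counts.
#' @export
generate_spectra <- function(spec) {
  axis <- synth_axis(spec)
  tpl <- synthetic_templates(spec)
  d <- spec$design
  n_tot <- sum(d$n)
  withr::local_seed(as.integer(spec$seed))
  rows <- matrix(0, n_tot, length(axis))
  origin <- character(n_tot); variety <- character(n_tot)
  r <- 0L
  for (i in seq_len(nrow(d))) {
    for (s in seq_len(d$n[i])) {
      r <- r + 1L
      offs <- runif(1, -spec$baseline_offset, spec$baseline_offset)
      slope <- runif(1, -spec$baseline_slope, spec$baseline_slope)
      rows[r, ] <- tpl[i, ] + offs + slope * (axis - axis[1]) +
        rnorm(length(axis), sd = spec$noise_sd)
      origin[r] <- d$origin[i]; variety[r] <- d$variety[i]
    }
  }
  as_spectra(rows, axis, origin = origin, variety = variety)
}

#' Ground-truth informative variables of a synthetic spec
#'
#' Indices of axis points within +/- 3 widths of any class-affected band
#' (bands named in the origin- or variety-effect tables, including their
#' shifted variants).
#'
#' @param spec a [synthetic_spec()].
#' @param effects which effect tables define "class-affected": `"all"`
#'   (default), `"origin"` or `"variety"`.
#' @return sorted integer vector of axis indices (empty if no class
#'   effects).
#' @export
ground_truth <- function(spec, effects = c("all", "origin", "variety")) {
  sets <- ground_truth_bands(spec, effects)
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Ground-truth support split by affected band
#'
#' @inheritParams ground_truth
#' @return named list of axis-index vectors, one per class-affected band.
#' @export
ground_truth_bands <- function(spec, effects = c("all", "origin",
                                                 "variety")) {
  effects <- match.arg(effects)
  axis <- synth_axis(spec)
  eff_cols <- function(df) {
    grep("^(amp|shift)_", names(df), value = TRUE)
  }
  affected <- character(0)
  shifts <- list()
  tables <- switch(effects,
                   all = list(spec$origin_effects, spec$variety_effects),
                   origin = list(spec$origin_effects),
                   variety = list(spec$variety_effects))
  for (df in tables) {
    for (cl in eff_cols(df)) {
      ctr <- sub("^(amp|shift)_", "", cl)
      varies <- if (grepl("^amp_", cl)) {
        length(unique(df[[cl]])) > 1
      } else {
        any(df[[cl]] != 0)
      }
      if (varies) {
        affected <- union(affected, ctr)
        if (grepl("^shift_", cl)) {
          shifts[[ctr]] <- range(c(0, df[[cl]]))
        }
      }
    }
  }
  out <- list()
  for (ctr in affected) {
    b <- spec$shared_bands[format_wn(spec$shared_bands$center) == ctr, ]
    if (!nrow(b)) next
    sh <- shifts[[ctr]] %||% c(0, 0)
    lo <- b$center + sh[1] - 3 * b$width
    hi <- b$center + sh[2] + 3 * b$width
    out[[ctr]] <- which(axis >= lo & axis <= hi)
  }
  out
}

#' Band-level recovery of a selection against ground truth
#'
#' Fraction of class-affected bands whose +/- 3 width support contains at
#' least one selected variable.
#'
#' @param selected_index integer axis indices chosen by a selection method.
#' @param spec the [synthetic_spec()] that generated the data.
#' @inheritParams ground_truth
#' @return fraction in [0, 1] (NA if the spec has no class effects).
#' @export
band_recovery <- function(selected_index, spec,
                          effects = c("all", "origin", "variety")) {
  sets <- ground_truth_bands(spec, effects)
  if (!length(sets)) return(NA_real_)
  mean(purrr::map_lgl(sets, ~ any(selected_index %in% .x)))
}
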