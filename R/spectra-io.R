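# Spectral dataset model and I/O.
#
# A spectral dataset is an ordinary tibble in "wide" form: the metadata
# columns `sample_id`, `origin`, `variety` first, then one numeric column per
# wavenumber, named by its value in cm^-1 (e.g. `"700"`, `"701.5"`). All
# pipeline functions take such a tibble as their first argument, so datasets
# chain with the pipe; `spectra_matrix()` and `wavenumbers()` give the
# matrix/axis view used internally.

.meta_cols <- c("sample_id", "origin", "variety")

#' Assemble a spectral dataset tibble
#'
#' Builds the package's canonical wide tibble from an absorbance matrix, a
#' wavenumber axis and per-sample labels, and validates it (unique ids,
#' strictly monotonic axis, varieties nested in origins). A descending axis is
#' stored ascending, with the absorbance columns reversed jointly.
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers numeric vector in cm^-1, strictly monotonic, one per
#'   column of `absorbance`.
#' @param origin,variety character vectors of per-sample class labels; every
#'   variety must occur under exactly one origin.
#' @param sample_id unique sample identifiers; generated if `NULL`.
#' @return a tibble with columns `sample_id`, `origin`, `variety`, then one
#'   numeric column per wavenumber in ascending order.
#' @export
#' @examples
#' as_spectra(matrix(rnorm(6), 2), c(700, 710, 720),
#'            origin = c("A", "A"), variety = c("a1", "a2"))
as_spectra <- function(absorbance, wavenumbers, origin, variety,
                       sample_id = NULL) {
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (length(wavenumbers) != ncol(absorbance)) {
    abort("`wavenumbers` must have one entry per column of `absorbance`.")
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("S%03d", seq_len(n))
  }
  out <- tibble(
    sample_id = as.character(sample_id),
    origin = as.character(origin),
    variety = as.character(variety)
  )
  colnames(absorbance) <- format_wn(wavenumbers)
  out <- dplyr::bind_cols(out, as_tibble(absorbance))
  validate_spectra(out)
}

format_wn <- function(x) {
  format(as.numeric(x), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Extract the absorbance matrix of a spectral dataset
#'
#' @param data a spectral dataset tibble (see [as_spectra()]).
#' @return numeric matrix (rows named by `sample_id`, columns by wavenumber).
#' @export
spectra_matrix <- function(data) {
  cols <- setdiff(names(data), .meta_cols)
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  m
}

#' Extract the wavenumber axis of a spectral dataset
#'
#' @inheritParams spectra_matrix
#' @return numeric vector in cm^-1.
#' @export
wavenumbers <- function(data) {
  as.numeric(setdiff(names(data), .meta_cols))
}

# Rebuild a dataset from its metadata and a (possibly new) matrix.
set_spectra_matrix <- function(data, m, wn = NULL) {
  wn <- wn %||% wavenumbers(data)
  colnames(m) <- format_wn(wn)
  dplyr::bind_cols(data[intersect(.meta_cols, names(data))], as_tibble(m))
}

#' Validate a spectral dataset tibble
#'
#' Checks the dataset invariants: metadata columns present, unique sample ids,
#' all-numeric finite absorbance, a strictly monotonic duplicate-free
#' wavenumber axis, and the nested design (each variety under exactly one
#' origin). A descending axis is reversed to ascending storage order.
#'
#' @inheritParams spectra_matrix
#' @return the validated tibble, axis ascending.
#' @export
validate_spectra <- function(data) {
  data <- as_tibble(data)
  missing <- setdiff(.meta_cols, names(data))
  if (length(missing)) {
    abort(paste0("missing metadata column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  spec_cols <- setdiff(names(data), .meta_cols)
  if (!length(spec_cols)) abort("dataset has no spectral columns")
  for (cl in spec_cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf(
        "non-numeric absorbance in column '%s', row %d", cl,
        if (is.na(bad)) 1L else bad))
    }
  }
  wn <- as.numeric(spec_cols)
  if (anyNA(wn)) abort("spectral column names must be numeric wavenumbers")
  d <- diff(wn)
  if (any(d == 0)) abort("duplicate wavenumbers in axis")
  if (!(all(d > 0) || all(d < 0))) {
    abort("wavenumber axis must be strictly monotonic")
  }
  if (all(d < 0)) { # store ascending; reverse columns jointly
    data <- data[c(.meta_cols, rev(spec_cols))]
  }
  nest <- unique(data[c("variety", "origin")])
  bad <- nest$variety[duplicated(nest$variety)]
  if (length(bad)) {
    abort(paste0("nesting violated: variety under multiple origins: ",
                 paste(unique(bad), collapse = ", ")))
  }
  data
}

#' Read a spectral dataset
#'
#' `wide_csv` expects the canonical interchange layout: columns `sample_id`,
#' `origin`, `variety`, then one column per wavenumber with the wavenumber as
#' header. `jcamp_dx` expects `path` to be a manifest CSV with columns `file`,
#' `sample_id`, `origin`, `variety`; each file is a single-spectrum JCAMP-DX
#' (XYDATA) record, and all spectra must share one axis.
#'
#' @param path path to the CSV (or JCAMP manifest).
#' @param format `"wide_csv"` (default) or `"jcamp_dx"`.
#' @return a validated spectral dataset tibble.
#' @export
read_spectra <- function(path, format = c("wide_csv", "jcamp_dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "wide_csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = "c", origin = "c", variety = "c",
                             .default = "c"))
    return(validate_spectra(num_spectral_cols(raw)))
  }
  manifest <- readr::read_csv(path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  need <- c("file", .meta_cols)
  if (!all(need %in% names(manifest))) {
    abort(paste0("JCAMP manifest must have columns: ",
                 paste(need, collapse = ", ")))
  }
  specs <- purrr::map(file.path(dirname(path), manifest$file), read_jcamp)
  axis0 <- specs[[1]]$wavenumber
  ok <- purrr::map_lgl(specs, ~ isTRUE(all.equal(.x$wavenumber, axis0)))
  if (!all(ok)) abort("JCAMP spectra in manifest have differing axes")
  m <- do.call(rbind, purrr::map(specs, "absorbance"))
  as_spectra(m, axis0, origin = manifest$origin, variety = manifest$variety,
             sample_id = manifest$sample_id)
}

# Coerce spectral columns read as character to numeric, reporting the first
# offending cell.
num_spectral_cols <- function(raw) {
  for (cl in setdiff(names(raw), .meta_cols)) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v) && !all(is.na(raw[[cl]]))) {
      abort(sprintf("non-numeric absorbance in column '%s', row %d",
                    cl, which(is.na(v))[1]))
    }
    raw[[cl]] <- v
  }
  raw
}

#' Write a spectral dataset as wide CSV
#'
#' @inheritParams spectra_matrix
#' @param path output file path.
#' @return `data`, invisibly.
#' @export
write_spectra <- function(data, path) {
  readr::write_csv(validate_spectra(data), path)
  invisible(data)
}

#' Read a single JCAMP-DX spectrum
#'
#' Minimal reader for tabular `XYDATA=(X++(Y..Y))` records with a linear axis
#' defined by `FIRSTX`, `LASTX` and `NPOINTS`; `XFACTOR`/`YFACTOR` scaling is
#' applied. Compressed (SQZ/DIF/DUP) encodings are not supported.
#'
#' @param path path to a JCAMP-DX file.
#' @return tibble with columns `wavenumber`, `absorbance`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  get_num <- function(key, default = NA_real_) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  firstx <- get_num("FIRSTX"); lastx <- get_num("LASTX")
  npoints <- get_num("NPOINTS")
  xfac <- get_num("XFACTOR", 1); yfac <- get_num("YFACTOR", 1)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) abort("no ##XYDATA record found")
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  ys <- unlist(purrr::map(body, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])
    v[-1] # first number on each line is the abscissa of its first point
  }))
  if (anyNA(c(firstx, lastx, npoints))) {
    abort("JCAMP header must define FIRSTX, LASTX and NPOINTS")
  }
  if (length(ys) != npoints) {
    abort(sprintf("JCAMP NPOINTS=%d but %d ordinates read",
                  npoints, length(ys)))
  }
  tibble(
    wavenumber = xfac * seq(firstx, lastx, length.out = npoints),
    absorbance = yfac * ys
  )
}

#' Trim a spectral dataset to a wavenumber window
#'
#' Keeps exactly the variables with `lo <= wavenumber <= hi` (closed
#' interval, order preserved). The default window 700-3450 cm^-1 discards the
#' noisy ends of a 400-4000 cm^-1 acquisition.
#'
#' @inheritParams spectra_matrix
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return the trimmed dataset tibble.
#' @export
trim_range <- function(data, lo = 700, hi = 3450) {
  if (lo >= hi) abort("`lo` must be smaller than `hi`")
  wn <- wavenumbers(data)
  keep <- wn >= lo & wn <= hi
  if (!any(keep)) abort("no variables in range")
  spec_cols <- setdiff(names(data), .meta_cols)
  data[c(.meta_cols, spec_cols[keep])]
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test partition
#'
#' Splits samples within each variety, drawing the training subset uniformly
#' at random under `seed`. Per-variety training counts come from `n_train`
#' when supplied (e.g. a published study design), otherwise from
#' `rounding`(`frac_train` * n); `"half_up"` rounds .5 upward.
#'
#' @inheritParams spectra_matrix
#' @param frac_train training fraction in (0, 1); default 2/3.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param rounding rounding rule for per-variety training counts.
#' @param n_train optional named integer vector (names = varieties) of exact
#'   per-variety training counts, overriding `frac_train`.
#' @return a partition tibble with columns `sample_id`, `origin`, `variety`,
#'   `role` (`"train"`/`"test"`) and attribute `seed`.
#' @export
stratified_split <- function(data, frac_train = 2 / 3, seed = 1L,
                             rounding = c("half_up", "floor", "ceiling"),
                             n_train = NULL) {
  if (frac_train <= 0 || frac_train >= 1) {
    abort("`frac_train` must be strictly between 0 and 1")
  }
  rounding <- match.arg(rounding)
  rnd <- switch(rounding, half_up = round_half_up,
                floor = floor, ceiling = ceiling)
  meta <- data[intersect(.meta_cols, names(data))]
  counts <- table(meta$variety)
  if (any(counts < 2)) abort("every variety needs at least 2 samples")
  withr::local_seed(as.integer(seed))
  parts <- lapply(split(seq_len(nrow(meta)), meta$variety), function(idx) {
    v <- meta$variety[idx[1]]
    k <- if (!is.null(n_train) && v %in% names(n_train)) {
      as.integer(n_train[[v]])
    } else {
      as.integer(rnd(frac_train * length(idx)))
    }
    k <- max(1L, min(length(idx) - 1L, k))
    idx[sample.int(length(idx), k)]
  })
  train_rows <- sort(unlist(parts, use.names = FALSE))
  out <- dplyr::mutate(
    meta,
    role = ifelse(dplyr::row_number() %in% train_rows, "train", "test"))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Subset a spectral dataset by partition role
#'
#' @inheritParams spectra_matrix
#' @param partition a partition tibble from [stratified_split()].
#' @param role `"train"` or `"test"`.
#' @return the matching rows of `data`.
#' @export
partition_rows <- function(data, partition, role = c("train", "test")) {
  role <- match.arg(role)
  ids <- partition$sample_id[partition$role == role]
  data[data$sample_id %in% ids, , drop = FALSE]
}

#' Write / read a partition as JSON
#'
#' Serialised as `{seed, train: [ids], test: [ids]}`.
#'
#' @param partition a partition tibble from [stratified_split()].
#' @param path JSON file path.
#' @return `write_partition()` returns the partition invisibly;
#'   `read_partition()` returns a tibble with `sample_id` and `role` plus the
#'   `seed` attribute.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(
    list(seed = attr(partition, "seed"),
         train = partition$sample_id[partition$role == "train"],
         test = partition$sample_id[partition$role == "test"]),
    path, auto_unbox = TRUE)
  invisible(partition)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(
    sample_id = c(x$train, x$test),
    role = rep(c("train", "test"), c(length(x$train), length(x$test))))
  attr(out, "seed") <- x$seed
  out
}
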