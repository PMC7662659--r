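# PCA exploration, accuracy scoring and the three classification designs.

#' Principal component analysis of a spectral dataset
#'
#' Column-mean-centered SVD of the absorbance matrix (no autoscaling:
#' absorbance units are homogeneous across the axis). Run it on pre-treated
#' (trimmed + denoised) spectra.
#'
#' @inheritParams spectra_matrix
#' @param n_pc number of components to keep, at most `min(n - 1, p)`.
#' @return an object of class `pca_spectra`: `scores` (n x n_pc), `loadings`
#'   (p x n_pc, orthonormal columns), `explained_pct` (per kept PC),
#'   `explained_pct_all` (all PCs, sums to 100), `center`, plus the sample
#'   metadata for plotting.
#' @export
run_pca <- function(data, n_pc = 3) {
  m <- spectra_matrix(data)
  n <- nrow(m); p <- ncol(m)
  if (n_pc < 1 || n_pc > min(n - 1, p)) {
    abort(sprintf("`n_pc` must be in 1..%d", min(n - 1, p)))
  }
  center <- colMeans(m)
  mc <- sweep(m, 2, center)
  if (max(abs(mc)) < 1e-14) abort("zero variance: constant dataset")
  s <- svd(mc)
  expl <- 100 * s$d^2 / sum(s$d^2)
  scores <- s$u %*% diag(s$d, length(s$d))
  structure(
    list(scores = scores[, seq_len(n_pc), drop = FALSE],
         loadings = s$v[, seq_len(n_pc), drop = FALSE],
         explained_pct = expl[seq_len(n_pc)],
         explained_pct_all = expl,
         center = center,
         meta = data[intersect(.meta_cols, names(data))],
         wavenumbers = wavenumbers(data)),
    class = "pca_spectra")
}

#' @exportS3Method generics::tidy
tidy.pca_spectra <- function(x, ...) {
  sc <- as_tibble(x$scores, .name_repair = ~ paste0("PC", seq_along(.x)))
  dplyr::bind_cols(x$meta, sc)
}

#' @exportS3Method generics::glance
glance.pca_spectra <- function(x, ...) {
  tibble(n_pc = ncol(x$scores),
         explained_pct = list(x$explained_pct),
         cumulative_pct = sum(x$explained_pct))
}

#' Score plot for a spectral PCA
#'
#' @param object a `pca_spectra`.
#' @param pcs which two components to display.
#' @param colour metadata column used for colour (`"origin"` or
#'   `"variety"`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_spectra <- function(object, pcs = c(1, 2), colour = "origin",
                                 ...) {
  df <- tidy(object)
  xn <- paste0("PC", pcs[1]); yn <- paste0("PC", pcs[2])
  lab <- function(i) sprintf("PC%d (%.2f%%)", pcs[i],
                             object$explained_pct[pcs[i]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xn]], y = .data[[yn]],
                                   colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Confusion matrix of predicted versus true labels
#'
#' @param truth true labels (rows of the result).
#' @param estimate predicted labels (columns).
#' @param levels label order; defaults to the sorted union.
#' @return integer count matrix, rows = true classes.
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  levels <- levels %||% sort(union(unique(truth), unique(estimate)))
  table(factor(truth, levels), factor(estimate, levels)) |>
    unclass()
}

#' Per-class and overall accuracy from a confusion matrix
#'
#' Per-class accuracy is the row-wise correct fraction (recall); overall is
#' `100 * trace / total`. Both are reported in percent, rounded to 2
#' decimals as in standard chemometrics report tables.
#'
#' @param confusion square non-negative count matrix, rows = true classes.
#' @return a list with `per_class` (named percent vector) and `overall`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!length(confusion) || sum(confusion) == 0) {
    abort("empty confusion matrix")
  }
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    abort("confusion matrix must hold non-negative counts")
  }
  per <- round(100 * diag(confusion) / pmax(rowSums(confusion), 1), 2)
  list(per_class = per,
       overall = round(100 * sum(diag(confusion)) / sum(confusion), 2))
}

task_labels <- function(data, task, origin = NULL) {
  switch(task,
         origins = data$origin,
         all_varieties = data$variety,
         varieties_within = {
           if (is.null(origin)) abort("`origin` required for varieties_within")
           data$variety
         },
         abort(paste0("unknown task: ", task)))
}

#' Run one classification design cell
#'
#' Executes the pipeline for one (task, variable subset, classifier) cell:
#' optional trim and wavelet denoising, wavelength selection fitted on the
#' training rows only, classifier training on the selected training columns,
#' scoring on the held-out test rows.
#'
#' Tasks: `"origins"` (classify the 4 geographic origins),
#' `"varieties_within"` (varieties of one `origin`; the dataset is first
#' subset to that origin), `"all_varieties"` (all varieties at once).
#' Variable inputs: `"full"`, `"uve_spa"`, `"ga_pls"`. The BPNN classifier
#' combined with the full spectral range is refused (training a
#' back-propagation network on thousands of input variables is not a
#' supported design).
#'
#' @inheritParams spectra_matrix
#' @param task one of `"origins"`, `"varieties_within"`, `"all_varieties"`.
#' @param variable_input `"full"`, `"uve_spa"` or `"ga_pls"`.
#' @param classifier classifier kind (see [fit_classifier()]).
#' @param partition a partition tibble from [stratified_split()]; rebuilt
#'   with `seed` if `NULL`.
#' @param origin origin name, required for `task = "varieties_within"`.
#' @param parameter classifier headline parameter (see [fit_classifier()]).
#' @param trim optional `c(lo, hi)` window applied before modeling.
#' @param wavelet optional [wavelet_config()] applied before modeling.
#' @param selection_args list of extra arguments for [uve_spa_select()] or
#'   [ga_pls_select()] (e.g. `list(config = ga_pls_config(n_runs = 10))`).
#' @param selected_index optional precomputed variable subset (column
#'   indices after trim), e.g. a selection fitted once on the origin task's
#'   training rows and reused across all task designs, as in the reference
#'   workflow. Skips refitting the selection; it must not have seen the
#'   test rows.
#' @param seed integer seed (selection, classifier and fallback partition).
#' @return an object of class `eval_report`: task metadata, `confusion`,
#'   `per_class_acc`, `overall_acc`, `selected_index`, `parameter`.
#' @export
run_task <- function(data, task = c("origins", "varieties_within",
                                    "all_varieties"),
                     variable_input = c("full", "uve_spa", "ga_pls"),
                     classifier = "PLSDA", partition = NULL, origin = NULL,
                     parameter = NULL, trim = NULL, wavelet = NULL,
                     selection_args = list(), selected_index = NULL,
                     seed = 1L) {
  task <- match.arg(task)
  variable_input <- match.arg(variable_input)
  kind <- toupper(classifier)
  if (kind == "BPNN" && variable_input == "full") {
    abort("BPNN with the full spectral range is not supported; select variables first (uve_spa or ga_pls)")
  }
  if (!is.null(trim)) data <- trim_range(data, trim[1], trim[2])
  if (!is.null(wavelet)) data <- denoise_spectra(data, wavelet)
  if (task == "varieties_within") {
    if (is.null(origin)) abort("`origin` required for varieties_within")
    data <- data[data$origin == origin, , drop = FALSE]
    if (length(unique(data$variety)) < 2) {
      abort(paste0("origin ", origin, " holds a single variety"))
    }
  }
  partition <- partition %||% stratified_split(data, seed = seed)
  train <- partition_rows(data, partition, "train")
  test <- partition_rows(data, partition, "test")
  y_train <- task_labels(train, task, origin)
  y_test <- task_labels(test, task, origin)
  x_train <- spectra_matrix(train)
  x_test <- spectra_matrix(test)
  sel <- if (!is.null(selected_index)) {
    list(index = as.integer(selected_index), result = NULL)
  } else {
    select_training_variables(x_train, y_train, variable_input,
                              selection_args, seed)
  }
  model <- fit_classifier(x_train[, sel$index, drop = FALSE], y_train,
                          kind = kind, parameter = parameter, seed = seed)
  pred <- predict(model, x_test[, sel$index, drop = FALSE])
  cm <- confusion_matrix(y_test, pred, levels = sort(unique(
    c(y_train, y_test))))
  acc <- accuracy(cm)
  structure(
    list(task = task, origin = origin, variable_input = variable_input,
         classifier = kind, parameter = model$spec$parameter,
         per_class_acc = acc$per_class, overall_acc = acc$overall,
         confusion = cm, selected_index = sel$index,
         selected_wavenumbers = wavenumbers(data)[sel$index],
         selection = sel$result, n_train = nrow(train), n_test = nrow(test)),
    class = "eval_report")
}

select_training_variables <- function(x_train, y_train, variable_input,
                                      selection_args, seed) {
  if (variable_input == "full") {
    return(list(index = seq_len(ncol(x_train)), result = NULL))
  }
  y_dummy <- one_hot(y_train)
  if (variable_input == "uve_spa") {
    args <- utils::modifyList(
      list(x = x_train, y = y_dummy, seed = seed,
           pls_factor = min(12, nrow(x_train) - 2L)),
      selection_args)
    res <- do.call(uve_spa_select, args)
  } else {
    args <- utils::modifyList(
      list(x = x_train, y = y_dummy,
           config = ga_pls_config(n_runs = 10, seed = seed)),
      selection_args)
    res <- do.call(ga_pls_select, args)
  }
  list(index = res$selected_index, result = res)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s%s | %s | %s | overall %.2f%%>\n",
              x$task, if (!is.null(x$origin)) paste0("(", x$origin, ")")
              else "",
              x$variable_input, x$classifier, x$overall_acc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  tibble(class = names(x$per_class_acc), accuracy = unname(x$per_class_acc),
         n = unname(rowSums(x$confusion)))
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(task = x$task, origin = x$origin %||% NA_character_,
         variable_input = x$variable_input, classifier = x$classifier,
         parameter = x$parameter, overall_acc = x$overall_acc,
         n_test = x$n_test)
}

#' Assemble report tables from evaluation cells
#'
#' One row per (task, variable input, classifier) cell: the classifier's
#' parameter, the per-class accuracies as columns and the overall accuracy.
#' Rows are ordered full, then UVE-SPA, then GA-PLS within each task.
#'
#' @param reports a list of `eval_report` objects.
#' @return a tibble.
#' @export
build_report_tables <- function(reports) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  rows <- purrr::map_dfr(reports, function(r) {
    per <- tibble::as_tibble_row(as.list(r$per_class_acc))
    dplyr::bind_cols(
      tibble(task = r$task, origin = r$origin %||% NA_character_,
             variable_input = r$variable_input, classifier = r$classifier,
             parameter = r$parameter),
      per,
      tibble(overall = r$overall_acc))
  })
  order_vi <- c(full = 1, uve_spa = 2, ga_pls = 3)
  dplyr::arrange(rows, .data$task, .data$origin,
                 order_vi[.data$variable_input], .data$classifier)
}

#' Write a report table as CSV or Markdown
#'
#' @param table a tibble from [build_report_tables()].
#' @param path output path; format chosen by extension (`.csv` or `.md`).
#' @return `table`, invisibly.
#' @export
write_report_table <- function(table, path) {
  if (grepl("\\.md$", path)) {
    cols <- names(table)
    fmt <- function(v) ifelse(is.na(v), "-", format(v, trim = TRUE))
    lines <- c(
      paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      purrr::map_chr(seq_len(nrow(table)), function(i) {
        paste0("| ", paste(fmt(unlist(table[i, ], use.names = FALSE)),
                           collapse = " | "), " |")
      }))
    writeLines(lines, path)
  } else {
    readr::write_csv(table, path)
  }
  invisible(table)
}

#' Accuracy bar plot for a set of evaluation reports
#'
#' @param object a list of `eval_report` objects (or one report).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_report_accuracy <- function(object, ...) {
  tab <- build_report_tables(object)
  tab$cell <- paste(tab$variable_input, tab$classifier, sep = "-")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cell, y = .data$overall,
                                    fill = .data$task)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "overall accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
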