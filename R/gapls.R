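# Genetic-algorithm PLS wavelength selection.
#
# Binary chromosomes encode variable subsets; fitness is the (negated)
# minimum cross-validated RMSE of a PLS model on the encoded subset. Several
# independent runs are aggregated into a per-variable selection frequency,
# and the final subset is read off an RMSECV trace built by adding variables
# in decreasing-frequency order.

#' GA-PLS configuration
#'
#' Defaults follow common GA wavelength-selection practice: population 30,
#' crossover probability 0.5, per-bit mutation probability 0.01, 1000
#' chromosome evaluations per run, frequency averaging over repeated runs.
#' Spectra wider than `max_genes` variables are encoded as adjacent windows
#' (window-mean intensities) so chromosomes stay short; selected windows are
#' mapped back to all member wavenumbers on output.
#'
#' @param population chromosomes per generation (even).
#' @param p_crossover probability that a parent pair undergoes uniform
#'   crossover.
#' @param p_mutation per-bit mutation probability.
#' @param n_evaluations fitness evaluations per run.
#' @param n_runs independent GA runs aggregated into the frequency.
#' @param fitness `"rmsecv"` (minimise RMSECV) or `"cv_variance"` (maximise
#'   cross-validated explained variance).
#' @param folds CV folds used inside the GA (venetian blinds).
#' @param a_max largest PLS component count considered.
#' @param max_genes cap on chromosome length before window averaging.
#' @param init_genes expected number of active bits in an initial chromosome.
#' @param trace_max longest subset size evaluated on the frequency trace.
#' @param seed integer seed.
#' @return a `ga_pls_config` list.
#' @export
ga_pls_config <- function(population = 30, p_crossover = 0.5,
                          p_mutation = 0.01, n_evaluations = 1000,
                          n_runs = 100, fitness = c("rmsecv", "cv_variance"),
                          folds = 5, a_max = 12, max_genes = 500,
                          init_genes = 10, trace_max = 60, seed = 1L) {
  fitness <- match.arg(fitness)
  if (population %% 2 != 0) abort("`population` must be even")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "ga_pls_config")
}

# Map p variables to <= max_genes adjacent windows; returns list with the
# window id of every variable and the member variables of every window.
make_windows <- function(p, max_genes) {
  w <- ceiling(p / max_genes)
  id <- ceiling(seq_len(p) / w)
  list(id = id, members = split(seq_len(p), id), width = w)
}

ga_fitness_fun <- function(xg, y, cfg) {
  n <- nrow(xg)
  tss <- sum(scale(y, scale = FALSE)^2)
  function(bits) {
    sel <- which(bits == 1L)
    a <- min(cfg$a_max, length(sel),
             n - ceiling(n / cfg$folds) - 1L)
    if (a < 1) return(list(score = -Inf, rmsecv = Inf))
    cv <- cross_validate_pls(xg[, sel, drop = FALSE], y, a,
                             folds = cfg$folds)
    rmsecv <- cv$rmsecv[cv$best_a]
    score <- if (cfg$fitness == "rmsecv") -rmsecv else {
      1 - rmsecv^2 * n * ncol(as.matrix(y)) / tss
    }
    list(score = score, rmsecv = rmsecv)
  }
}

# One GA run. Returns the per-gene frequency in the final population, the
# best chromosome and its RMSECV/score.
ga_run <- function(fit_fun, ngenes, cfg) {
  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(ngenes, 1)] <- 1L
    bits
  }
  new_bits <- function() {
    repair(as.integer(runif(ngenes) < cfg$init_genes / ngenes))
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evals <- 0L
  # every evaluation counts toward the budget; the cache only skips the
  # numeric work for chromosomes seen before
  evaluate <- function(bits) {
    evals <<- evals + 1L
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fit_fun(bits)
    cache[[key]] <- val
    val
  }
  pop <- replicate(cfg$population, new_bits(), simplify = FALSE)
  scores <- purrr::map_dbl(pop, ~ evaluate(.x)$score)
  while (evals < cfg$n_evaluations) {
    elite <- pop[[which.max(scores)]]
    nxt <- list(elite)
    while (length(nxt) < cfg$population) {
      pick <- function() { # tournament of 2
        i <- sample.int(cfg$population, 2)
        pop[[i[which.max(scores[i])]]]
      }
      a <- pick(); b <- pick()
      if (runif(1) < cfg$p_crossover) { # uniform crossover
        swap <- runif(ngenes) < 0.5
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      }
      mut <- function(z) {
        flip <- runif(ngenes) < cfg$p_mutation
        z[flip] <- 1L - z[flip]
        repair(z)
      }
      nxt <- c(nxt, list(mut(a)), list(mut(b)))
    }
    pop <- nxt[seq_len(cfg$population)]
    scores <- purrr::map_dbl(pop, ~ evaluate(.x)$score)
  }
  best <- which.max(scores)
  best_val <- evaluate(pop[[best]])
  list(freq = Reduce(`+`, pop) / cfg$population,
       best_bits = pop[[best]], best_rmsecv = best_val$rmsecv,
       best_score = best_val$score)
}

#' GA-PLS wavelength selection
#'
#' Repeats `n_runs` seeded GA searches (tournament selection, uniform
#' crossover, bit-flip mutation, elitism 1), aggregates per-variable
#' selection frequencies across runs weighted by each run's final fitness,
#' and builds an RMSECV trace by adding variables in decreasing-frequency
#' order. Three marks are placed on the trace: the *global* model (trace
#' minimum), the *suggested* model (smallest size within one standard error
#' of the minimum) and the *better* model (smallest size with RMSECV within
#' 2% of the minimum); the better model's variables are the selection.
#'
#' @inheritParams uve_select
#' @param config a [ga_pls_config()].
#' @return an object of class `ga_pls_result`: `frequency` (per original
#'   variable), `gene_frequency`, `rmsecv_trace` tibble, `model_marks`,
#'   `selected_index`, `windows`, `runs` summary tibble.
#' @export
ga_pls_select <- function(x, y, config = ga_pls_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  p <- ncol(x)
  withr::local_seed(as.integer(config$seed))
  win <- if (p > config$max_genes) make_windows(p, config$max_genes) else {
    list(id = seq_len(p), members = as.list(seq_len(p)), width = 1L)
  }
  ngenes <- length(win$members)
  xg <- if (win$width > 1L) {
    do.call(cbind, lapply(win$members, function(j) {
      rowMeans(x[, j, drop = FALSE])
    }))
  } else {
    x
  }
  fit_fun <- ga_fitness_fun(xg, y, config)
  runs <- purrr::map(seq_len(config$n_runs),
                     ~ ga_run(fit_fun, ngenes, config))
  rmse_best <- purrr::map_dbl(runs, "best_rmsecv")
  w <- 1 / pmax(rmse_best, 1e-12)
  w <- w / sum(w)
  gene_freq <- Reduce(`+`, purrr::map2(runs, w, ~ .x$freq * .y))
  ord <- order(-gene_freq, seq_len(ngenes))
  k_top <- min(config$trace_max, sum(gene_freq > 0))
  trace <- purrr::map_dbl(seq_len(k_top), function(k) {
    fit_fun(as.integer(seq_len(ngenes) %in% ord[seq_len(k)]))$rmsecv
  })
  global <- which.min(trace)
  se <- trace_standard_error(xg[, ord[seq_len(global)], drop = FALSE], y,
                             config)
  suggested <- which(trace <= trace[global] + se)[1]
  better <- which(trace <= 1.02 * trace[global])[1]
  sel_genes <- ord[seq_len(better)]
  structure(
    list(frequency = gene_freq[win$id],
         gene_frequency = gene_freq,
         rmsecv_trace = tibble(k = seq_len(k_top), rmsecv = trace),
         model_marks = c(global = global, better = better,
                         suggested = suggested),
         selected_index = sort(unlist(win$members[sel_genes],
                                      use.names = FALSE)),
         windows = win,
         runs = tibble(run = seq_len(config$n_runs), rmsecv = rmse_best,
                       weight = w),
         config = config),
    class = "ga_pls_result")
}

# Standard error of the CV RMSE at a given subset: per-fold RMSE spread at
# the subset's best component count.
trace_standard_error <- function(xs, y, cfg) {
  n <- nrow(xs)
  fold_id <- venetian_folds(n, cfg$folds)
  a <- min(cfg$a_max, ncol(xs), n - ceiling(n / cfg$folds) - 1L)
  cv <- cross_validate_pls(xs, y, a, folds = cfg$folds)
  per_fold <- purrr::map_dbl(sort(unique(fold_id)), function(f) {
    hold <- fold_id == f
    fit <- fit_pls(xs[!hold, , drop = FALSE], y[!hold, , drop = FALSE],
                   cv$best_a)
    sqrt(mean((y[hold, , drop = FALSE] -
                 predict(fit, xs[hold, , drop = FALSE]))^2))
  })
  sd(per_fold) / sqrt(length(per_fold))
}

#' @exportS3Method generics::tidy
tidy.ga_pls_result <- function(x, ...) {
  tibble(variable = seq_along(x$frequency), frequency = x$frequency,
         selected = seq_along(x$frequency) %in% x$selected_index)
}

#' @exportS3Method generics::glance
glance.ga_pls_result <- function(x, ...) {
  tibble(n_selected = length(x$selected_index),
         n_genes = length(x$gene_frequency),
         k_global = x$model_marks[["global"]],
         k_better = x$model_marks[["better"]],
         k_suggested = x$model_marks[["suggested"]],
         rmsecv_min = min(x$rmsecv_trace$rmsecv))
}

#' RMSECV trace plot for a GA-PLS selection
#'
#' @param object a `ga_pls_result`.
#' @param ... unused.
#' @return a ggplot object with the global/better/suggested marks.
#' @exportS3Method ggplot2::autoplot
autoplot.ga_pls_result <- function(object, ...) {
  tr <- object$rmsecv_trace
  marks <- tibble(
    model = names(object$model_marks),
    k = as.integer(object$model_marks),
    rmsecv = tr$rmsecv[object$model_marks])
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$k, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(colour = .data$model), size = 3,
                        shape = 8) +
    ggplot2::labs(x = "variables included (by decreasing frequency)",
                  y = "RMSECV") +
    ggplot2::theme_minimal()
}
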