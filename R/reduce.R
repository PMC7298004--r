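#' Reduce the training database to its most generic subset
#'
#' Searches for the training subset whose fitted model minimises the
#' classification error over the \emph{full} database: items removed from
#' the training stage are still scored and counted, which guards against
#' over-fitting to idiosyncratic spectra.  Every admissible subset (at
#' least two items per class) is explored exhaustively while the candidate
#' count stays within \code{exhaustive_limit}; beyond that a greedy
#' backward elimination is used and a warning is emitted.
#'
#' @param features numeric matrix, one training item per row.
#' @param labels two-class labels.
#' @param eval_features,eval_labels database used to measure the error
#'   (default: the full training database itself).
#' @param exhaustive_limit maximum number of candidate subsets for the
#'   exhaustive search (default \code{2^20}).
#' @param positive swarming class label.
#' @param ... passed to [swarm_dfa()].
#' @return List with \code{subset} (row indices kept), \code{error}
#'   (percentage over the evaluation database), \code{model} (fitted on
#'   the reduced subset), \code{method} (\code{"exhaustive"} or
#'   \code{"greedy"}).
#' @export
reduce_training_set <- function(features, labels,
                                eval_features = features,
                                eval_labels = labels,
                                exhaustive_limit = 2^20,
                                positive = "PTS", ...) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  eval_features <- as.matrix(eval_features)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("need exactly two classes")
  score_subset <- function(idx) {
    if (min(table(labels[idx])) < 2L) return(NULL)
    m <- tryCatch(swarm_dfa(features[idx, , drop = FALSE], labels[idx],
                            positive = positive, ...),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    m <- retune_threshold(m, eval_features, eval_labels)
    list(model = m,
         error = classification_error(m, eval_features, eval_labels))
  }
  if (2^n <= exhaustive_limit) {
    best <- NULL
    for (code in seq_len(2^n) - 1L) {
      idx <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
      if (length(idx) < 4L) next
      res <- score_subset(idx)
      if (is.null(res)) next
      if (is.null(best) || res$error < best$error ||
          (res$error == best$error && length(idx) < length(best$subset)))
        best <- c(res, list(subset = idx))
    }
    if (is.null(best)) stop("no admissible subset keeps 2 items per class")
    best$method <- "exhaustive"
    return(best[c("subset", "error", "model", "method")])
  }
  warning("search space exceeds exhaustive_limit; ",
          "using greedy backward elimination")
  idx <- seq_len(n)
  cur <- score_subset(idx)
  repeat {
    cand <- NULL
    for (drop_i in idx) {
      trial <- setdiff(idx, drop_i)
      if (min(table(labels[trial])) < 2L) next
      res <- score_subset(trial)
      if (is.null(res)) next
      if (is.null(cand) || res$error < cand$error)
        cand <- c(res, list(subset = trial))
    }
    if (is.null(cand) || cand$error > cur$error) break
    idx <- cand$subset
    cur <- cand
  }
  list(subset = idx, error = cur$error, model = cur$model,
       method = "greedy")
}

#' Parametric optimisation over a configuration grid
#'
#' Full factorial evaluation of a processing-configuration grid: for every
#' combination, \code{db_builder} assembles the training and evaluation
#' databases under that configuration, a model is fitted, and the
#' percentage classification error over the evaluation database is
#' recorded.  The traversal order is the deterministic row order of
#' \code{expand.grid} over the supplied axes.
#'
#' @param db_builder function taking one configuration (a one-row list)
#'   and returning \code{list(train_features, train_labels, eval_features,
#'   eval_labels)}.
#' @param grid named list of parameter vectors, e.g.
#'   \code{list(f_lo = c(18, 100), keep_fraction = 0.4)}.  Axes may cover
#'   amplitude scaling, crop band, training-window length, hour window,
#'   kept-score fraction, number of DFs, or history days.
#' @param positive swarming class label.
#' @param ... fixed arguments passed to [swarm_dfa()].
#' @return List with \code{best_config} (one-row data frame),
#'   \code{best_error}, \code{model} (refitted at the best
#'   configuration), and \code{table} (per-configuration error table).
#' @export
parametric_optimisation <- function(db_builder, grid, positive = "PTS",
                                    ...) {
  if (!length(grid)) stop("empty configuration grid")
  tab <- expand.grid(grid, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  errors <- rep(NA_real_, nrow(tab))
  fit_one <- function(i) {
    cfg <- as.list(tab[i, , drop = FALSE])
    db <- db_builder(cfg)
    args <- list(x = db$train_features, labels = db$train_labels,
                 positive = positive, ...)
    if (!is.null(cfg$keep_fraction)) args$keep_fraction <- cfg$keep_fraction
    if (!is.null(cfg$n_df)) args$n_df <- cfg$n_df
    m <- do.call(swarm_dfa, args)
    m <- retune_threshold(m, db$eval_features, db$eval_labels)
    list(model = m,
         error = classification_error(m, db$eval_features, db$eval_labels))
  }
  models <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    res <- fit_one(i)
    errors[i] <- res$error
    models[[i]] <- res$model
  }
  tab$error <- errors
  best <- which.min(errors)
  list(best_config = tab[best, , drop = FALSE], best_error = errors[best],
       model = models[[best]], table = tab)
}
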