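#' Cross-correlation product
#'
#' The zero-lag cross-correlation used to score a feature against a
#' discriminant-function curve: the inner product of the (optionally
#' centred) feature with the curve.  Linear in the feature.
#'
#' @param feature numeric vector.
#' @param curve numeric vector of the same length.
#' @param center either \code{TRUE} (subtract the feature's scalar mean,
#'   the default), \code{FALSE}, or a numeric centring vector (the model's
#'   training mean spectrum).
#' @return A scalar.
#' @export
ccp <- function(feature, curve, center = TRUE) {
  feature <- as.numeric(feature)
  if (length(feature) != length(curve))
    stop("feature and curve lengths differ (", length(feature), " vs ",
         length(curve), ")")
  x <- if (isTRUE(center)) feature - mean(feature)
  else if (isFALSE(center)) feature
  else feature - as.numeric(center)
  sum(x * curve)
}

#' Keep the leading fraction of PCA scores
#'
#' The classifiers project the first \code{ceiling(fraction * n)} principal
#' components (by count, not by explained variance) into the discriminant
#' analysis; the published configuration keeps 40 percent.
#'
#' @param n_components number of available components.
#' @param fraction in (0, 1].
#' @return Integer vector of component indices.
#' @export
select_scores <- function(n_components, fraction = 0.4) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  seq_len(ceiling(fraction * n_components))
}

# Fisher discriminant axes in score space.  With two classes the
# between-class scatter has rank 1; axes beyond DF1 are the remaining
# eigenvectors of the whitened between-class scatter (eigenvalues zero,
# order fixed by the symmetric eigensolver), i.e. successive orthogonal
# directions in whitened space carrying the residual between-class
# variance, with ties broken by index.
fit_dfa_axes <- function(scores, labels, n_df, ridge = 1e-6) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes are required")
  d <- ncol(scores)
  if (n_df > d) stop("n_df exceeds the score dimension")
  mu <- colMeans(scores)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- scores[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Sw <- Sw + crossprod(sweep(Xc, 2, mc))
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  Sw <- Sw / max(nrow(scores) - 2L, 1L)
  lam <- ridge * sum(diag(Sw)) / d
  if (lam <= 0) lam <- ridge
  Sw <- Sw + diag(lam, d)
  ew <- eigen(Sw, symmetric = TRUE)
  Wisqrt <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  M <- Wisqrt %*% Sb %*% Wisqrt
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  axes <- Wisqrt %*% em$vectors[, seq_len(n_df), drop = FALSE]
  axes <- sweep(axes, 2, sqrt(colSums(axes^2)), "/")
  list(axes = axes, eigenvalues = em$values[seq_len(n_df)])
}

#' Optimise the alarm threshold on the criterion axis
#'
#' Exhaustive scan over the midpoints of consecutive sorted unique
#' criterion values (plus outer cuts): returns the threshold minimising the
#' number of misclassifications, where values below the threshold are
#' classified as the swarming (PTS) state.  Ties are broken toward the
#' larger margin: the midpoint of the widest optimal gap.
#'
#' @param criteria numeric criterion values.
#' @param labels labels with the swarming class first level or given by
#'   \code{positive}.
#' @param positive label value denoting the swarming class.
#' @return The optimal threshold (scalar).
#' @export
optimize_threshold <- function(criteria, labels, positive = "PTS") {
  labels <- as.character(labels)
  keep <- is.finite(criteria)
  criteria <- criteria[keep]; labels <- labels[keep]
  if (!any(labels == positive) || all(labels == positive))
    stop("both classes must be present")
  u <- sort(unique(criteria))
  cuts <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  widths <- c(1, diff(u), 1)
  errs <- vapply(cuts, function(th)
    sum((criteria < th) != (labels == positive)), numeric(1))
  best <- which(errs == min(errs))
  cuts[best[which.max(widths[best])]]
}

#' Fit the swarm discriminant model
#'
#' The central fitting routine of the package: principal-component
#' reduction of the training features, Fisher discriminant-function
#' analysis on the leading scores, back-projection of the discriminant axes
#' into feature space as DF curves, class centroids in DF space, and an
#' optimised alarm threshold on the criterion value (ratio of Euclidean
#' distances to the swarming and non-swarming centroids; values below the
#' threshold indicate the swarming state).
#'
#' Scoring new spectra needs only the cross-correlation product of the
#' centred feature with each DF curve, which reproduces the explicit
#' PCA-projection scores exactly.
#'
#' @param x numeric matrix of training features, one row per item.
#' @param labels two-class labels; \code{positive} names the swarming
#'   class.
#' @param keep_fraction fraction of PCA scores kept, by count
#'   (default 0.4).
#' @param n_df number of discriminant functions, 2 or 3 (default 3).
#' @param positive swarming class label (default \code{"PTS"}).
#' @param ridge within-class scatter regularisation, as a fraction of
#'   \code{trace/dim} (default 1e-6); needed because feature length far
#'   exceeds the training count.
#' @param feature_cfg optional list describing how features are built from
#'   spectra (stored; used by [hourly_alarm()]).
#' @return An object of class \code{swarm_dfa} with components
#'   \code{center} (training mean spectrum), \code{rotation} (selected PCA
#'   components), \code{sdev}, \code{selected}, \code{axes},
#'   \code{curves} (feature-space DF curves, one column per DF),
#'   \code{centroid_pts}, \code{centroid_ns}, \code{threshold},
#'   \code{train} (training coordinates, criteria, labels).
#' @seealso [predict.swarm_dfa()], [classification_error()],
#'   [optimize_threshold()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 8), matrix(rnorm(40, 2), 8))
#' fit <- swarm_dfa(x, rep(c("PTS", "NS"), each = 8))
#' fit
#' predict(fit, x[1:2, ])
#' @export
swarm_dfa <- function(x, labels, keep_fraction = 0.4, n_df = 3,
                      positive = "PTS", ridge = 1e-6,
                      feature_cfg = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) != 2L) stop("labels must contain exactly two classes")
  if (!positive %in% classes)
    stop("positive class '", positive, "' absent from labels")
  if (min(table(labels)) < 2L) stop("need at least 2 items per class")
  if (all(apply(x, 2, stats::var) < 1e-30))
    stop("zero-variance training database")

  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- pca$sdev > 1e-12 * pca$sdev[1]
  rotation <- pca$rotation[, keep, drop = FALSE]
  sdev <- pca$sdev[keep]
  selected <- select_scores(ncol(rotation), keep_fraction)
  n_df <- min(n_df, length(selected))
  rot_sel <- rotation[, selected, drop = FALSE]
  scores <- sweep(x, 2, pca$center) %*% rot_sel

  dfa <- fit_dfa_axes(scores, labels, n_df, ridge)
  curves <- rot_sel %*% dfa$axes
  coords <- scores %*% dfa$axes
  negative <- setdiff(classes, positive)
  centroid_pts <- colMeans(coords[labels == positive, , drop = FALSE])
  centroid_ns <- colMeans(coords[labels == negative, , drop = FALSE])

  model <- structure(list(
    center = pca$center, rotation = rot_sel, sdev = sdev,
    n_components = ncol(rotation), keep_fraction = keep_fraction,
    selected = selected, axes = dfa$axes, eigenvalues = dfa$eigenvalues,
    curves = curves, n_df = n_df,
    centroid_pts = centroid_pts, centroid_ns = centroid_ns,
    positive = positive, negative = negative,
    threshold = NA_real_, feature_cfg = feature_cfg,
    train = list(coords = coords, labels = labels),
    call = match.call()),
    class = "swarm_dfa")
  crit <- apply(coords, 1, criterion, model = model)
  model$train$criteria <- crit
  model$threshold <- optimize_threshold(crit, labels, positive)
  model
}

#' DF-space coordinates of a feature
#'
#' One cross-correlation product per DF curve (ordered DF1..DFk), after
#' centring the feature by the model's training mean spectrum.
#'
#' @param feature numeric feature vector (model feature length).
#' @param model a \code{swarm_dfa}.
#' @return Numeric vector of length \code{model$n_df}.
#' @export
df_coordinates <- function(feature, model) {
  stopifnot(inherits(model, "swarm_dfa"))
  vapply(seq_len(ncol(model$curves)), function(j)
    ccp(feature, model$curves[, j], center = model$center), numeric(1))
}

#' Criterion value of a DF-space point
#'
#' Euclidean distance to the swarming (PTS) centroid divided by Euclidean
#' distance to the non-swarming (NS) centroid.  Values below the model
#' threshold indicate the swarming state.  Returns \code{Inf} when the
#' point coincides with the NS centroid.
#'
#' @param point numeric DF-space coordinates.
#' @param model a \code{swarm_dfa} with centroids set.
#' @return Non-negative scalar (possibly \code{Inf}).
#' @export
criterion <- function(point, model) {
  d_pts <- sqrt(sum((point - model$centroid_pts)^2))
  d_ns <- sqrt(sum((point - model$centroid_ns)^2))
  if (d_ns == 0) return(Inf)
  d_pts / d_ns
}

#' Percentage classification error of a model on a database
#'
#' 100 times the fraction of items whose criterion-vs-threshold
#' classification disagrees with the label.
#'
#' @param model a \code{swarm_dfa}.
#' @param features numeric matrix, one feature per row.
#' @param labels true labels.
#' @param threshold alarm threshold (default the model's optimised one).
#' @return Percentage in [0, 100].
#' @export
classification_error <- function(model, features, labels,
                                 threshold = model$threshold) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty database")
  crit <- predict(model, features, type = "criterion")
  pred <- ifelse(crit < threshold, model$positive, model$negative)
  100 * mean(pred != as.character(labels))
}

#' Re-optimise a fitted model's threshold on a wider criterion set
#'
#' The training phase optimises the threshold over all available scored
#' spectra, not just the reduced training database; this helper rescores
#' the supplied features with the fitted curves and stores the new optimum.
#'
#' @inheritParams classification_error
#' @return The model with an updated \code{threshold}.
#' @export
retune_threshold <- function(model, features, labels) {
  crit <- predict(model, as.matrix(features), type = "criterion")
  model$threshold <- optimize_threshold(crit, labels, model$positive)
  model
}
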