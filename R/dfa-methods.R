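#' @export
print.swarm_dfa <- function(x, ...) {
  n <- length(x$train$labels)
  cat("Swarm discriminant model (PCA + DFA)\n")
  cat(sprintf("  training items : %d (%d %s, %d %s)\n", n,
              sum(x$train$labels == x$positive), x$positive,
              sum(x$train$labels == x$negative), x$negative))
  cat(sprintf("  feature length : %d\n", length(x$center)))
  cat(sprintf("  PCA scores kept: %d of %d (fraction %.2f)\n",
              length(x$selected), x$n_components, x$keep_fraction))
  cat(sprintf("  DF curves      : %d\n", x$n_df))
  cat(sprintf("  alarm threshold: %.4g (criterion below => swarming)\n",
              x$threshold))
  invisible(x)
}

#' @export
summary.swarm_dfa <- function(object, ...) {
  err <- 100 * mean(
    ifelse(object$train$criteria < object$threshold,
           object$positive, object$negative) != object$train$labels)
  out <- list(model = object, training_error = err,
              centroid_separation = sqrt(sum(
                (object$centroid_pts - object$centroid_ns)^2)),
              criteria_range = range(object$train$criteria[
                is.finite(object$train$criteria)]))
  class(out) <- "summary.swarm_dfa"
  out
}

#' @export
print.summary.swarm_dfa <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training classification error: %.2f%%\n",
              x$training_error))
  cat(sprintf("  centroid separation in DF space: %.4g\n",
              x$centroid_separation))
  cat(sprintf("  training criterion range: %.3g .. %.3g\n",
              x$criteria_range[1], x$criteria_range[2]))
  invisible(x)
}

#' DF curves of a fitted model
#'
#' @param object a \code{swarm_dfa}.
#' @param ... unused.
#' @return Matrix with one column per discriminant function (feature-space
#'   curves); rows follow the training feature bins.
#' @export
coef.swarm_dfa <- function(object, ...) {
  cn <- paste0("DF", seq_len(ncol(object$curves)))
  structure(object$curves, dimnames = list(NULL, cn))
}

#' @export
fitted.swarm_dfa <- function(object, ...) object$train$criteria

#' Score new features with a fitted swarm model
#'
#' @param object a \code{swarm_dfa}.
#' @param newdata numeric matrix (items by feature length) or a single
#'   feature vector.
#' @param type \code{"criterion"} (default) for criterion values,
#'   \code{"coords"} for DF-space coordinates, \code{"class"} for
#'   PTS/NS labels from the threshold.
#' @param ... unused.
#' @return Vector, matrix or character vector according to \code{type}.
#' @export
predict.swarm_dfa <- function(object, newdata,
                              type = c("criterion", "coords", "class"),
                              ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(as.numeric(newdata), 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("feature length ", ncol(newdata), " does not match the model (",
         length(object$center), ")")
  coords <- sweep(newdata, 2, object$center) %*% object$curves
  if (type == "coords") {
    colnames(coords) <- paste0("DF", seq_len(ncol(coords)))
    return(coords)
  }
  crit <- apply(coords, 1, criterion, model = object)
  if (type == "criterion") return(crit)
  ifelse(crit < object$threshold, object$positive, object$negative)
}

#' Plot the DF-space training scatter of a fitted model
#'
#' Shows the first two DF coordinates of the training items, the class
#' centroids, and (as a contour label in the margin) the alarm threshold.
#'
#' @param x a \code{swarm_dfa}.
#' @param ... passed to \code{plot.default}.
#' @importFrom graphics points legend
#' @export
plot.swarm_dfa <- function(x, ...) {
  co <- x$train$coords
  if (ncol(co) < 2) stop("model has fewer than 2 DF axes")
  pts <- x$train$labels == x$positive
  plot(co[, 1], co[, 2], col = ifelse(pts, "red3", "forestgreen"),
       pch = ifelse(pts, 17, 19), xlab = "DF1", ylab = "DF2",
       main = sprintf("DF space (threshold %.3g)", x$threshold), ...)
  points(x$centroid_pts[1], x$centroid_pts[2], pch = 8, cex = 2,
         col = "red3")
  points(x$centroid_ns[1], x$centroid_ns[2], pch = 8, cex = 2,
         col = "forestgreen")
  legend("topright", c("PTS", "NS"), col = c("red3", "forestgreen"),
         pch = c(17, 19), bty = "n")
  invisible(x)
}
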