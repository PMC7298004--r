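test_that("kept PCA components recover the generating eigenvectors", {
  # known 2-D covariance with eigenvectors along (1,1)/sqrt(2), (1,-1)/sqrt(2)
  set.seed(12)
  n <- 400
  z <- cbind(stats::rnorm(n, sd = 3), stats::rnorm(n, sd = 0.5))
  R <- matrix(c(1, 1, 1, -1), 2) / sqrt(2)
  x <- z %*% t(R)
  labels <- rep(c("PTS", "NS"), length.out = n)   # labels irrelevant to PCA
  fit <- swarm_dfa(x, labels, keep_fraction = 1, n_df = 2)
  v1 <- fit$rotation[, 1]
  expect_gt(abs(sum(v1 * R[, 1])), 0.99)
  expect_true(all(diff(fit$sdev) <= 1e-12))

  # collinear points: the first component carries all the variance
  xc <- cbind(1:10, 2 * (1:10))
  fitc <- swarm_dfa(xc, rep(c("PTS", "NS"), 5), keep_fraction = 1,
                    n_df = 1)
  expect_gt(fitc$sdev[1]^2 / sum(fitc$sdev^2), 1 - 1e-12)

  expect_error(swarm_dfa(matrix(1, 8, 4), rep(c("PTS", "NS"), 4)),
               "zero-variance")
})

test_that("score selection keeps the leading components by count", {
  expect_equal(select_scores(10, 0.4), 1:4)
  expect_equal(select_scores(7, 1.0), 1:7)
  expect_equal(select_scores(5, 0.4), 1:2)
  expect_error(select_scores(5, 0), "fraction")
})

test_that("DF1 matches the closed-form Fisher direction", {
  set.seed(13)
  n <- 200
  x <- rbind(matrix(stats::rnorm(2 * n), n),
             sweep(matrix(stats::rnorm(2 * n), n), 2, c(3, 1), "+"))
  labels <- rep(c("PTS", "NS"), each = n)
  fit <- swarm_dfa(x, labels, keep_fraction = 1, n_df = 2)
  # isotropic within-class scatter: Fisher direction is the mean difference
  d <- colMeans(x[labels == "PTS", ]) - colMeans(x[labels == "NS", ])
  cosang <- abs(sum(fit$curves[, 1] * d)) /
    sqrt(sum(fit$curves[, 1]^2) * sum(d^2))
  expect_gt(cosang, 0.97)

  # label swap flips nothing but possibly the sign of the axis
  fit2 <- swarm_dfa(x, rev(labels), keep_fraction = 1, n_df = 2)
  cos12 <- abs(sum(fit$curves[, 1] * fit2$curves[, 1])) /
    sqrt(sum(fit$curves[, 1]^2) * sum(fit2$curves[, 1]^2))
  expect_equal(cos12, 1, tolerance = 1e-6)

  # perfectly separated clusters classify their training set exactly
  db <- separable_db(gap = 8)
  fit3 <- swarm_dfa(db$x, db$labels)
  expect_equal(classification_error(fit3, db$x, db$labels), 0)
})

test_that("DF curves reproduce explicit PCA-projection scores", {
  db <- separable_db(n_per_class = 10, p = 30, gap = 2, seed = 14)
  fit <- swarm_dfa(db$x, db$labels)
  explicit <- sweep(db$x, 2, fit$center) %*% fit$rotation %*% fit$axes
  via_ccp <- t(apply(db$x, 1, df_coordinates, model = fit))
  expect_equal(via_ccp, explicit, tolerance = 1e-9, ignore_attr = TRUE)

  # features orthogonal to every kept component score zero
  set.seed(99)
  r <- stats::rnorm(ncol(db$x))
  ortho <- r - fit$rotation %*% crossprod(fit$rotation, r)
  null_vec <- fit$center + as.numeric(ortho)
  expect_equal(max(abs(df_coordinates(null_vec, fit))), 0,
               tolerance = 1e-9)
  expect_equal(df_coordinates(fit$center, fit), rep(0, 3))
})

test_that("the cross-correlation product is a centred inner product", {
  expect_equal(ccp(c(1, -1), c(1, 1), center = FALSE), 0)
  set.seed(15)
  x <- stats::rnorm(50); y <- stats::rnorm(50); z <- stats::rnorm(50)
  brute <- sum((x - mean(x)) * y)
  expect_equal(ccp(x, y), brute)
  # linearity under shared centring
  mu <- stats::rnorm(50)
  expect_equal(ccp(x, y, center = mu) + ccp(z, y, center = mu),
               ccp(x + z, y, center = 2 * mu))
  expect_error(ccp(1:3, 1:4), "lengths differ")
})

test_that("the criterion is a centroid-distance ratio with an Inf sentinel", {
  model <- list(centroid_pts = c(0, 0), centroid_ns = c(2, 0))
  expect_equal(criterion(c(0, 0), model), 0)
  expect_equal(criterion(c(1, 5), model), 1)
  expect_equal(criterion(c(2, 0), model), Inf)

  # invariance under a joint isometry of point and centroids
  set.seed(16)
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- stats::rnorm(2)
  p <- stats::rnorm(2)
  model2 <- list(centroid_pts = as.numeric(R %*% model$centroid_pts + shift),
                 centroid_ns = as.numeric(R %*% model$centroid_ns + shift))
  expect_equal(criterion(as.numeric(R %*% p + shift), model2),
               criterion(p, model))
})

test_that("threshold optimisation matches an exhaustive oracle", {
  expect_equal(optimize_threshold(c(0.2, 0.3, 1.5, 1.8),
                                  c("PTS", "PTS", "NS", "NS")), 0.9)
  expect_equal(optimize_threshold(c(0.4, 1.6), c("PTS", "NS")), 1.0)

  brute_errors <- function(crit, lab) {
    cuts <- sort(unique(c(crit - 1e-9, crit + 1e-9)))
    min(vapply(cuts, function(th)
      sum((crit < th) != (lab == "PTS")), numeric(1)))
  }
  set.seed(17)
  for (rep in 1:20) {
    crit <- round(stats::runif(12), 2)
    lab <- sample(c("PTS", "NS"), 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    th <- optimize_threshold(crit, lab)
    got <- sum((crit < th) != (lab == "PTS"))
    expect_equal(got, brute_errors(crit, lab))
  }
  expect_error(optimize_threshold(c(1, 2), c("PTS", "PTS")), "both classes")
})

test_that("classification error counts misclassified spectra as a percentage", {
  db <- separable_db(gap = 8, seed = 18)
  fit <- swarm_dfa(db$x, db$labels)
  set.seed(18)
  eval_x <- db$x[rep(1:16, length.out = 56) + 0, ] +
    matrix(stats::rnorm(56 * 12, sd = 0.01), 56)
  eval_lab <- rep(db$labels, length.out = 56)
  expect_equal(classification_error(fit, eval_x, eval_lab), 0)
  wrong <- eval_lab
  wrong[1] <- "NS"
  expect_equal(round(classification_error(fit, eval_x, wrong), 2), 1.79)
  flipped <- ifelse(eval_lab == "PTS", "NS", "PTS")
  e <- classification_error(fit, eval_x, eval_lab)
  expect_equal(classification_error(fit, eval_x, flipped), 100 - e)
})

test_that("training-set reduction never beats the full set and handles duplicates", {
  db <- separable_db(n_per_class = 5, p = 6, gap = 6, seed = 19)
  x <- rbind(db$x, db$x[c(1, 6), ])          # exact duplicates
  lab <- c(db$labels, db$labels[c(1, 6)])
  full_fit <- swarm_dfa(x, lab)
  full_err <- classification_error(full_fit, x, lab)
  red <- reduce_training_set(x, lab, exhaustive_limit = 2^12)
  expect_equal(red$method, "exhaustive")
  expect_lte(red$error, full_err)
  expect_lt(length(red$subset), nrow(x))     # duplicates are removable

  greedy <- suppressWarnings(
    reduce_training_set(db$x, db$labels, exhaustive_limit = 2))
  exact <- reduce_training_set(db$x, db$labels, exhaustive_limit = 2^10)
  expect_equal(greedy$error, exact$error)
  expect_error(reduce_training_set(db$x[1:3, ], db$labels[1:3]))
})

test_that("parametric optimisation scans the grid deterministically", {
  db <- separable_db(seed = 20)
  builder <- function(cfg) {
    cols <- seq_len(cfg$p_use)
    list(train_features = db$x[, cols, drop = FALSE],
         train_labels = db$labels,
         eval_features = db$x[, cols, drop = FALSE],
         eval_labels = db$labels)
  }
  single <- parametric_optimisation(builder, list(p_use = 12))
  expect_equal(single$best_config$p_use, 12)
  expect_equal(nrow(single$table), 1L)

  two <- parametric_optimisation(builder, list(p_use = c(2, 12),
                                               keep_fraction = c(0.4, 1)))
  expect_equal(nrow(two$table), 4L)
  again <- parametric_optimisation(builder, list(p_use = c(2, 12),
                                                 keep_fraction = c(0.4, 1)))
  expect_identical(two$table, again$table)
  expect_error(parametric_optimisation(builder, list()), "empty")
})

test_that("a crop that keeps the planted band wins the optimisation", {
  # synthetic cohort whose discriminating signature sits at 21 Hz:
  # cropping from 18 Hz keeps it, cropping from 100 Hz discards it
  sw <- simulate_series(mini_swarm_scenario(days = 18, swarm_day = 15,
                                            seed = 27))
  ns <- simulate_series(mini_quiet_scenario(days = 18, seed = 28))
  cfg0 <- strategy_config("instantaneous")
  raw_sw <- hivewatch:::night_raw_matrix(sw$series, cfg0)
  raw_ns <- hivewatch:::night_raw_matrix(ns$series, cfg0)
  pts <- raw_sw[8:15, ]                       # ramp nights
  nsx <- rbind(raw_sw[1:2, ], raw_ns[c(1:4, 8:11), ])
  builder <- function(cfg) {
    cfgi <- strategy_config("instantaneous", f_lo = cfg$f_lo)
    x <- hivewatch:::s1_featurise(rbind(pts, nsx), sw$series$grid, cfgi)
    lab <- c(rep("PTS", nrow(pts)), rep("NS", nrow(nsx)))
    list(train_features = x, train_labels = lab,
         eval_features = x, eval_labels = lab)
  }
  res <- parametric_optimisation(builder, list(f_lo = c(18, 100)))
  expect_equal(res$best_config$f_lo, 18)
})
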