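night_frame <- function(amp, n_bins = length(amp)) {
  spectrum_frame(as.POSIXct("2014-04-01 03:00:00", tz = "UTC"),
                 freq_grid(0, 3, n_bins), amp)
}

test_that("instantaneous features normalise and log as specified", {
  fr <- night_frame(rep(5, 300))
  expect_equal(as.numeric(instantaneous_feature(fr, log_scale = FALSE)),
               rep(1, 261))
  expect_equal(as.numeric(instantaneous_feature(fr)), rep(0, 261))

  set.seed(6)
  fr2 <- night_frame(stats::rlnorm(300))
  f1 <- instantaneous_feature(fr2)
  fr3 <- night_frame(7.3 * fr2$amplitudes)
  expect_equal(as.numeric(instantaneous_feature(fr3)), as.numeric(f1))
  expect_length(f1, 261)

  miss <- spectrum_frame(fr$timestamp, fr$grid, rep(NA_real_, 300),
                         quality = "missing")
  expect_error(instantaneous_feature(miss), "missing")
  zero <- night_frame(c(rep(1, 9), 0, rep(1, 290)))  # zero inside the crop
  expect_error(instantaneous_feature(zero, normalise = "none"),
               "positive")
})

test_that("the intra-day 2DFT matches closed-form transforms", {
  Tn <- 100
  # constant time course -> only the DC modulation bin, equal to the level
  amp <- matrix(3, Tn, 8)
  s <- make_series(Tn, n_bins = 8, amp = amp)
  img <- daily_2dft(s, as.Date("2014-04-01"))
  expect_equal(dim(img$magnitudes), c(8, 51))
  expect_equal(img$magnitudes[, 1], rep(3, 8))
  expect_equal(max(abs(img$magnitudes[, -1])), 0)

  # sinusoidal modulation at 12 cycles/window -> single off-DC peak at
  # modulation bin 12 with one-sided magnitude b/2
  b <- 0.5
  tc <- 2 + b * cos(2 * pi * 12 * (0:(Tn - 1)) / Tn)
  amp2 <- matrix(rep(tc, 8), Tn, 8)
  img2 <- daily_2dft(make_series(Tn, n_bins = 8, amp = amp2),
                     as.Date("2014-04-01"))
  offdc <- img2$magnitudes[1, -1]
  expect_equal(which.max(offdc), 12)
  expect_equal(max(offdc), b / 2, tolerance = 1e-9)

  # circular shift of the frame order leaves the magnitudes unchanged
  sh <- amp2[c(31:Tn, 1:30), ]
  img3 <- daily_2dft(make_series(Tn, n_bins = 8, amp = sh),
                     as.Date("2014-04-01"))
  expect_equal(img3$magnitudes, img2$magnitudes, tolerance = 1e-9)
})

test_that("2DFT magnitudes satisfy Parseval's identity per time course", {
  set.seed(7)
  Tn <- 100
  amp <- matrix(stats::rlnorm(Tn * 4), Tn, 4)
  img <- daily_2dft(make_series(Tn, n_bins = 4, amp = amp),
                    as.Date("2014-04-01"))
  for (bpos in 1:4) {
    m <- img$magnitudes[bpos, ]
    two_sided <- sum(m[1]^2 + m[51]^2 + 2 * sum(m[2:50]^2))
    expect_equal(two_sided, mean(amp[, bpos]^2), tolerance = 1e-9)
  }
})

test_that("gap policy interpolates sparse holes and rejects sparse days", {
  Tn <- 100
  amp <- matrix(stats::rlnorm(Tn * 4), Tn, 4)
  q <- rep("ok", Tn); q[c(40, 40 + 1)] <- "missing"
  amp[q == "missing", ] <- NA_real_
  s <- make_series(Tn, n_bins = 4, amp = amp, quality = q)
  img <- daily_2dft(s, as.Date("2014-04-01"))
  expect_true(all(is.finite(img$magnitudes)))

  q2 <- rep("ok", Tn); q2[30:45] <- "missing"
  amp2 <- amp; amp2[30:45, ] <- NA_real_
  s2 <- make_series(Tn, n_bins = 4, amp = amp2, quality = q2)
  expect_false(day_usable(s2, as.Date("2014-04-01")))
  expect_error(daily_2dft(s2, as.Date("2014-04-01")), "unusable")
})

test_that("the across-day 3DFT matches closed forms", {
  mk_img <- function(day, mat) {
    structure(list(magnitudes = mat, day = as.Date(day),
                   grid = freq_grid(0, 3, nrow(mat)), n_frames = 100),
              class = "image_2dft")
  }
  days <- as.Date("2014-04-01") + 0:9
  base <- matrix(2, 5, 6)

  t3 <- evolution_3dft(lapply(days, mk_img, mat = base))
  expect_equal(dim(t3$magnitudes), c(5, 6, 6))
  # identical images every day -> only the across-day DC plane is nonzero
  expect_equal(t3$magnitudes[, , 1], base)
  expect_equal(max(abs(t3$magnitudes[, , -1])), 0)
  # maximum across-day frequency is 0.5 cycles/day = 3.5 cycles/week
  expect_equal((dim(t3$magnitudes)[3] - 1) / t3$history_days * 7, 3.5)

  # a pixel alternating a, b concentrates off-DC energy at Nyquist
  mats <- lapply(1:10, function(d) {
    m <- base; m[2, 3] <- if (d %% 2) 1 else 3; m
  })
  t4 <- evolution_3dft(mapply(mk_img, days, mats, SIMPLIFY = FALSE))
  px <- t4$magnitudes[2, 3, ]
  expect_equal(which.max(px[-1]), 5)          # Nyquist bin (0.5 cyc/day)
  expect_equal(px[6], 1, tolerance = 1e-9)    # |a - b| / 2
  expect_equal(max(abs(px[2:5])), 0, tolerance = 1e-9)

  expect_error(evolution_3dft(lapply(days[c(1:4, 6:10)], mk_img,
                                     mat = base)), "consecutive")
  expect_error(evolution_3dft(list(mk_img(days[1], base))), "at least 2")
})

test_that("3DFT is invariant to circular shifts of the day order", {
  mk_img <- function(day, mat) {
    structure(list(magnitudes = mat, day = as.Date(day),
                   grid = freq_grid(0, 3, nrow(mat)), n_frames = 100),
              class = "image_2dft")
  }
  set.seed(8)
  mats <- lapply(1:10, function(d) matrix(stats::rlnorm(12), 3, 4))
  days <- as.Date("2014-04-01") + 0:9
  a <- evolution_3dft(mapply(mk_img, days, mats, SIMPLIFY = FALSE))
  b <- evolution_3dft(mapply(mk_img, days, mats[c(4:10, 1:3)],
                             SIMPLIFY = FALSE))
  expect_equal(a$magnitudes, b$magnitudes, tolerance = 1e-9)
})

test_that("vectorisation is a recorded, invertible row-major flatten", {
  m <- matrix(1:6, 2, 3, byrow = TRUE)
  v <- vectorize(m)
  expect_length(v, 6)
  expect_equal(as.numeric(v), c(1, 2, 3, 4, 5, 6))
  expect_equal(devectorize(v), m)

  set.seed(10)
  a <- array(stats::rnorm(24), c(2, 3, 4))
  expect_equal(devectorize(vectorize(a)), a)

  big <- array(0, c(261, 51, 6))
  expect_length(vectorize(big), 79866)
})
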