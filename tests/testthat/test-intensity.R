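test_that("Gaussian smoothing preserves constants, symmetry and the delta limit", {
  expect_equal(smooth_intensity(rep(0.4, 60), 3), rep(0.4, 60))
  # unit impulse: symmetric bump, peak below one
  x <- c(rep(0, 10), 1, rep(0, 10))
  s <- smooth_intensity(x, 2)
  expect_lt(max(s), 1)
  expect_equal(which.max(s), 11L)
  expect_equal(s[11 - (1:5)], s[11 + (1:5)])
  # sigma -> 0 limit returns the input
  x2 <- c(0.1, 0.8, 0.3, 0.55, 0)
  expect_equal(smooth_intensity(x2, 1e-3), x2, tolerance = 1e-6)
  # output stays in [0, 1] for unit-interval input
  set.seed(2)
  x3 <- runif(200)
  s3 <- smooth_intensity(x3, 4)
  expect_true(all(s3 >= 0 & s3 <= 1))
  expect_error(smooth_intensity(numeric(0), 1), "non-empty")
  expect_error(smooth_intensity(x2, 0), "> 0")
})

test_that("active-frame detection applies an inclusive threshold", {
  m <- detect_active_frames(c(0.1, 0.6, 0.7, 0.2), 0.5)
  expect_identical(which(m) - 1L, c(1L, 2L))
  expect_identical(sum(m), 2L)
  expect_false(any(detect_active_frames(rep(0, 10), 0.5)))
  # boundary rule: exactly at threshold counts as active
  expect_true(all(detect_active_frames(rep(0.5, 5), 0.5)))
})

test_that("raising the activation threshold never adds active frames", {
  set.seed(31)
  for (i in 1:20) {
    x <- smooth_intensity(runif(120), 2)
    t1 <- runif(1, 0.05, 0.45)
    t2 <- t1 + runif(1, 0.05, 0.5)
    lo <- detect_active_frames(x, t1)
    hi <- detect_active_frames(x, t2)
    expect_true(all(which(hi) %in% which(lo)))
  }
})

test_that("phase segmentation labels trapezoids onset/apex/offset in order", {
  x <- c(rep(0.02, 5), seq(0.1, 0.9, length.out = 9), rep(0.9, 6),
         seq(0.82, 0.1, length.out = 9), rep(0.02, 5))
  act <- detect_active_frames(x, 0.5)
  ph <- segment_phases(x, act)
  seg <- activation_segments(ph)
  expect_equal(nrow(seg), 1L)
  expect_true(all(seg$onset_frames > 0, seg$apex_frames > 0,
                  seg$offset_frames > 0))
  inside <- as.character(ph$phase[!is.na(ph$segment)])
  expect_identical(rle(inside)$values, c("onset", "apex", "offset"))
  expect_true(all(ph$phase[is.na(ph$segment)] == "neutral"))

  # single-frame activation is pure apex
  y <- c(0.1, 0.1, 0.9, 0.1, 0.1)
  ph1 <- segment_phases(y, detect_active_frames(y, 0.5))
  expect_identical(as.character(ph1$phase), c("neutral", "neutral", "apex",
                                              "neutral", "neutral"))

  # two separated trapezoids give two segments
  z <- c(x, x)
  ph2 <- segment_phases(z, detect_active_frames(z, 0.5))
  expect_equal(max(ph2$segment, na.rm = TRUE), 2L)
})

test_that("au_intensity recovers noise-free trapezoid boundaries within the kernel width", {
  sigma <- 3
  p <- archetype_params("C")
  p$score_noise_sd <- 0
  p$disgust_sync_prob <- 0
  gen <- generate_au_scores(p, aus = au_names()[1:4], n_frames = 400,
                            seed = 42)
  ii <- au_intensity(gen$scores, c(A = -2, B = 0), sigma_frames = sigma,
                     threshold = 0.5)
  tol <- ceiling(sigma)
  for (a in unique(gen$truth$episodes$au)) {
    eps <- gen$truth$episodes[gen$truth$episodes$au == a, ]
    d <- ii[ii$au == a, ]
    runs <- rle(d$active)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    det_start <- (starts[runs$values]) - 1L  # 0-based
    det_end <- ends[runs$values]             # half-open
    # drop episodes whose apex never crosses the threshold
    eps <- eps[eps$apex >= 0.55, ]
    expect_equal(length(det_start), nrow(eps))
    for (j in seq_len(nrow(eps))) {
      # expected crossing frames of the true trapezoid at threshold 0.5
      on <- eps$end_frame[j] - eps$start_frame[j]
      # reconstruct ramp lengths from the stored profile via the raw intensity
      prof <- d$intensity[(eps$start_frame[j] + 1):(eps$end_frame[j])]
      cross <- range(which(prof >= 0.5))
      true_start <- eps$start_frame[j] + cross[1] - 1L
      true_end <- eps$start_frame[j] + cross[2]
      expect_lte(abs(det_start[j] - true_start), tol)
      expect_lte(abs(det_end[j] - true_end), tol)
    }
  }
})

test_that("per-AU Platt models are honored and missing models rejected", {
  sc <- tibble::tibble(frame = rep(0:9, 2),
                       au = rep(c("AU1", "AU2"), each = 10),
                       score = rep(1, 20))
  models <- list(AU1 = c(A = -2, B = 0), AU2 = c(A = -0.5, B = 0))
  ii <- au_intensity(sc, models, sigma_frames = 1)
  i1 <- unique(round(ii$intensity[ii$au == "AU1"], 10))
  i2 <- unique(round(ii$intensity[ii$au == "AU2"], 10))
  expect_equal(i1, round(platt_probability(models$AU1, 1), 10))
  expect_equal(i2, round(platt_probability(models$AU2, 1), 10))
  expect_error(au_intensity(sc, list(AU1 = c(A = -2, B = 0))), "AU2")
})
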