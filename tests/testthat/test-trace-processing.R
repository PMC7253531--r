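test_that("smooth_trace is a centred moving average with shrunken edges", {
  fps <- 20
  expect_equal(smooth_trace(raw_trace(rep(3, 50), fps))$values, rep(3, 50))

  # unit impulse mid-trace spreads to 0.2 over the 5 covered frames
  x <- numeric(41); x[21] <- 1
  sm <- smooth_trace(raw_trace(x, fps), 5)$values
  expect_equal(sm[19:23], rep(0.2, 5))
  expect_equal(sum(sm), 1)                 # mass preserved in the interior
  expect_length(sm, 41)

  # edges: first value averages over a single frame, second over three
  y <- c(1, numeric(20))
  smy <- smooth_trace(raw_trace(y, fps), 5)$values
  expect_equal(smy[1], 1)
  expect_equal(smy[2], 1 / 3)

  expect_error(smooth_trace(raw_trace(x, fps), 4),
               class = "caltrace_param_error")
  expect_error(smooth_trace(raw_trace(1:3, fps), 5),
               class = "caltrace_param_error")
})

test_that("correct_drift removes slow drift while preserving the baseline", {
  fps <- 20
  t <- (0:(300 * fps - 1)) / fps

  # constant trace unchanged
  cst <- correct_drift(raw_trace(rep(7, length(t)), fps))
  expect_equal(cst$values, rep(7, length(t)), tolerance = 1e-9)

  # linear ramp on baseline 100: corrected stays within 1% of 100 away from
  # the edge blocks (natural-spline extrapolation is linear there too)
  ramp <- 100 + 0.05 * t
  cor <- correct_drift(raw_trace(ramp, fps))$values
  inner <- (25 * fps):(275 * fps)
  expect_true(all(abs(cor[inner] - mean(ramp)) / 100 < 0.01))
  # baseline (mean) preserved exactly
  expect_equal(mean(cor), mean(ramp), tolerance = 1e-9)

  # sinusoidal drift (period >= 100 s) is attenuated
  sine <- 100 + 5 * sin(2 * pi * t / 150)
  cors <- correct_drift(raw_trace(sine, fps))$values
  expect_lt(sd(cors), 0.1 * sd(sine))

  expect_error(correct_drift(raw_trace(rep(1, 30 * fps), fps), block_s = 25),
               class = "caltrace_param_error")
})

test_that("correct_drift preserves transient amplitudes on slow drift", {
  fps <- 20; dur <- 300
  model <- transient_model(amplitude = 5, tau = 1)
  times <- seq(20, 280, by = 20)
  clean <- reconstruct(grid_train(times, dur), model,
                       list(fps = fps, duration = dur))$values
  t <- (seq_along(clean) - 1) / fps
  drifted <- 100 + clean + 2 * sin(2 * pi * 0.01 * t)   # 0.01 Hz drift
  cor <- correct_drift(raw_trace(drifted, fps))$values
  for (tt in times) {
    # peak height against the local pre-onset baseline (0.5 s before)
    peak <- max(cor[(tt * fps + 1):(tt * fps + 5)]) - cor[tt * fps - 9]
    expect_lt(abs(peak - 5) / 5, 0.05)
  }
})

test_that("smoothing and drift correction are linear operators", {
  fps <- 20
  set.seed(42)
  a <- rnorm(100 * fps, 100, 2)
  b <- 50 + 0.02 * seq_len(100 * fps)
  for (op in list(function(x) smooth_trace(raw_trace(x, fps))$values,
                  function(x) correct_drift(raw_trace(x, fps))$values)) {
    expect_equal(op(a + b), op(a) + op(b), tolerance = 1e-9)
  }
})

test_that("F0 estimation is robust to sparse transients and guards zero", {
  fps <- 20
  expect_equal(estimate_f0(raw_trace(rep(12.5, 100), fps)), 12.5)

  # baseline 100 with sparse positive transients (<10% of frames)
  x <- rep(100, 2000)
  x[sample.int(2000, 150)] <- 100 + runif(150, 5, 20)
  expect_lt(abs(estimate_f0(raw_trace(x, fps)) - 100) / 100, 0.01)

  expect_error(estimate_f0(raw_trace(rep(0, 100) + 0, fps)),
               class = "caltrace_baseline_error")
})

test_that("normalize_dff applies the percent formula and inverts exactly", {
  fps <- 20
  f0 <- 80
  tr <- raw_trace(c(80, 80.8, 160, 40), fps)
  nt <- normalize_dff(tr, f0)
  expect_equal(nt$values, c(0, 1, 100, -50))
  # algebraic round trip
  expect_equal(f0 * (1 + nt$values / 100), tr$values)
  # strictly monotone in F*
  expect_true(all(diff(normalize_dff(raw_trace(sort(runif(50, 1, 200)), fps),
                                     f0)$values) > 0))
  expect_error(normalize_dff(tr, 0), class = "caltrace_param_error")
})

test_that("fov_extent converts pixel counts to millimetres", {
  expect_equal(fov_extent(960, 4.40), 4.224)
  expect_equal(fov_extent(720, 4.40), 3.168)
  expect_equal(fov_extent(0, 4.40), 0)
  expect_error(fov_extent(-1, 4.40), class = "caltrace_param_error")
})

test_that("detect_rois finds blob centres and enforces separation", {
  # empty image -> empty set
  expect_equal(nrow(detect_rois(matrix(0, 32, 32), 7, 0.5)$centers), 0)

  # three Gaussian blobs, 20 px apart; oracle = the blob centres themselves
  img <- matrix(0, 64, 64)
  centers <- rbind(c(15, 15), c(15, 40), c(40, 25))   # 0-based truth
  for (k in 1:3) {
    for (dy in -6:6) for (dx in -6:6) {
      y <- centers[k, 1] + dy + 1; x <- centers[k, 2] + dx + 1
      img[y, x] <- img[y, x] + exp(-(dy^2 + dx^2) / 8)
    }
  }
  rois <- detect_rois(img, size_px = 7, intensity_threshold = 0.5,
                      min_separation_px = 10)
  expect_equal(nrow(rois$centers), 3)
  ord <- order(rois$centers[, 1], rois$centers[, 2])
  expect_true(all(abs(rois$centers[ord, ] - centers[order(centers[, 1]), ]) <= 1))
  expect_equal(rois$size_px, 7L)
  expect_equal(rois$size_px^2, 49)   # 7-px square ROI covers 49 pixels
})

test_that("extract_traces averages ROI pixels per frame", {
  g <- test_geometry(duration = 1, frame_shape = c(16, 16))
  # constant movie -> constant trace
  mv <- movie_stack(array(5, dim = c(20, 16, 16)), g)
  tr <- extract_traces(mv, roi_set(rbind(c(7, 7)), 7))
  expect_equal(tr[[1]]$values, rep(5, 20))

  # ROI pixels set to 0..48 -> mean 24 every frame
  f <- array(0, dim = c(20, 16, 16))
  for (i in 1:20) f[i, 5:11, 5:11] <- matrix(0:48, 7, 7)
  tr2 <- extract_traces(movie_stack(f, g), roi_set(rbind(c(7, 7)), 7))
  expect_equal(tr2[[1]]$values, rep(24, 20))

  # single-pixel ROI returns that pixel's series
  f[, 3, 4] <- seq_len(20)
  tr3 <- extract_traces(movie_stack(f, g), roi_set(rbind(c(2, 3)), 1))
  expect_equal(tr3[[1]]$values, as.numeric(1:20))

  expect_error(extract_traces(mv, roi_set(rbind(c(0, 0)), 7)),
               class = "caltrace_param_error")
})

test_that("movie rendering round-trips through trace extraction", {
  g <- test_geometry(duration = 10, frame_shape = c(32, 32))
  m <- transient_model(amplitude = 2, tau = 1)
  st <- grid_train(c(2, 5, 5.4), 10)
  mov <- render_movie(list(list(spikes = st, center = c(15, 15))), m, g,
                      baseline = 100, noise_sd = 0)
  got <- extract_traces(mov, roi_set(rbind(c(15, 15)), 7))[[1]]
  want <- render_fluorescence(st, m, g, baseline = 100, noise_sd = 0)
  expect_lt(max(abs(got$values - want$values) / want$values), 0.01)

  # empty population -> flat background
  bg <- render_movie(list(), m, g, baseline = 50, noise_sd = 0)
  expect_equal(range(bg$frames), c(50, 50))

  # margin violation
  expect_error(render_movie(list(list(spikes = st, center = c(0, 0))), m, g),
               class = "caltrace_param_error")
})

test_that("movies survive a 16-bit TIFF round trip", {
  g <- test_geometry(duration = 2, frame_shape = c(24, 24))
  st <- grid_train(c(0.5, 1), 2)
  mov <- render_movie(list(list(spikes = st, center = c(11, 11))),
                      transient_model(amplitude = 5), g,
                      baseline = 1000, noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mov, path)
  back <- read_movie_tiff(path, g)
  expect_equal(dim(back$frames), dim(mov$frames))
  # 16-bit quantization: worst-case error one grey level
  expect_lt(max(abs(back$frames - mov$frames)), 1.01)
})
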