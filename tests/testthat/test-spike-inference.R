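test_that("single_transient follows the exponential template", {
  m <- transient_model(amplitude = 2, tau = 1, threshold = 0.8)
  expect_equal(single_transient(0, m), 2)
  expect_equal(single_transient(1, m), 2 / exp(1))
  expect_equal(single_transient(-0.5, m), 0)
  # numeric integral over [0, inf) ~ amplitude * tau
  expect_equal(integrate(single_transient, 0, Inf, model = m)$value,
               2 * 1, tolerance = 1e-6)
})

test_that("peel recovers noiseless transients exactly and honours the threshold", {
  m <- transient_model(amplitude = 2, tau = 1, threshold = 0.8)

  # all-zero trace -> empty train, zero residual
  zero <- normalized_trace(rep(0, 200), 100, 20)
  p0 <- peel(zero, m)
  expect_length(p0$spikes$times, 0)
  expect_equal(max(abs(p0$residual$values)), 0)

  # one transient at 5.0 s -> one spike at 5.0 s, residual < 1e-6
  tr <- noiseless_dff(5, 20, m)
  p1 <- peel(tr, m)
  expect_equal(p1$spikes$times, 5.0)
  expect_lt(max(abs(p1$residual$values)), 1e-6)
  expect_true(p1$converged)

  # amplitude below the 0.8% detection threshold -> nothing detected
  weak <- noiseless_dff(5, 20, transient_model(amplitude = 0.5, tau = 1))
  expect_length(peel(weak, m)$spikes$times, 0)
})

test_that("reconstruct inverts peel on noiseless multi-spike input", {
  m <- transient_model(amplitude = 1.5, tau = 1, threshold = 0.8)
  times <- c(2, 2.5, 2.8, 7, 10, 10.2, 15.55)
  tr <- noiseless_dff(times, 20, m)
  p <- peel(tr, m)
  expect_equal(p$spikes$times, round(times * 20) / 20, tolerance = 1e-9)
  rec <- reconstruct(p$spikes, m, list(fps = 20, duration = 20))
  expect_lt(max(abs(rec$values - tr$values)), 1e-6)

  # empty train -> zero trace
  expect_equal(reconstruct(spike_train(numeric(0), 5), m, 20)$values,
               rep(0, 100))

  # two spikes 0.5 s apart: peak after the second = A * (1 + exp(-0.5/tau))
  two <- reconstruct(grid_train(c(1, 1.5), 5), m,
                     list(fps = 20, duration = 5))
  expect_equal(max(two$values), 1.5 * (1 + exp(-0.5)), tolerance = 1e-9)
})

test_that("noiseless detection is complete for resolvable spike trains", {
  # every spike with amplitude >= threshold and ISI > 2 frames is found
  # within +/- 1 frame
  m <- transient_model(amplitude = 1, tau = 1, threshold = 0.8)
  for (s in 1:10) {
    set.seed(300 + s)
    n_spk <- sample(3:12, 1)
    times <- sort(sample(seq(0.2, 55, by = 0.05), n_spk))
    while (any(diff(times) <= 0.1)) {
      times <- sort(sample(seq(0.2, 55, by = 0.05), n_spk))
    }
    tr <- noiseless_dff(times, 60, m)
    got <- peel(tr, m)$spikes$times
    expect_length(got, n_spk)
    expect_true(all(abs(got - times) <= 0.05 + 1e-9))
  }
})

test_that("peel matches a plain-R reference scan on random inputs", {
  # independent single-pass reference: threshold crossings of the residual
  # computed with plain R vector operations
  ref_peel <- function(x, model, fps, min_dur = 2) {
    tmpl <- single_transient((0:(length(x) - 1)) / fps, model)
    onsets <- integer(0)
    res <- x
    repeat {
      above <- which(res > model$threshold)
      found <- FALSE
      for (i in above) {
        if (i %in% onsets) next
        j <- i
        while (j <= length(res) && res[j] >= model$threshold / 2) j <- j + 1
        if ((j - i) >= min_dur || j > length(res)) {
          onsets <- c(onsets, i)
          idx <- i:length(res)
          res[idx] <- res[idx] - tmpl[idx - i + 1]
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
    sort((onsets - 1) / fps)
  }
  m <- transient_model(amplitude = 1, tau = 1, threshold = 0.8)
  for (s in 1:5) {
    set.seed(700 + s)
    times <- sort(runif(6, 1, 25))
    times <- round(times * 20) / 20
    times <- times[c(TRUE, diff(times) > 0.15)]
    tr <- noiseless_dff(times, 30, m)
    x_noisy <- tr$values + rnorm(length(tr$values), 0, 0.05)
    got <- peel(normalized_trace(x_noisy, 100, 20), m)$spikes$times
    want <- ref_peel(x_noisy, m, 20)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("peel is robust at noise SD = amplitude / 8", {
  m <- transient_model(amplitude = 1, tau = 1, threshold = 0.8)
  spec <- phenotype_spec("low", background_rate = 0.2, burst_rate = 0,
                         spikes_per_burst_mean = 0, intra_burst_isi = 0,
                         duration = 100)
  hits <- 0; total <- 0; fp <- 0; dur_total <- 0
  set.seed(1234)
  for (s in 1:20) {
    st <- simulate_spike_train(spec, 500 + s)
    truth <- round(st$times * 20) / 20
    tr <- noiseless_dff(st$times, 100, m)
    noisy <- normalized_trace(tr$values + rnorm(length(tr$values), 0, 1 / 8),
                              100, 20)
    got <- peel(noisy, m)$spikes$times
    # under noise the threshold crossing can slip a frame or two, so hits
    # are matched within +/- 2 frames (100 ms); anything unmatched is a
    # genuine false positive
    mm <- match_spikes(truth, got, tol_s = 0.1)
    hits <- hits + mm$hits; total <- total + length(truth)
    fp <- fp + mm$false_pos; dur_total <- dur_total + 100
  }
  expect_gte(hits / total, 0.9)
  expect_lte(fp / (dur_total / 10), 0.1)
})

test_that("peeling terminates and flags non-convergence", {
  m <- transient_model(amplitude = 1, tau = 1, threshold = 0.8)
  tr <- noiseless_dff(c(1, 3, 5, 7), 10, m)
  expect_warning(p <- peel(tr, m, max_iterations = 2))
  expect_false(p$converged)
  expect_length(p$spikes$times, 2)

  # after normal termination no Schmitt event remains in the residual
  p2 <- peel(tr, m)
  expect_true(p2$converged)
  expect_lt(max(p2$residual$values), m$threshold)
})

test_that("per-trace amplitude calibration tracks the true event height", {
  true_m <- transient_model(amplitude = 2.5, tau = 1, threshold = 0.8)
  tr <- noiseless_dff(c(3, 10, 17, 24), 30, true_m)
  p <- peel(tr, transient_model(amplitude = 1, tau = 1, threshold = 0.8),
            calibrate = TRUE)
  expect_equal(p$model$amplitude, 2.5, tolerance = 0.05)
  expect_length(p$spikes$times, 4)
})
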