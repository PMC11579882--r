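test_that("zero-lag Butterworth: DC gain, attenuation and phase", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  # constant through a low-pass is unchanged; through a 20 Hz high-pass ~ 0
  const <- rep(2.5, length(t))
  expect_lt(max(abs(butterworth_zero_lag(const, rate, 6, "low") - 2.5)), 1e-9)
  expect_lt(max(abs(butterworth_zero_lag(const, rate, 20, "high"))), 1e-6 * 2.5)
  # sinusoid at cutoff/10: attenuation below 1 % (two-pass analytic gain
  # 1/(1+(f/fc)^4) ~ 0.9999) and zero lag
  x <- sin(2 * pi * 0.6 * t)
  y <- butterworth_zero_lag(x, rate, 6, "low")
  i <- 100:(length(t) - 100)
  gain <- max(abs(y[i])) / max(abs(x[i]))
  expect_gt(gain, 0.99)
  expect_equal(gain, 1 / (1 + (0.6 / 6)^4), tolerance = 1e-3)
  cc <- stats::ccf(y[i], x[i], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("zero-lag filtering preserves symmetry", {
  rate <- 100
  n <- 1001
  pulse <- exp(-((seq_len(n) - 501) / 30)^2)
  y <- butterworth_zero_lag(pulse, rate, 6, "low")
  expect_lt(max(abs(y - rev(y))), 1e-9)
})

test_that("filter rejects invalid cutoffs and too-short series", {
  expect_error(butterworth_zero_lag(rnorm(100), 100, 50, "low"), "Nyquist")
  expect_error(butterworth_zero_lag(rnorm(100), 100, 60, "low"), "Nyquist")
  expect_error(butterworth_zero_lag(rnorm(5), 100, 6, "low"), "short")
})

test_that("noisy-channel detection flags large-amplitude channels", {
  set.seed(4)
  sig <- matrix(rnorm(2000 * 8), ncol = 8)
  expect_equal(sum(detect_noisy_channels(sig)), 0)
  sig[, 5] <- sig[, 5] * 100
  expect_equal(which(detect_noisy_channels(sig)), 5L)
  expect_error(detect_noisy_channels(matrix(rnorm(100), ncol = 1)), "two channels")
  # all channels equally huge: none stands out -> empty, not an error
  expect_equal(sum(detect_noisy_channels(sig * 100)), 1L)
})

test_that("noisy-channel detection recovers the generator's labels", {
  fx <- emg_fixture()
  truth_noisy <- fx$cfg$channel_map == "noisy"
  mask <- fx$proc$noisy_mask
  sensitivity <- sum(mask & truth_noisy) / sum(truth_noisy)
  expect_gte(sensitivity, 0.9)
  expect_equal(sum(mask & !truth_noisy), 0)
})

test_that("re-referencing removes the noisy channels' average contribution", {
  set.seed(7)
  n <- 1000; p <- 6
  e <- matrix(rnorm(n * p), ncol = p)
  e[, 3] <- e[, 3] + 40 * sin(seq_len(n) / 50)   # contaminated electrode
  s <- e - rowMeans(e)                            # hardware average reference
  rec <- structure(list(time = seq_len(n) / 2000, rate = 2000, signals = s,
                        channel_map = rep("tib_ant", p), gain = 23),
                   class = "EmgRecording")
  mask <- rep(FALSE, p); mask[3] <- TRUE
  out <- rereference(rec, mask)
  clean <- which(!mask)
  expected <- e[, clean] - rowMeans(e[, clean])
  expect_lt(max(abs(out$signals[, clean] - expected)), 1e-9)
  expect_true(all(out$signals[, 3] == 0))
  # empty mask: identity (signals already have zero row mean)
  out0 <- rereference(rec, rep(FALSE, p))
  expect_lt(max(abs(out0$signals - s)), 1e-9)
  # all but one flagged: the survivor is referenced against itself -> zero
  mask1 <- rep(TRUE, p); mask1[2] <- FALSE
  out1 <- rereference(rec, mask1)
  expect_lt(max(abs(out1$signals)), 1e-12)
  # idempotence on clean data
  out2 <- rereference(out, mask)
  expect_lt(max(abs(out2$signals - out$signals)), 1e-9)
  expect_error(rereference(rec, rep(TRUE, p)), "clean")
})

test_that("envelope extraction: window parity, spike robustness, zero input", {
  n <- 8000; rate <- 2000
  set.seed(8)
  base <- matrix(rnorm(2 * n, sd = 0.1), ncol = 2)
  rec <- structure(list(time = seq_len(n) / rate, rate = rate, signals = base,
                        channel_map = c("a", "b"), gain = 23),
                   class = "EmgRecording")
  env <- extract_envelope(rec)
  expect_equal(env$window_samples, 321)          # round(0.16 * 2000) forced odd
  expect_true(all(env$envelopes >= 0))
  # a single extreme spike barely perturbs the median envelope, while a
  # linear 6 Hz low-pass envelope is blown up by it (the reason a moving
  # median is used at all)
  spiked <- base
  spiked[4000, 1] <- 50
  rec2 <- rec; rec2$signals <- spiked
  env2 <- extract_envelope(rec2)
  lin_env <- function(s) butterworth_zero_lag(
    abs(butterworth_zero_lag(s, rate, 20, "high")), rate, 6, "low")
  med_inflation <- env2$envelopes[4000, 1] - env$envelopes[4000, 1]
  lin_inflation <- lin_env(spiked[, 1])[4000] - lin_env(base[, 1])[4000]
  expect_lt(med_inflation, 0.2 * lin_inflation)
  # brute-force median oracle at the spike instant
  hp <- butterworth_zero_lag(spiked[, 1], rate, 20, "high")
  w <- 160
  expect_equal(env2$envelopes[4000, 1],
               stats::median(abs(hp[(4000 - w):(4000 + w)])), tolerance = 1e-12)
  rec3 <- rec; rec3$signals <- matrix(0, n, 2)
  expect_true(all(extract_envelope(rec3)$envelopes == 0))
  expect_error(extract_envelope(structure(list(time = 1:10 / rate, rate = rate,
                                               signals = matrix(0, 10, 1)),
                                          class = "EmgRecording")), "window")
})

test_that("task-maximum normalisation", {
  mk <- function(env) structure(list(time = seq_len(nrow(env)), rate = 2000,
                                     envelopes = env, labels = c("a", "b")),
                                class = "EnvelopeSet")
  a <- mk(cbind(c(0, 2, 1), c(0, 0, 0)))
  b <- mk(cbind(c(0, 4, 1), c(0, 0, 0)))
  out <- suppressMessages(normalize_envelopes(list(a, b)))
  expect_equal(max(out[[1]]$envelopes[, 1]), 2 / 4)   # peakA / peakB
  expect_equal(max(out[[2]]$envelopes[, 1]), 1)
  expect_true(all(out[[1]]$envelopes[, 2] == 0))      # all-zero channel, no NaN
  expect_false(any(is.nan(out[[1]]$envelopes)))
  single <- suppressMessages(normalize_envelopes(list(b)))[[1]]
  expect_equal(max(single$envelopes[, 1]), 1)
})

test_that("muscle averaging: passthrough, duplicates, missing muscle", {
  n <- 50
  env7 <- matrix(runif(n * 7), ncol = 7)
  set1 <- structure(list(time = seq_len(n), rate = 100, envelopes = env7,
                         labels = wearlab:::MUSCLES), class = "EnvelopeSet")
  out <- muscle_envelopes(set1)
  expect_equal(unname(out$envelopes), unname(env7))
  dup <- structure(list(time = seq_len(n), rate = 100,
                        envelopes = cbind(env7, env7),
                        labels = rep(wearlab:::MUSCLES, 2)), class = "EnvelopeSet")
  expect_equal(muscle_envelopes(dup)$envelopes, out$envelopes)
  expect_error(muscle_envelopes(set1, assignment = rep("tib_ant", 7)), "soleus")
})

test_that("muscle envelopes recovered from the synthetic grid match profiles", {
  fx <- emg_fixture()
  u <- (fx$rec$time / fx$cfg$stride_period) %% 1
  env <- fx$proc$muscle$envelopes
  for (m in colnames(env)) {
    prof <- eval_profile(fx$cfg$envelope_profiles[[m]], u)
    expect_gt(cor(env[, m], prof), 0.9)
  }
  expect_true(all(env >= 0 & env <= 1))
})

test_that("envelope bounds hold on random recordings (property)", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 4000
    sig <- matrix(rnorm(n * 4, sd = runif(1, 0.01, 10)), ncol = 4)
    rec <- structure(list(time = seq_len(n) / 2000, rate = 2000, signals = sig,
                          channel_map = letters[1:4], gain = 23),
                     class = "EmgRecording")
    env <- suppressMessages(normalize_envelopes(extract_envelope(rec)))[[1]]
    expect_true(all(env$envelopes >= 0 & env$envelopes <= 1 + 1e-12))
  }
})
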