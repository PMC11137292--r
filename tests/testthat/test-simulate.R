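test_that("the spike template follows the damped-cosine form", {
  p <- spike_template_params(A = 2, tau1 = 1.5e-3, tau2 = 0.8e-3)
  v <- spike_template(p, sampling_rate = 20000, support = 56 / 20000)
  expect_length(v, 56L)
  expect_true(max(abs(v)) <= 2 + 1e-12)
  # value at the grid origin equals A when tau_ph = 0
  t0 <- which.min(abs(seq_len(56) - 1 - 28))  # t = 0 sample
  expect_equal(v[t0], 2)
  # zero amplitude produces silence
  p0 <- spike_template_params(A = 0, tau1 = 1e-3, tau2 = 1e-3)
  expect_equal(spike_template(p0, 20000, 56 / 20000), rep(0, 56))
  expect_error(spike_template_params(A = 1, tau1 = -1, tau2 = 1), "> 0")
  expect_error(spike_template(p, 20000, 0), "> 0")
})

test_that("the Gaussian envelope kills the template beyond 3 widths", {
  p <- spike_template_params(A = 1, tau1 = 1.6e-3, tau2 = 0.9e-3)
  v <- spike_template(p, sampling_rate = 40000, support = 12e-3)
  t <- (seq_along(v) - 1) / 40000 - 6e-3
  expect_true(all(abs(v[abs(t) > 3 * p$tau2]) < 1e-6 * p$A))
})

test_that("Poisson spike trains are seeded, sorted and rate-consistent", {
  expect_identical(generate_spike_times(3.3, 0), numeric(0))
  a <- generate_spike_times(3.3, 50, seed = 5)
  b <- generate_spike_times(3.3, 50, seed = 5)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 50))
  # empirical rate over 50 seeded runs within 3 sigma of 3.3 Hz
  counts <- vapply(1:50, function(s)
    length(generate_spike_times(3.3, 200, seed = s)), numeric(1))
  rate_hat <- mean(counts) / 200
  se <- sqrt(3.3 / (200 * 50))
  expect_lt(abs(rate_hat - 3.3), 3 * se)
})

test_that("the refractory veto enforces the minimum interval", {
  st <- generate_spike_times(100, 20, seed = 9, refractory = 0.05)
  expect_true(all(diff(st) >= 0.05))
})

test_that("additive noise hits the requested level and is seeded", {
  sig <- sin(seq(0, 20 * pi, length.out = 1e6))
  noisy <- add_noise_at_snr(sig, snr = 4, seed = 31)
  expect_identical(noisy, add_noise_at_snr(sig, snr = 4, seed = 31))
  target <- max(abs(sig)) / 4
  expect_lt(abs(stats::sd(noisy - sig) - target) / target, 0.02)
  # rms convention and noise-level convention scale as documented
  n2 <- add_noise_at_snr(sig, 2, seed = 1, sd_ref = "rms")
  expect_lt(abs(stats::sd(n2 - sig) - sqrt(mean(sig^2)) / 2) /
              (sqrt(mean(sig^2)) / 2), 0.05)
  n3 <- add_noise_at_snr(sig, 0.5, seed = 1, sd_ref = "noise-level")
  expect_lt(abs(stats::sd(n3 - sig) - 0.5 * sqrt(mean(sig^2))) /
              (0.5 * sqrt(mean(sig^2))), 0.05)
  expect_identical(add_noise_at_snr(sig, Inf), sig)
  expect_error(add_noise_at_snr(rep(0, 10), 2), "all-zero")
  expect_error(add_noise_at_snr(sig, -1), "> 0")
})

test_that("simulated spike datasets have the requested class structure", {
  es <- simulate_dataset1(n_per_class = 25, snr = 1.25, duration = 20,
                          seed = 42)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es), c(100L, 56L))
  expect_equal(as.numeric(table(attr(es, "label"))), rep(25, 4))
  expect_true(all(es >= 0 & es <= 1))
  # same configuration + seed reproduces the epoch matrix bit for bit
  es2 <- simulate_dataset1(n_per_class = 25, snr = 1.25, duration = 20,
                           seed = 42)
  expect_identical(unclass(es), unclass(es2))
  expect_error(simulate_dataset1(n_per_class = 1000, duration = 5, seed = 1),
               "increase 'duration'")
})

test_that("spike epochs out-radius noise epochs at moderate noise", {
  es <- simulate_dataset1(n_per_class = 60, snr = 2.0, duration = 40,
                          seed = 77)
  feats <- extract_features_batch(es, graph = "wvg")
  rmean <- rowMeans(feats[, 1:56])
  lab <- feats$label
  expect_gt(mean(rmean[lab == 3]), mean(rmean[lab == 4]))
})

test_that("the pipeline width is 2N end to end", {
  es <- simulate_dataset1(n_per_class = 5, snr = 0.5, duration = 10,
                          seed = 3)
  feats <- extract_features_batch(es, graph = "wvg")
  expect_equal(ncol(feats), 2L * 56L + 1L)  # 112 features + label
})

test_that("the EEG surrogate is seeded and segments 4:1", {
  sur <- simulate_eeg_surrogate(10, seed = 8)
  expect_equal(dim(sur$signals), c(10L, 4096L))
  expect_equal(sur$label, rep_len(1:5, 10))
  sur2 <- simulate_eeg_surrogate(10, seed = 8)
  expect_identical(sur$signals, sur2$signals)
  ep <- surrogate_epochs(sur, N = 1024)
  expect_equal(dim(ep), c(40L, 1024L))
  expect_equal(attr(ep, "label"), rep(rep_len(1:5, 10), each = 4L))
  expect_true(all(ep >= 0 & ep <= 1))
})

test_that("surrogate classes separate in Gershgorin center medians", {
  # ictal-like bursts (class 5) versus low-amplitude interictal (class 3)
  sur <- simulate_eeg_surrogate(16, classes = c(3, 5), seed = 12)
  ep <- surrogate_epochs(sur, N = 256)
  feats <- extract_features_batch(ep, graph = "wvg")
  cmed <- rowMeans(feats[, 257:512])
  lab <- feats$label
  p <- stats::wilcox.test(cmed[lab == 5], cmed[lab == 3])$p.value
  expect_lt(p, 0.05)
})
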