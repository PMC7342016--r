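test_that("log-spaced grid matches the closed form and handles edge cases", {
  g <- log_spaced_grid(5, 31, 20)
  # independent oracle: equal steps in log space
  expect_equal(g$bin_centers, exp(seq(log(5), log(31), length.out = 20)))
  expect_equal(g$bin_centers[1], 5)
  expect_equal(g$bin_centers[20], 31)
  ratios <- g$bin_centers[-1] / g$bin_centers[-20]
  expect_equal(ratios, rep((31 / 5)^(1 / 19), 19))

  expect_equal(log_spaced_grid(5, 31, 2)$bin_centers, c(5, 31))
  expect_error(log_spaced_grid(5, 5, 20), "range")
  expect_error(log_spaced_grid(-1, 31, 20), "range")
  expect_error(log_spaced_grid(5, 31, 1), "n_bins")
})

test_that("band assignment rounds bin centers and reproduces the 5/6/9 split", {
  g <- log_spaced_grid(5, 31, 20)
  bands <- assign_bands(g)
  expect_named(bands, c("theta", "alpha", "beta"))
  expect_equal(vapply(bands, function(b) length(b$member_bins), 1L),
               c(theta = 5L, alpha = 6L, beta = 9L))
  # partition: every bin in exactly one band
  all_members <- sort(unname(unlist(lapply(bands, `[[`, "member_bins"))))
  expect_equal(all_members, 1:20)
  # rounding rule on specific centers, evaluated from the grid formula
  c5 <- 5 * (31 / 5)^(4 / 19)     # 7.341 -> 7 -> theta
  c6 <- 5 * (31 / 5)^(5 / 19)     # 8.081 -> 8 -> alpha
  c11 <- 5 * (31 / 5)^(10 / 19)   # 13.058 -> 13 -> alpha
  expect_equal(round(c5), 7); expect_true(5 %in% bands$theta$member_bins)
  expect_equal(round(c6), 8); expect_true(6 %in% bands$alpha$member_bins)
  expect_equal(round(c11), 13); expect_true(11 %in% bands$alpha$member_bins)
  # a two-bin grid leaves alpha empty -> not a valid partition
  expect_error(assign_bands(log_spaced_grid(5, 31, 2)), "no member bins")
  # ranges that miss part of the grid are rejected
  expect_error(assign_bands(g, list(theta = c(5, 7), alpha = c(8, 13))),
               "partition")
})

test_that("Morlet power peaks at the stimulus frequency and discards phase", {
  fs <- 250
  times <- seq(-600, 1099, by = 1000 / fs)
  w1 <- sin(2 * pi * 10 * times / 1000)
  w2 <- -w1                                  # opposite phase
  ep <- waveform_epochs(rbind(w1, w2), fs)
  g <- log_spaced_grid(5, 31, 20)
  tf <- morlet_power(ep, g)
  sel <- tf$times > 0 & tf$times < 800
  pw <- rowMeans(matrix(tf$power[1, 1, , sel], 20))
  expect_equal(g$bin_centers[which.max(pw)], 5 * (31 / 5)^(7 / 19)) # 9.79 Hz
  expect_gt(max(pw) / min(pw), 10)
  # phase invariance: magnitudes identical for sign-flipped input
  expect_equal(tf$power[1, 1, , ], tf$power[2, 1, , ])
  # zero input -> zero power
  tf0 <- morlet_power(waveform_epochs(matrix(0, 1, length(times)), fs), g)
  expect_equal(max(abs(tf0$power)), 0)
  # wavelet longer than the epoch is rejected
  short <- waveform_epochs(matrix(rnorm(50), 1), fs)
  expect_error(morlet_power(short, g), "wavelet")
})

test_that("baseline normalization is a dB ratio, invariant to global gain", {
  times <- seq(-600, 798, by = 2)
  p <- array(3, dim = c(2, 1, 3, length(times)))
  p[1, 1, 1, times >= 0] <- 30              # 10x baseline -> +10 dB
  tf <- manual_tf(p, times)
  out <- baseline_normalize(tf, c(-500, -300))
  expect_equal(out$power[2, 1, 1, 10], 0)   # value equals its baseline mean
  expect_equal(out$power[1, 1, 1, length(times)], 10)
  # doubling all raw values changes nothing
  tf2 <- manual_tf(2 * p, times)
  expect_equal(baseline_normalize(tf2, c(-500, -300))$power, out$power)
  # nonpositive baseline rejected
  bad <- manual_tf(array(0, dim = c(1, 1, 1, length(times))), times)
  expect_error(baseline_normalize(bad, c(-500, -300)), "baseline")
})

test_that("downsampling averages 20 ms bins anchored at stimulus onset", {
  times <- seq(0, 799, by = 1)              # 1000 Hz over [0, 800)
  const <- manual_tf(array(7, dim = c(1, 1, 1, length(times))), times,
                     normalized = TRUE)
  d <- downsample_tf(const, 50)
  expect_equal(length(d$times), 40)         # 800 / 20 half-open bins
  expect_equal(d$times, seq(0, 780, by = 20))
  expect_equal(as.vector(d$power), rep(7, 40))
  # linear ramp: each 20 ms mean equals the ramp at the bin midpoint
  ramp <- manual_tf(array(rep(0.5 * times + 2, each = 1),
                          dim = c(1, 1, 1, length(times))), times,
                    normalized = TRUE)
  dr <- downsample_tf(ramp, 50)
  expect_equal(as.vector(dr$power), 0.5 * (dr$times + 9.5) + 2)
  # incomplete trailing bin dropped
  times2 <- seq(0, 809, by = 1)
  part <- manual_tf(array(1, dim = c(1, 1, 1, length(times2))), times2,
                    normalized = TRUE)
  expect_equal(length(downsample_tf(part, 50)$times), 40)
  # rate must divide
  expect_error(downsample_tf(const, 33), "divisible")
})

test_that("band vectors: averaging yields one feature per electrode", {
  times <- seq(0, 80, by = 20)
  nchan <- 63
  set.seed(4)
  p <- array(rexp(2 * nchan * 20 * length(times)),
             dim = c(2, nchan, 20, length(times)))
  tf <- manual_tf(p, times, normalized = TRUE)
  tf$channels <- easycap_montage()$channel
  bands <- assign_bands(tf$grid)
  avg <- band_vectors(tf, bands$alpha, "average")
  expect_equal(dim(avg), c(2, 63, length(times)))
  cat_ <- band_vectors(tf, bands$alpha, "concatenate")
  expect_equal(dim(cat_), c(2, 6 * 63, length(times)))
  # explicit average check on one cell
  expect_equal(avg[1, 5, 2], mean(p[1, 5, bands$alpha$member_bins, 2]))
  # concatenate keeps channel-major layout within each bin
  expect_equal(cat_[1, 63 + 5, 2], p[1, 5, bands$alpha$member_bins[2], 2])
  # single-bin band: both modes identical
  single <- structure(list(name = "one", nominal_range = c(8, 8),
                           member_bins = 7L), class = "band_spec")
  expect_equal(band_vectors(tf, single, "average"),
               band_vectors(tf, single, "concatenate"),
               ignore_attr = TRUE)
})
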