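test_that("pseudo-trials average disjoint 25% shares", {
  x <- array(rep(1:40, 2), dim = c(40, 1, 1))
  attr(x, "object") <- rep(1L, 40)
  set.seed(1)
  ps <- make_pseudotrials(x, 4)
  expect_equal(dim(ps$vectors), c(1, 4, 1, 1))
  # exhaustive partition: pseudo-trial means recombine to the grand mean
  expect_equal(mean(ps$vectors), mean(1:40))
  # identical trials -> identical pseudo-trials
  xc <- array(5, dim = c(12, 2, 3))
  attr(xc, "object") <- rep(1:3, each = 4)
  psc <- make_pseudotrials(xc, 4)
  expect_equal(as.vector(psc$vectors), rep(5, length(psc$vectors)))
  # remainder trials are dropped: 41 trials -> shares of 10
  x41 <- array(c(1:41, 1:41), dim = c(41, 1, 2))
  attr(x41, "object") <- rep(1L, 41)
  set.seed(2)
  ps41 <- make_pseudotrials(x41, 4)
  expect_equal(dim(ps41$vectors)[2], 4)
  # each pseudo-trial is a mean of 10 integers in 1..41
  expect_true(all(ps41$vectors * 10 == round(ps41$vectors * 10)))
  # too few trials
  x3 <- array(1, dim = c(3, 1, 1)); attr(x3, "object") <- rep(1L, 3)
  expect_error(make_pseudotrials(x3, 4), "fewer")
})

test_that("pairwise linear SVM separates, and is antisymmetric in labels", {
  set.seed(3)
  a <- matrix(rnorm(40, mean = 2), 4)
  b <- matrix(rnorm(40, mean = -2), 4)
  fit <- train_pair_classifier(a, b)
  sc <- c(a %*% fit$weights + fit$bias, b %*% fit$weights + fit$bias)
  expect_equal(sc > 0, rep(c(TRUE, FALSE), each = 4)) # 100% training accuracy
  swapped <- train_pair_classifier(b, a)
  expect_equal(swapped$weights, -fit$weights)
  expect_equal(swapped$bias, -fit$bias)
  expect_error(train_pair_classifier(a[0, , drop = FALSE], b), "exemplar")
})

test_that("held-out accuracy under random labels converges to chance", {
  set.seed(4)
  accs <- replicate(150, {
    tr_a <- matrix(rnorm(32), 4); tr_b <- matrix(rnorm(32), 4)
    te <- matrix(rnorm(64), 8)
    fit <- train_pair_classifier(tr_a, tr_b)
    sc <- drop(te %*% fit$weights) + fit$bias
    mean((sc > 0) == rep(c(TRUE, FALSE), each = 4))
  })
  expect_gt(mean(accs), 0.44)
  expect_lt(mean(accs), 0.56)
})

test_that("time generalization is internally consistent and label-covariant", {
  # 4 trials per condition: pseudo-trials are a permutation of the trials,
  # so results are exactly invariant to relabeling of the objects
  mk <- function(perm = 1:3) {
    set.seed(7)
    x <- array(rnorm(12 * 6 * 3), dim = c(12, 6, 3))
    structure(x, times = c(0, 20, 40), object = rep(perm, each = 4))
  }
  tg <- cross_task_timegen(mk(), mk(), c(0, 20), c(0, 20, 40),
                           n_pseudo = 4, n_repeats = 3, seed = 5)
  expect_equal(dim(tg$accuracy), c(2, 3))
  expect_equal(dim(tg$per_pair), c(2, 3, 3, 3))
  # reported map = mean over the unordered pairs
  for (i in 1:2) for (j in 1:3) {
    m <- tg$per_pair[i, j, , ]
    expect_equal(tg$accuracy[i, j], mean(m[lower.tri(m)]))
    expect_equal(m, t(m))                    # symmetric slices
    expect_true(all(is.na(diag(m))))
  }
  # relabeling objects 1,2,3 -> 3,1,2 permutes per_pair consistently
  tg2 <- cross_task_timegen(mk(c(3, 1, 2)), mk(c(3, 1, 2)),
                            c(0, 20), c(0, 20, 40),
                            n_pseudo = 4, n_repeats = 3, seed = 5)
  perm <- c(3, 1, 2)   # new label of old object k
  expect_equal(tg2$per_pair[, , perm, perm], tg$per_pair)
  expect_equal(tg2$accuracy, tg$accuracy)
  # unknown analysis times rejected
  expect_error(cross_task_timegen(mk(), mk(), 10, c(0, 20), n_repeats = 1),
               "time axis")
})

test_that("within-task CV is perfect for noiseless separable patterns", {
  pat <- matrix(rnorm(4 * 6), 4, 6)
  x <- array(0, dim = c(16, 6, 2))
  for (tr in 1:16) x[tr, , ] <- pat[(tr - 1) %/% 4 + 1, ]
  attr(x, "times") <- c(0, 20)
  attr(x, "object") <- rep(1:4, each = 4)
  wt <- within_task_cv(x, c(0, 20), n_repeats = 2, seed = 1)
  expect_equal(as.vector(wt$accuracy), c(100, 100))
  expect_equal(dim(wt$per_pair), c(2, 4, 4))
})

test_that("electrode halves follow the montage fixture", {
  m <- easycap_montage()
  expect_equal(nrow(m), 63)
  expect_equal(sum(m$anterior), 35)
  expect_equal(sum(m$posterior), 37)
  expect_equal(sum(m$anterior & m$posterior), 9)
  ant <- m$channel[m$anterior]; post <- m$channel[m$posterior]
  expect_true("Oz" %in% post && !("Oz" %in% ant))
  expect_true("Cz" %in% post && "Cz" %in% ant)
  expect_true("Fp1" %in% ant && !("Fp1" %in% post))
  ep <- structure(list(data = array(1, dim = c(2, 3, 4)),
                       task = rep("perception", 2), object = 1:2,
                       times = c(0, 1, 2, 3),
                       channels = c("Oz", "Cz", "Fp1"), sampling_rate = 1000),
                  class = "epoch_set")
  expect_equal(electrode_subset(ep, "posterior")$channels, c("Oz", "Cz"))
  expect_equal(electrode_subset(ep, "anterior")$channels, c("Cz", "Fp1"))
  ep$channels <- c("Oz", "Cz", "Nonsense")
  expect_error(electrode_subset(ep, "anterior"), "unknown channel")
})

test_that("participant-specific alpha peak recovers a planted frequency", {
  cfg <- sim_config(n_participants = 1, n_channels = 16, n_objects = 6,
                    trials_per_object_per_task = 12, sampling_rate = 250,
                    shared_band = c(10, 10), posterior_fraction = 0.5,
                    snr = 0.5, alpha_background = 0.1, seed = 1)
  p <- simulate_participant(cfg, 1)
  pa <- peak_alpha_band(p$epochs$perception, times = seq(200, 600, 100),
                        n_repeats = 10, seed = 2)
  expect_equal(pa$peak, 10)
  expect_equal(pa$band, c(9, 11))
  # accuracy profile is informative around the peak
  expect_gt(pa$accuracy[["10"]], pa$accuracy[["13"]])
})

test_that("flat data tie-break selects the lowest candidate frequency", {
  fs <- 250
  times <- seq(-600, 1099, by = 1000 / fs)
  waves <- matrix(1, 8, length(times))       # constant: all trials identical
  ep <- waveform_epochs(waves, fs)
  ep$object <- rep(1:2, each = 4)
  pa <- peak_alpha_band(ep, times = c(200, 400), n_repeats = 2, seed = 3)
  expect_equal(pa$peak, 8)
  expect_equal(length(unique(round(pa$accuracy, 10))), 1)  # exact tie
})

test_that("alpha power split bins trials by sign and equalizes counts", {
  times <- seq(0, 780, by = 20)
  p <- array(0, dim = c(10, 2, 6, length(times)))
  stat <- c(rep(1, 3), rep(-1, 7))           # 3 enhanced, 7 suppressed
  for (tr in 1:10) p[tr, , , ] <- stat[tr]
  tf <- manual_tf(p, times, normalized = TRUE)
  band <- assign_bands(tf$grid)$alpha
  sp <- alpha_power_split(tf, band, window = c(0, 800), seed = 1)
  expect_equal(sp$enhanced, 1:3)
  expect_equal(sp$suppressed, 4:10)
  expect_length(sp$equalized$suppressed, 3)
  expect_true(all(sp$equalized$suppressed %in% 4:10))
  # all-positive trials -> empty suppressed class
  p2 <- p; p2[] <- 1
  expect_error(alpha_power_split(manual_tf(p2, times, normalized = TRUE),
                                 band), "empty class")
})

test_that("broadband vectors subtract the pre-stimulus mean per trial", {
  fs <- 250
  times <- seq(-600, 1099, by = 1000 / fs)
  set.seed(9)
  waves <- matrix(rnorm(2 * length(times), mean = 3), 2)
  ep <- waveform_epochs(waves, fs)
  bv <- broadband_vectors(ep)
  pre <- times >= -600 & times < 0
  for (tr in 1:2) {
    expect_equal(mean(bv[tr, 1, pre]), 0)
    expect_equal(bv[tr, 1, ], waves[tr, ] - mean(waves[tr, pre]))
  }
  expect_equal(attr(bv, "band"), "broadband")
})
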