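fs <- 1000
t1k <- (0:999) / fs

test_that("time-domain features match their closed forms on a unit sine", {
  x <- sin(2 * pi * 10 * t1k)
  td <- time_domain(x)
  expect_equal(unname(td["RMS"]), 1 / sqrt(2), tolerance = 0.001 * sqrt(2))
  expect_equal(unname(td["MAV"]), 2 / pi, tolerance = 0.002 / (2 / pi))
  expect_error(time_domain(rep(1, 100)), "constant")
  expect_error(time_domain(c(1, 2)), "length")
})

test_that("ZC and SSC equal brute-force enumeration", {
  x <- rep(c(1, -1), 500)
  td <- time_domain(x)
  expect_identical(unname(td["ZC"]), 999)
  expect_identical(unname(td["WL"]), 2 * 999)

  sine <- sin(2 * pi * 10 * t1k)
  td <- time_domain(sine)
  expect_identical(unname(td["ZC"]), as.numeric(oracle_zc(sine)))
  expect_identical(unname(td["SSC"]), as.numeric(oracle_ssc(sine)))

  set.seed(42)
  for (i in 1:10) {
    r <- sample(c(-1, 1), 200, replace = TRUE) * runif(200)
    td <- time_domain(r)
    expect_identical(unname(td["ZC"]), as.numeric(oracle_zc(r)))
    expect_identical(unname(td["SSC"]), as.numeric(oracle_ssc(r)))
  }
})

test_that("spectral features locate pure and mixed tones", {
  x10 <- sin(2 * pi * 10 * t1k)
  fd <- freq_domain(x10, fs)
  expect_equal(unname(fd["MPF"]), 10, tolerance = 0.05)
  expect_equal(unname(fd["MDF"]), 10, tolerance = 0.05)

  mix <- sin(2 * pi * 10 * t1k) + sin(2 * pi * 30 * t1k)
  expect_equal(unname(freq_domain(mix, fs)["MPF"]), 20, tolerance = 0.05)

  set.seed(1)
  mpf <- mean(replicate(20, unname(freq_domain(rnorm(1000), fs)["MPF"])))
  expect_equal(mpf, fs / 4, tolerance = 0.1)

  expect_error(freq_domain(rep(0, 1000), fs), "zero")
  expect_error(freq_domain(rnorm(32), fs), "length")
})

test_that("wavelet-packet energies are a partition of signal energy", {
  set.seed(2)
  x <- rnorm(1024)
  wp <- wavelet_packet(x)
  expect_equal(unname(wp["WPE"]), sum(wp[paste0("WP", 1:8)]))
  expect_equal(unname(wp["WPE"]), sum(x^2), tolerance = 1e-10)

  # 20 Hz tone lives in band 1 (0-62.5 Hz at 1 kHz sampling)
  tone <- sin(2 * pi * 20 * t1k)
  wp <- wavelet_packet(tone)
  expect_gt(wp["WP1"] / wp["WPE"], 0.8)

  # 230 Hz tone lives in band 4 (187.5-250 Hz)
  tone4 <- sin(2 * pi * 230 * t1k)
  wp4 <- wavelet_packet(tone4)
  expect_identical(names(which.max(wp4[paste0("WP", 1:8)])), "WP4")

  # white noise spreads evenly over the 8 bands
  set.seed(3)
  fr <- rowMeans(replicate(100, {
    w <- wavelet_packet(rnorm(1000))
    w[paste0("WP", 1:8)] / w["WPE"]
  }))
  expect_true(all(abs(fr - 0.125) < 0.05))

  expect_error(wavelet_packet(rnorm(100)), "divisible")
})

test_that("LZ76 complexity matches the brute-force parser", {
  expect_identical(lz76_complexity(rep(c(0, 1), 8))$count, 3L)
  expect_identical(lz76_complexity(rep(c(0, 1), 500))$count, 3L)
  set.seed(7)
  for (i in 1:30) {
    bits <- sample(0:1, sample(50:200, 1), replace = TRUE)
    expect_identical(lz76_complexity(bits)$count, oracle_lz76(bits))
  }
})

test_that("SampEn and ApEn agree with the direct-definition oracle", {
  set.seed(11)
  for (i in 1:12) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.9)), 300))
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
                 tolerance = 1e-10)
    expect_equal(approx_entropy(x, 2, r), oracle_apen(x, 2, r),
                 tolerance = 1e-10)
  }
})

test_that("entropies separate periodic from stochastic signals", {
  sine <- sin(2 * pi * 10 * t1k)
  expect_lt(sample_entropy(sine), 0.2)

  set.seed(5)
  se_noise <- replicate(20, sample_entropy(rnorm(1000)))
  expect_equal(mean(se_noise), 2.2, tolerance = 0.3 / 2.2)

  # ordering holds rep by rep for matched length/SD
  wins <- 0L
  for (i in 1:50) {
    n <- rnorm(1000)
    s <- sin(2 * pi * 10 * t1k + runif(1, 0, 2 * pi)) * sd(n)
    if (sample_entropy(n) > sample_entropy(s)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)

  # regularity limit: tolerance far above the jitter scale, so every
  # template matches and the entropy collapses to zero
  expect_lt(approx_entropy(rep(1, 300) + rnorm(300, sd = 1e-6), 2, r = 0.01),
            0.05)
})

test_that("fractal dimension distinguishes a line from noise", {
  line <- seq(0, 1, length.out = 1000)
  expect_equal(box_counting_fd(line), 1.0, tolerance = 0.1)

  set.seed(6)
  wins <- 0L
  for (i in 1:50) {
    fd_n <- box_counting_fd(rnorm(500))
    fd_s <- box_counting_fd(sin(2 * pi * 5 * (0:499) / 500 + runif(1)))
    if (fd_n > fd_s) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("feature vectors scale the way their definitions dictate", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.6), 1000))
  a <- channel_features(x, fs)
  b <- channel_features(3 * x, fs)
  lin <- c("RMS", "SD", "MAV", "WL")
  expect_equal(unname(b[lin]), unname(3 * a[lin]), tolerance = 1e-8)
  quad <- c("WPE", paste0("WP", 1:8))
  expect_equal(unname(b[quad]), unname(9 * a[quad]), tolerance = 1e-8)
  invar <- c("kurtosis", "ZC", "SSC", "MPF", "MDF", "LZC", "DistEn")
  expect_equal(unname(b[invar]), unname(a[invar]), tolerance = 1e-8)
})

test_that("extraction yields 25 named features per channel, 75 for three", {
  set.seed(9)
  rec3 <- structure(list(channels = matrix(rnorm(8400), 3), force = rep(50, 2800),
                         fs = fs, channel_labels = c("RF", "VL", "VM")),
                    class = "mmg_recording")
  wins <- slide_windows(rec3, window_spec(1000, 100))
  fm <- extract_all(wins, fs, channel_labels = c("RF", "VL", "VM"))
  expect_identical(ncol(fm$features), 75L)
  expect_identical(colnames(fm$features)[1:2], c("RF_RMS", "RF_kurtosis"))
  expect_identical(colnames(fm$features)[26], "VL_RMS")

  rec1 <- structure(list(channels = matrix(rnorm(1000), 1), force = rep(50, 1000),
                         fs = fs, channel_labels = "RF"),
                    class = "mmg_recording")
  fm1 <- extract_all(slide_windows(rec1, window_spec(1000, 100)), fs, "RF")
  expect_identical(ncol(fm1$features), 25L)

  # deterministic column order
  fm2 <- extract_all(wins, fs, channel_labels = c("RF", "VL", "VM"))
  expect_identical(colnames(fm$features), colnames(fm2$features))

  # failures carry the window index
  bad <- wins
  bad[[2]]$channels[1, ] <- 0
  expect_error(extract_all(bad, fs, c("RF", "VL", "VM")), "window 2")
})

test_that("feature CSV round-trips", {
  set.seed(10)
  fm <- structure(list(features = matrix(rnorm(20), 4, 5,
                                         dimnames = list(NULL, letters[1:5])),
                       force = 1:4, channel_labels = NULL),
                  class = "feature_matrix")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back$features, fm$features, tolerance = 1e-10)
  expect_equal(back$force, fm$force)
})
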