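noise_free <- trace_sim_params(signal_sd = 0, background_sd = 0, seed = 1)

test_that("registration recovers constructed shifts and refuses garbage", {
  ref <- make_reference(seed = 2)
  brk <- locate_recognition_site(ref)
  pr <- simulate_trace_pair(ref, c(`0` = 1), trace_sim_params(seed = 3))
  expect_identical(estimate_offset(pr$control, pr$control,
                                   break_position = brk), 0L)
  # prepending rows shifts the best offset by the same amount
  shifted <- trace_data(as.data.frame(pr$control)[c(1:3, 1:nrow(pr$control)),
                                                  c("A", "C", "G", "T")])
  expect_identical(estimate_offset(pr$control, shifted,
                                   break_position = brk), 3L)
  # uncorrelated sample fails registration
  junk <- random_trace(nrow(pr$control), seed = 99)
  expect_error(estimate_offset(pr$control, junk, break_position = brk),
               "registration failed")
})

test_that("registration equals an exhaustive correlation argmax", {
  ref <- make_reference(seed = 4)
  brk <- locate_recognition_site(ref)
  cfg <- decomposition_config()
  for (s in 1:25) {
    d_true <- sample(-5:5, 1)
    pr <- simulate_trace_pair(ref, c(`0` = 0.7, `-3` = 0.3),
                              trace_sim_params(seed = s, signal_sd = 0.1))
    samp_df <- as.data.frame(pr$sample)[, c("A", "C", "G", "T")]
    samp <- if (d_true >= 0)
      trace_data(samp_df[c(seq_len(d_true), seq_len(nrow(samp_df))), ])
    else trace_data(samp_df[-seq_len(-d_true), ])
    got <- estimate_offset(pr$control, samp, cfg, brk)
    # independent brute-force argmax over the full offset range
    win <- seq(brk - 100L, brk - 20L)
    cm <- t(as.matrix(as.data.frame(pr$control)[win, c("A", "C", "G", "T")]))
    best <- -Inf; best_d <- NA
    for (d in -20:20) {
      idx <- win + d
      if (idx[1] < 1 || idx[length(idx)] > nrow(samp)) next
      sm <- t(as.matrix(as.data.frame(samp)[idx, c("A", "C", "G", "T")]))
      r <- suppressWarnings(cor(as.vector(sm), as.vector(cm)))
      if (is.finite(r) && r > best + 1e-12) { best <- r; best_d <- d }
    }
    expect_identical(got, as.integer(best_d))
    expect_identical(got, as.integer(d_true))
  }
})

test_that("shifted models displace the control by exactly k", {
  ref <- make_reference(seed = 6)
  brk <- locate_recognition_site(ref)
  cfg <- decomposition_config()
  pr <- simulate_trace_pair(ref, c(`0` = 1), noise_free)
  M <- build_shifted_models(pr$control, cfg, brk)
  dw <- attr(M, "window")
  w <- seq(dw[1], dw[2])
  cm <- t(as.matrix(as.data.frame(pr$control)[, c("A", "C", "G", "T")]))
  expect_equal(M[, "0"], as.vector(cm[, w]))
  expect_equal(M[, "-23"], as.vector(cm[, w + 23]))
  expect_equal(M[, "10"], as.vector(cm[, w - 10]))
})

test_that("shifted models of a non-repetitive control are full rank", {
  ref <- make_reference(seed = 8)
  brk <- locate_recognition_site(ref)
  K <- 5L
  cfg <- decomposition_config(max_indel = K,
                              decomp_window = c(brk + K + 6L,
                                                brk + K + 5L + 3L * (2L * K + 1L)))
  pr <- simulate_trace_pair(ref, c(`0` = 1), noise_free)
  M <- build_shifted_models(pr$control, cfg, brk)
  expect_identical(qr(M)$rank, 2L * K + 1L)
})

test_that("out-of-bounds decomposition windows are configuration errors", {
  ref <- make_reference(seed = 6)
  brk <- locate_recognition_site(ref)
  pr <- simulate_trace_pair(ref, c(`0` = 1), noise_free)
  n <- nrow(pr$control)
  expect_error(build_shifted_models(pr$control,
                                    decomposition_config(decomp_window =
                                                           c(brk + 40L, n)),
                                    brk),
               "out of control bounds")
  expect_error(build_shifted_models(pr$control,
                                    decomposition_config(decomp_window =
                                                           c(brk + 10L, n - 45L)),
                                    brk),
               "start after break")
})

test_that("background fraction matches direct per-position computation", {
  # secondary channels at zero give 0; four equal channels give 0.75
  clean <- trace_data(cbind(A = rep(1, 30), C = 0, G = 0, T = 0))
  expect_equal(background_qc(clean, c(1, 30)), 0)
  flat <- trace_data(cbind(A = rep(1, 30), C = 1, G = 1, T = 1))
  expect_equal(background_qc(flat, c(1, 30)), 0.75)
  for (s in 1:10) {
    tr <- random_trace(80, seed = s)
    got <- background_qc(tr, c(11, 70))
    m <- as.matrix(as.data.frame(tr)[11:70, c("A", "C", "G", "T")])
    fr <- apply(m, 1, function(r) if (sum(r) > 0)
      (sum(r) - max(r)) / sum(r) else NA_real_)
    expect_equal(got, mean(fr, na.rm = TRUE))
  }
  expect_error(background_qc(clean, c(1, 10)), "at least 20")
})

test_that("noise-free mixtures decompose exactly", {
  ref <- make_reference(seed = 10)
  # identity: sample equals control
  pr <- simulate_trace_pair(ref, c(`0` = 1), noise_free)
  sp <- decompose(pr$control, pr$control, ref)
  expect_equal(unname(sp$weights[["0"]]), 1)
  expect_equal(sp$r_squared, 1)
  # constructed two-component mixture
  pr2 <- simulate_trace_pair(ref, c(`0` = 0.6, `-2` = 0.4), noise_free)
  sp2 <- decompose(pr2$control, pr2$sample, ref)
  expect_equal(unname(sp2$weights[["0"]]), 0.6, tolerance = 1e-6)
  expect_equal(unname(sp2$weights[["-2"]]), 0.4, tolerance = 1e-6)
  expect_gt(sp2$r_squared, 1 - 1e-9)
  # pure HR event
  pr3 <- simulate_trace_pair(ref, c(`-23` = 1), noise_free)
  sp3 <- decompose(pr3$control, pr3$sample, ref)
  expect_equal(unname(sp3$weights[["-23"]]), 1, tolerance = 1e-9)
})

test_that("decomposition equals the exhaustive active-set oracle", {
  ref <- make_reference(seed = 12)
  brk <- locate_recognition_site(ref)
  cfg <- small_cfg(brk)
  for (s in 1:15) {
    truth <- withr::with_seed(s, {
      w <- rgamma(4, 1)
      setNames(w / sum(w), sample(-5:5, 4))
    })
    pr <- simulate_trace_pair(ref, truth, trace_sim_params(seed = 100 + s),
                              max_indel = 5L)
    sp <- decompose(pr$control, pr$sample, ref, cfg)
    M <- build_shifted_models(pr$control, cfg, brk)
    dw <- attr(M, "window")
    sm <- t(as.matrix(as.data.frame(pr$sample)[seq(dw[1], dw[2]),
                                               c("A", "C", "G", "T")]))
    x <- nnls_exhaustive(M, as.vector(sm))
    expect_equal(unname(sp$weights), x / sum(x), tolerance = 1e-6)
  }
})

test_that("weights conserve mass and stay non-negative", {
  ref <- make_reference(seed = 14)
  for (s in 1:25) {
    truth <- withr::with_seed(s, {
      w <- rgamma(5, 0.7)
      setNames(w / sum(w), sample(setdiff(-35:35, integer(0)), 5))
    })
    pr <- simulate_trace_pair(ref, truth, trace_sim_params(seed = 200 + s))
    sp <- decompose(pr$control, pr$sample, ref)
    expect_true(all(sp$weights >= 0))
    expect_equal(sum(sp$weights), 1, tolerance = 1e-9)
  }
})

test_that("default-noise recovery stays within 0.02 per weight", {
  ref <- make_reference(seed = 16)
  for (s in 1:20) {
    truth <- c(`0` = 0.45, `-23` = 0.35, `-1` = 0.1, `2` = 0.1)
    pr <- simulate_trace_pair(ref, truth, trace_sim_params(seed = 300 + s))
    sp <- decompose(pr$control, pr$sample, ref)
    for (k in names(truth))
      expect_lt(abs(sp$weights[[k]] - truth[[k]]), 0.02)
    expect_gt(sp$r_squared, 0.9)
  }
})

test_that("increasing noise never increases mean goodness of fit", {
  ref <- make_reference(seed = 18)
  truth <- c(`0` = 0.5, `-23` = 0.3, `-4` = 0.2)
  sds <- c(0.02, 0.05, 0.1, 0.2)
  mean_r2 <- vapply(sds, function(sg) {
    mean(vapply(1:15, function(s) {
      pr <- simulate_trace_pair(ref, truth,
                                trace_sim_params(signal_sd = sg,
                                                 background_sd = sg / 2,
                                                 seed = 1000 * sg + s))
      decompose(pr$control, pr$sample, ref)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("high background flags QC failure and classification refuses it", {
  ref <- make_reference(seed = 20)
  pr <- simulate_trace_pair(ref, c(`0` = 0.7, `-23` = 0.3),
                            trace_sim_params(background_sd = 0.25, seed = 21))
  sp <- decompose(pr$control, pr$sample, ref)
  expect_false(sp$qc_pass)
  expect_gt(sp$background, 0.15)
  expect_error(classify_spectrum(sp), "QC")
})
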