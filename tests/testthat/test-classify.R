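test_that("ideal spike profiles have even-only power with coordinated phases", {
  for (phi in 0:5) {
    prof <- simulate_staccato(12, 4, e0 = 1, de = 10, phi_index = phi)
    co <- dft(prof$value)
    # closed form: odd coefficients exactly zero, even ones magnitude 2*dE
    expect_true(all(Mod(co[c(2, 4, 6, 8, 10, 12)]) < 1e-9))
    expect_equal(Mod(co[c(3, 5, 7)]), rep(20, 3), tolerance = 1e-9)
    sp <- power_spectrum(co, 48)
    # folded even powers are in ratio 2:2:1 (k = 2, 4 fold two mirrors,
    # k = 6 is the unpaired Nyquist term), hence RP24 = 2/3
    expect_equal(rp24(sp), 2 / 3, tolerance = 1e-9)
    expect_identical(spectral_parity(sp), Inf)
    expect_equal(pvec(co, prof$value), 0, tolerance = 1e-12)
    expect_equal(spike_variance_fraction(prof$value), 1, tolerance = 1e-12)
  }
})

test_that("spectral parity matches an independent power-ratio computation", {
  set.seed(51)
  for (i in 1:20) {
    v <- simulate_staccato(12, 4, 1, 10, sample(0:5, 1),
                           noise_sd = 0.1, seed = sample.int(1e6, 1))$value
    sp_val <- spectral_parity(power_spectrum(dft(v), 48))
    even <- sum(vapply(c(2L, 4L, 6L), function(k) power_oracle(v, k), numeric(1)))
    odd <- sum(vapply(c(1L, 3L, 5L), function(k) power_oracle(v, k), numeric(1)))
    expect_equal(sp_val, log(even / odd), tolerance = 1e-9)
    expect_gt(sp_val, 2)  # spikes dominate even frequencies
  }
})

test_that("a pure cosine is not mistaken for a spike profile", {
  v <- cos(2 * pi * t12 / 24) + 2
  sp <- spectral_parity(power_spectrum(dft(v), 48))
  expect_identical(sp, Inf)  # all power at k = 2: parity alone cannot separate
  expect_true(is.na(pvec(dft(v), v)))  # only one usable even coefficient
  expect_lt(spike_variance_fraction(v), 0.5)
  # the joint screen therefore does not flag it
  scores <- score_rhythmicity(
    tibble::tibble(transcript_id = "a", condition = "young",
                   time = t12, value = v),
    n_perm = 200, seed = 1
  )
  expect_false(scores$staccato)
})

test_that("pvec is well above zero for smooth noisy profiles", {
  set.seed(52)
  vals <- replicate(200, {
    v <- simulate_sinusoid(12, 4, 2, 10, runif(1, 0, 2 * pi), snr = 2)$value
    pvec(dft(v), v)
  })
  expect_gt(stats::median(vals, na.rm = TRUE), 0.15)
})

test_that("max/min fold change covers all degenerate cases", {
  expect_equal(max_min_fold(seq(2, 3, length.out = 12)), 1.5)
  expect_equal(max_min_fold(rep(7, 12)), 1)
  expect_identical(max_min_fold(c(0, rep(2, 10), 5)), Inf)
  expect_true(is.na(max_min_fold(rep(0, 12))))
})

test_that("detectability combines fold change and median expression", {
  th <- rhythm_thresholds()
  expect_true(is_detectable(1.6, 2, th))
  expect_false(is_detectable(1.45, 2, th))
  expect_true(is_detectable(1.45, 2, th, "fold_relaxed"))
  expect_false(is_detectable(3, 0.5, th))
  expect_true(is_detectable(Inf, 2, th))
  expect_false(is_detectable(NA_real_, 2, th))
})

test_that("threshold invariants are enforced", {
  expect_error(rhythm_thresholds(q_rhythmic = 0.08), "strictly below")
  expect_error(rhythm_thresholds(fold_relaxed = 1.6), "strictly below")
})

test_that("pairwise classification follows the label definitions", {
  th <- rhythm_thresholds()
  # rhythmic + detectable young, arrhythmic old
  expect_equal(classify_pair(0.01, 0.2, 2.0, 1.1, 5, 5, thresholds = th), "ELC")
  # mirror image
  expect_equal(classify_pair(0.2, 0.01, 1.1, 2.0, 5, 5, thresholds = th), "LLC")
  # rhythmic both; relaxed 1.4-fold passes in old
  expect_equal(classify_pair(0.01, 0.04, 2.0, 1.45, 5, 3, thresholds = th), "RLC")
  # q in the open indeterminate band
  expect_equal(classify_pair(0.06, 0.2, 2.0, 2.0, 5, 5, thresholds = th),
               "indeterminate")
  # rhythmic young but not detectable there
  expect_equal(classify_pair(0.01, 0.2, 1.2, 1.1, 5, 5, thresholds = th), "NR")
  # rhythmic both but relaxed fold fails in old
  expect_equal(classify_pair(0.01, 0.04, 2.0, 1.2, 5, 5, thresholds = th), "NR")
  # spike screen wins over everything
  expect_equal(classify_pair(0.01, 0.2, 2.0, 1.1, 5, 5,
                             staccato_a = TRUE, thresholds = th),
               "staccato_filtered")
  expect_error(classify_pair(NA, 0.2, 2, 2, 5, 5, thresholds = th), "q-value")
})

test_that("lowering the young q-value never demotes ELC to NR", {
  th <- rhythm_thresholds()
  for (q in c(0.05, 0.03, 0.01, 0.001)) {
    expect_equal(classify_pair(q, 0.2, 2.0, 1.1, 5, 5, thresholds = th), "ELC")
  }
})

test_that("classification partitions every transcript exactly once", {
  sim <- simulate_dataset(15, 15, 15, 15, 15, snr = 10, seed = 13)
  scores <- score_rhythmicity(sim$expression, n_perm = 200, seed = 13)
  classes <- classify_transcripts(scores)
  expect_equal(nrow(classes), nrow(sim$truth))
  expect_setequal(classes$transcript_id, sim$truth$transcript_id)
  expect_true(all(classes$class %in% c("ELC", "RLC", "LLC", "NR",
                                       "indeterminate", "staccato_filtered")))
})

test_that("classification rejects transcripts missing one condition", {
  sim <- simulate_dataset(3, 0, 0, 0, 0, snr = 10, seed = 2)
  scores <- score_rhythmicity(sim$expression, n_perm = 200, seed = 2)
  expect_error(classify_transcripts(scores[-1, ]), "missing one condition")
})

test_that("overlap summary counts rhythmic-detectable transcripts per age", {
  scores <- tibble::tibble(
    transcript_id = rep(c("a", "b", "c"), 2),
    condition = rep(c("young", "old"), each = 3),
    q_value = c(0.01, 0.01, 0.5, 0.01, 0.5, 0.01),
    max_min_fold = 2, median_expr = 5, staccato = FALSE
  )
  ov <- rhythmic_overlap_summary(scores)
  expect_equal(ov$only_a, 1)  # b
  expect_equal(ov$only_b, 1)  # c
  expect_equal(ov$both, 1)    # a
})
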