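test_that("noiseless forward model matches closed-form signals", {
  g <- protocol_gradients()
  a <- box_atlas(5)
  # pure water: b0 gives s0, b=1000 gives exp(-b*d_water) = exp(-3)
  tr <- uniform_truth(a, fw = 1, fa = 0.3)
  dwi <- synthesize_dwi(tr, g)
  expect_equal(dwi[3, 3, 3, 1], 1)                      # b0 -> s0
  expect_equal(dwi[3, 3, 3, 10], exp(-3), tolerance = 1e-12)
  expect_true(all(dwi[1, 1, 1, ] == 0))                 # background stays 0

  # tensor compartment along its principal axis: exp(-b*l1)
  l <- c(1.5e-3, 0.4e-3, 0.4e-3)
  fa <- fractional_anisotropy(l[1], l[2], l[3])
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  D <- tensor_from_fa_md(fa, mean(l), c(1, 0, 0))
  expect_equal(sort(eigen(D)$values, decreasing = TRUE), l,
               tolerance = 1e-9)
  tr2 <- uniform_truth(a, fw = 0, fa = fa, md = mean(l), dir = c(1, 0, 0))
  dwi2 <- synthesize_dwi(tr2, gt)
  expect_equal(dwi2[3, 3, 3, 2], exp(-1.5), tolerance = 1e-9)

  # general mixture agrees with the independent per-voxel oracle
  tr3 <- uniform_truth(a, fw = 0.3, fa = 0.5, dir = c(1, 1, 0))
  dwi3 <- synthesize_dwi(tr3, g)
  D3 <- tensor_from_fa_md(0.5, 0.7e-3, c(1, 1, 0))
  expect_equal(dwi3[3, 3, 3, ], fwd_signal(g, 0.3, D3), tolerance = 1e-12)
})

test_that("shape mismatches and invalid noise are rejected", {
  g <- protocol_gradients()
  tr <- uniform_truth(box_atlas(5))
  tr$s0 <- array(1, dim = c(4, 4, 4))
  expect_error(synthesize_dwi(tr, g), "shapes disagree")
  tr2 <- uniform_truth(box_atlas(5))
  expect_error(synthesize_dwi(tr2, g, sigma = -1), "sigma")
})

test_that("Rician noise is seed-deterministic and biased upward at low SNR", {
  g <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  tr <- uniform_truth(box_atlas(8), fw = 1, fa = 0.3)  # signal exp(-3) ~ 0.05
  d1 <- synthesize_dwi(tr, g, sigma = 0.05, seed = 9)
  d2 <- synthesize_dwi(tr, g, sigma = 0.05, seed = 9)
  d3 <- synthesize_dwi(tr, g, sigma = 0.05, seed = 10)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  # Rician bias: E[magnitude] > true signal when sigma ~ signal
  inside <- tr$atlas > 0
  truth_sig <- exp(-3)
  noisy <- d1[, , , 2][inside]
  expect_gt(mean(noisy), truth_sig)
  # Gaussian toggle is unbiased at the same scale
  dg <- synthesize_dwi(tr, g, sigma = 0.05, seed = 9, noise = "gaussian")
  expect_lt(abs(mean(dg[, , , 2][inside]) - truth_sig), 0.01)
})

test_that("session simulation applies site shift and retest jitter", {
  g <- protocol_gradients(12, 2)
  a <- generate_atlas(c(10, 10, 10), 16, seed = 1)
  tr <- make_ground_truth(a, seed = 2)
  coh <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 2, MSA = 1, PSP = 1),
    n_retrospective = c(PD = 0, MSA = 0, PSP = 0), seed = 3))
  eff <- default_effect_spec(strength = 1, site_sd = 0.05, retest_sd = 0.05)
  s <- simulate_subject_dwi(coh[1, ], tr, eff, g, sigma = 0, seed = 5)
  expect_named(s, c("1", "2"))
  expect_false(identical(s[["1"]], s[["2"]]))  # retest jitter
  # no nuisances and no noise: sessions identical
  eff0 <- default_effect_spec(strength = 1, site_sd = 0, retest_sd = 0)
  s0 <- simulate_subject_dwi(coh[1, ], tr, eff0, g, sigma = 0, seed = 5)
  expect_identical(s0[["1"]], s0[["2"]])
})
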