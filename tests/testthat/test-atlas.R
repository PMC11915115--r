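test_that("atlas partitions the interior into the requested nonempty regions", {
  a <- generate_atlas(c(24, 24, 24), 132, seed = 1)
  labs <- table(a[a > 0])
  expect_equal(length(labs), 132L)
  expect_true(all(labs >= 8))
  expect_true(all(sort(unique(as.vector(a))) == 0:132))
  # border is background
  expect_true(all(a[1, , ] == 0) && all(a[, , 24] == 0))
  # determinism and seed sensitivity (geometry may differ, counts hold)
  expect_identical(a, generate_atlas(c(24, 24, 24), 132, seed = 1))
  a2 <- generate_atlas(c(24, 24, 24), 132, seed = 2)
  expect_equal(length(table(a2[a2 > 0])), 132L)
})

test_that("atlas regions are 6-connected components", {
  a <- generate_atlas(c(12, 12, 12), 10, seed = 3)
  for (lab in c(1L, 5L, 10L)) {
    sel <- a == lab
    comp <- aidp:::.largest_component(sel)
    expect_equal(sum(comp), sum(sel))
  }
})

test_that("single-region and capacity edge cases behave", {
  a1 <- generate_atlas(c(8, 8, 8), 1, seed = 1)
  expect_true(all(a1[2:7, 2:7, 2:7] == 1L))
  expect_true(all(a1[c(1, 8), , ] == 0L))
  expect_error(generate_atlas(c(6, 6, 6), 132), "capacity")
})

test_that("ground truth satisfies its field invariants", {
  a <- generate_atlas(c(10, 10, 10), 8, seed = 2)
  tr <- make_ground_truth(a, seed = 4)
  expect_true(all(tr$fw >= 0 & tr$fw <= 1))
  expect_true(all(tr$s0 >= 0))
  # tensors positive semidefinite inside the brain
  idx <- which(a > 0)[1:20]
  tc <- matrix(tr$tensor, ncol = 6L)
  for (i in idx) {
    d <- tc[i, ]
    D <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    expect_gte(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # per-region MD equals the generator's md
  md <- (tc[idx, 1] + tc[idx, 2] + tc[idx, 3]) / 3
  expect_equal(md, rep(0.7e-3, length(idx)), tolerance = 1e-12)
})

test_that("plant_effects is local, clipped and exact on FAt", {
  a <- generate_atlas(c(10, 10, 10), 8, seed = 2)
  tr <- make_ground_truth(a, seed = 4)
  # identity on empty effect
  eff0 <- effect_spec(effects = list(MSA = data.frame(region = integer(),
                                                      d_fw = numeric(),
                                                      d_fat = numeric())))
  expect_identical(plant_effects(tr, eff0, "MSA"), tr)
  expect_identical(plant_effects(tr, default_effect_spec(), "none"), tr)

  eff <- effect_spec(effects = list(
    MSA = data.frame(region = 3L, d_fw = 0.2, d_fat = -0.1)))
  out <- plant_effects(tr, eff, "MSA")
  inside <- a == 3L
  expect_equal(out$fw[inside], pmin(tr$fw[inside] + 0.2, 1))
  expect_identical(out$fw[!inside], tr$fw[!inside])
  expect_identical(out$tensor[, , , 1][!inside], tr$tensor[, , , 1][!inside])
  # FAt shift realised exactly (closed-form deviatoric rescale)
  fa_before <- field_fa(tr$tensor)
  fa_after <- field_fa(out$tensor)
  expect_equal(fa_after[inside], pmin(pmax(fa_before[inside] - 0.1, 0), 0.99),
               tolerance = 1e-8)
  expect_equal(fa_after[!inside], fa_before[!inside])

  # clipping at 1
  big <- effect_spec(effects = list(
    MSA = data.frame(region = 3L, d_fw = 2, d_fat = 0)))
  expect_true(all(plant_effects(tr, big, "MSA")$fw <= 1))
  # unknown region errors
  bad <- effect_spec(effects = list(
    MSA = data.frame(region = 99L, d_fw = 0.1, d_fat = 0)))
  expect_error(plant_effects(tr, bad, "MSA"), "unknown atlas region")
})
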