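test_that("pearson correlation handles identity, inversion and independence", {
  set.seed(5)
  a <- array(runif(32^3), c(32, 32, 32))
  expect_equal(pearson_cc(a, a), 1)
  expect_equal(pearson_cc(a, max(a) - a), -1)
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    pearson_cc(array(runif(32^3), c(32, 32, 32)),
               array(runif(32^3), c(32, 32, 32)))
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.05)
  expect_error(pearson_cc(a, array(1, dim(a))), "zero variance")
})

test_that("gaussian-style volumes hit the requested correlation", {
  v1 <- make_coloc_volume(c(32, 32, 8), rho = 1, noise_frac = 0, seed = 1)
  expect_equal(pearson_cc(v1$channel_a, v1$channel_b), 1, tolerance = 1e-9)
  # independence at 64^3 voxels
  rs <- vapply(1:20, function(s) {
    v <- make_coloc_volume(c(64, 64, 64), rho = 0, seed = s)
    pearson_cc(v$channel_a, v$channel_b)
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.05)
  v9 <- make_coloc_volume(c(64, 64, 16), rho = 0.9, seed = 3)
  r9 <- pearson_cc(v9$channel_a, v9$channel_b)
  expect_gte(r9, 0.85); expect_lte(r9, 0.95)
  vn <- make_coloc_volume(c(32, 32, 8), rho = -0.7, seed = 2)
  expect_equal(pearson_cc(vn$channel_a, vn$channel_b), -0.7, tolerance = 0.08)
  expect_error(make_coloc_volume(c(16, 16, 4), rho = 0.99, noise_frac = 0.5),
               "unattainable")
})

test_that("generated correlation is monotone in the target", {
  for (s in 1:10) {
    rs <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
      v <- make_coloc_volume(c(32, 32, 8), rho = rho, seed = s)
      pearson_cc(v$channel_a, v$channel_b)
    }, numeric(1))
    expect_true(all(diff(rs) > 0))
  }
})

test_that("costes thresholds bottom out for perfectly correlated channels", {
  set.seed(8)
  a <- array(runif(16^3), c(16, 16, 16))
  v <- volume_pair(a, a)
  expect_warning(th <- costes_thresholds(v), "never reached zero")
  expect_true(th$exhausted)
  r <- suppressWarnings(coloc_stats(v))
  expect_equal(r$pcc, 1)
  expect_equal(r$percent_material_a, 100, tolerance = 1)
  expect_equal(r$percent_material_b, 100, tolerance = 1)
  expect_true(r$correlated)
})

test_that("disjoint spot fields yield near-zero colocalization", {
  v <- make_coloc_volume(c(64, 64, 16), coloc_fraction = 0, style = "blobs",
                         seed = 5)
  r <- suppressWarnings(coloc_stats(v))
  expect_lt(r$percent_material_a, 15)
  expect_lt(r$percent_material_b, 15)
  expect_false(r$correlated)
})

test_that("percent material recovers the generating mass fraction", {
  v <- make_coloc_volume(c(64, 64, 16), coloc_fraction = 0.5, style = "blobs",
                         seed = 1)
  r <- coloc_stats(v)
  expect_false(r$threshold_exhausted)
  expect_lt(abs(r$percent_material_a - 50), 10)
  expect_lt(abs(r$percent_material_b - 50), 10)
  # monotone in the generating fraction
  pm <- vapply(c(0.2, 0.5, 0.8), function(f) {
    vv <- make_coloc_volume(c(64, 64, 16), coloc_fraction = f,
                            style = "blobs", seed = 1)
    suppressWarnings(coloc_stats(vv))$percent_material_a
  }, numeric(1))
  expect_true(all(diff(pm) > 0))
})

test_that("the correlation classification boundary is inclusive", {
  v <- make_coloc_volume(c(32, 32, 8), coloc_fraction = 0.5, style = "blobs",
                         seed = 2)
  r <- suppressWarnings(coloc_stats(v))
  p0 <- r$pcc
  at <- suppressWarnings(coloc_stats(v, cutoff = p0))
  above <- suppressWarnings(coloc_stats(v, cutoff = p0 + 1e-9))
  expect_true(at$correlated)       # pcc >= cutoff
  expect_false(above$correlated)   # pcc < cutoff
})

test_that("colocalization statistics are invariant to intensity scaling", {
  v <- make_coloc_volume(c(32, 32, 8), coloc_fraction = 0.5, style = "blobs",
                         seed = 3)
  k <- 3.7
  vk <- volume_pair(k * v$channel_a, v$channel_b, v$voxel_size)
  r <- suppressWarnings(coloc_stats(v))
  rk <- suppressWarnings(coloc_stats(vk))
  expect_equal(rk$pcc, r$pcc, tolerance = 1e-9)
  expect_equal(rk$percent_material_a, r$percent_material_a, tolerance = 1e-9)
  expect_equal(rk$percent_material_b, r$percent_material_b, tolerance = 1e-9)
  expect_equal(rk$t_a, k * r$t_a, tolerance = 1e-9)
})

test_that("percent material is monotone non-increasing in either threshold", {
  v <- make_coloc_volume(c(32, 32, 8), coloc_fraction = 0.5, style = "blobs",
                         seed = 4)
  base <- suppressWarnings(costes_thresholds(v))
  pm_at <- function(ta, tb) {
    th <- list(t_a = ta, t_b = tb, slope = base$slope,
               intercept = base$intercept, exhausted = FALSE)
    r <- coloc_stats(v, thresholds = th)
    c(r$percent_material_a, r$percent_material_b)
  }
  qs <- stats::quantile(as.vector(v$channel_a), c(0.5, 0.7, 0.9, 0.99))
  pm_a <- t(vapply(qs, function(ta) pm_at(ta, base$t_b), numeric(2)))
  expect_true(all(diff(pm_a[, 1]) <= 0))
  expect_true(all(diff(pm_a[, 2]) <= 0))
  qs_b <- stats::quantile(as.vector(v$channel_b), c(0.5, 0.7, 0.9, 0.99))
  pm_b <- t(vapply(qs_b, function(tb) pm_at(base$t_a, tb), numeric(2)))
  expect_true(all(diff(pm_b[, 1]) <= 0))
  expect_true(all(diff(pm_b[, 2]) <= 0))
})

test_that("empty colocalized sets degrade gracefully", {
  set.seed(9)
  a <- array(runif(1000), c(10, 10, 10))
  b <- array(runif(1000), c(10, 10, 10))
  v <- volume_pair(a, b)
  th <- list(t_a = 2, t_b = 2, slope = 1, intercept = 0, exhausted = FALSE)
  r <- coloc_stats(v, thresholds = th)
  expect_identical(r$percent_material_a, 0)
  expect_identical(r$percent_material_b, 0)
  expect_true(is.na(r$pcc))
  expect_false(r$correlated)
})

test_that("volume pairs validate their invariants", {
  a <- array(1, c(4, 4, 2))
  expect_error(volume_pair(a, array(1, c(4, 4, 3))), "identical")
  expect_error(volume_pair(a, a - 2), "non-negative")
  expect_error(volume_pair(a, a, voxel_size = c(1, 1, 0)), "voxel_size > 0")
})
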