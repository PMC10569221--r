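test_that("the 85th-percentile threshold interpolates order statistics", {
  # predictions 1..100: h = 99*0.85 + 1 = 85.15 -> threshold 85.15, 85 healthy
  hs <- healthy_set(1:100, pct = 85)
  expect_equal(hs$threshold, 85.15)
  expect_equal(sum(hs$mask), 85)
  expect_true(all(which(hs$mask) == 1:85))
  # two-point interpolation: {0, 10} -> 0 + 0.85 * 10 = 8.5
  hs2 <- healthy_set(c(0, 10), pct = 85)
  expect_equal(hs2$threshold, 8.5)
  expect_equal(hs2$mask, c(TRUE, FALSE))
  # positive affine transformations leave the mask unchanged
  set.seed(5)
  p <- rnorm(200)
  expect_equal(healthy_set(3.2 * p + 7)$mask, healthy_set(p)$mask)
  # degenerate distribution is an error
  expect_error(healthy_set(rep(1, 10)), "identical")
  # direction = "high": healthy means above the symmetric threshold
  hi <- healthy_set(1:100, pct = 85, direction = "high")
  expect_equal(sum(hi$mask), 85)
  expect_true(all(which(hi$mask) == 16:100))
})

test_that("the Goldilocks Day is the compositional mean of the healthy set", {
  # 3-composition toy with a hand-computed oracle
  comps <- rbind(c(8, 11, 4, 1), c(9, 10, 4, 1), c(7, 12, 4, 1))
  colnames(comps) <- behavior_parts()
  preds <- c(10, 12, 50)
  mask <- c(TRUE, TRUE, FALSE)
  res <- goldilocks_day(comps, preds, mask)
  g <- c(sqrt(8 * 9), sqrt(11 * 10), 4, 1)  # part-wise geometric means
  expect_equal(unname(res$goldilocks), 24 * g / sum(g), tolerance = 1e-12)
  expect_equal(res$n_healthy, 2L)
  expect_equal(unname(res$part_ranges["min", ]), c(8, 10, 4, 1))
  expect_equal(unname(res$part_ranges["max", ]), c(9, 11, 4, 1))
  expect_equal(res$outcome_range, c(10, 12))
  # singleton healthy set collapses to that composition
  res1 <- goldilocks_day(comps, preds, c(TRUE, FALSE, FALSE))
  expect_equal(unname(res1$goldilocks), unname(close_comp(comps[1, ])),
               tolerance = 1e-9)
  expect_equal(unname(res1$part_ranges["min", ]), unname(res1$part_ranges["max", ]))
  expect_error(goldilocks_day(comps, preds, rep(FALSE, 3)), "empty")
})

test_that("the Goldilocks ilr vector is the mean of healthy ilr vectors (hull property)", {
  df <- toy_participants(n = 120, sigma = 2, seed = 13)
  fit <- fit_comp_lm(df, "y")
  res <- estimate_goldilocks(fit)
  basis <- make_contrast_basis()
  zh <- ilr_coords(fit$compositions, basis)[healthy_set(predict_empirical(fit))$mask, ]
  zg <- ilr_coords(res$goldilocks, basis)
  expect_equal(unname(zg), unname(colMeans(zh)), tolerance = 1e-9)
  # the mean therefore lies inside the coordinate-wise envelope of the hull
  expect_true(all(zg >= apply(zh, 2, min) - 1e-9 & zg <= apply(zh, 2, max) + 1e-9))
  # on non-degenerate data the Goldilocks parts also lie within their
  # healthy-set hour ranges
  expect_true(all(res$goldilocks >= res$part_ranges["min", ] - 1e-9 &
                  res$goldilocks <= res$part_ranges["max", ] + 1e-9))
})

test_that("Goldilocks composition is invariant to covariate profile and SBP", {
  df <- toy_participants(n = 150, sigma = 2, seed = 21)
  fit <- fit_comp_lm(df, "y")
  # profile shifts predictions uniformly: same mask, same Goldilocks day,
  # outcome range shifted by the same constant
  p_mean <- predict_empirical(fit, profile = "mean")
  prof <- c(sex = 1, maternal_bmi = 30, maternal_edu = 1, snacking = 1)
  p_prof <- predict_empirical(fit, profile = prof)
  expect_equal(diff(range(p_prof - p_mean)), 0, tolerance = 1e-10)
  m1 <- healthy_set(p_mean)$mask
  m2 <- healthy_set(p_prof)$mask
  expect_equal(m1, m2)
  g1 <- goldilocks_day(fit$compositions, p_mean, m1)
  g2 <- goldilocks_day(fit$compositions, p_prof, m2)
  expect_equal(g1$goldilocks, g2$goldilocks, tolerance = 1e-9)
  expect_equal(g1$part_ranges, g2$part_ranges, tolerance = 1e-9)
  expect_equal(g2$outcome_range - g1$outcome_range,
               rep((p_prof - p_mean)[1], 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # SBP invariance of the full estimate
  fit2 <- fit_comp_lm(df, "y", basis = make_contrast_basis(alt_sbp()))
  res1 <- estimate_goldilocks(fit)
  res2 <- estimate_goldilocks(fit2)
  expect_equal(res1$goldilocks, res2$goldilocks, tolerance = 1e-9)
  expect_equal(res1$threshold, res2$threshold, tolerance = 1e-9)
})

test_that("per-participant prediction profiles are supported and may reorder the mask", {
  df <- toy_participants(n = 100, sigma = 2, seed = 33)
  fit <- fit_comp_lm(df, "y")
  p_obs <- predict_empirical(fit, profile = "observed")
  expect_length(p_obs, fit$n)
  # observed-profile predictions equal the model's fitted values
  expect_equal(p_obs, unname(stats::fitted(fit$model)), tolerance = 1e-10)
})

test_that("a generating gradient that rewards less SB yields a low-SB Goldilocks Day", {
  # outcome strictly increasing in the SB balance (z2)
  df <- toy_participants(n = 200, sigma = 1, seed = 55,
                         beta_ilr = c(z1 = 0, z2 = 5, z3 = 0))
  fit <- fit_comp_lm(df, "y")
  preds <- predict_empirical(fit)
  hs <- healthy_set(preds)
  res <- goldilocks_day(fit$compositions, preds, hs, fit = fit)
  unhealthy_mean <- comp_mean(fit$compositions[!hs$mask, , drop = FALSE])
  expect_lt(res$goldilocks[["sb"]], unhealthy_mean[["sb"]])
  # and its predicted outcome is below the healthy threshold
  expect_lt(res$outcome_at_goldilocks, hs$threshold)
})

test_that("tetrahedron coordinates are barycentric with behaviours at the apices", {
  V <- tetra_vertices()
  # unit edge length
  expect_equal(as.numeric(dist(V)), rep(1, 6), tolerance = 1e-12)
  # a pure behaviour sits on its apex (limiting geometry, closure not used)
  for (k in 1:4) {
    p <- rep(0, 4); p[k] <- 24
    expect_equal(as.numeric(tetra_coords(p)[1, c("x", "y", "z")]),
                 unname(V[k, ]), tolerance = 1e-12)
  }
  # the equal-parts day sits at the centroid
  expect_equal(as.numeric(tetra_coords(c(6, 6, 6, 6))[1, c("x", "y", "z")]),
               unname(colMeans(V)), tolerance = 1e-12)
  # (12, 12, eps, eps) approaches the sleep-SB edge midpoint
  eps <- 1e-9
  expect_equal(as.numeric(tetra_coords(c(12, 12, eps, eps))[1, c("x", "y", "z")]),
               unname((V[1, ] + V[2, ]) / 2), tolerance = 1e-8)
  # all empirical points lie inside the hull: barycentric weights in [0, 1]
  comps <- random_comps(100, seed = 12)
  pts <- tetra_coords(comps, value = rnorm(100))
  expect_true(all(is.finite(as.matrix(pts))))
  expect_equal(nrow(pts), 100)
})

test_that("tetrahedron JSON export round-trips coordinates and labels", {
  comps <- random_comps(5, seed = 2)
  pts <- tetra_coords(comps, value = 1:5)
  path <- tempfile(fileext = ".json")
  export_tetra(pts, path, meta = list(cell = "children.vat_cm2"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$vertices$label, behavior_parts())
  expect_equal(back$points$x, pts$x, tolerance = 1e-12)
  expect_equal(back$points$z, pts$z, tolerance = 1e-12)
  expect_equal(back$points$value, 1:5)
  expect_equal(nrow(back$points), 5)
  expect_equal(back$meta$cell, "children.vat_cm2")
  # single point still exports 4 labelled vertices
  p1 <- tetra_coords(c(8, 11, 4, 1))
  path1 <- tempfile(fileext = ".json")
  export_tetra(p1, path1)
  b1 <- jsonlite::read_json(path1, simplifyVector = TRUE)
  expect_equal(nrow(b1$points), 1)
  expect_equal(nrow(b1$vertices), 4)
})
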