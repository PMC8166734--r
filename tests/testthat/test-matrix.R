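test_that("error_grid is symmetric, zero-containing and validated", {
  g <- error_grid(12)
  expect_equal(g$values, -12:12)
  expect_true(0 %in% g$values)
  expect_equal(g$values, -rev(g$values))
  expect_equal(error_grid(24, 1)$values, -24:24)
  expect_equal(error_grid(6, 2)$values, seq(-6, 6, 2))
  expect_error(error_grid(12, 5), "does not divide")
  expect_error(error_grid(12, 0), "positive")
})

test_that("scenario presets encode the two study groups", {
  s1 <- scenario_preset("group1")
  expect_equal(s1$catalog$sizes, seq(44, 66, 2))
  expect_equal(s1$grid$max_abs_pct, 12)
  expect_equal(s1$report_side, "positive_only")
  s2 <- scenario_preset("group2", report_side = "both")
  expect_equal(s2$catalog$sizes, seq(38, 72, 2))
  expect_equal(s2$grid$max_abs_pct, 24)
  expect_equal(s2$report_side, "both")
})

test_that("bin_label keeps 0..8 and combines larger deviations", {
  expect_identical(bin_label(c(0L, 5L, 8L, 9L, 15L)),
                   c("0", "5", "8", ">8", ">8"))
  # unsigned labels use the magnitude
  expect_identical(bin_label(c(-3L, -9L)), c("3", ">8"))
  # signed labels preserve the sign
  expect_identical(bin_label(c(-3L, 3L, -9L, 9L), signed = TRUE),
                   c("-3", "3", "<-8", ">8"))
})

test_that("build_matrix has the documented shape and cell values", {
  m1 <- build_matrix(scenario_preset("group1"))
  expect_equal(dim(m1$deviation_mm), c(12L, 13L))
  expect_equal(m1$deviation_mm["52", "8"], 4)
  expect_identical(m1$deviation_steps["52", "8"], 2L)
  expect_equal(unname(m1$deviation_mm[, "0"]), rep(0, 12L))

  m1b <- build_matrix(scenario_preset("group1", report_side = "both"))
  expect_equal(dim(m1b$deviation_mm), c(12L, 25L))

  m2b <- build_matrix(scenario_preset("group2", report_side = "both"))
  expect_equal(dim(m2b$deviation_mm), c(18L, 49L))
})

test_that("every matrix cell matches an independent oracle recomputation", {
  for (preset in c("group1", "group2")) {
    config <- scenario_preset(preset, report_side = "both")
    m <- build_matrix(config)
    for (i in seq_along(m$sizes)) {
      proj <- m$sizes[[i]] * (100 + m$errors) / 100
      snapped <- vapply(proj, oracle_snap, numeric(1L),
                        catalog = config$catalog, true_mm = m$sizes[[i]])
      expect_equal(unname(m$deviation_mm[i, ]), snapped - m$sizes[[i]])
    }
  }
})

test_that("snapped deviations are symmetric and monotone on the grids", {
  for (preset in c("group1", "group2")) {
    m <- build_matrix(scenario_preset(preset, report_side = "both"))
    inc <- m$config$catalog$increment
    for (i in seq_along(m$sizes)) {
      s <- m$sizes[[i]]
      # exact midpoints are tie-rule territory; exclude them
      at_mid <- abs(abs(s * m$errors / 100) %% inc - inc / 2) < 1e-9
      pos_idx <- which(m$errors > 0 & !at_mid)
      neg_idx <- which(m$errors < 0 & !at_mid)
      expect_equal(abs(m$deviation_mm[i, pos_idx]),
                   abs(m$deviation_mm[i, rev(neg_idx)]),
                   ignore_attr = TRUE)
      # |steps| non-decreasing in |e| along the positive half-row
      right <- abs(m$deviation_steps[i, m$errors >= 0])
      expect_true(all(diff(right) >= 0L))
    }
    # pre-snap deviation strictly increases with size at fixed e != 0
    for (j in which(m$errors != 0)) {
      presnap <- abs(m$projected_mm[, j] - m$sizes)
      expect_true(all(diff(presnap) > 0))
    }
  }
})

test_that("summary reports the grid maxima", {
  s1 <- summary(build_matrix(scenario_preset("group1")))
  expect_equal(s1$max_abs_presnap_mm, 7.9)   # 66 * 12% = 7.92
  expect_equal(s1$max_abs_snapped_mm, 8)
  expect_equal(s1$max_abs_steps, 4L)

  # degenerate scenario: single size, zero error
  s0 <- summary(build_matrix(scenario(make_catalog(52, 54, 2), error_grid(0))))
  expect_equal(s0$max_abs_presnap_mm, 0)
  expect_equal(s0$max_abs_steps, 0L)

  # group 2 from the stated formula: 72 * 24% = 17.28 -> snap 90 -> 9 steps
  s2 <- summary(build_matrix(scenario_preset("group2")))
  expect_equal(s2$max_abs_presnap_mm, 17.3)
  expect_equal(s2$max_abs_snapped_mm, 18)
  expect_equal(s2$max_abs_steps, 9L)
})

test_that("figure_series yields one straight line per size on the full grid", {
  fs <- figure_series(scenario_preset("group1"))
  expect_equal(length(unique(fs$size_mm)), 12L)
  expect_equal(nrow(fs), 12L * 25L)
  s66 <- fs[fs$size_mm == 66, ]
  expect_equal(s66$projected_mm[s66$error_pct == -12], 58.08)
  expect_equal(s66$projected_mm[s66$error_pct == 12], 73.92)
  expect_equal(fs$projected_mm[fs$error_pct == 0],
               fs$size_mm[fs$error_pct == 0])
  # 18 series for the large sample
  expect_equal(length(unique(figure_series(scenario_preset("group2"))$size_mm)),
               18L)
})

test_that("round_half_away rounds table cells away from zero", {
  expect_equal(templacal:::round_half_away(c(0.05, -0.05, 7.92, 2.25), 1L),
               c(0.1, -0.1, 7.9, 2.3))
})
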