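test_that("the landscape generator is deterministic and hits the target proportion", {
  a <- gen_fractal_landscape(64, p = 0.5, roughness = 2, seed = 7)
  b <- gen_fractal_landscape(64, p = 0.5, roughness = 2, seed = 7)
  expect_identical(a$cells, b$cells)
  expect_lte(abs(proportion_habitat(a) - 0.5), 1 / 64^2)

  for (p in c(0.1, 0.33, 0.9)) {
    ls <- gen_fractal_landscape(32, p = p, roughness = 1.5, seed = 3)
    expect_lte(abs(proportion_habitat(ls) - p), 1 / 32^2)
  }

  expect_error(gen_fractal_landscape(4, p = 0.5), "at least 8")
  expect_error(gen_fractal_landscape(32, p = 0), "\\(0, 1\\)")
  expect_error(gen_fractal_landscape(32, p = 0.5, roughness = -1), "non-negative")
})

test_that("white noise yields more patches than smooth surfaces at equal cover", {
  wins <- 0L
  for (s in 1:20) {
    white <- gen_fractal_landscape(48, p = 0.5, roughness = 0, seed = s)
    smooth <- gen_fractal_landscape(48, p = 0.5, roughness = 3, seed = s)
    if (label_patches(white)$n_patches > label_patches(smooth)$n_patches) {
      wins <- wins + 1L
    }
  }
  expect_gt(wins, 10L) # majority over seeds
})

test_that("loss scenarios only ever remove habitat and stay within the target", {
  base <- gen_fractal_landscape(48, p = 0.5, roughness = 2, seed = 12)
  H <- sum(base$cells == 1L)
  for (kind in c("random", "erosion", "patch_removal", "dissection",
                 "perforation")) {
    res <- suppressWarnings(
      apply_loss(base, loss_scenario(kind, 0.15, seed = 2))
    )
    t1 <- res$landscape$cells
    expect_true(all(t1[base$cells == 0L] == 0L)) # no habitat created
    expect_true(all(t1[base$cells == 1L] %in% c(0L, 1L)))
    expect_equal(res$realized_fraction,
                 (H - sum(t1 == 1L)) / H)
    if (kind == "patch_removal") {
      expect_lte(res$realized_fraction, 0.15)
    } else {
      expect_lte(res$realized_fraction, 0.15 + 1 / H)
    }
  }
  expect_error(apply_loss(binary_landscape(matrix(0L, 8, 8), 30),
                          loss_scenario("random", 0.1)), "no habitat")
  expect_error(loss_scenario("random", 1.5), "\\(0, 1\\)")
  expect_error(loss_scenario("shrinkage", 0.1), "should be one of")
})

test_that("random loss removes exactly the ceiling of the target count", {
  base <- gen_fractal_landscape(32, p = 0.4, roughness = 1, seed = 9)
  H <- sum(base$cells == 1L)
  f <- 0.137
  res <- apply_loss(base, loss_scenario("random", f, seed = 4))
  expect_equal(sum(res$landscape$cells == 1L), H - ceiling(f * H))
  expect_equal(res$removed_cells, ceiling(f * H))
})

test_that("patch removal takes whole smallest patches first and never splits", {
  # two patches: 2 cells and 10 cells; target 0.2 of 12 cells allows only the small one
  m <- matrix(0L, 6, 8)
  m[1, 1:2] <- 1L
  m[4:5, 2:6] <- 1L
  ls <- binary_landscape(m, cell_size = 30)
  res <- apply_loss(ls, loss_scenario("patch_removal", 0.2))
  expect_equal(res$realized_fraction, 2 / 12)
  expect_equal(res$removed_cells, 2L)
  lab1 <- label_patches(res$landscape)
  expect_equal(lab1$n_patches, 1L)
  expect_equal(lab1$patch_sizes, 10L)

  # a single patch larger than the target: nothing removed, with a warning
  single <- binary_landscape(matrix(1L, 4, 4), cell_size = 30)
  expect_warning(res0 <- apply_loss(single, loss_scenario("patch_removal", 0.3)),
                 "exceeds the removal target")
  expect_equal(res0$realized_fraction, 0)
  expect_identical(res0$landscape$cells, single$cells)
})

test_that("dissection cuts a strip and can split a bar into two patches", {
  m <- matrix(0L, 10, 10)
  m[5, ] <- 1L # 1x10 bar
  ls <- binary_landscape(m, cell_size = 30)
  split_seen <- FALSE
  for (s in 1:40) {
    res <- apply_loss(ls, loss_scenario("dissection", 0.1, seed = s))
    expect_lte(res$removed_cells, 1L) # target ceil(0.1*10) = 1
    n_after <- label_patches(res$landscape)$n_patches
    if (n_after == 2L) split_seen <- TRUE
  }
  expect_true(split_seen) # an interior column cut splits the bar
})

test_that("perforation removes only interior cells", {
  base <- gen_fractal_landscape(48, p = 0.6, roughness = 2.5, seed = 15)
  res <- apply_loss(base, loss_scenario("perforation", 0.05, seed = 1))
  removed <- which(base$cells == 1L & res$landscape$cells == 0L)
  # every removed cell had 4 habitat rook neighbors at t0 (first removal is
  # provably interior; later ones are interior w.r.t. the shrinking map, which
  # is still a subset of t0 habitat neighbors only for the 4 rook directions)
  m0 <- base$cells
  nr <- nrow(m0)
  for (idx in removed) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    expect_false(r == 1 || r == nr || c == 1 || c == ncol(m0))
  }
  expect_gt(res$removed_cells, 0)
})

test_that("cohorts are reproducible from the master seed and sized as configured", {
  cfg <- cohort_config(n_landscapes = 10, grid_cells = 32, radii = c(250, 400),
                       seed = 99)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_equal(nrow(a), 20L) # 10 landscapes x 2 radii
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$seed, rep(99L + 1:10, each = 2))

  # a different master seed gives a different cohort
  c2 <- gen_cohort(cohort_config(n_landscapes = 10, grid_cells = 32,
                                 radii = c(250, 400), seed = 100))
  expect_false(identical(a$p_habitat_t0, c2$p_habitat_t0))
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(radii = c(500, 250)), "radii")
  expect_error(cohort_config(radii = c(250, 5000)), "does not fit")
  expect_error(cohort_config(scenario_weights = c(random = 0.5)), "sum to 1")
  expect_error(cohort_config(scenario_weights = c(melt = 1)), "kinds")
  expect_error(cohort_config(loss_range = c(0, 0.5)))
})

test_that("a pure patch-removal cohort only ever decreases patch counts", {
  cfg <- cohort_config(
    n_landscapes = 15, grid_cells = 48, radii = 600,
    scenario_weights = c(random = 0, erosion = 0, patch_removal = 1,
                         dissection = 0, perforation = 0),
    p_range = c(0.3, 0.6), seed = 7
  )
  rec <- gen_cohort(cfg) |> add_change()
  lost <- rec[rec$realized_fraction > 0 & rec$forest_loss > 0, ]
  expect_gt(nrow(lost), 0)
  expect_true(all(lost$delta_patch_number <= 0))
})
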