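test_that("forest loss is the difference of proportions, gains negative", {
  expect_equal(forest_loss(0.60, 0.45), 0.15)
  expect_equal(forest_loss(0.30, 0.30), 0)
  expect_equal(forest_loss(0.30, 0.40), -0.10)
  expect_error(forest_loss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("only strictly losing landscapes are retained, order preserved", {
  rec <- tibble::tibble(id = c("a", "b", "c"), forest_loss = c(0.1, 0, -0.2))
  expect_equal(retain_losing(rec)$id, "a")
  expect_equal(nrow(retain_losing(rec[rec$forest_loss < 0, ])), 0L)
  expect_error(retain_losing(tibble::tibble(id = "a")), "forest_loss")

  withr::with_seed(5, {
    loss <- runif(50, -0.5, 0.5)
    rec <- tibble::tibble(id = seq_len(50), forest_loss = loss)
    kept <- retain_losing(rec)
    expect_equal(nrow(kept), sum(loss > 0))
    expect_equal(kept$id, rec$id[rec$forest_loss > 0])
  })
})

test_that("classification orients every metric so positive = more fragmented", {
  expect_equal(as.character(classify_change(3 - 5, "patch_number")), "decrease")
  # mean patch size growing from 0.5 to 0.9 ha is decreasing fragmentation
  expect_equal(as.character(classify_change(0.9 - 0.5, "mean_patch_size")),
               "decrease")
  expect_equal(as.character(classify_change(1e-15, "edge_density", eps = 1e-9)),
               "no_change")
  expect_equal(as.character(classify_change(0.2, "ffi")), "increase")
  expect_error(classify_change(1, "compactness"), "should be one of")
  expect_error(classify_change(1, "ffi", eps = -1), "non-negative")
})

test_that("patch-number classification ignores eps and exactly one class is assigned", {
  for (eps in c(0, 1e-3, 10)) {
    expect_equal(as.character(classify_change(1L, "patch_number", eps)), "increase")
    expect_equal(as.character(classify_change(-1L, "patch_number", eps)), "decrease")
    expect_equal(as.character(classify_change(0L, "patch_number", eps)), "no_change")
  }
  withr::with_seed(6, {
    d <- c(rnorm(50), 0)
    cls <- classify_change(d, "edge_density")
    expect_false(any(is.na(cls)))
    expect_equal(levels(cls), c("increase", "decrease", "no_change"))
  })
})

test_that("mean-patch-size classification equals an oriented metric on the negated delta", {
  withr::with_seed(7, {
    d <- rnorm(100)
    expect_equal(classify_change(d, "mean_patch_size"),
                 classify_change(-d, "edge_density"))
  })
})

test_that("cover bins are left-closed with a closed top bin", {
  expect_equal(as.character(bin_cover(0.35)), "[0.2,0.4)")
  expect_equal(as.character(bin_cover(1.0)), "[0.8,1]")
  expect_equal(as.character(bin_cover(0.2)), "[0.2,0.4)")
  expect_equal(as.character(bin_cover(0)), "[0,0.2)")
  expect_error(bin_cover(1.3), "\\[0, 1\\]")
})

test_that("loss bins are right-closed on (0,1] and NA for non-losses", {
  expect_equal(as.character(bin_loss(0.05)), "(0,0.1]")
  expect_equal(as.character(bin_loss(0.1)), "(0,0.1]")
  expect_equal(as.character(bin_loss(0.11)), "(0.1,0.2]")
  expect_true(is.na(bin_loss(0)))
  expect_true(is.na(bin_loss(-0.2)))
})

hand_records <- function() {
  tibble::tibble(
    id = sprintf("r%d", 1:4),
    biome = c("A", "A", "A", "A"),
    radius_m = 250,
    p_habitat_t0 = c(0.5, 0.6, 0.7, 0.8),
    p_habitat_t1 = c(0.4, 0.5, 0.6, 0.7),
    n_patches_t0 = c(2L, 3L, 5L, 4L),
    n_patches_t1 = c(3L, 4L, 4L, 4L),
    edge_density_t0 = c(10, 10, 10, 10),
    edge_density_t1 = c(12, 12, 8, 10),
    mean_patch_size_t0 = c(1, 1, 1, 1),
    mean_patch_size_t1 = c(0.5, 0.5, 2, 1)
  )
}

test_that("summaries reproduce a hand tally and sum to 100", {
  rec <- hand_records() |> add_change() |> retain_losing()
  # patch number: +1, +1, -1, 0  -> 50% increase, 25% decrease, 25% no change
  s <- summarize_outcomes(rec, group_by = "radius", metrics = "patch_number")
  expect_equal(s$n, 4L)
  expect_equal(s$pct_increase, 50)
  expect_equal(s$pct_decrease, 25)
  expect_equal(s$pct_no_change, 25)

  one <- summarize_outcomes(rec[1, ], group_by = "radius")
  expect_true(all(one$pct_increase %in% c(0, 100) &
                  one$pct_decrease %in% c(0, 100) &
                  one$pct_no_change %in% c(0, 100)))
  expect_error(summarize_outcomes(rec[0, ], "radius"), "no records")
})

test_that("summary percentages sum to 100 per group on random cohorts", {
  withr::with_seed(8, {
    n <- 1000
    rec <- tibble::tibble(
      radius_m = sample(c(250, 500, 1000), n, replace = TRUE),
      biome = sample(forest_biomes, n, replace = TRUE),
      p_habitat_t0 = runif(n),
      forest_loss = runif(n, 1e-4, 0.9),
      delta_patch_number = sample(-3:3, n, replace = TRUE),
      delta_edge_density = rnorm(n),
      delta_mean_patch_size = rnorm(n)
    ) |>
      dplyr::mutate(
        cover_bin = bin_cover(p_habitat_t0),
        loss_bin = bin_loss(forest_loss),
        class_patch_number = classify_change(delta_patch_number, "patch_number"),
        class_edge_density = classify_change(delta_edge_density, "edge_density"),
        class_mean_patch_size = classify_change(delta_mean_patch_size,
                                                "mean_patch_size")
      )
    for (g in c("radius", "cover_bin", "loss_bin", "biome")) {
      s <- summarize_outcomes(rec, group_by = g)
      expect_true(all(abs(s$pct_increase + s$pct_decrease + s$pct_no_change
                          - 100) < 1e-9))
      expect_true(all(s$n > 0))
      # per grouping and metric, group sizes account for every record
      tot <- dplyr::summarize(dplyr::group_by(s, metric), n = sum(n))
      expect_true(all(tot$n == nrow(rec)))
    }
  })
})

test_that("add_change computes loss and deltas consistently with its inputs", {
  rec <- hand_records() |> add_change()
  expect_equal(rec$forest_loss, rec$p_habitat_t0 - rec$p_habitat_t1,
               tolerance = 1e-12)
  expect_equal(rec$delta_patch_number, rec$n_patches_t1 - rec$n_patches_t0)
  expect_equal(rec$delta_mean_patch_size,
               rec$mean_patch_size_t1 - rec$mean_patch_size_t0)
})
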