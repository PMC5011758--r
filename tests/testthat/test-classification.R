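test_that("count_holes applies the strict half-depth bridge rule", {
  expect_identical(count_holes(2.0, 0.8), 2L)   # 0.8 < 1.0
  expect_identical(count_holes(2.0, 1.2), 1L)   # 1.2 >= 1.0
  expect_identical(count_holes(2.0, 1.0), 1L)   # boundary -> milder (one hole)
  expect_identical(count_holes(2.0, NULL), 1L)  # no bridge
  expect_identical(count_holes(2.0, 0), 2L)
  expect_error(count_holes(2.0, 2.5), "geometrically impossible")
  expect_error(count_holes(-1, 0.5), "vd1_mm")
})

test_that("classify_lesion applies cyst rule first, then Hd1, strictly", {
  awl <- awl_spec(1.2, 2.0)
  expect_identical(classify_lesion(2.0, 3.0, awl), "residual_hole")
  expect_identical(classify_lesion(2.5, 3.0, awl), "peri_hole_resorption")
  # cyst irrespective of Hd1
  expect_identical(classify_lesion(1.0, 4.0, awl), "subchondral_cyst")
  expect_identical(classify_lesion(5.0, 4.0, awl), "subchondral_cyst")
  # boundaries fall to the milder class (strict inequalities)
  expect_identical(classify_lesion(2.4, 0.5, awl), "residual_hole")
  expect_identical(classify_lesion(2.5, 3.6, awl), "peri_hole_resorption")
  # vectorized
  expect_identical(classify_lesion(c(2.0, 2.5, 1.0), c(3.0, 3.0, 4.0), awl),
                   c("residual_hole", "peri_hole_resorption", "subchondral_cyst"))
  expect_error(classify_lesion(c(1, 2), 1, awl), "equal length")
  expect_error(classify_lesion(-1, 1, awl), "non-negative")
})

test_that("custom threshold_config changes the classification", {
  awl <- awl_spec(1.2, 2.0)
  cfg <- threshold_config(hd1_multiplier = 3, hd2_multiplier = 4)
  expect_identical(classify_lesion(2.5, 3.0, awl, cfg), "residual_hole")
  expect_identical(classify_lesion(2.5, 5.0, awl, cfg), "subchondral_cyst")
  expect_error(threshold_config(hd1_multiplier = -1), "hd1_multiplier")
})

test_that("classify_osteophyte requires strict protrusion above the line", {
  bridge_above <- structure(list(present = TRUE, apex_depth_mm = -0.2),
                            class = "bridge_measure")
  bridge_below <- structure(list(present = TRUE, apex_depth_mm = 0.3),
                            class = "bridge_measure")
  bridge_at <- structure(list(present = TRUE, apex_depth_mm = 0),
                         class = "bridge_measure")
  expect_true(classify_osteophyte(bridge_above, NULL))
  expect_false(classify_osteophyte(bridge_below, NULL))
  expect_false(classify_osteophyte(bridge_at, NULL))
  osteo <- data.frame(h0_mm = 0.3, width_mm = 0.5, area_mm2 = 0.1,
                      location = "peripheral")
  expect_true(classify_osteophyte(NULL, osteo))
  expect_false(classify_osteophyte(NULL, NULL))
})

test_that("check_reconstitution is TRUE only when no slice deviates", {
  expect_true(check_reconstitution(NULL))
  expect_true(check_reconstitution(list(NULL, NULL)))
  fake_region <- structure(list(), class = "defect_region")
  expect_false(check_reconstitution(fake_region))
  expect_false(check_reconstitution(list(NULL, fake_region)))
})

test_that("an intact phantom slice reports complete reconstitution", {
  g <- matrix(40L, 200, 400)
  g[90:200, ] <- 180L
  img <- calibrated_image(g, 0.015)
  rep <- analyze_defect(img, awl = awl_spec())
  expect_true(rep$reconstituted)
  expect_identical(unname(rep$class_counts["complete_reconstitution"]), 1L)
  expect_identical(sum(rep$class_counts) - rep$class_counts[["complete_reconstitution"]], 0L)
})

test_that("analyze_defect recovers a simple residual hole end to end", {
  ph <- generate_phantom(simple_spec(hd1 = 2.0, hd2 = 1.5, depth = 1.6))
  rep <- analyze_defect(ph$image, awl = awl_spec())
  expect_false(rep$reconstituted)
  expect_identical(nrow(rep$holes), 1L)
  expect_identical(rep$holes$class, "residual_hole")
  m <- as.data.frame(rep)
  expect_equal(m$hd1_mm, 2.0, tolerance = 0.03)
  expect_equal(m$vd1_mm, 1.6, tolerance = 0.03)
})

test_that("worst-case severity aggregates a hole across slices", {
  # slice 1 renders a residual hole, slice 2 the same hole eroded open
  ph1 <- generate_phantom(simple_spec(hd1 = 2.0, hd2 = 1.5, seed = 1L))
  ph2 <- generate_phantom(simple_spec(hd1 = 3.1, hd2 = 2.4, seed = 2L))
  rep <- analyze_defect(list(ph1$image, ph2$image), awl = awl_spec())
  expect_identical(nrow(rep$holes), 1L)
  expect_identical(rep$holes$n_slices, 2L)
  expect_identical(rep$holes$class, "peri_hole_resorption")
})

test_that("annotated cement line and extent drive the analysis", {
  sp <- simple_spec(hd1 = 2.0, hd2 = 1.5, slope = 0.02)
  ph <- generate_phantom(sp)
  ann <- annotation_set(
    cement_line_endpoints = rbind(c(0, sp$cement_line_depth_mm),
                                  c(8, sp$cement_line_depth_mm + 8 * 0.02)),
    defect_extent_mm = c(2.8, 5.2),
    awl = awl_spec()
  )
  rep <- analyze_defect(ph$image, annotations = ann)
  expect_identical(rep$holes$class, "residual_hole")
  expect_equal(as.data.frame(rep)$hd1_mm, 2.0, tolerance = 0.03)
})

test_that("threshold_sweep counts are monotone in each multiplier", {
  set.seed(99)
  m <- data.frame(hd1_mm = runif(200, 0, 6), hd2_mm = runif(200, 0, 6))
  tab <- threshold_sweep(m)
  expect_identical(nrow(tab), 9L)
  expect_identical(rowSums(tab[, 3:5]), rep(200, 9))
  for (h2 in unique(tab$hd2_multiplier)) {
    sub <- tab[tab$hd2_multiplier == h2, ]
    sub <- sub[order(sub$hd1_multiplier), ]
    expect_true(all(diff(sub$peri_hole_resorption) <= 0))
  }
  for (h1 in unique(tab$hd1_multiplier)) {
    sub <- tab[tab$hd1_multiplier == h1, ]
    sub <- sub[order(sub$hd2_multiplier), ]
    expect_true(all(diff(sub$subchondral_cyst) <= 0))
  }
  expect_error(threshold_sweep(data.frame()), "non-empty")
})
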