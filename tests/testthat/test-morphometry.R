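test_that("fit_cement_line recovers a known sloped line from the mask", {
  sp <- simple_spec(slope = 0.025, line_depth = 1.3)
  ph <- generate_phantom(sp)
  line <- fit_cement_line(segment_bone(ph$image))
  expect_lt(abs(line$intercept_mm - 1.3), 0.02)
  expect_lt(abs(line$slope - 0.025), 0.005)
})

test_that("annotated endpoints give the exact line", {
  sp <- simple_spec()
  ph <- generate_phantom(sp)
  line <- fit_cement_line(segment_bone(ph$image),
                          endpoints = rbind(c(1, 1.25), c(7, 1.37)))
  expect_equal(line$intercept_mm, 1.23)
  expect_equal(line$slope, 0.02)
  expect_identical(line$provenance, "annotated")
})

test_that("the line fit resists a defect occupying most of the width", {
  sp <- phantom_spec(
    list(lesion_spec(2.6, 2.8, 1.7, 2.0), lesion_spec(5.4, 2.8, 1.7, 2.0)),
    cement_line_depth_mm = 1.2, cement_line_slope = -0.015,
    bridge_vd2_mm = 1.6, seed = 5L
  )
  ph <- generate_phantom(sp)
  line <- fit_cement_line(segment_bone(ph$image))
  expect_lt(abs(line$intercept_mm - 1.2), 0.03)
  expect_lt(abs(line$slope - -0.015), 0.005)
})

test_that("detect_defect_region finds the defect and NULL on intact bone", {
  ph <- generate_phantom(simple_spec(hd1 = 2.0, center = 4))
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  expect_s3_class(reg, "defect_region")
  expect_equal(reg$x_left_mm, 3.0, tolerance = 0.05)
  expect_equal(reg$x_right_mm, 5.0, tolerance = 0.05)

  intact <- calibrated_image(rbind(matrix(40L, 80, 400), matrix(180L, 120, 400)),
                             0.015)
  m2 <- segment_bone(intact)
  l2 <- fit_cement_line(m2)
  expect_null(detect_defect_region(m2, l2))
})

test_that("detect_bridge finds a sub-line bridge at the right place", {
  sp <- bridge_spec(vd2 = 0.6, mid = 4)
  ph <- generate_phantom(sp)
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  br <- detect_bridge(mask, line, reg)
  expect_true(br$present)
  expect_lt(abs(br$apex_depth_mm - 0.6), 0.03)
  bf <- subchondral:::bridge_floor_interval(sp)
  expect_equal(br$apex_x_mm, mean(bf), tolerance = 0.05)
})

test_that("a single cavity has no bridge", {
  ph <- generate_phantom(simple_spec())
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  expect_false(detect_bridge(mask, line, reg)$present)
})

test_that("measure_vertical and measure_horizontal recover spec values", {
  sp <- simple_spec(hd1 = 2.2, hd2 = 1.6, depth = 1.7)
  ph <- generate_phantom(sp)
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  vert <- measure_vertical(mask, line, reg)
  expect_equal(vert$vd1_mm, 1.7, tolerance = 0.03)
  expect_null(vert$vd2_mm)
  hor <- measure_horizontal(mask, line, reg, awl_spec())
  expect_equal(hor$hd1_mm, 2.2, tolerance = 0.03)
  expect_equal(hor$hd2_mm, 1.6, tolerance = 0.03)
})

test_that("a bulb cyst's Hd2 exceeds its opening and is recovered", {
  sp <- simple_spec(hd1 = 1.6, hd2 = 3.9, depth = 1.5)
  ph <- generate_phantom(sp)
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  hor <- measure_horizontal(mask, line, reg, awl_spec())
  expect_equal(hor$hd1_mm, 1.6, tolerance = 0.03)
  expect_equal(hor$hd2_mm, 3.9, tolerance = 0.03)
})

test_that("a shallow cavity warns and reports hd2 = 0", {
  # depth below the Hd2 level: build with a deep spec, then use a long awl
  sp <- simple_spec(hd1 = 2.0, hd2 = 1.5, depth = 1.1)
  ph <- generate_phantom(sp)
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  long_awl <- awl_spec(1.2, 3.0)  # Hd2 level at 1.5 mm > depth
  expect_warning(hor <- measure_horizontal(mask, line, reg, long_awl),
                 "does not reach")
  expect_identical(hor$hd2_mm, 0)
})

test_that("measure_osteophyte finds height and location of a cap", {
  sp <- simple_spec(osteophyte = list(center_x_mm = 5.4, h0_mm = 0.35,
                                      width_mm = 0.7))
  ph <- generate_phantom(sp)
  mask <- segment_bone(ph$image)
  line <- fit_cement_line(mask)
  reg <- detect_defect_region(mask, line)
  os <- measure_osteophyte(mask, line, reg)
  expect_identical(nrow(os), 1L)
  expect_lt(abs(os$h0_mm - 0.35), 0.03)
})

test_that("label_components distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE
  l4 <- label_components(m, 4L)
  l8 <- label_components(m, 8L)
  expect_identical(max(l4), 3L)
  expect_identical(max(l8), 1L)
})
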