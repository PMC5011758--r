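test_that("lesion_spec and awl_spec validate and auto-select profiles", {
  expect_identical(lesion_spec(4, 2, 1.5, 1.6)$profile, "trapezoid")
  expect_identical(lesion_spec(4, 2, 3.0, 1.6)$profile, "bulb")
  expect_error(lesion_spec(4, -1, 1, 1), "hd1_mm")
  expect_error(awl_spec(0, 2), "diameter_mm")
})

test_that("phantom_spec enforces its geometric invariants", {
  # Hd2 level below cavity depth
  expect_error(simple_spec(depth = 0.8), "Hd2 level below cavity depth")
  # lesion wider than defect
  expect_error(phantom_spec(lesion_spec(4, 2, 1.5, 1.6),
                            defect_extent_mm = c(3.5, 4.5)),
               "lesion wider than defect")
  # bridge needs two lesions
  expect_error(phantom_spec(lesion_spec(4, 2, 1.5, 1.6), bridge_vd2_mm = 0.5),
               "two lesions")
  # two-lesion sections are trapezoid-only
  expect_error(phantom_spec(list(lesion_spec(3, 1, 2, 1.6),
                                 lesion_spec(5, 1, 0.7, 1.6)),
                            bridge_vd2_mm = 0.5),
               "trapezoid")
  # sub-line bridge requires adjacent openings
  expect_error(phantom_spec(list(lesion_spec(2.5, 1, 0.7, 1.6),
                                 lesion_spec(5.5, 1, 0.7, 1.6)),
                            bridge_vd2_mm = 0.5),
               "adjacent")
  # bridge top above both cavity bases
  expect_error(bridge_spec(vd2 = 1.9), "above both cavity bases")
})

test_that("generate_phantom is deterministic and ground truth is analytic", {
  sp <- simple_spec(noise = 8, porosity = 0.1, seed = 11L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  # ground truth echoes the spec analytically
  expect_equal(a$truth$lesions$hd1_mm, 2.0)
  expect_equal(a$truth$lesions$hd2_mm, 1.5)
  expect_equal(a$truth$vd1_mm, 1.6)
  expect_identical(a$truth$hole_count, 1L)
})

test_that("ground-truth classes equal the rules applied to analytic values", {
  # forced classes straight from the spec values
  expect_identical(generate_phantom(simple_spec(2.0, 1.5))$truth$lesions$class,
                   "residual_hole")
  expect_identical(generate_phantom(simple_spec(2.6, 1.9))$truth$lesions$class,
                   "peri_hole_resorption")
  expect_identical(generate_phantom(simple_spec(2.0, 3.8))$truth$lesions$class,
                   "subchondral_cyst")
  # spec-oracle consistency on random specs
  for (s in 1:25) {
    sp <- sample_random_spec(seed = s)
    tr <- ground_truth(sp)
    expect_identical(tr$lesions$class,
                     classify_lesion(tr$lesions$hd1_mm, tr$lesions$hd2_mm,
                                     sp$awl))
    if (!is.na(tr$vd2_mm))
      expect_identical(tr$hole_count, count_holes(tr$vd1_mm, tr$vd2_mm))
  }
})

test_that("bridge height controls the analytic hole count", {
  low <- bridge_spec(vd2 = 0.6, da = 1.8, db = 2.0)    # 0.6 < 0.5 * 2.0
  high <- bridge_spec(vd2 = 1.2, da = 1.8, db = 2.0)   # 1.2 >= 1.0
  expect_identical(ground_truth(low)$hole_count, 2L)
  expect_identical(ground_truth(high)$hole_count, 1L)
})

test_that("osteophyte ground truth echoes the cap", {
  sp <- simple_spec(osteophyte = list(center_x_mm = 5.5, h0_mm = 0.3,
                                      width_mm = 0.7))
  tr <- ground_truth(sp)
  expect_true(tr$osteophyte_present)
  expect_equal(tr$osteophyte$h0_mm, 0.3)
  expect_identical(tr$osteophyte$location, "peripheral")
})

test_that("sample_random_spec is reproducible and respects forced ranges", {
  s1 <- sample_random_spec(seed = 123L)
  s2 <- sample_random_spec(seed = 123L)
  expect_identical(s1, s2)
  # ranges forcing hd2 > 3 * awl diameter -> every class is a cyst
  rg <- phantom_ranges(two_lesion_prob = 0, bulb_prob = 1,
                       hd1_single_mm = c(1.0, 1.6),
                       bulb_hd2_extra_mm = c(2.8, 3.6),
                       osteophyte_prob = 0)
  for (s in 1:10) {
    tr <- ground_truth(sample_random_spec(rg, seed = s))
    expect_identical(tr$lesions$class, "subchondral_cyst")
  }
  expect_error(phantom_ranges(not_a_range = 1), "unknown range")
})

test_that("hd1 straddling twice the awl diameter yields both mild classes", {
  rg <- phantom_ranges(two_lesion_prob = 0, bulb_prob = 0,
                       osteophyte_prob = 0)
  cls <- vapply(1:60, function(s)
    ground_truth(sample_random_spec(rg, seed = s))$lesions$class, character(1))
  expect_true(all(c("residual_hole", "peri_hole_resorption") %in% cls))
})

test_that("rendered bone and background straddle the default threshold", {
  ph <- generate_phantom(simple_spec(noise = 10, porosity = 0.15, seed = 3L))
  m <- segment_bone(ph$image)
  deep <- m$pixels[round(3.5 / 0.015):round(4.4 / 0.015), ]
  expect_gt(mean(deep), 0.6)   # mostly bone below, minus pores
  top <- m$pixels[1:round(0.8 / 0.015), ]
  expect_lt(mean(top), 0.05)   # background above the line
})
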