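test_that("annotation_set validates and lists offending keys", {
  expect_error(annotation_set(cement_line_endpoints = matrix(1, 2, 3)),
               "cement_line")
  expect_error(annotation_set(cement_line_endpoints = rbind(c(1, 2), c(1, 2))),
               "distinct")
  expect_error(annotation_set(cement_line_endpoints = rbind(c(1, 2), c(1, 3))),
               "vertical")
  expect_error(annotation_set(defect_extent_mm = c(5, 2)), "x_left < x_right")
  expect_error(annotation_set(awl = list(d = 1)), "awl_spec")
  ann <- annotation_set(cement_line_endpoints = rbind(c(0, 1.2), c(8, 1.3)),
                        defect_extent_mm = c(2, 6), awl = awl_spec())
  expect_s3_class(ann, "annotation_set")
})

test_that("annotations round-trip through JSON", {
  ann <- annotation_set(cement_line_endpoints = rbind(c(0, 1.2), c(8, 1.36)),
                        defect_extent_mm = c(2.5, 5.5),
                        awl = awl_spec(1.2, 2.0))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(unname(back$cement_line_endpoints),
               unname(ann$cement_line_endpoints))
  expect_equal(back$defect_extent_mm, ann$defect_extent_mm)
  expect_equal(back$awl$diameter_mm, 1.2)
})

test_that("unknown annotation keys error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"defect_extent_mm": [1, 2], "bogus": 1}', path)
  expect_error(read_annotations(path), "unknown keys")
})
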