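test_that("percent agreement is the concordant fraction times 100", {
  r1 <- c("a", "a", "b", "c")
  r2 <- c("a", "b", "b", "c")
  expect_equal(percent_agreement(r1, r2), 75)
  expect_equal(percent_agreement(r1, r1), 100)
})

test_that("kappa is 1 for identical non-constant ratings", {
  r <- rep(c("x", "y", "z"), times = c(5, 3, 2))
  expect_equal(cohen_kappa(r, r), 1)
})

test_that("kappa is 0 on the 4-item example with p_o = p_e = 0.5", {
  # oracle by hand: table (a,a),(a,b),(b,a),(b,b): p_o = 0.5,
  # marginals 0.5/0.5 for both raters so p_e = 0.5, kappa = 0
  r1 <- c("a", "a", "b", "b")
  r2 <- c("a", "b", "a", "b")
  expect_equal(cohen_kappa(r1, r2), 0)
})

test_that("kappa matches the closed-form oracle on a 3-category table", {
  # hand oracle: r1 = a,a,b,b,c,c,a,b ; r2 = a,b,b,c,c,a,a,b
  r1 <- c("a", "a", "b", "b", "c", "c", "a", "b")
  r2 <- c("a", "b", "b", "c", "c", "a", "a", "b")
  p_o <- mean(r1 == r2)                       # 5/8
  p1 <- table(factor(r1, c("a", "b", "c"))) / 8
  p2 <- table(factor(r2, c("a", "b", "c"))) / 8
  p_e <- sum(p1 * p2)
  expect_equal(cohen_kappa(r1, r2), (p_o - p_e) / (1 - p_e))
  # cross-check against the independently implemented e1071 version
  skip_if_not_installed("e1071")
  ca <- e1071::classAgreement(table(r1, r2))
  expect_equal(cohen_kappa(r1, r2), ca$kappa)
})

test_that("constant identical ratings give kappa 1 with a warning", {
  r <- rep("a", 5)
  expect_warning(k <- cohen_kappa(r, r), "undefined")
  expect_equal(k, 1)
  expect_warning(k2 <- cohen_kappa(rep("a", 4), c("a", "a", "a", "a")), "undefined")
  expect_equal(k2, 1)
})

test_that("rating vectors are validated", {
  expect_error(rating_table(c("a", "b"), "a"), "equal length")
  expect_error(rating_table(character(0), character(0)), "non-empty")
  expect_error(rating_table(c("a", NA), c("a", "b")), "missing")
})

test_that("agreement_stats bundles n, agreement and kappa", {
  r1 <- c("a", "a", "b", "b")
  r2 <- c("a", "b", "a", "b")
  st <- agreement_stats(r1, r2)
  expect_equal(st$n, 4)
  expect_equal(st$n_agree, 2)
  expect_equal(st$percent_agreement, 50)
  expect_equal(st$kappa, 0)
  expect_equal(dim(st$table), c(2L, 2L))
})

test_that("read_ratings accepts item_id, rater_a, rater_b CSVs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,rater_a,rater_b", "1,x,x", "2,x,y", "3,y,y"), path)
  r <- read_ratings(path)
  expect_identical(names(r), c("rater1", "rater2"))
  expect_identical(r$rater1, c("x", "x", "y"))
  expect_identical(r$rater2, c("x", "y", "y"))
})
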