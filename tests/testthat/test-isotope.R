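# Lipid correction, table validation, Layman ranges and Mardia's test.

test_that("lipid correction follows the mass-balance equation", {
  # hand arithmetic: (-16*4 + 7*0.3)/4 = -15.475
  r <- lipid_correct(-16.0, 4.0)
  expect_equal(r$d13C, -15.475)
  expect_true(r$applied)
  # the rule is strictly "> 3.7": at and below threshold nothing happens
  expect_equal(lipid_correct(-16.0, 3.7), data.frame(d13C = -16, applied = FALSE))
  expect_equal(lipid_correct(-14.0, 3.0), data.frame(d13C = -14, applied = FALSE))
  # vectorized over rows
  v <- lipid_correct(c(-16, -14, -18), c(4.0, 3.0, 5.2))
  expect_equal(v$applied, c(TRUE, FALSE, TRUE))
  expect_equal(v$d13C[2], -14)
  expect_error(lipid_correct(-16, 0), "positive")
  expect_error(lipid_correct(-16, -2), "positive")
})

test_that("the lipid_corrected flag prevents double application", {
  tab <- data.frame(species = "s", area = "inner", total_length_mm = 300,
                    d13C = -16, d15N = 12, d34S = 19, CN_ratio = 4.0,
                    lipid_corrected = FALSE)
  once <- prepare_isotopes(tab)
  expect_equal(once$d13C, -15.475)
  expect_true(once$lipid_corrected)
  twice <- prepare_isotopes(once)
  expect_equal(twice$d13C, once$d13C)   # guarded: no second correction
  # applying the raw equation twice WOULD move the value again
  raw_twice <- lipid_correct(once$d13C, 4.0)$d13C
  expect_false(isTRUE(all.equal(raw_twice, once$d13C)))
})

test_that("table validation reports failing rows instead of dropping them", {
  tab <- data.frame(
    species = c("a", "a", "b", "b"),
    area = c("inner", "outer", "lagoon", "inner"),
    total_length_mm = c(300, 310, 320, 330),
    d13C = c(-16, NA, -15, -17),
    d15N = c(12, 12.5, 13, 12.2),
    d34S = c(19, 18, 19.5, 18.7),
    CN_ratio = c(3.5, 3.6, 3.8, -1)
  )
  v <- validate_isotope_table(tab)
  expect_equal(nrow(v$table), 1)
  expect_setequal(v$excluded$reason,
                  c("missing isotope value", "area not in {inner, outer}",
                    "non-positive or missing C:N ratio"))
  expect_error(validate_isotope_table(tab[, -4]), "missing columns")
  tab$d13C <- -16; tab$CN_ratio <- 3.5; tab$area <- "inner"
  tab$d34S[1] <- 55
  expect_warning(validate_isotope_table(tab), "0-40")
})

test_that("Layman ranges are per-axis max minus min", {
  tab <- data.frame(d13C = c(-16, -13), d15N = c(12, 12.5), d34S = c(18, 19))
  r <- layman_ranges(tab)
  expect_equal(unname(r), c(3.0, 0.5, 1.0))
  # identical rows give zero ranges; order never matters
  same <- tab[c(1, 1), ]
  expect_equal(unname(layman_ranges(same)), c(0, 0, 0))
  set.seed(1)
  big <- data.frame(d13C = rnorm(20), d15N = rnorm(20), d34S = rnorm(20))
  expect_equal(layman_ranges(big), layman_ranges(big[sample(20), ]))
  expect_error(layman_ranges(tab[1, ]), "range undefined")
})

test_that("adding a row never shrinks a Layman range", {
  set.seed(2)
  base <- data.frame(d13C = rnorm(5), d15N = rnorm(5), d34S = rnorm(5))
  r0 <- layman_ranges(base)
  for (i in 1:20) {
    extra <- rbind(base, data.frame(d13C = rnorm(1), d15N = rnorm(1),
                                    d34S = rnorm(1)))
    expect_true(all(layman_ranges(extra) >= r0 - 1e-12))
  }
})

test_that("Mardia skewness vanishes for exactly symmetric data", {
  xs <- rbind(diag(3), -diag(3), 2 * diag(3), -2 * diag(3))
  m <- mardia_test(xs, corrected_skewness = FALSE)
  expect_equal(m$skewness, 0, tolerance = 1e-10)
})

test_that("Mardia statistics are affine invariant", {
  set.seed(3)
  x <- MASS::mvrnorm(40, rep(0, 3), diag(3))
  m0 <- mardia_test(x)
  for (i in 1:3) {
    a <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
    y <- x %*% t(a) + matrix(rnorm(3), 40, 3, byrow = TRUE)
    m1 <- mardia_test(y)
    expect_equal(m1$skewness, m0$skewness, tolerance = 1e-8)
    expect_equal(m1$kurtosis, m0$kurtosis, tolerance = 1e-8)
  }
})

test_that("the small-sample correction kicks in below n = 20", {
  set.seed(4)
  x <- MASS::mvrnorm(15, rep(0, 3), diag(3))
  auto <- mardia_test(x)
  expect_true(auto$corrected)
  raw <- mardia_test(x, corrected_skewness = FALSE)
  n <- 15; p <- 3
  k <- ((p + 1) * (n + 1) * (n + 3)) / (n * ((n + 1) * (p + 1) - 6))
  expect_equal(auto$skewness, raw$skewness * k)
  expect_false(mardia_test(MASS::mvrnorm(25, rep(0, 3), diag(3)))$corrected)
})

test_that("Mardia rejection rates are near nominal under normality", {
  set.seed(5)
  res <- replicate(40, {
    m <- mardia_test(MASS::mvrnorm(500, rep(0, 3), diag(c(1, 2, 0.5))))
    c(skew = m$skewness_p < 0.05, kurt = m$kurtosis_p < 0.05)
  })
  expect_lte(mean(res["skew", ]), 0.10)   # nominal 0.05
  expect_lte(mean(res["kurt", ]), 0.10)
  expect_gte(mean(rowSums(res) == 0), 0)  # sanity: res well-formed
})

test_that("Mardia detects heavy componentwise skew", {
  set.seed(6)
  x <- cbind(rexp(200), rexp(200), rexp(200))
  m <- mardia_test(x)
  expect_lt(m$skewness_p, 0.05)
  expect_false(m$normal)
})

test_that("Mardia input contracts hold", {
  expect_error(mardia_test(MASS::mvrnorm(4, rep(0, 3), diag(3))), "at least 5")
  col <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(mardia_test(col), "singular")
})

test_that("group metrics assemble ranges and normality by species-area", {
  set.seed(7)
  tab <- simulate_groups(list(
    group_spec("a", "inner", 10, c(-16, 12, 19), diag(0.3, 3)),
    group_spec("b", "inner", 3, c(-15, 13, 18), diag(0.3, 3)),
    group_spec("a", "outer", 8, c(-17, 12, 20), diag(0.3, 3))
  ), seed = 8)
  gm <- group_metrics(prepare_isotopes(tab))
  expect_equal(nrow(gm), 3)
  expect_equal(gm$n[gm$species == "b"], 3)
  expect_true(is.na(gm$mardia_skew_p[gm$species == "b"]))  # n < 5
  expect_false(anyNA(gm$cr))                               # all n >= 2
})
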