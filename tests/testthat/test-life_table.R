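test_that("CSV life tables read back what was written, and closure is forced", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex,qx", "46,female,0.002", "47,female,0.0022", "48,female,1"), path)
  lt <- read_life_table(path, "csv")
  expect_s3_class(lt, "life_table")
  expect_equal(lt$qx[lt$age == 46], 0.002)
  expect_equal(lt$qx[lt$age == 48], 1)

  # round trip on the CSV dialect is the identity
  out <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, out)
  back <- read_life_table(out, "csv")
  expect_equal(back[c("sex", "age", "qx")], lt[c("sex", "age", "qx")],
               ignore_attr = TRUE)
})

test_that("malformed life-table files fail with named columns and rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,qx", "46,0.002"), path)
  expect_error(read_life_table(path, "csv"), "missing column 'sex'")

  writeLines(c("age,sex,qx", "46,female,1.3", "47,female,1"), path)
  expect_error(read_life_table(path, "csv"), "qx outside \\[0, 1\\] at row 1")
})

test_that("HMD-style text tables parse, including the open-ended terminal age", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Spain, Life tables (period 1x1), Females",
    "",
    "  Year          Age         mx       qx       ax         lx      dx      Lx       Tx      ex",
    "  2016           45      0.00110  0.00110   0.50     97000     107   96947  3900000   40.21",
    "  2016           46      0.00210  0.00210   0.50     96893     203   96792  3803053   39.25",
    "  2016           47      0.00230  0.00230   0.50     96690     222   96579  3706261   38.33",
    "  2016           48      0.00250  0.00250   0.50     96468     241   96347  3609682   37.42",
    "  2016           49+     0.70000  1.00000   0.50       100     100      50       50    0.50"
  ), path)
  # hand parse of the fixture: q(46) printed as 0.00210, terminal 49+ closes at 1
  lt <- read_life_table(path, "hmd_txt", sex = "female")
  expect_equal(lt$qx[lt$age == 46], 0.00210)
  expect_equal(lt$age[nrow(lt)], 49L)
  expect_equal(lt$qx[nrow(lt)], 1)
  expect_error(read_life_table(path, "csv"), "missing column")
})

test_that("constant-hazard synthesis reduces to q = 1 - exp(-a)", {
  lt <- synthetic_life_table(a = 0.01, b = 0, c = 0, max_age = 50, sex = "x")
  expect_equal(unique(lt$qx[-nrow(lt)]), 1 - exp(-0.01))
  expect_equal(lt$qx[nrow(lt)], 1)
  expect_error(synthetic_life_table(a = 0), "positive")
  expect_error(synthetic_life_table(a = 1, max_age = 130), "120")
})

test_that("Gompertz-Makeham q matches fine-step numeric hazard integration", {
  a <- 2.7e-5; b <- 0.095; cc <- 5e-4
  lt <- synthetic_life_table(a, b, cc, sex = "x")
  for (x in c(46, 70, 90)) {
    tt <- seq(x, x + 1, length.out = 20001)
    m <- cc + a * exp(b * tt)
    H_num <- sum((m[-1] + m[-length(m)]) / 2) * (tt[2] - tt[1])  # trapezoid
    expect_equal(lt$qx[lt$age == x], 1 - exp(-H_num), tolerance = 1e-6)
  }
})

test_that("annual survival products match the closed-form survivor function", {
  a <- 2.7e-5; b <- 0.095; cc <- 5e-4
  lt <- synthetic_life_table(a, b, cc, sex = "x")
  sub <- lt[lt$age >= 46 & lt$age <= 99, ]
  s_table <- prod(1 - sub$qx)
  expect_equal(s_table, gm_surv(100, 46, a, b, cc), tolerance = 1e-4)
})

test_that("fixture life tables hit their target life expectancy and shape", {
  lt <- fixture_life_table()
  expect_equal(life_expectancy(lt, 46, "female"), 37, tolerance = 0.01)
  expect_equal(life_expectancy(lt, 46, "male"), 33, tolerance = 0.01)
  for (s in c("female", "male")) {
    q <- lt$qx[lt$sex == s & lt$age >= 30 & lt$age <= 100]
    expect_true(all(diff(q) >= 0))
    expect_equal(lt$qx[lt$sex == s][nrow(lt[lt$sex == s, ])], 1)
  }
})

test_that("death_prob applies the relative risk on the hazard scale", {
  lt <- flat_table(0.01)
  # rr = 1 is the identity
  expect_equal(death_prob(lt, 50, rr = 1), 0.01)
  # direct evaluation of 1 - (1 - q)^rr
  expect_equal(death_prob(lt, 50, rr = 1.68), 1 - 0.99^1.68)
  # cross-check against fine-step integration of the scaled hazard
  h <- -log(1 - 0.01)
  expect_equal(death_prob(lt, 50, rr = 1.68), 1 - exp(-1.68 * h), tolerance = 1e-12)
  # absorbing boundary: terminal q = 1 stays 1 under any rr
  expect_equal(death_prob(lt, 110, rr = 0.3), 1)
  # above the table maximum: certain death
  expect_equal(death_prob(lt, 200, rr = 1), 1)
  expect_error(death_prob(lt, 50, sex = "male"), "not present")
  expect_error(death_prob(lt, 50, rr = 0), "positive")
})

test_that("the adjusted death probability is nondecreasing in the relative risk", {
  set.seed(42)
  for (i in 1:200) {
    q <- runif(1, 0.0001, 0.999)
    rr <- sort(runif(2, 0.1, 5))
    lt <- flat_table(q)
    expect_lte(death_prob(lt, 50, rr = rr[1]), death_prob(lt, 50, rr = rr[2]))
  }
})

test_that("mixed-sex queries weight the two sexes by the female fraction", {
  lt <- fixture_life_table()
  qf <- death_prob(lt, 60, rr = 1.68, sex = "female")
  qm <- death_prob(lt, 60, rr = 1.68, sex = "male")
  expect_equal(death_prob(lt, 60, rr = 1.68, female_fraction = 0.681),
               0.681 * qf + 0.319 * qm)
})
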