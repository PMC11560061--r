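test_that("mean criterion is the weighted inverse test information", {
  one <- items(1, 0)
  expect_equal(crit_mean(one, ability_grid(0, 1)), 4.0)
  # weight splitting across duplicated points changes nothing
  split <- combine_schemes(list(list(grid = ability_grid(0, 1), mass = 1),
                                list(grid = ability_grid(0, 1), mass = 1)))
  expect_equal(crit_mean(one, split), 4.0)
  expect_equal(crit_mean(items(1, c(0, 0)), ability_grid(0, 1)), 2.0)
})

test_that("growth criterion matches hand evaluation and its symmetries", {
  des <- growth_design(items(1, -0.5), items(1, 0), items(1, 0.5))
  g1 <- ability_grid(-0.5, 1)
  g2 <- ability_grid(0.5, 1)
  expect_equal(crit_growth(des, g1, g2), 4.123679, tolerance = 1e-6)

  # reflection: negate difficulties, swap unique roles and grids
  set.seed(3)
  for (k in 1:5) {
    d <- random_design(3, 2, 3)
    h1 <- make_normal_grid(-0.7, 1, 11, 3)
    h2 <- make_normal_grid(0.7, 1, 11, 3)
    mirrored <- growth_design(items(d$unique2$a, -d$unique2$b),
                              items(d$common$a, -d$common$b),
                              items(d$unique1$a, -d$unique1$b))
    expect_equal(crit_growth(d, h1, h2), crit_growth(mirrored, h1, h2),
                 tolerance = 1e-12)
    # adding an anchor strictly decreases the criterion
    bigger <- growth_design(d$unique1, rbind(d$common, items(1, 0)), d$unique2)
    expect_lt(crit_growth(bigger, h1, h2), crit_growth(d, h1, h2))
  }
})

test_that("percentile criterion standardizes weights across both sums", {
  des <- growth_design(items(1, 0), NULL, items(1, 0))
  p1 <- make_percentile_grid(50, 0, 1)
  expect_equal(crit_percentile(des, p1, p1), 4.0)
  des2 <- growth_design(items(2, 0), NULL, items(2, 0))
  expect_equal(crit_percentile(des2, p1, p1), 1.0)
  # with one-point grids the percentile and growth criteria coincide up to
  # the joint standardization (each grid mass 1/2 instead of 1)
  expect_equal(crit_percentile(des, p1, p1),
               crit_growth(des, p1, p1) / 2)
})

test_that("criterion evaluation equals a naive double-loop oracle", {
  set.seed(19)
  for (k in 1:100) {
    n1 <- sample(1:4, 1); nc <- sample(0:3, 1); n2 <- sample(1:4, 1)
    d <- random_design(n1, nc, n2)
    g1 <- make_normal_grid(runif(1, -1, 0), 1, sample(3:12, 1), runif(1, 2, 4))
    g2 <- make_normal_grid(runif(1, 0, 1), 1, sample(3:12, 1), runif(1, 2, 4))
    expected <- naive_crit_growth(d, g1, g2)
    expect_equal(crit_growth(d, g1, g2), expected, tolerance = 1e-12)
    # compiled batch path agrees too
    a <- c(d$unique1$a, d$common$a, d$unique2$a)
    b <- c(d$unique1$b, d$common$b, d$unique2$b)
    obj <- growthdesign:::make_growth_objective(a, n1, nc, n2, g1, g2)
    expect_equal(obj(b), expected, tolerance = 1e-12)
  }
})

test_that("case objectives assemble the documented weight schemes", {
  sp <- criterion_spec(d = 1, a_level = 1, n1 = 2, nc = 1, n2 = 2, l = 7,
                       half_width = 3)
  b <- c(-0.8, -0.2, 0.1, 0.4, 0.9)

  # case 1 is the growth criterion itself
  obj1 <- build_case_objective(1, sp)
  des <- unpack_design(b, 1, 2, 1, 2)
  expect_equal(obj1(b),
               crit_growth(des, make_normal_grid(-0.5, 1, 7, 3),
                           make_normal_grid(0.5, 1, 7, 3)),
               tolerance = 1e-12)

  # case 4 with zero shift duplicates case 1's weights, renormalized
  sp4 <- sp; sp4$group_shift <- 0
  obj4 <- build_case_objective(4, sp4)
  expect_equal(obj4(b), obj1(b) / 2, tolerance = 1e-12)

  # case 3: six-component weighted sum, summed by hand
  sp3 <- sp; sp3$percentiles <- c(25, 50, 75)
  obj3 <- build_case_objective(3, sp3)
  q1 <- qnorm(c(.25, .5, .75), -0.5, 1)
  q2 <- qnorm(c(.25, .5, .75), 0.5, 1)
  w <- c(dnorm(q1, -0.5, 1), dnorm(q2, 0.5, 1))
  w <- w / sum(w)
  hand <- sum(w[1:3] / sapply(q1, function(t) naive_tif(rbind(des$unique1, des$common), t))) +
          sum(w[4:6] / sapply(q2, function(t) naive_tif(rbind(des$common, des$unique2), t)))
  expect_equal(obj3(b), hand, tolerance = 1e-12)

  # case 2 combines the growth and percentile schemes with equal mass
  sp2 <- sp; sp2$percentiles <- c(25, 75)
  obj2 <- build_case_objective(2, sp2)
  pg1 <- make_percentile_grid(c(25, 75), -0.5, 1)
  pg2 <- make_percentile_grid(c(25, 75), 0.5, 1)
  expect_equal(obj2(b),
               obj1(b) / 4 + crit_percentile(des, pg1, pg2) / 2,
               tolerance = 1e-12)

  expect_error(obj1(b[-1]), "length")
  expect_error(build_case_objective(5, sp), "1, 2, 3 or 4")
})

test_that("asymptotic variances carry the sample-size factors", {
  des <- growth_design(items(1, -0.5), items(1, 0), items(1, 0.5))
  expect_equal(asymptotic_var_growth(des, -0.5, 0.5), 4.123679,
               tolerance = 1e-6)
  # duplicating every ability doubles N and halves the variance
  v1 <- asymptotic_var_growth(des, c(-0.5, 0.2), c(0.5, 0.1))
  v2 <- asymptotic_var_growth(des, rep(c(-0.5, 0.2), each = 2),
                              rep(c(0.5, 0.1), each = 2))
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
  # degenerate single-form case reduces to the one-test expression
  abil <- c(-0.3, 0.4, 1.1)
  expect_equal(asymptotic_var_growth(des, abil, numeric(0)),
               sum(1 / test_information(form1_items(des), abil)) / 9,
               tolerance = 1e-12)
  expect_error(asymptotic_var_growth(des, c(0, 1), c(0), N1 = 3), "match")

  expect_equal(asymptotic_var_percentile(
    growth_design(items(1, 0), NULL, items(1, 0)), 0, 0), 8.0)
  expect_equal(asymptotic_var_percentile(
    growth_design(items(2, 0), NULL, items(2, 0)), 0, 0), 2.0)
})

test_that("criteria scale-link to the asymptotic variance", {
  set.seed(5)
  d <- random_design(2, 2, 2)
  th1 <- -0.4; th2 <- 0.6
  N <- 7
  crit <- crit_growth(d, ability_grid(th1, 1), ability_grid(th2, 1))
  v <- asymptotic_var_growth(d, rep(th1, N), rep(th2, N))
  expect_equal(crit, N * v, tolerance = 1e-12)
})

test_that("growth designs validate their structure", {
  expect_error(growth_design(NULL, NULL, items(1, 0)), "non-empty|at least one")
  d <- growth_design(items(1, 1), items(1, 0), items(1, -1))
  expect_equal(form1_items(d)$b, c(1, 0))
  expect_equal(form2_items(d)$b, c(0, -1))
  expect_error(unpack_design(1:4, 1, 2, 1, 2), "length")
  u <- unpack_design(c(-1, -0.5, 0, 0.5, 1), 1.5, 2, 1, 2)
  expect_equal(u$common$b, 0)
  expect_equal(u$unique2$b, c(0.5, 1))
})
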