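test_that("paired t-test matches the closed form and handles edge cases", {
  # alternating differences with zero mean
  a <- c(1, 0, 1, 0, 1, 0, 1, 0)
  b <- c(0, 1, 0, 1, 0, 1, 0, 1)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$df, 7L)
  # random pairs vs closed-form formula
  set.seed(71)
  for (k in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    tt <- paired_ttest(x, y)
    d <- x - y
    t_ref <- mean(d) / (sd(d) / sqrt(8))
    expect_equal(tt$t, t_ref, tolerance = 1e-12)
    expect_equal(tt$p, 2 * pt(-abs(t_ref), 7), tolerance = 1e-12)
  }
  expect_warning(z <- paired_ttest(1:4, (1:4) - 2), "zero-variance")
  expect_true(is.nan(z$t))
})

test_that("rm ANOVA matches the projection-matrix oracle to 1e-8", {
  set.seed(72)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    y <- array(rnorm(n * 6, sd = runif(1, 0.5, 3)), c(n, 2, 3))
    # occasionally induce sphericity violations via correlated sectors
    if (k %% 3 == 0) y[, , 2] <- y[, , 1] + rnorm(n * 2, sd = 0.6)
    res <- rm_anova_2x3(cells_to_long(y))
    ora <- oracle_rm_anova(y)
    expect_equal(res$F, ora$F, tolerance = 1e-8)
    expect_equal(res$df_num, c(1L, 2L, 2L))
    expect_equal(res$df_den, c(n - 1L, 2L * (n - 1L), 2L * (n - 1L)))
    expect_equal(res$p_uncorrected, ora$p, tolerance = 1e-8)
    expect_equal(res$epsilon_gg, ora$epsilon, tolerance = 1e-8)
    expect_equal(res$p_gg, ora$p_gg, tolerance = 1e-8)
    expect_equal(res$mauchly_p[-1], ora$mauchly_p[-1], tolerance = 1e-8)
  }
})

test_that("rm ANOVA agrees with the car package reference", {
  skip_if_not_installed("car")
  set.seed(73)
  n <- 8
  y <- array(rnorm(n * 6), c(n, 2, 3))
  y[, , 3] <- y[, , 3] + y[, , 1] * 0.8  # non-spherical
  res <- rm_anova_2x3(cells_to_long(y))
  # car: multivariate linear model with within-subject idata
  Y <- cbind(y[, 1, 1], y[, 1, 2], y[, 1, 3], y[, 2, 1], y[, 2, 2], y[, 2, 3])
  idata <- expand.grid(sector = factor(c("A", "B", "C")),
                       world = factor(c("W1", "W2")))
  idata <- idata[, c("world", "sector")]
  Y2 <- cbind(y[, 1, 1], y[, 1, 2], y[, 1, 3], y[, 2, 1], y[, 2, 2],
              y[, 2, 3])
  colnames(Y2) <- paste0("c", 1:6)
  idata2 <- data.frame(world = factor(rep(c("W1", "W2"), each = 3)),
                       sector = factor(rep(c("A", "B", "C"), 2)))
  mlm <- lm(Y2 ~ 1)
  av <- car::Anova(mlm, idata = idata2, idesign = ~ world * sector,
                   type = "III")
  s <- summary(av, multivariate = FALSE)
  un <- s$univariate.tests
  expect_equal(res$F[res$effect == "world"], un["world", "F value"],
               tolerance = 1e-6)
  expect_equal(res$F[res$effect == "sector"], un["sector", "F value"],
               tolerance = 1e-6)
  expect_equal(res$F[res$effect == "world:sector"],
               un["world:sector", "F value"], tolerance = 1e-6)
  sph <- s$sphericity.tests
  expect_equal(res$mauchly_p[res$effect == "sector"],
               sph["sector", "p-value"], tolerance = 1e-6)
  pva <- s$pval.adjustments
  expect_equal(res$epsilon_gg[res$effect == "sector"],
               unname(pva["sector", "GG eps"]), tolerance = 1e-6)
})

test_that("epsilon respects its theoretical bounds", {
  set.seed(74)
  for (k in 1:10) {
    y <- array(rnorm(48), c(8, 2, 3))
    res <- rm_anova_2x3(cells_to_long(y))
    expect_identical(res$epsilon_gg[res$effect == "world"], 1)
    expect_gte(res$epsilon_gg[res$effect == "sector"], 0.5)
    expect_lte(res$epsilon_gg[res$effect == "sector"], 1 + 1e-12)
  }
})

test_that("rm ANOVA is invariant to constant shifts and flags missing cells", {
  set.seed(75)
  y <- array(rnorm(48), c(8, 2, 3))
  r0 <- rm_anova_2x3(cells_to_long(y))
  r1 <- rm_anova_2x3(transform(cells_to_long(y), value = value + 100))
  expect_equal(r1$F, r0$F, tolerance = 1e-9)
  d <- cells_to_long(y)
  expect_error(rm_anova_2x3(d[-5, ]), "missing cell.*S05")
  expect_error(rm_anova_2x3(d[d$subject %in% c("S01", "S02"), ]),
               "at least 3")
})

test_that("one-way sector ANOVA matches aov on balanced data", {
  set.seed(76)
  n <- 8
  y <- matrix(rnorm(n * 3), n, 3)
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n), 3),
                  sector = rep(c("A", "B", "C"), each = n),
                  value = as.vector(y))
  res <- rm_anova_sector(d)
  fit <- summary(aov(value ~ sector + Error(subject / sector), data = d))
  tab <- fit[["Error: subject:sector"]][[1]]
  expect_equal(res$F, tab["sector", "F value"], tolerance = 1e-9)
  expect_equal(res$p_uncorrected, tab["sector", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 14L)
})

test_that("report lines follow the F(df1,df2) convention and suppress epsilon of 1", {
  set.seed(77)
  y <- array(rnorm(48), c(8, 2, 3))
  res <- rm_anova_2x3(cells_to_long(y))
  lines <- format_anova_lines(res, metric = "median_y")
  expect_length(lines, 3L)
  expect_match(lines[1], "^median_y \\| world: F\\(1,7\\) = ")
  expect_match(lines[2], "F\\(2,14\\)")
  # 2-level world effect never prints an epsilon
  expect_false(grepl("eps_GG", lines[1]))
})
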