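tab <- read_species_table()
tree <- read_newick()

test_that("mutational burden is the rate times the effective genome size", {
  agt <- tab[tab$label == "Agt", ]
  b <- mutational_burden(agt)
  expect_equal(b$burden, 0.30e-10 * 0.50e7)
  expect_equal(b$burden, 1.5e-4)
  expect_equal(log10(b$burden), log10(agt$u_id) + log10(agt$Ge))
})

test_that("log-log OLS matches the closed-form normal equations", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      x <- 10^runif(n, -2, 8)
      y <- 10^(2 - 0.7 * log10(x) + rnorm(n, 0, 0.5))
      fit <- loglog_regression(x, y)
      oracle <- ols_closed_form(log10(x), log10(y))
      expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
      expect_equal(fit$se_slope, oracle$se_slope, tolerance = 1e-10)
      expect_equal(fit$se_intercept, oracle$se_intercept, tolerance = 1e-10)
      expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
    }
  })
  # exactly collinear points give r2 = 1
  expect_equal(
    suppressWarnings(loglog_regression(c(1, 10, 100), c(2, 20, 200)))$r2, 1)
  expect_error(loglog_regression(c(1, 2), c(1, 2)), "3 points")
  expect_error(loglog_regression(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("p-values fall as residual variance shrinks", {
  withr::with_seed(5, {
    x <- 10^seq(1, 8, length.out = 12)
    noise <- scale(rnorm(12))[, 1]  # one residual shape, rescaled below
    p <- vapply(c(1, 0.5, 0.2, 0.05), function(s) {
      y <- 10^(1 - 0.5 * log10(x) + s * noise)
      loglog_regression(x, y)$p_value
    }, numeric(1))
    expect_true(all(diff(p) < 0))
  })
})

test_that("subset regressions reduce df and reproduce the full fit", {
  uni <- subset_regression(tab, c("bacteria", "unicellular_eukaryote"))
  expect_identical(uni$n, 10L)
  expect_identical(uni$df, 8L)
  full <- subset_regression(tab, NULL)
  direct <- loglog_regression(tab$Ne, tab$u_id * tab$Ge)
  expect_equal(full$slope, direct$slope)
  expect_equal(full$r2, direct$r2)
  expect_error(subset_regression(tab, "no_such_group"), "fewer than 3")
})

test_that("independent contrasts match the closed form and ape", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  cs <- pic_contrasts(two, c(A = 3, B = 1))
  expect_equal(abs(cs$contrast), 2 / sqrt(2))

  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(4:10, 1)
      tr <- ape::rcoal(n)
      trait <- setNames(rnorm(n), tr$tip.label)
      mine <- pic_contrasts(tr, trait)
      theirs <- ape::pic(trait[tr$tip.label], tr)
      expect_equal(sort(abs(mine$contrast)), sort(abs(unname(theirs))),
                   tolerance = 1e-10)
    }
  })
  expect_error(pic_contrasts(two, c(A = 1)), "missing trait")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3)), "bifurcating")
})

test_that("contrasts are variance-standardized under Brownian motion", {
  tr <- ape::rcoal(8, br = "coalescent")
  cons <- withr::with_seed(32, {
    unlist(lapply(1:300, function(i) {
      trait <- ape::rTraitCont(tr, model = "BM", sigma = 1)
      pic_contrasts(tr, trait)$contrast
    }))
  })
  expect_equal(sd(cons), 1, tolerance = 0.1)
})

test_that("PIC through-origin slope equals the Brownian GLS slope", {
  withr::with_seed(33, {
    for (rep in 1:15) {
      n <- sample(4:8, 1)
      tr <- ape::rcoal(n)
      x <- setNames(rnorm(n), tr$tip.label)
      y <- setNames(0.6 * x + rnorm(n, 0, 0.3), tr$tip.label)
      fit <- origin_regression(pic_contrasts(tr, x), pic_contrasts(tr, y))
      expect_equal(fit$slope, gls_brownian_slope(tr, x, y),
                   tolerance = 1e-8)
    }
  })
})

test_that("through-origin fits are orientation invariant and exact on proportional data", {
  cx <- c(1, -2, 3, 0.5)
  cy <- 2 * cx
  fit <- suppressWarnings(origin_regression(cx, cy))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r2, 1)
  expect_identical(fit$df, 3L)

  withr::with_seed(34, {
    cx <- rnorm(10); cy <- -0.5 * cx + rnorm(10, 0, 0.2)
    base <- origin_regression(cx, cy)
    flip <- c(-1, rep(1, 9))
    flipped <- origin_regression(cx * flip, cy * flip)
    expect_equal(flipped$slope, base$slope)
    expect_equal(flipped$r2, base$r2)
    oracle <- origin_closed_form(abs(cx) * 0 + cx * sign(cx),
                                 cy * sign(cx))
    expect_equal(base$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(base$se_slope, oracle$se_slope, tolerance = 1e-10)
    expect_equal(base$r2, oracle$r2, tolerance = 1e-10)
  })
  # zero predictor contrasts stay in the df
  z <- origin_regression(c(0, 1, 2), c(0.5, 1, 2))
  expect_identical(z$df, 2L)
})

test_that("antimutator thresholds scale as 1/(ploidy Ne s t Ge)", {
  ec <- tab[tab$label == "Ec", ]
  th <- antimutator_threshold(ec, s_coeff = 0.01, t_link = 2)
  expect_equal(th$delta_u_id, 1 / (ec$Ne * 0.01 * 2 * ec$Ge))
  expect_equal(th$delta_u_id, 7.1e-14, tolerance = 0.02)
  expect_equal(th$fraction_of_u_id, 0.0019, tolerance = 0.02)

  ec2 <- ec; ec2$Ne <- 2 * ec$Ne
  expect_equal(antimutator_threshold(ec2)$delta_u_id, th$delta_u_id / 2)

  hs <- tab[tab$label == "Hs", ]
  th_hs <- antimutator_threshold(hs)
  expect_equal(th_hs$delta_u_id, 1 / (2 * hs$Ne * 0.01 * 2 * hs$Ge))

  # dimensionless fraction: rescaling u_id and delta jointly cancels
  ec3 <- ec; ec3$u_id <- 10 * ec$u_id; ec3$Ne <- ec$Ne / 10
  expect_equal(antimutator_threshold(ec3)$fraction_of_u_id,
               th$fraction_of_u_id)
})

test_that("the reproduction report is complete, stable and df-consistent", {
  rep1 <- reproduce_analysis(tab, tree)
  expect_named(rep1$fits, c("fig1a", "fig1b", "fig3", "unicellular", "pic"))
  expect_true(all(rep1$checks$pass))
  expect_identical(nrow(rep1$contrasts), 14L)

  rep2 <- reproduce_analysis(tab, tree)
  expect_identical(rep1$fits$fig1a$slope, rep2$fits$fig1a$slope)
  expect_identical(rep1$contrasts, rep2$contrasts)
  expect_identical(rep1$barrier, rep2$barrier)

  # removing one species lowers every df by one
  tab14 <- tab[tab$label != "Sc", ]
  tree14 <- ape::drop.tip(tree, "Sc")
  rep14 <- reproduce_analysis(tab14, tree14)
  expect_identical(rep14$fits$fig1a$df, rep1$fits$fig1a$df - 1L)
  expect_identical(rep14$fits$fig3$df, rep1$fits$fig3$df - 1L)
  expect_identical(rep14$fits$pic$df, rep1$fits$pic$df - 1L)

  # broom-style accessors
  td <- generics::tidy(rep1)
  expect_identical(nrow(td), 5L)
  g <- generics::glance(rep1$fits$fig1a)
  expect_equal(g$r.squared, rep1$fits$fig1a$r2)
})

test_that("report plots build without error", {
  p1 <- ggplot2::autoplot(loglog_regression(tab$Ne, tab$u_id * tab$Ge))
  expect_s3_class(p1, "ggplot")
  p2 <- plot_burden_ne(tab)
  expect_s3_class(p2, "ggplot")
})
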