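test_that("a perfect power law is recovered exactly", {
  d <- tibble::tibble(x = 10^seq(0, 2, length.out = 10))
  d$y <- d$x^2
  f <- sma_fit(d, x, y)
  expect_equal(f$exponent, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(f$valid)
})

test_that("the SMA slope equals sign(r) * sd_y / sd_x (independent two-pass oracle)", {
  two_pass_sd <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    lx <- rnorm(n, sd = runif(1, 0.2, 2))
    ly <- runif(1, -2, 2) * lx + rnorm(n, sd = runif(1, 0.05, 1))
    d <- tibble::tibble(x = 10^lx, y = 10^ly)
    f <- sma_fit(d, x, y)
    r <- stats::cor(lx, ly)
    expected <- (if (r < 0) -1 else 1) * two_pass_sd(ly) / two_pass_sd(lx)
    if (f$offset_included) {
      expect_equal(f$exponent, expected, tolerance = 1e-12)
    }
  }
})

test_that("uncorrelated data is flagged invalid (permutation oracle)", {
  set.seed(7)
  lx <- rnorm(20)
  ly <- sample(2 * lx)  # permutation destroys the pairing
  # independent oracle: the correlation really is non-significant here
  expect_gte(stats::cor.test(lx, ly)$p.value, 0.05)
  d <- tibble::tibble(x = 10^lx, y = 10^ly)
  f <- sma_fit(d, x, y)
  expect_false(f$valid)
  expect_gte(f$p_value, 0.05)
})

test_that("SMA is symmetric: exponent(x~y) is the reciprocal of exponent(y~x)", {
  set.seed(31)
  for (i in 1:10) {
    d <- tibble::tibble(x = 10^rnorm(40))
    d$y <- 10^(0.7 * log10(d$x) + rnorm(40, sd = 0.3))
    fxy <- sma_fit(d, x, y)
    fyx <- sma_fit(d, y, x)
    expect_equal(fxy$exponent, 1 / fyx$exponent, tolerance = 1e-10)
  }
})

test_that("rescaling x shifts the offset but never the exponent", {
  set.seed(41)
  d <- tibble::tibble(x = 10^runif(50, 1, 3))
  d$y <- 10^(-1.2 * log10(d$x) + 1 + rnorm(50, sd = 0.1))
  f1 <- sma_fit(d, x, y)
  d2 <- dplyr::mutate(d, x = x * 1e6)
  f2 <- sma_fit(d2, x, y)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("the offset is dropped when not significantly different from zero", {
  set.seed(51)
  lx <- rnorm(60, sd = 1)
  ly <- 1.3 * lx + rnorm(60, sd = 0.05)  # true elevation 0
  f0 <- sma_fit(tibble::tibble(x = 10^lx, y = 10^ly), x, y)
  expect_false(f0$offset_included)
  expect_equal(f0$offset_b, 1)
  fy <- sma_fit(tibble::tibble(x = 10^lx, y = 10^(ly + 2)), x, y)
  expect_true(fy$offset_included)
})

test_that("degenerate and domain errors are raised", {
  d <- tibble::tibble(x = rep(10, 5), y = 10^rnorm(5))
  expect_error(sma_fit(d, x, y), "degenerate")
  d2 <- tibble::tibble(x = c(-1, 2, 3), y = c(1, 2, 3))
  expect_error(sma_fit(d2, x, y), "positive")
  expect_error(sma_fit(tibble::tibble(x = 1:2, y = 1:2), x, y), "3 complete")
})

test_that("through-origin SMA has the closed form and its symmetries", {
  x <- c(-1, 0.5, 2, -0.3)
  f <- sma_fit_through_origin(x, -1.5 * x)
  expect_equal(f$exponent, -1.5, tolerance = 1e-12)
  expect_true(f$through_origin)
  set.seed(61)
  xc <- rnorm(30)
  yc <- 0.8 * xc + rnorm(30, sd = 0.2)
  f1 <- sma_fit_through_origin(xc, yc)
  f2 <- sma_fit_through_origin(xc, -yc)
  expect_equal(f1$exponent, -f2$exponent, tolerance = 1e-12)
  expect_error(sma_fit_through_origin(rep(0, 5), rep(0, 5)), "degenerate")
})

test_that("through-origin SMA minimises the triangle-area loss (grid-search oracle)", {
  sma_loss <- function(b, x, y) sum((y - b * x)^2) / (2 * abs(b))
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(25)
    y <- runif(1, -2, 2) * x + rnorm(25, sd = 0.3)
    f <- sma_fit_through_origin(x, y)
    sgn <- if (f$exponent < 0) -1 else 1
    # coarse log-spaced grid then local refinement
    grid <- sgn * 10^seq(-3, 3, length.out = 2000)
    losses <- vapply(grid, sma_loss, numeric(1), x = x, y = y)
    b0 <- grid[which.min(losses)]
    opt <- optimize(function(b) sma_loss(b, x, y),
                    interval = sort(c(b0 / 1.1, b0 * 1.1)), tol = 1e-10)
    expect_equal(f$exponent, opt$minimum, tolerance = 1e-6)
  }
})

test_that("exponent CIs cover the generating exponent at the stated rate", {
  # clean-regime recovery: S = -1.05, 0.15 dex scatter, n = 900
  covered <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    cfg <- one_clade_config(seed = 3000 + i, n = 900, scatter = 0.15,
                            frac_amax = 0)
    tr <- generate_traits(cfg)
    f <- sma_fit(tr, d_s, a_gc)
    if (f$ci_exponent[1] <= -1.05 && -1.05 <= f$ci_exponent[2]) {
      covered <- covered + 1
    }
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("the allometry table reports both relationships per selection", {
  tr <- generate_traits(synthetic_config(seed = 5))
  tab <- fit_allometries(tr)
  expect_setequal(unique(tab$selection), names(default_selections()))
  expect_equal(nrow(tab), 2 * length(default_selections()))
  all_s <- tab[tab$selection == "all_species" & tab$x == "d_s", ]
  expect_equal(all_s$n, nrow(tr))
  amax_row <- tab[tab$selection == "all_species" & tab$x == "a_gc", ]
  expect_equal(amax_row$n, sum(!is.na(tr$a_max)))
  expect_true(all(tab$ci_exponent_lo <= tab$exponent, na.rm = TRUE))
  expect_true(all(tab$exponent <= tab$ci_exponent_hi, na.rm = TRUE))
})

test_that("tidy and glance return the documented tibbles", {
  d <- tibble::tibble(x = 10^runif(30, 1, 3))
  d$y <- 10^(-1 * log10(d$x) + 1 + rnorm(30, 0.05))
  f <- sma_fit(d, x, y)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
  gl <- glance(f)
  expect_equal(gl$n, 30)
  expect_true(gl$r2 >= 0 && gl$r2 <= 1)
})
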