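test_that("ROR matches the closed form and an independent logistic fit", {
  # symmetric table
  r <- compute_ror(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_lt(r$ror_low, 1)
  expect_gt(r$ror_high, 1)

  # direct evaluation, cross-checked against glm's Wald interval
  r2 <- compute_ror(10, 90, 100, 9800)
  expect_equal(r2$ror, (10 * 9800) / (90 * 100))
  fit <- suppressWarnings(glm(cbind(c(10, 100), c(90, 9800)) ~ c(1, 0),
                              family = binomial))
  or <- exp(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  expect_equal(r2$ror, unname(or), tolerance = 1e-6)
  expect_equal(r2$ror_low, unname(exp(log(or) - qnorm(0.975) * se)),
               tolerance = 1e-6)

  # reconstructed strongest signal reproduces the published point value
  r3 <- compute_ror(141, 954, 150, 54335639)
  expect_equal(r3$ror, 53538.3, tolerance = 1e-4)

  # zero cell: undefined, flagged as NA, defined under continuity correction
  expect_true(is.na(compute_ror(5, 5, 0, 5)$ror))
  expect_true(is.finite(compute_ror(5, 5, 0, 5, continuity = TRUE)$ror))
})

test_that("PRR and chi-square follow the printed conventions", {
  # independence
  p <- compute_prr_chi2(10, 90, 100, 900)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  # reconstructed tables reproduce the published PRRs
  expect_equal(compute_prr_chi2(100, 995, 143, 54335646)$prr, 34700.5,
               tolerance = 1e-5)
  expect_equal(compute_prr_chi2(141, 954, 150, 54335639)$prr, 46644.4,
               tolerance = 1e-5)

  # chi-square on the low-count reconstructed table is within 0.2% of print
  ci <- compute_prr_chi2(3, 1092, 22073, 54313716)
  expect_equal(ci$chi2, 14.67, tolerance = 0.002)

  # c = 0 leaves the PRR undefined
  expect_true(is.na(compute_prr_chi2(5, 5, 0, 10)$prr))
})

test_that("chi-square equals the four-cell oracle, with and without Yates", {
  tabs <- random_tables(200, seed = 5)
  got <- compute_prr_chi2(tabs$a, tabs$b, tabs$c, tabs$d)
  gotc <- compute_prr_chi2(tabs$a, tabs$b, tabs$c, tabs$d, correct = TRUE)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(unlist(tabs[i, c("a", "b", "c", "d")]), 2, byrow = TRUE)
    expect_equal(got$chi2[i],
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-12)
    expect_equal(gotc$chi2[i],
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("IC point estimate is the log2 observed-to-expected ratio", {
  ic <- compute_bcpnn_ic(141, 954, 150, 54335639, estimator = "gamma")
  expect_equal(round(ic$ic, 2), 14.55)
  expect_equal(compute_bcpnn_ic(10, 90, 100, 900, estimator = "gamma")$ic, 0)
  # identity with the relative reporting ratio holds exactly
  tabs <- random_tables(50, seed = 8)
  st <- signal_stats(cbind(term = as.character(seq_len(nrow(tabs))), tabs),
                     prior = mgps_prior(), ic_estimator = "gamma")
  expect_identical(st$ic, log2(st$rr))
})

test_that("Monte-Carlo IC dispersion matches a large brute-force posterior sample", {
  a <- 20; b <- 80; c <- 200; d <- 9700
  got <- compute_bcpnn_ic(a, b, c, d, estimator = "mc", n_draws = 1e5,
                          seed = 21)
  # oracle: independent million-draw simulation of the Dirichlet posterior
  set.seed(99)
  g <- matrix(rgamma(4e6, shape = rep(c(a, b, c, d) + 1, each = 1e6)),
              ncol = 4)
  tot <- rowSums(g)
  ics <- log2(g[, 1] * tot / ((g[, 1] + g[, 2]) * (g[, 1] + g[, 3])))
  expect_equal(got$ic_sd, sd(ics), tolerance = 0.1)
  expect_equal(got$ic, log2(a * (a + b + c + d) / ((a + b) * (a + c))))
  # seeded: reproducible
  again <- compute_bcpnn_ic(a, b, c, d, estimator = "mc", n_draws = 1e5,
                            seed = 21)
  expect_identical(got, again)
  expect_error(compute_bcpnn_ic(1, 1, 1, 1, estimator = "bogus"))
})

test_that("MGPS prior fitting recovers simulated parameters", {
  true <- mgps_prior(0.2, 0.1, 2, 4, 1 / 3)
  set.seed(1234)
  n <- 5000
  E <- exp(runif(n, log(0.1), log(50)))
  comp <- runif(n) < true$w
  lam <- ifelse(comp, rgamma(n, true$alpha1, true$beta1),
                rgamma(n, true$alpha2, true$beta2))
  a <- rpois(n, lam * E)
  fit <- fit_mgps(a, E)
  # the mixture is exchangeable: compare under the better labelling
  rel <- function(f) max(
    abs(c(f$alpha1 - 0.2, f$beta1 - 0.1, f$alpha2 - 2, f$beta2 - 4,
          f$w - 1 / 3) / c(0.2, 0.1, 2, 4, 1 / 3)))
  swap <- list(alpha1 = fit$alpha2, beta1 = fit$beta2, alpha2 = fit$alpha1,
               beta2 = fit$beta1, w = 1 - fit$w)
  expect_lt(min(rel(fit), rel(swap)), 0.25)
  # optimality: likelihood at the optimum is at least that at the truth
  expect_gte(fit$loglik, mgps_loglik(true, a, E))
})

test_that("MGPS fit degenerates gracefully to one component", {
  set.seed(77)
  n <- 2000
  E <- exp(runif(n, log(0.5), log(20)))
  lam <- rgamma(n, 2, 4)
  a <- rpois(n, lam * E)
  fit <- fit_mgps(a, E)
  # the dominant component should absorb nearly all the weight
  w_dom <- max(fit$w, 1 - fit$w)
  expect_gte(w_dom, 0.95)
  expect_error(fit_mgps(rep(0, 100), rep(1, 100)),
               class = "faers_value_error")
  expect_error(fit_mgps(1:5, 1:5), class = "faers_value_error")
})

test_that("EBGM matches numerical posterior integration to 4 decimals", {
  pr <- mgps_prior(1, 1, 1, 1, 0.5)
  cases <- list(c(a = 12, E = 3), c(a = 2, E = 0.5), c(a = 40, E = 55))
  for (cs in cases) {
    a <- cs[["a"]]; E <- cs[["E"]]
    got <- compute_ebgm(a, E, pr)
    # quadrature oracle: unnormalised posterior density over lambda
    post <- function(l) {
      pri <- pr$w * dgamma(l, pr$alpha1, pr$beta1) +
        (1 - pr$w) * dgamma(l, pr$alpha2, pr$beta2)
      pri * dpois(a, l * E)
    }
    Z <- integrate(post, 0, 200, rel.tol = 1e-12)$value
    elog <- integrate(function(l) log(l) * post(l) / Z, 0, 200,
                      rel.tol = 1e-12)$value
    q05 <- uniroot(function(q) integrate(post, 0, q,
                                         rel.tol = 1e-12)$value / Z - 0.05,
                   c(1e-8, 200), tol = 1e-10)$root
    expect_equal(got$ebgm, exp(elog), tolerance = 1e-4)
    expect_equal(got$ebgm05, q05, tolerance = 1e-4)
    expect_equal(got$rr, a / E)
  }
})

test_that("shrinkage pulls the EBGM toward 1 and vanishes with information", {
  pr <- mgps_prior(1, 1, 1, 1, 0.5)     # weak prior centred at 1
  g <- compute_ebgm(30, 6, pr)
  expect_gt(g$ebgm, 1)
  expect_lt(g$ebgm, g$rr)
  # a -> infinity with rr fixed: ebgm -> rr
  g2 <- compute_ebgm(30000, 6000, pr)
  expect_equal(g2$ebgm, g2$rr, tolerance = 1e-3)
  # a = E with a prior sharply concentrated at lambda = 1
  sharp <- mgps_prior(1e6, 1e6, 1e6, 1e6, 0.5)
  expect_equal(compute_ebgm(10, 10, sharp)$ebgm, 1, tolerance = 1e-3)
})

test_that("statistics depend only on the four counts", {
  st1 <- signal_stats(data.frame(term = "x", a = 12, b = 88, c = 40, d = 960),
                      prior = mgps_prior(), ic_estimator = "gamma")
  st2 <- signal_stats(data.frame(term = "renamed", a = 12, b = 88, c = 40,
                                 d = 960),
                      prior = mgps_prior(), ic_estimator = "gamma")
  num <- vapply(st1, is.numeric, TRUE)
  expect_equal(st1[, num], st2[, num])
})
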