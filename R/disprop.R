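# Disproportionality statistics on 2x2 tables
#
#        event   other
# focal    a       b
# other    c       d
#
# All four methods compare the observed count a with its expectation under
# independence E = (a+b)(a+c)/N. Zero-cell tables yield NA ("undefined
# statistic") rather than errors, so a whole batch of tables can be scored.

#' Reporting odds ratio with lognormal confidence interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' With a zero cell the statistic is undefined and returned as `NA` unless
#' `continuity = TRUE`, which adds 0.5 to all four cells of affected tables
#' (Haldane-Anscombe).
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param conf Confidence level, default 0.95.
#' @param continuity Apply the 0.5 correction to zero-cell tables.
#' @return `data.frame` with `ror`, `ror_low`, `ror_high`.
#' @examples
#' compute_ror(141, 954, 150, 54335639)
#' @export
compute_ror <- function(a, b, c, d, conf = 0.95, continuity = FALSE) {
  assert_counts(a, b, c, d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (continuity && any(zero)) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  ror <- ifelse(zero, NA_real_, (a * d) / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(ror = ror,
             ror_low = exp(log(ror) - z * se),
             ror_high = exp(log(ror) + z * se))
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square statistic is the Pearson
#' four-cell sum `sum((O - E)^2 / E)` without continuity correction by
#' default, the convention that pairs with the PRR signal threshold
#' (`PRR >= 2` with `chi2 >= 4`); `correct = TRUE` applies the Yates
#' correction.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param correct Apply the Yates continuity correction.
#' @return `data.frame` with `prr`, `chi2`. `prr` is `NA` when `c = 0` or
#'   `a + b = 0`.
#' @export
compute_prr_chi2 <- function(a, b, c, d, correct = FALSE) {
  assert_counts(a, b, c, d)
  N <- a + b + c + d
  prr <- ifelse(c == 0 | a + b == 0 | c + d == 0, NA_real_,
                (a / (a + b)) / (c / (c + d)))
  e11 <- (a + b) * (a + c) / N
  e10 <- (a + b) * (b + d) / N
  e01 <- (c + d) * (a + c) / N
  e00 <- (c + d) * (b + d) / N
  dev <- function(o, e) {
    x <- abs(o - e)
    if (correct) x <- pmax(x - 0.5, 0)
    x^2 / e
  }
  chi2 <- dev(a, e11) + dev(b, e10) + dev(c, e01) + dev(d, e00)
  chi2[e11 == 0 | e10 == 0 | e01 == 0 | e00 == 0] <- NA_real_
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component with lower credibility bound
#'
#' The point estimate is the observed-to-expected information component
#' `IC = log2(a N / ((a+b)(a+c)))`. The lower bound `IC - 2 SD` subtracts
#' twice the posterior standard deviation of the IC, obtained by one of two
#' estimators:
#' \describe{
#'   \item{`"mc"`}{(default) Monte-Carlo sampling of the cell-probability
#'     posterior, Dirichlet with unit priors (`Dirichlet(a+1, b+1, c+1, d+1)`);
#'     the SD of the sampled `log2` IC is used. Deterministic given `seed`.}
#'   \item{`"gamma"`}{closed-form gamma approximation: the posterior of the
#'     observed/expected ratio is approximated by `Gamma(a + 1, E + 1)`, so
#'     `SD(IC) = sqrt(trigamma(a + 1)) / log(2)`.}
#' }
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param estimator `"mc"` or `"gamma"`.
#' @param n_draws Monte-Carlo sample size per table.
#' @param seed Optional seed for the Monte-Carlo estimator.
#' @return `data.frame` with `ic`, `ic_sd`, `ic_minus_2sd`; all `NA` when a
#'   margin is zero.
#' @export
compute_bcpnn_ic <- function(a, b, c, d, estimator = c("mc", "gamma"),
                             n_draws = 1e5, seed = NULL) {
  estimator <- match.arg(estimator)
  assert_counts(a, b, c, d)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  bad <- a == 0 | E == 0
  ic <- ifelse(bad, NA_real_, log2(a / E))
  if (estimator == "gamma") {
    sd_ic <- ifelse(bad, NA_real_, sqrt(trigamma(a + 1)) / log(2))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    sd_ic <- vapply(seq_along(a), function(i) {
      if (bad[i]) return(NA_real_)
      g11 <- stats::rgamma(n_draws, a[i] + 1)
      g10 <- stats::rgamma(n_draws, b[i] + 1)
      g01 <- stats::rgamma(n_draws, c[i] + 1)
      g00 <- stats::rgamma(n_draws, d[i] + 1)
      tot <- g11 + g10 + g01 + g00
      icd <- log2(g11 * tot / ((g11 + g10) * (g11 + g01)))
      stats::sd(icd)
    }, numeric(1))
  }
  data.frame(ic = ic, ic_sd = sd_ic, ic_minus_2sd = ic - 2 * sd_ic)
}

#' Construct an MGPS gamma-mixture prior
#'
#' The DuMouchel multi-item gamma-Poisson shrinker models the observed count
#' `a`, given its independence expectation `E`, as Poisson with mean
#' `lambda * E`, where the relative reporting rate `lambda` follows a
#' two-component gamma mixture prior
#' `w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)`.
#'
#' @param alpha1,beta1,alpha2,beta2 Positive shape/rate parameters.
#' @param w Mixture weight of the first component, in (0, 1).
#' @param loglik Optional log marginal likelihood attained (set by
#'   [fit_mgps()]).
#' @return An object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                       w = 1 / 3, loglik = NA_real_) {
  p <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(p)) || any(p <= 0) || !is.finite(w) || w <= 0 || w >= 1) {
    stop_faers("mgps_prior needs positive parameters and w in (0, 1)",
               class = "faers_value_error")
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = loglik),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("<mgps_prior> two-component gamma mixture\n")
  cat(sprintf("  component 1: Gamma(%.4g, %.4g)  weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(%.4g, %.4g)  weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood: %.6f\n", x$loglik))
  invisible(x)
}

#' Marginal log-likelihood of (a, E) pairs under an MGPS prior
#'
#' Marginally, `a ~ w NB(alpha1, beta1/(beta1+E)) +
#' (1-w) NB(alpha2, beta2/(beta2+E))`.
#'
#' @param prior An `mgps_prior`.
#' @param a Observed counts.
#' @param E Expected counts under independence.
#' @return The summed log-likelihood.
#' @export
mgps_loglik <- function(prior, a, E) {
  sum(log(mgps_marginal(prior, a, E)))
}

mgps_marginal <- function(prior, a, E) {
  p1 <- stats::dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E))
  p2 <- stats::dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E))
  prior$w * p1 + (1 - prior$w) * p2
}

#' Fit the MGPS prior by maximum marginal likelihood
#'
#' Maximises the mixture negative-binomial marginal likelihood of the observed
#' `(a, E)` pairs by direct numerical optimisation over the log-transformed
#' gamma parameters and the logit mixture weight, starting from DuMouchel's
#' canonical values (0.2, 0.1, 2, 4, 1/3).
#'
#' @param a Observed counts over all drug-event tables.
#' @param E Matching independence expectations.
#' @param init Optional starting `mgps_prior`.
#' @param max_iter Iteration cap for the optimiser.
#' @param tol Relative convergence tolerance on the objective.
#' @return A fitted `mgps_prior` with the attained `loglik` and attribute
#'   `convergence` (0 = converged).
#' @export
fit_mgps <- function(a, E, init = mgps_prior(), max_iter = 10000, tol = 1e-8) {
  if (length(a) < 10L) {
    stop_faers("MGPS fitting needs at least 10 (a, E) pairs",
               class = "faers_value_error")
  }
  if (length(a) != length(E) || any(E <= 0)) {
    stop_faers("a and E must match in length with E > 0",
               class = "faers_value_error")
  }
  if (all(a == 0)) {
    stop_faers("degenerate data: all observed counts are zero",
               class = "faers_value_error")
  }
  theta0 <- c(log(init$alpha1), log(init$beta1), log(init$alpha2),
              log(init$beta2), stats::qlogis(init$w))
  nll <- function(theta) {
    pr <- list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
               alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
               w = stats::plogis(theta[5]))
    m <- mgps_marginal(pr, a, E)
    if (any(!is.finite(m)) || any(m <= 0)) return(1e12)
    -sum(log(m))
  }
  fit <- stats::nlminb(theta0, nll,
                       control = list(iter.max = max_iter,
                                      eval.max = 4 * max_iter,
                                      rel.tol = tol))
  th <- fit$par
  out <- mgps_prior(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]),
                    stats::plogis(th[5]), loglik = -fit$objective)
  attr(out, "convergence") <- fit$convergence
  out
}

#' Empirical Bayes geometric mean and fifth posterior percentile
#'
#' Under the MGPS model the posterior of the relative reporting rate `lambda`
#' for a table with observed `a` and expectation `E` is again a two-component
#' gamma mixture with components `Gamma(alpha_j + a, beta_j + E)` and weights
#' proportional to the prior-weighted negative-binomial likelihoods. Reported
#' are `EBGM = 2^(E[log2 lambda])`, the geometric mean of the posterior, and
#' `EBGM05`, its fifth percentile (numerical inversion of the mixture CDF to
#' 1e-6 relative accuracy), alongside the raw observed/expected ratio
#' `rr = a / E`.
#'
#' @param a,E Observed counts and independence expectations (vectorised).
#' @param prior An `mgps_prior`.
#' @param percentile Lower posterior percentile to report, default 0.05.
#' @return `data.frame` with `ebgm`, `ebgm05`, `rr`.
#' @export
compute_ebgm <- function(a, E, prior, percentile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (any(E <= 0)) {
    stop_faers("E must be positive", class = "faers_value_error")
  }
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  l1 <- log(prior$w) +
    stats::dnbinom(a, size = prior$alpha1,
                   prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$w) +
    stats::dnbinom(a, size = prior$alpha2,
                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  q2 <- 1 - q1
  elog <- q1 * (digamma(s1) - log(r1)) + q2 * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  ebgm05 <- vapply(seq_along(a), function(i) {
    mixture_gamma_quantile(percentile, c(q1[i], q2[i]),
                           c(s1[i], s2[i]), c(r1[i], r2[i]))
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05, rr = a / E)
}

# Quantile of a two-component gamma mixture by bisection on the CDF,
# to 1e-6 relative accuracy.
mixture_gamma_quantile <- function(p, wts, shapes, rates) {
  cdf <- function(x) sum(wts * stats::pgamma(x, shape = shapes, rate = rates))
  lo <- min(stats::qgamma(p, shape = shapes, rate = rates))
  hi <- max(stats::qgamma(p, shape = shapes, rate = rates))
  if (hi <= lo) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-6 * max(hi, 1e-12)) break
  }
  (lo + hi) / 2
}

#' Compute the full statistics panel for a set of contingency tables
#'
#' Runs all four disproportionality methods over the tables produced by
#' [build_contingency()] and binds the results into one row per term. The
#' MGPS prior is fitted to the tables' own `(a, E)` pairs unless supplied;
#' with fewer than 10 tables the canonical DuMouchel prior is used with a
#' warning.
#'
#' @param tables Contingency `data.frame` (`term`, `a`, `b`, `c`, `d`).
#' @param prior Optional `mgps_prior`; fitted from the data when `NULL`.
#' @param ic_estimator,n_draws,seed Passed to [compute_bcpnn_ic()].
#' @param conf Confidence level for the ROR interval.
#' @return `data.frame`: the input columns plus `ror`, `ror_low`, `ror_high`,
#'   `prr`, `chi2`, `ic`, `ic_minus_2sd`, `ebgm`, `ebgm05`, `rr`.
#' @export
signal_stats <- function(tables, prior = NULL, ic_estimator = "mc",
                         n_draws = 1e5, seed = NULL, conf = 0.95) {
  stopifnot(all(c("term", "a", "b", "c", "d") %in% names(tables)))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  if (is.null(prior)) {
    if (length(a) >= 10L && any(a > 0)) {
      prior <- fit_mgps(a, E)
    } else {
      warning("fewer than 10 tables: using the canonical DuMouchel prior",
              call. = FALSE)
      prior <- mgps_prior()
    }
  }
  out <- cbind(
    tables,
    compute_ror(a, b, c, d, conf = conf),
    compute_prr_chi2(a, b, c, d),
    compute_bcpnn_ic(a, b, c, d, estimator = ic_estimator,
                     n_draws = n_draws, seed = seed),
    compute_ebgm(a, E, prior)
  )
  attr(out, "prior") <- prior
  out
}
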