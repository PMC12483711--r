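test_that("links are mutually inverse monotone maps with positive slope", {
  for (nm in c("identity", "log", "logit", "scaled_logit")) {
    lk <- make_link(nm, lower = -1, upper = 1)
    x <- switch(nm, identity = seq(-5, 5, length.out = 21),
                log = exp(seq(-4, 4, length.out = 21)),
                logit = seq(0.01, 0.99, length.out = 21),
                scaled_logit = seq(-0.98, 0.98, length.out = 21))
    expect_equal(lk$linkinv(lk$linkfun(x)), x, tolerance = 1e-12)
    eta <- seq(-6, 6, length.out = 31)
    expect_true(all(diff(lk$linkinv(eta)) > 0))
    expect_true(all(lk$mu.eta(eta) > 0))
    fd <- fd_grad(function(e) lk$linkinv(e[1]), 0.3)
    expect_equal(lk$mu.eta(0.3), fd, tolerance = 1e-7)
  }
  lg <- make_link("logit")
  expect_identical(lg$linkfun(0.5), 0)
  expect_equal(lg$mu.eta(0), 0.25)
  expect_equal(make_link("scaled-logit", -1, 1)$linkinv(0), 0)
  expect_error(make_link("probit"), "probit")
})

test_that("location-scale Beta shape mapping and moments are exact", {
  expect_equal(beta_ls_shapes(0.5, sqrt(1 / 3)), list(a = 1, b = 1))
  expect_equal(beta_ls_shapes(0.2, 0.5), list(a = 0.6, b = 2.4))
  expect_equal(family_moments("beta_ls",
                              list(mu = 0.5, sigma = 0.5))$variance, 0.0625)
  expect_error(beta_ls_shapes(0, 0.5), "mu")
  expect_error(beta_ls_shapes(0.5, 1), "sigma")
})

test_that("log-densities match known values and reductions", {
  expect_equal(family_logpdf("beta_ls", 0.3,
                             list(mu = 0.5, sigma = sqrt(1 / 3))), 0)
  expect_equal(family_logpdf("bernoulli", 1, list(mu = 0.5)), log(0.5))
  # zero-slant Skew-Normal reduces to the Normal for any y
  y <- seq(-4, 4, length.out = 17)
  expect_equal(
    family_logpdf("skew_normal", y, list(mu = 0.3, sigma = 1.4, nu = 0.5)),
    dnorm(y, 0.3, 1.4, log = TRUE), tolerance = 1e-12)
  expect_error(family_logpdf("beta_ls", 1.2,
                             list(mu = 0.5, sigma = 0.5)), "support")
})

test_that("densities integrate to one over the support", {
  set.seed(71)
  for (rep in 1:3) {
    th <- random_theta("normal")
    expect_equal(integrate(function(y)
      exp(family_logpdf("normal", y, th)), -Inf, Inf,
      rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    th <- random_theta("beta_ls")
    expect_equal(integrate(function(y)
      exp(family_logpdf("beta_ls", y, th)), 0, 1,
      rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    th <- random_theta("skew_normal")
    expect_equal(integrate(function(y)
      exp(family_logpdf("skew_normal", y, th)), -Inf, Inf,
      rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    th <- random_theta("bernoulli")
    expect_equal(sum(exp(family_logpdf("bernoulli", c(0, 1), th))), 1,
                 tolerance = 1e-12)
  }
})

test_that("analytic parameter derivatives match finite differences", {
  set.seed(42)
  for (fname in c("bernoulli", "normal", "beta_ls", "skew_normal")) {
    fam <- get_family(fname)
    for (rep in 1:100) {
      th <- random_theta(fname)
      y <- random_y(fname, th)
      d <- family_dlogpdf(fam, y, th)
      for (r in fam$roles) {
        fd <- fd_grad(function(v) {
          th2 <- th; th2[[r]] <- v[1]
          family_logpdf(fam, y, th2)
        }, th[[r]], h = 1e-6)
        expect_equal(unname(d[1, r]), fd, tolerance = 1e-6,
                     label = sprintf("%s d/d%s", fname, r))
      }
    }
  }
})

test_that("beta_ls density is reflection invariant in (y, mu)", {
  set.seed(5)
  for (rep in 1:20) {
    th <- random_theta("beta_ls")
    y <- runif(1, 0.05, 0.95)
    expect_equal(
      family_logpdf("beta_ls", y, th),
      family_logpdf("beta_ls", 1 - y,
                    list(mu = 1 - th$mu, sigma = th$sigma)),
      tolerance = 1e-12)
  }
})

test_that("skew-normal moments: symmetric point, slant limit, skewness bound", {
  m <- sn_moments(0, 1, 0.5)
  expect_equal(m$mean, 0)
  expect_equal(m$variance, 1)
  expect_equal(m$skewness, 0)
  expect_equal(sn_moments(0, 1, 1 - 1e-12)$mean, sqrt(2 / pi),
               tolerance = 1e-9)
  sup <- abs(sn_moments(0, 1, 1 - 1e-10)$skewness)
  expect_equal(sup, 0.9953, tolerance = 1e-3)
  nus <- seq(0.01, 0.99, length.out = 99)
  expect_true(all(abs(sn_moments(0, 1, nus)$skewness) < sup + 1e-12))
  expect_error(sn_moments(0, -1, 0.5), "omega")
  expect_error(sn_moments(0, 1, 1), "nu")
})

test_that("samplers reproduce the families' moments", {
  n <- 2e5
  for (fname in c("bernoulli", "normal", "beta_ls", "skew_normal")) {
    set.seed(9)
    th <- random_theta(fname)
    y <- family_sample(fname, n, th, seed = 123)
    mo <- family_moments(fname, th)
    se_mean <- sqrt(mo$variance / n)
    expect_lt(abs(mean(y) - mo$mean), 3 * se_mean + 1e-12)
    se_var <- sd((y - mo$mean)^2) / sqrt(n)
    expect_lt(abs(var(y) - mo$variance), 3 * se_var + 1e-12)
  }
})

test_that("sampler and log-density agree through the entropy identity", {
  # mean log-density of draws ~ negative differential entropy
  for (fname in c("beta_ls", "skew_normal")) {
    set.seed(11)
    th <- random_theta(fname)
    y <- family_sample(fname, 5e4, th, seed = 77)
    lp <- family_logpdf(fname, y, th)
    supp <- if (fname == "beta_ls") c(1e-12, 1 - 1e-12) else c(-Inf, Inf)
    neg_ent <- integrate(function(u) {
      l <- family_logpdf(fname, u, th)
      exp(l) * l
    }, supp[1], supp[2], rel.tol = 1e-9)$value
    expect_lt(abs(mean(lp) - neg_ent), 3 * sd(lp) / sqrt(length(lp)))
  }
})

test_that("boundary nudging moves exact 0/1 inside the interval and counts", {
  out <- nudge_unit_interval(c(0, 0.4, 1, NA, 0.999), eps = 1e-3)
  expect_equal(out$y, c(1e-3, 0.4, 1 - 1e-3, NA, 0.999))
  expect_equal(out$n_nudged, 2L)
})
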