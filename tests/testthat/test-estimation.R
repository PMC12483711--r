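test_that("marginal log-likelihood matches closed forms and a brute-force integral", {
  # single uninformative binary item: every row contributes log 0.5
  m0 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = 0, loadings = list(0))))),
    latent = list(q = 1, mode = "identity")))
  dat <- data.frame(u = rep(c(0, 1), 10))
  expect_equal(as.numeric(marginal_loglik(dat, numeric(0), m0, gh_grid(9, 1))),
               20 * log(0.5), tolerance = 1e-12)
  # zero-loading model: value exactly invariant to the number of nodes
  tp <- study1_true_params(3, seed = 2)
  d0 <- tp$delta
  d0[tp$model$index$comp == "z1"] <- 0
  dat <- simulate_lss(tp$model, d0, 25, seed = 3)
  expect_equal(
    as.numeric(marginal_loglik(dat, d0, tp$model, gh_grid(5, 1))),
    as.numeric(marginal_loglik(dat, d0, tp$model, gh_grid(45, 1))),
    tolerance = 1e-12)
  # informative model vs dense trapezoid integration over z in [-8, 8]
  set.seed(9)
  tp <- study1_true_params(3, seed = 9)
  dat <- simulate_lss(tp$model, tp$delta, 20, seed = 10)
  ll <- marginal_loglik(dat, tp$delta, tp$model, gh_grid(100, 1))
  zs <- seq(-8, 8, length.out = 4001)
  vals <- unpack_params(tp$model, tp$delta)
  lphi <- dnorm(zs, log = TRUE)
  ll_brute <- sum(vapply(seq_len(20), function(j) {
    lf <- lphi
    for (i in 1:3) {
      vi <- vals$items[[i]]
      th <- list(mu = plogis(vi$mu$intercept + vi$mu$loadings * zs),
                 sigma = plogis(vi$sigma$intercept + vi$sigma$loadings * zs))
      lf <- lf + family_logpdf("beta_ls", dat[j, i], th)
    }
    log(sum(exp(lf)) * (zs[2] - zs[1]) -
          (zs[2] - zs[1]) * (exp(lf[1]) + exp(lf[4001])) / 2)
  }, 0))
  expect_equal(as.numeric(ll), ll_brute, tolerance = 1e-6)
})

test_that("analytic score matches finite differences on mixed models", {
  set.seed(33)
  for (q in 1:2) {
    model <- mixed_model(q)
    delta <- random_delta(model)
    dat <- simulate_lss(model, delta, 30, seed = 100 + q)
    grid <- gh_grid(7, q)
    sc <- marginal_score(dat, delta, model, grid)
    fd <- fd_grad(function(d)
      as.numeric(marginal_loglik(dat, d, model, grid)), delta)
    expect_equal(unname(sc), fd, tolerance = 1e-5)
  }
})

test_that("score vanishes at the closed-form MLE of the reduced model", {
  m0 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = "free", loadings = list(0))))),
    latent = list(q = 1, mode = "identity")))
  set.seed(4)
  dat <- data.frame(u = rbinom(200, 1, 0.3))
  delta_hat <- qlogis(mean(dat$u))
  sc <- marginal_score(dat, delta_hat, m0, gh_grid(9, 1))
  expect_lt(abs(sc), 1e-9)
  expect_equal(length(sc), 1L)
})

test_that("warm start recovers loading structure up to a global sign", {
  tp <- study1_true_params(5, seed = 17)
  dat <- simulate_lss(tp$model, tp$delta, 800, seed = 18)
  d0 <- warm_start(dat, tp$model)
  pos <- which(tp$model$index$role == "mu" & tp$model$index$comp == "z1")
  cr <- cor(d0[pos], tp$delta[pos])
  expect_gt(abs(cr), 0.9)
  # deterministic
  expect_identical(warm_start(dat, tp$model), d0)
  # pure-noise data: loadings start much closer to zero than under signal
  d_null <- tp$delta
  d_null[tp$model$index$comp == "z1"] <- 0
  dat0 <- simulate_lss(tp$model, d_null, 800, seed = 19)
  d00 <- warm_start(dat0, tp$model)
  expect_lt(max(abs(d00[tp$model$index$comp == "z1"])), 0.45)
  expect_lt(mean(abs(d00[pos])), 0.5 * mean(abs(d0[pos])))
})

test_that("fitting a reduced model reproduces closed-form estimates and SEs", {
  m0 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = "free", loadings = list(0)))),
    list(name = "x", family = "normal",
         equations = list(mu = list(intercept = "free", loadings = list(0)),
                          sigma = list(intercept = "free",
                                       loadings = list(0))))),
    latent = list(q = 1, mode = "identity")))
  set.seed(6)
  dat <- data.frame(u = rbinom(400, 1, 0.35), x = rnorm(400, 1, 2))
  fit <- lss_fit(dat, m0, gh_grid(9, 1), em_iters = 3)
  pbar <- mean(dat$u)
  expect_equal(unname(fit$delta["u.mu.intercept"]), qlogis(pbar),
               tolerance = 1e-6)
  expect_equal(unname(fit$delta["x.mu.intercept"]), mean(dat$x),
               tolerance = 1e-6)
  sd_n <- sqrt(mean((dat$x - mean(dat$x))^2))
  expect_equal(unname(fit$delta["x.sigma.intercept"]), log(sd_n),
               tolerance = 1e-5)
  se_closed <- 1 / sqrt(400 * pbar * (1 - pbar))
  expect_equal(unname(fit$se["u.mu.intercept"]), se_closed,
               tolerance = 1e-3)
  expect_true(fit$convergence$converged)
})

test_that("fits ascend, keep a monotone EM trace, and are reflection invariant", {
  tp <- study1_true_params(4, seed = 23)
  dat <- simulate_lss(tp$model, tp$delta, 300, seed = 24)
  grid <- gh_grid(15, 1)
  d0 <- warm_start(dat, tp$model)
  fit <- lss_fit(dat, tp$model, grid, em_iters = 4)
  expect_gte(fit$loglik,
             as.numeric(marginal_loglik(dat, d0, tp$model, grid)))
  expect_true(all(diff(fit$convergence$em_trace) > -1e-8))
  d_flip <- unname(fit$delta)
  pos <- tp$model$index$comp == "z1"
  d_flip[pos] <- -d_flip[pos]
  expect_equal(as.numeric(marginal_loglik(dat, d_flip, tp$model, grid)),
               fit$loglik, tolerance = 1e-10)
})

test_that("the empirical information matches a numerical Hessian", {
  tp <- study1_true_params(3, seed = 41)
  dat <- simulate_lss(tp$model, tp$delta, 1500, seed = 42)
  grid <- gh_grid(15, 1)
  fit <- lss_fit(dat, tp$model, grid, em_iters = 3, se = TRUE)
  H <- matrix(0, fit$K, fit$K)
  dh <- unname(fit$delta)
  for (k in seq_len(fit$K)) {
    h <- 1e-4 * (1 + abs(dh[k]))
    dp <- dh; dp[k] <- dp[k] + h
    dm <- dh; dm[k] <- dm[k] - h
    H[, k] <- (marginal_score(dat, dp, tp$model, grid) -
                 marginal_score(dat, dm, tp$model, grid)) / (2 * h)
  }
  se_hess <- sqrt(diag(solve(-(H + t(H)) / 2)))
  # cross-product vs observed information: equal up to sampling error
  expect_lt(max(abs(fit$se / se_hess - 1)), 0.2)
})

test_that("information matrix is symmetric PSD with a working singularity flag", {
  tp <- study1_true_params(4, seed = 51)
  dat <- simulate_lss(tp$model, tp$delta, 250, seed = 52)
  grid <- gh_grid(15, 1)
  ia <- information_and_se(dat, tp$delta, tp$model, grid)
  expect_equal(ia$information, t(ia$information))
  expect_gt(ia$diagnostic$min_eigenvalue, 0)
  expect_false(ia$diagnostic$singular)
  expect_true(all(ia$se > 0))
  # duplicated factor (identical loading columns, no restrictions)
  cfg <- list(items = lapply(1:4, function(i)
    list(name = paste0("y", i), family = "normal",
         equations = list(mu = list(intercept = "free",
                                    loadings = list("free", "free")),
                          sigma = list(intercept = "free",
                                       loadings = list(0, 0))))),
    latent = list(q = 2, mode = "identity"))
  mdup <- suppressWarnings(build_model(cfg))
  ddup <- numeric(n_free_params(mdup))
  idx <- mdup$index
  for (i in 1:4) {
    ddup[idx$item %in% i & idx$comp == "intercept" & idx$role == "mu"] <- 0.2
    ddup[idx$item %in% i & idx$comp == "z1"] <- 0.8   # identical columns
    ddup[idx$item %in% i & idx$comp == "z2"] <- 0.8
    ddup[idx$item %in% i & idx$role == "sigma"] <- -0.1
  }
  dat2 <- simulate_lss(mdup, ddup, 150, seed = 53)
  ia2 <- information_and_se(dat2, ddup, mdup, gh_grid(7, 2))
  expect_true(ia2$diagnostic$singular)
  expect_true(all(is.na(ia2$se)))
})

test_that("AIC and BIC follow their definitions and penalize complexity", {
  ic <- aic_bic(-100, 10, 100)
  expect_equal(ic$AIC, 220)
  expect_equal(ic$BIC, 200 + 10 * log(100))
  ic2 <- aic_bic(-100, 12, 100)
  expect_gt(ic2$AIC, ic$AIC)
  expect_gt(ic2$BIC, ic$BIC)
})

test_that("EAP scores shrink toward the prior exactly when items are uninformative", {
  # zero loadings: posterior equals prior for every row
  m0 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = "free", loadings = list(0))))),
    latent = list(q = 1, mode = "identity")))
  dat <- data.frame(u = rbinom(30, 1, 0.5))
  fit0 <- lss_fit(dat, m0, gh_grid(21, 1), start = "spec", em_iters = 2,
                  se = FALSE)
  sc0 <- eap_scores(dat, fit0)
  expect_equal(sc0$eap.z1, rep(0, 30), tolerance = 1e-8)
  expect_equal(sc0$var.z1, rep(1, 30), tolerance = 1e-6)
  # informative items: EAP tracks the true latent draw and contracts
  tp <- study1_true_params(10, seed = 61)
  dat <- simulate_lss(tp$model, tp$delta, 400, seed = 62)
  z <- attr(dat, "z")
  fit <- lss_fit(dat, tp$model, gh_grid(21, 1), em_iters = 3, se = FALSE)
  sc <- eap_scores(dat, fit)
  expect_gt(abs(cor(sc$eap.z1, z[, 1])), 0.8)
  expect_true(all(sc$var.z1 < 1))
  # an all-missing row falls back to the prior
  dat2 <- dat
  dat2[1, ] <- NA
  sc2 <- eap_scores(dat2, fit)
  expect_equal(sc2$eap.z1[1], 0, tolerance = 1e-8)
  expect_equal(sc2$var.z1[1], 1, tolerance = 1e-6)
})
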