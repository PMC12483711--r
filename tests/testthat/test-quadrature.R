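test_that("tensor grids have the documented sizes and normalized weights", {
  g <- gh_grid(45, 2)
  expect_equal(nrow(g$nodes), 2025L)
  g <- gh_grid(35, 2)
  expect_equal(nrow(g$nodes), 1225L)
  expect_true(all(g$weights > 0))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_error(gh_grid(100, 3, budget = 1e5), "budget")
  expect_error(gh_grid(1, 1), "m = 2")
})

test_that("grids integrate standard-normal moments exactly up to degree 2m-1", {
  truth <- c(1, 0, 1, 0, 3, 0, 15)      # E[t^d], d = 0..6
  for (m in c(4, 10)) {
    g <- gh_grid(m, 1)
    for (d in 0:6)
      expect_lt(abs(sum(g$weights * g$nodes[, 1]^d) - truth[d + 1]), 1e-10)
  }
  # per-coordinate exactness survives the tensor product
  g2 <- gh_grid(5, 2)
  expect_lt(abs(sum(g2$weights * g2$nodes[, 2]^4) - 3), 1e-10)
  expect_lt(abs(sum(g2$weights * g2$nodes[, 1]^2 * g2$nodes[, 2]^2) - 1),
            1e-10)
})

test_that("posterior node weights behave like a posterior", {
  grid <- gh_grid(15, 1)
  m0 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = "free", loadings = list(0))))),
    latent = list(q = 1, mode = "identity")))
  # zero loadings: likelihood constant in z, posterior = prior
  w <- posterior_weights(1, c(0.3), m0, grid)
  expect_equal(w, grid$weights, tolerance = 1e-12)
  # informative binary item, y = 1: posterior mean strictly positive
  m1 <- build_model(list(items = list(
    list(name = "u", family = "bernoulli",
         equations = list(mu = list(intercept = "free",
                                    loadings = list("free"))))),
    latent = list(q = 1, mode = "identity")))
  w1 <- posterior_weights(1, c(0, 2), m1, grid)
  expect_gt(sum(w1 * grid$nodes[, 1]), 0.1)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  # all-missing row: prior weights
  expect_equal(posterior_weights(NA, c(0, 2), m1, grid), grid$weights,
               tolerance = 1e-12)
})

test_that("posterior moments recover the prior and degenerate cases", {
  grid <- gh_grid(35, 2)
  L <- correlation_cholesky(0.3, 2)
  pm <- posterior_moments(grid$weights, grid, L)
  expect_equal(pm$mean, c(0, 0), tolerance = 1e-8)
  expect_equal(pm$second_moment, L %*% t(L), tolerance = 1e-8,
               ignore_attr = TRUE)
  onehot <- rep(0, nrow(grid$nodes)); onehot[101] <- 1
  pm1 <- posterior_moments(onehot, grid, L)
  zk <- drop(L %*% grid$nodes[101, ])
  expect_equal(pm1$mean, zk, ignore_attr = TRUE)
  expect_equal(pm1$variance, matrix(0, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(2)
  w <- runif(nrow(grid$nodes)); w <- w / sum(w)
  ev <- eigen(posterior_moments(w, grid, L)$variance,
              symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("zero-loading marginal equals the product of univariate marginals", {
  cfg <- list(items = list(
    list(name = "a", family = "beta_ls",
         equations = list(mu = list(intercept = "free", loadings = list(0)),
                          sigma = list(intercept = "free",
                                       loadings = list(0)))),
    list(name = "b", family = "skew_normal",
         equations = list(mu = list(intercept = "free", loadings = list(0)),
                          sigma = list(intercept = "free", loadings = list(0)),
                          nu = list(intercept = "free", loadings = list(0))))),
    latent = list(q = 1, mode = "identity"))
  model <- build_model(cfg)
  delta <- c(0.3, -1, 0.1, -0.2, 0.4)
  dat <- simulate_lss(model, delta, 30, seed = 5)
  closed <- sum(family_logpdf("beta_ls", dat$a,
                              list(mu = plogis(0.3), sigma = plogis(-1)))) +
    sum(family_logpdf("skew_normal", dat$b,
                      list(mu = 0.1, sigma = exp(-0.2), nu = plogis(0.4))))
  for (m in c(2, 5, 45)) {
    ll <- marginal_loglik(dat, delta, model, gh_grid(m, 1))
    expect_equal(as.numeric(ll), closed, tolerance = 1e-10)
  }
})

test_that("the likelihood saturates in the number of quadrature points", {
  # moderate loadings: per-case posteriors stay wide enough for a fixed
  # 21-point rule; strong loadings sharpen them and need denser rules
  model <- study1_model(5)
  idx <- model$index
  d <- numeric(n_free_params(model))
  d[idx$role == "mu" & idx$comp == "intercept"] <- c(0, -0.5, 0.5, -1, 1)
  d[idx$role == "mu" & idx$comp == "z1"] <- c(0.3, -0.4, 0.5, 0.35, -0.45)
  d[idx$role == "sigma" & idx$comp == "intercept"] <- -1
  d[idx$role == "sigma" & idx$comp == "z1"] <- c(0.1, -0.1, 0.15, 0.1, -0.12)
  dat <- simulate_lss(model, d, 200, seed = 7)
  ll21 <- marginal_loglik(dat, d, model, gh_grid(21, 1))
  ll45 <- marginal_loglik(dat, d, model, gh_grid(45, 1))
  expect_lt(abs(ll21 - ll45) / 200, 1e-6)
})
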