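test_that("free-parameter counts match the study designs", {
  expect_equal(n_free_params(study1_model(5)), 20L)
  expect_equal(n_free_params(study2_model()), 65L)
  expect_equal(n_free_params(study1_model(5, heteroscedastic = FALSE)), 15L)
})

test_that("packing is a lossless bijection with fixed entries restored", {
  set.seed(31)
  for (model in list(study1_model(4), study2_model(3, 2), mixed_model(2))) {
    K <- n_free_params(model)
    delta <- rnorm(K)
    vals <- unpack_params(model, delta)
    expect_identical(pack_params(model, vals), delta)
    # fixed entries never enter delta but reappear at their spec value
    for (i in seq_along(model$items)) {
      it <- model$items[[i]]
      for (r in it$family$roles) {
        fixed <- which(!it$eq[[r]]$load_free)
        expect_equal(vals$items[[i]][[r]]$loadings[fixed],
                     it$eq[[r]]$load_value[fixed])
      }
    }
  }
  expect_error(unpack_params(study1_model(3), rnorm(5)), "K = 12")
})

test_that("zero-loading spec collapses to independent univariate models", {
  cfg <- list(items = list(
    list(name = "a", family = "bernoulli",
         equations = list(mu = list(intercept = "free", loadings = list(0)))),
    list(name = "b", family = "normal",
         equations = list(mu = list(intercept = "free", loadings = list(0)),
                          sigma = list(intercept = "free",
                                       loadings = list(0))))),
    latent = list(q = 1, mode = "identity"))
  model <- build_model(cfg)
  delta <- c(0.4, 0.2, -0.1)
  set.seed(8)
  dat <- simulate_lss(model, delta, 50, seed = 3)
  ll <- marginal_loglik(dat, delta, model, gh_grid(9, 1))
  direct <- sum(family_logpdf("bernoulli", dat$a, list(mu = plogis(0.4)))) +
    sum(family_logpdf("normal", dat$b, list(mu = 0.2, sigma = exp(-0.1))))
  expect_equal(as.numeric(ll), direct, tolerance = 1e-10)
})

test_that("model construction validates its inputs", {
  expect_error(build_model(list(items = list(), latent = list(q = 1))),
               "no items")
  expect_error(build_model(list(
    items = list(list(name = "x", family = "gamma")),
    latent = list(q = 1))), "gamma")
  expect_error(build_model(list(
    items = list(list(name = "x", family = "normal",
                      equations = list(nu = list()))),
    latent = list(q = 1))), "unknown equation")
  expect_error(build_model(list(
    items = list(list(name = "x", family = "normal",
                      equations = list(mu = list(loadings = list("free"))))),
    latent = list(q = 2))), "loading spec")
  expect_error(build_model(list(items = list(list(family = "normal")),
                                latent = list(q = 0))), "q >= 1")
})

test_that("under-restricted multi-factor specs warn about rotation", {
  cfg <- list(items = lapply(1:4, function(i)
    list(name = paste0("y", i), family = "normal")),
    latent = list(q = 2, mode = "correlation"))
  expect_warning(build_model(cfg), "rotation")
  expect_silent(m <- exploratory_model(rep("normal", 4), 2))
  # echelon: location loading (1,2) fixed at 0
  expect_false(m$items[[1]]$eq$mu$load_free[2])
  expect_true(m$items[[2]]$eq$mu$load_free[2])
})

test_that("correlation Cholesky factors are valid and exact", {
  expect_equal(correlation_cholesky(0, 2), diag(2))
  L <- correlation_cholesky(-0.28, 2)
  expect_equal(L[2, ], c(-0.28, 0.96), tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:10) {
    rho <- runif(3, -0.45, 0.45)
    L <- correlation_cholesky(rho, 3)
    expect_true(all(L[upper.tri(L)] == 0))
    expect_equal(rowSums(L^2), rep(1, 3), tolerance = 1e-12)
    R <- L %*% t(L)
    expect_equal(R[lower.tri(R)], rho, tolerance = 1e-12)
    expect_equal(diag(R), rep(1, 3), tolerance = 1e-12)
  }
  expect_error(correlation_cholesky(c(0.9, 0.9, -0.9), 3),
               "positive-definite")
  expect_error(correlation_cholesky(0.5, 3), "expected 3")
})

test_that("unconstrained correlation map round-trips with exact Jacobian", {
  set.seed(12)
  for (q in 2:3) {
    gam <- rnorm(q * (q - 1) / 2, 0, 0.7)
    rho <- latentlss:::rho_from_gamma(gam, q)
    expect_equal(latentlss:::gamma_from_rho(rho, q), gam, tolerance = 1e-9)
    cg <- latentlss:::chol_from_gamma(gam, q, jacobian = TRUE)
    expect_equal(cg$L %*% t(cg$L),
                 correlation_cholesky(rho, q) %*%
                   t(correlation_cholesky(rho, q)), tolerance = 1e-12)
    for (g in seq_along(gam)) {
      fd <- matrix(0, q, q)
      h <- 1e-6
      gp <- gam; gp[g] <- gp[g] + h
      gm <- gam; gm[g] <- gm[g] - h
      fd <- (latentlss:::chol_from_gamma(gp, q)$L -
               latentlss:::chol_from_gamma(gm, q)$L) / (2 * h)
      expect_equal(cg$dL[[g]], fd, tolerance = 1e-7)
    }
  }
})

test_that("likelihood is invariant to jointly flipping one factor's signs", {
  set.seed(21)
  model <- mixed_model(2)
  delta <- random_delta(model)
  dat <- simulate_lss(model, delta, 40, seed = 14)
  grid <- gh_grid(7, 2)
  ll <- marginal_loglik(dat, delta, model, grid)
  idx <- model$index
  for (r in 1:2) {
    d2 <- delta
    pos <- which(idx$comp == paste0("z", r) & idx$role != "rho")
    d2[pos] <- -d2[pos]
    d2[idx$role == "rho"] <- -d2[idx$role == "rho"]  # (2,1) touches both once
    expect_equal(as.numeric(marginal_loglik(dat, d2, model, grid)),
                 as.numeric(ll), tolerance = 1e-10)
  }
})
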