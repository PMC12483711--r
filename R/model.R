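## ---- measurement-equation specs ------------------------------------------

# canonical equation spec: list(int_free, int_value, load_free (logical q),
# load_value (numeric q)). For free entries `*_value` is the start value.
parse_equation <- function(spec, q, role, item_name) {
  default_start_load <- 0.1
  out <- list(int_free = TRUE, int_value = 0,
              load_free = rep(TRUE, q), load_value = rep(default_start_load, q))
  if (!is.null(spec$intercept)) {
    ic <- spec$intercept
    if (is.list(ic)) {
      out$int_free <- isTRUE(ic$free)
      out$int_value <- if (!is.null(ic$value)) as.numeric(ic$value) else 0
    } else if (identical(ic, "free")) {
      out$int_free <- TRUE
    } else if (is.numeric(ic)) {
      out$int_free <- FALSE
      out$int_value <- ic
    } else stop(sprintf("item '%s', %s: bad intercept spec", item_name, role),
                call. = FALSE)
  }
  if (!is.null(spec$loadings)) {
    ld <- spec$loadings
    if (length(ld) != q)
      stop(sprintf("item '%s', %s: %d loading spec(s) given, q = %d",
                   item_name, role, length(ld), q), call. = FALSE)
    for (j in seq_len(q)) {
      lj <- if (is.list(ld)) ld[[j]] else ld[j]
      if (identical(lj, "free")) {
        out$load_free[j] <- TRUE
      } else if (is.list(lj)) {
        out$load_free[j] <- isTRUE(lj$free)
        out$load_value[j] <- if (!is.null(lj$value)) as.numeric(lj$value) else
          default_start_load
      } else if (!is.na(suppressWarnings(as.numeric(lj)))) {
        out$load_free[j] <- FALSE
        out$load_value[j] <- as.numeric(lj)
      } else stop(sprintf("item '%s', %s: bad loading spec '%s'",
                          item_name, role, lj), call. = FALSE)
    }
  }
  if (!is.null(spec$start)) {  # start value for a free intercept
    out$int_value <- as.numeric(spec$start)
  }
  out
}

## ---- model construction ---------------------------------------------------

#' Build a latent location-scale-shape model
#'
#' A model lists, for every observed variable, its measurement family and one
#' measurement equation per distributional parameter (an intercept plus one
#' loading per latent variable, each either free or fixed), together with a
#' latent specification: `q` factors whose prior is multivariate normal with
#' either the identity covariance (`mode = "identity"`) or a free correlation
#' matrix (`mode = "correlation"`, strictly-lower-triangle entries free,
#' packed last in the parameter vector).
#'
#' Equation specs: `intercept` is `"free"`, a number (fixed at that value),
#' or `list(free =, value =)`; `loadings` is a length-`q` vector/list of the
#' same forms (numbers, typically 0, fix the entry). Omitted equations
#' default to everything free. A warning is issued when fewer than
#' `q*(q-1)/2` restrictions are present, since such specs are rotationally
#' indeterminate.
#'
#' @param config list with elements `items` (list of
#'   `list(name, family, equations)`) and `latent` (`list(q, mode)`).
#' @return an object of class `lss_model`.
#' @examples
#' m <- build_model(list(
#'   items = list(
#'     list(name = "y1", family = "bernoulli",
#'          equations = list(mu = list(intercept = "free", loadings = "free")))),
#'   latent = list(q = 1, mode = "identity")))
#' n_free_params(m)
#' @export
build_model <- function(config) {
  latent <- config$latent
  if (is.null(latent$q) || latent$q < 1)
    stop("latent spec must give q >= 1", call. = FALSE)
  q <- as.integer(latent$q)
  mode <- if (is.null(latent$mode)) "identity" else latent$mode
  if (!mode %in% c("identity", "correlation"))
    stop(sprintf("unknown latent mode: '%s'", mode), call. = FALSE)
  if (length(config$items) < 1) stop("model has no items", call. = FALSE)

  items <- vector("list", length(config$items))
  for (i in seq_along(config$items)) {
    it <- config$items[[i]]
    fam <- get_family(it$family)
    nm <- if (!is.null(it$name)) it$name else paste0("y", i)
    eqs <- if (is.null(it$equations)) list() else it$equations
    extra <- setdiff(names(eqs), fam$roles)
    if (length(extra))
      stop(sprintf("item '%s' (family %s): unknown equation(s) %s; expected %s",
                   nm, fam$name, paste(extra, collapse = ", "),
                   paste(fam$roles, collapse = ", ")), call. = FALSE)
    eq <- lapply(fam$roles, function(r)
      parse_equation(if (r %in% names(eqs)) eqs[[r]] else list(), q, r, nm))
    names(eq) <- fam$roles
    items[[i]] <- list(name = nm, family = fam, eq = eq)
  }
  nms <- vapply(items, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicated item names", call. = FALSE)

  model <- structure(list(items = items,
                          latent = list(q = q, mode = mode),
                          item_names = nms),
                     class = "lss_model")
  model$index <- build_index(model)
  model$pmap <- build_pmap(model)

  n_restr <- sum(vapply(items, function(it)
    sum(!unlist(lapply(it$eq, `[[`, "load_free"))), 0L)) +
    if (mode == "identity") q * (q - 1L) / 2L else 0L
  if (n_restr < q * (q - 1L) / 2L)
    warning(sprintf(paste("model has %d loading/covariance restrictions;",
                          "at least %d are needed to pin down rotation"),
                    n_restr, q * (q - 1L) / 2L), call. = FALSE)
  model
}

# flat index of free parameters, in packing order
build_index <- function(model) {
  q <- model$latent$q
  rows <- list()
  for (i in seq_along(model$items)) {
    it <- model$items[[i]]
    for (r in it$family$roles) {
      e <- it$eq[[r]]
      if (e$int_free)
        rows[[length(rows) + 1L]] <- data.frame(
          item = i, role = r, comp = "intercept",
          label = sprintf("%s.%s.intercept", it$name, r))
      for (j in which(e$load_free))
        rows[[length(rows) + 1L]] <- data.frame(
          item = i, role = r, comp = paste0("z", j),
          label = sprintf("%s.%s.z%d", it$name, r, j))
    }
  }
  if (model$latent$mode == "correlation") {
    ij <- vech_index(q)
    for (g in seq_len(nrow(ij)))
      rows[[length(rows) + 1L]] <- data.frame(
        item = NA_integer_, role = "rho",
        comp = sprintf("%d,%d", ij[g, 1], ij[g, 2]),
        label = sprintf("rho.%d.%d", ij[g, 1], ij[g, 2]))
  }
  if (!length(rows))
    return(data.frame(item = integer(0), role = character(0),
                      comp = character(0), label = character(0),
                      pos = integer(0)))
  idx <- do.call(rbind, rows)
  idx$pos <- seq_len(nrow(idx))
  idx
}

# positions of each item/role's free intercept and loadings in the packed
# vector (NA where fixed), for fast score assembly
build_pmap <- function(model) {
  idx <- model$index
  q <- model$latent$q
  lapply(seq_along(model$items), function(i) {
    it <- model$items[[i]]
    pm <- lapply(it$family$roles, function(r) {
      ip <- idx$pos[idx$item %in% i & idx$role == r & idx$comp == "intercept"]
      lp <- rep(NA_integer_, q)
      for (j in seq_len(q)) {
        pj <- idx$pos[idx$item %in% i & idx$role == r &
                        idx$comp == paste0("z", j)]
        if (length(pj)) lp[j] <- pj
      }
      list(int = if (length(ip)) ip else NA_integer_, load = lp)
    })
    names(pm) <- it$family$roles
    pm
  })
}

#' Number of free parameters
#' @param model an `lss_model`.
#' @return integer K, the length of the packed parameter vector.
#' @export
n_free_params <- function(model) nrow(model$index)

#' @export
print.lss_model <- function(x, ...) {
  q <- x$latent$q
  cat(sprintf("<lss_model> %d item(s), q = %d (%s), K = %d free parameter(s)\n",
              length(x$items), q, x$latent$mode, n_free_params(x)))
  fams <- table(vapply(x$items, function(it) it$family$name, ""))
  cat("  families:", paste(sprintf("%s x %d", names(fams), fams),
                           collapse = ", "), "\n")
  invisible(x)
}

## ---- packing --------------------------------------------------------------

# strictly-lower-triangle index pairs, column-major (vech order)
vech_index <- function(q) {
  if (q < 2) return(matrix(integer(0), 0, 2))
  ij <- which(lower.tri(diag(q)), arr.ind = TRUE)
  ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
}

# empty values skeleton filled with the spec's fixed/start values
values_template <- function(model) {
  vals <- lapply(model$items, function(it)
    lapply(it$eq, function(e)
      list(intercept = e$int_value, loadings = e$load_value)))
  q <- model$latent$q
  rho <- if (model$latent$mode == "correlation")
    numeric(q * (q - 1) / 2) else numeric(0)
  list(items = vals, rho = rho)
}

#' Pack structured parameter values into the flat free-parameter vector
#'
#' `pack_params` collects the free entries of a structured value set (one
#' intercept and `q` loadings per item equation, plus the free latent
#' correlations) into the flat vector `delta` of length `K`;
#' `unpack_params` inverts it, restoring fixed entries from the model spec.
#' The round trip is exact.
#'
#' @param model an `lss_model`.
#' @param values structured values as produced by `unpack_params`.
#' @return `pack_params`: numeric vector of length `K`.
#' @export
pack_params <- function(model, values) {
  idx <- model$index
  delta <- numeric(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    if (idx$role[p] == "rho") {
      g <- match(idx$comp[p],
                 sprintf("%d,%d", vech_index(model$latent$q)[, 1],
                         vech_index(model$latent$q)[, 2]))
      delta[p] <- values$rho[g]
    } else {
      v <- values$items[[idx$item[p]]][[idx$role[p]]]
      delta[p] <- if (idx$comp[p] == "intercept") v$intercept else
        v$loadings[as.integer(sub("z", "", idx$comp[p]))]
    }
  }
  delta
}

#' @rdname pack_params
#' @param delta flat free-parameter vector of length `K`.
#' @return `unpack_params`: a list with `items` (per item, per role:
#'   `intercept`, `loadings`) and `rho` (free correlation entries,
#'   vech order).
#' @export
unpack_params <- function(model, delta) {
  K <- n_free_params(model)
  if (length(delta) != K)
    stop(sprintf("delta has length %d; model has K = %d free parameters",
                 length(delta), K), call. = FALSE)
  vals <- values_template(model)
  idx <- model$index
  rho_g <- 0L
  for (p in seq_len(K)) {
    if (idx$role[p] == "rho") {
      rho_g <- rho_g + 1L
      vals$rho[rho_g] <- delta[p]
    } else if (idx$comp[p] == "intercept") {
      vals$items[[idx$item[p]]][[idx$role[p]]]$intercept <- delta[p]
    } else {
      j <- as.integer(sub("z", "", idx$comp[p]))
      vals$items[[idx$item[p]]][[idx$role[p]]]$loadings[j] <- delta[p]
    }
  }
  vals
}

# start vector from the spec's stored start values
model_start <- function(model) pack_params(model, values_template(model))

## ---- latent covariance ----------------------------------------------------

#' Cholesky factor of a correlation matrix from its free entries
#'
#' Builds the correlation matrix with unit diagonal and strictly-lower
#' entries `rho_entries` (vech order: (2,1), (3,1), ..., (q,q-1)) and returns
#' its lower-triangular Cholesky factor, whose rows have unit Euclidean norm.
#'
#' @param rho_entries numeric vector of length `q*(q-1)/2`.
#' @param q number of latent variables.
#' @return lower-triangular `q x q` matrix `L` with `L %*% t(L)` equal to the
#'   correlation matrix.
#' @examples
#' correlation_cholesky(-0.28, 2)  # second row (-0.28, 0.96)
#' @export
correlation_cholesky <- function(rho_entries, q) {
  if (length(rho_entries) != q * (q - 1) / 2)
    stop(sprintf("expected %d correlation entries for q = %d, got %d",
                 q * (q - 1) / 2, q, length(rho_entries)), call. = FALSE)
  R <- diag(q)
  ij <- vech_index(q)
  R[ij] <- rho_entries
  R[ij[, c(2, 1), drop = FALSE]] <- rho_entries
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) <= 0))
    stop("correlation entries do not form a positive-definite correlation matrix",
         call. = FALSE)
  t(ch)
}

# L (and, optionally, its Jacobian) from unconstrained reals via the
# tanh / row-normalized hyperspherical map: row i uses c_ij = tanh(gamma_ij),
# l_ij = c_ij * prod_{k<j} s_ik, l_ii = prod_{k<i} s_ik, s = sqrt(1 - c^2).
# Guarantees positive-definiteness for any real input.
chol_from_gamma <- function(gamma, q, jacobian = FALSE) {
  gamma <- pmin(pmax(gamma, -8), 8)   # tanh(8) ~ 1 - 2e-7: keeps L full rank
  L <- diag(q)
  ij <- vech_index(q)
  C <- matrix(0, q, q)
  C[ij] <- tanh(gamma)
  S <- sqrt(1 - C^2)
  for (i in seq_len(q)[-1]) {
    cum <- cumprod(c(1, S[i, seq_len(i - 1)]))
    L[i, seq_len(i - 1)] <- C[i, seq_len(i - 1)] * cum[seq_len(i - 1)]
    L[i, i] <- cum[i]
  }
  if (!jacobian) return(list(L = L))
  dL <- vector("list", nrow(ij))
  for (g in seq_len(nrow(ij))) {
    i <- ij[g, 1]; m <- ij[g, 2]
    D <- matrix(0, q, q)
    cum <- cumprod(c(1, S[i, seq_len(i - 1)]))
    # row i only; dc/dgamma = s^2, and for j > m
    # dl_ij/dgamma_m = l_ij * (-c_m/s_m^2) * s_m^2 = -l_ij * c_m
    D[i, m] <- cum[m] * S[i, m]^2
    js <- seq_len(i)[seq_len(i) > m]
    for (j in js) D[i, j] <- -L[i, j] * C[i, m]
    dL[[g]] <- D
  }
  list(L = L, dL = dL)
}

# inverse of chol_from_gamma through the correlation matrix
gamma_from_rho <- function(rho, q) {
  L <- correlation_cholesky(rho, q)
  ij <- vech_index(q)
  gamma <- numeric(nrow(ij))
  # recover c row by row: c_ij = l_ij / prod_{k<j} s_ik
  for (i in seq_len(q)[-1]) {
    s_prod <- 1
    for (j in seq_len(i - 1)) {
      cij <- L[i, j] / s_prod
      cij <- max(min(cij, 1 - 1e-12), -1 + 1e-12)
      gamma[ij[, 1] == i & ij[, 2] == j] <- atanh(cij)
      s_prod <- s_prod * sqrt(1 - cij^2)
    }
  }
  gamma
}

rho_from_gamma <- function(gamma, q) {
  L <- chol_from_gamma(gamma, q)$L
  (L %*% t(L))[vech_index(q)]
}

# Jacobian dL/drho_g via the Cholesky differential:
# dL = L * Phi(L^{-1} dR L^{-T}), Phi = lower triangle with halved diagonal.
dL_drho <- function(rho, q) {
  L <- correlation_cholesky(rho, q)
  Linv <- backsolve(t(L), diag(q), upper.tri = TRUE, transpose = TRUE)
  ij <- vech_index(q)
  out <- vector("list", nrow(ij))
  for (g in seq_len(nrow(ij))) {
    dR <- matrix(0, q, q)
    dR[ij[g, 1], ij[g, 2]] <- 1
    dR[ij[g, 2], ij[g, 1]] <- 1
    M <- Linv %*% dR %*% t(Linv)
    Phi <- M
    Phi[upper.tri(Phi)] <- 0
    diag(Phi) <- diag(Phi) / 2
    out[[g]] <- L %*% Phi
  }
  out
}

# split delta into measurement part and correlation part
split_delta <- function(model, delta) {
  is_rho <- model$index$role == "rho"
  list(meas = delta[!is_rho], rho = delta[is_rho], is_rho = is_rho)
}

# L for the latent prior implied by delta
latent_chol <- function(model, delta) {
  q <- model$latent$q
  if (model$latent$mode == "identity") return(diag(q))
  correlation_cholesky(split_delta(model, delta)$rho, q)
}

## ---- convenience constructors --------------------------------------------

#' One-factor heteroscedastic Beta model
#'
#' `p` location-scale Beta items, each with free intercept and loading in
#' both the location and the scale equation, on a single standard-normal
#' factor (`K = 4p`). Setting `heteroscedastic = FALSE` fixes all scale
#' loadings to 0.
#'
#' @param p number of items.
#' @param heteroscedastic should the scale equations load on the factor?
#' @return an `lss_model`.
#' @export
study1_model <- function(p, heteroscedastic = TRUE) {
  build_model(list(
    items = lapply(seq_len(p), function(i) list(
      name = paste0("y", i), family = "beta_ls",
      equations = list(
        mu = list(intercept = "free", loadings = list("free")),
        sigma = list(intercept = "free",
                     loadings = if (heteroscedastic) list("free") else list(0))))),
    latent = list(q = 1, mode = "identity")))
}

#' Two-factor item-response / response-time model
#'
#' `p_sn` Skew-Normal response-time items whose location, scale, and shape
#' equations all load on factor 1 (latent speed), and `p_bin` Bernoulli
#' items loading on factor 2 (latent ability), with a free speed-ability
#' correlation (`K = 2 p_bin + 6 p_sn + 1` by default).
#'
#' @param p_bin number of binary items.
#' @param p_sn number of Skew-Normal items.
#' @return an `lss_model`.
#' @export
study2_model <- function(p_bin = 8, p_sn = 8) {
  bin <- lapply(seq_len(p_bin), function(i) list(
    name = paste0("u", i), family = "bernoulli",
    equations = list(mu = list(intercept = "free",
                               loadings = list(0, "free")))))
  sn <- lapply(seq_len(p_sn), function(i) {
    eq <- list(intercept = "free", loadings = list("free", 0))
    list(name = paste0("t", i), family = "skew_normal",
         equations = list(mu = eq, sigma = eq, nu = eq))
  })
  build_model(list(items = c(bin, sn),
                   latent = list(q = 2, mode = "correlation")))
}

#' Exploratory model with the echelon identification pattern
#'
#' All equations free except that the upper triangle of the location loading
#' matrix (entries `(i, j)` with `j > i`) is fixed to 0 and the latent
#' covariance is the identity, the standard echelon scheme for resolving
#' rotational indeterminacy.
#'
#' @param families character vector of family names, one per item.
#' @param q number of latent variables.
#' @param names optional item names.
#' @return an `lss_model`.
#' @export
exploratory_model <- function(families, q, names = NULL) {
  p <- length(families)
  if (is.null(names)) names <- paste0("y", seq_len(p))
  items <- lapply(seq_len(p), function(i) {
    roles <- family_roles(families[i])
    eqs <- lapply(roles, function(r) {
      lds <- as.list(rep("free", q))
      if (r == roles[1] && i < q) for (j in seq((i + 1), q)) lds[[j]] <- 0
      list(intercept = "free", loadings = lds)
    })
    names(eqs) <- roles
    list(name = names[i], family = families[i], equations = eqs)
  })
  build_model(list(items = items, latent = list(q = q, mode = "identity")))
}
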