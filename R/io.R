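## ---- tabular data ---------------------------------------------------------

#' Read person-by-item data from CSV/TSV
#'
#' Reads a delimited file with a header row (comma-separated, or
#' tab-separated for `.tsv`/`.txt`), one row per respondent and one numeric
#' column per observed variable; empty cells become missing values. When a
#' model is supplied, column names are validated against the model's items
#' and unit-interval (Beta) columns with values on the closed boundary are
#' nudged inside `(0, 1)` by `boundary_eps`, with the number of moved values
#' reported.
#'
#' @param path file path.
#' @param model optional `lss_model` for validation and boundary handling.
#' @param boundary_eps boundary offset for Beta items (default 1e-3).
#' @param quiet suppress the nudge message?
#' @return data frame of numeric columns.
#' @export
read_lss_data <- function(path, model = NULL, boundary_eps = 1e-3,
                          quiet = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) || is.logical(df[[j]])) next
    raw <- trimws(as.character(df[[j]]))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                   raw[bad[1]], bad[1], names(df)[j]), call. = FALSE)
    df[[j]] <- num
  }
  if (!is.null(model)) {
    missing_items <- setdiff(model$item_names, names(df))
    if (length(missing_items))
      stop(sprintf("data columns {%s} do not provide model items {%s}",
                   paste(names(df), collapse = ", "),
                   paste(model$item_names, collapse = ", ")), call. = FALSE)
    df <- df[model$item_names]
    n_nudged <- 0L
    for (i in seq_along(model$items)) {
      if (model$items[[i]]$family$name != "beta_ls") next
      nd <- nudge_unit_interval(df[[i]], boundary_eps)
      df[[i]] <- nd$y
      n_nudged <- n_nudged + nd$n_nudged
    }
    if (n_nudged > 0 && !quiet)
      message(sprintf("moved %d boundary value(s) inside (0,1) by eps = %g",
                      n_nudged, boundary_eps))
  }
  df
}

## ---- model configs --------------------------------------------------------

# canonical config list for serialization (fully explicit free/value form)
model_to_config <- function(model) {
  list(
    items = lapply(seq_along(model$items), function(i) {
      it <- model$items[[i]]
      list(name = it$name, family = it$family$name,
           equations = lapply(it$eq, function(e)
             list(intercept = list(free = e$int_free, value = e$int_value),
                  loadings = list(free = as.list(e$load_free),
                                  value = as.list(e$load_value)))))
    }),
    latent = list(q = model$latent$q, mode = model$latent$mode))
}

config_from_canonical <- function(cfg) {
  cfg$items <- lapply(cfg$items, function(it) {
    it$equations <- lapply(it$equations, function(e) {
      q <- length(e$loadings$free)
      list(intercept = list(free = isTRUE(e$intercept$free),
                            value = as.numeric(e$intercept$value)),
           loadings = lapply(seq_len(q), function(j)
             list(free = isTRUE(e$loadings$free[[j]]),
                  value = as.numeric(e$loadings$value[[j]]))))
    })
    it
  })
  cfg
}

#' Read / write a model configuration file
#'
#' Model specs serialize to YAML (default) or JSON (`.json` extension), one
#' block per item giving the family and the free/fixed pattern of every
#' measurement equation, plus the latent block. Files written by
#' `write_model_config()` re-read to an identical model, and rewriting a
#' file just read reproduces it byte for byte.
#'
#' @param path file path (`.yml`/`.yaml` or `.json`).
#' @return `read_model_config()`: an `lss_model`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  build_model(config_from_canonical(cfg))
}

#' @rdname read_model_config
#' @param model an `lss_model` (or a raw config list).
#' @return `write_model_config()`: `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- if (inherits(model, "lss_model")) model_to_config(model) else model
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(cfg, precision = 15), path)
  }
  invisible(path)
}

## ---- results --------------------------------------------------------------

# tiny FNV-1a hash for provenance headers (no external digest dependency)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime without losing precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_header <- function(seed, config) {
  c(sprintf("# latentlss %s", as.character(utils::packageVersion("latentlss"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("# config_hash=%s", fnv1a(config)))
}

#' Serialize a fitted model to JSON and CSV
#'
#' `write_fit_json()` stores the estimates keyed by item/role/component
#' together with standard errors, fit statistics, convergence and
#' identification records, and the full model config (so the fit can be
#' reloaded for scoring). `write_fit_csv()` writes the flat
#' parameter/estimate/SE table with a provenance comment header.
#'
#' @param fit an `lss_fit`.
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  idx <- fit$model$index
  est <- lapply(seq_len(nrow(idx)), function(p) list(
    item = if (is.na(idx$item[p])) NA else fit$model$item_names[idx$item[p]],
    role = idx$role[p], component = idx$comp[p],
    estimate = unname(fit$delta[p]), se = unname(fit$se[p])))
  cfg <- model_to_config(fit$model)
  out <- list(
    package = paste("latentlss",
                    as.character(utils::packageVersion("latentlss"))),
    seed = if (is.null(seed)) NA else seed,
    config_hash = fnv1a(cfg),
    loglik = fit$loglik, K = fit$K, n = fit$n,
    AIC = fit$AIC, BIC = fit$BIC,
    convergence = fit$convergence[c("converged", "em_iters", "grad_norm")],
    identification = fit$identification,
    grid = fit$grid,
    estimates = est,
    model = cfg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_fit_csv <- function(fit, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, model_to_config(fit$model)), con)
  utils::write.csv(summary(fit), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param report an `lss_report` from [run_study()].
#' @export
write_report_csv <- function(report, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  tab <- report$table
  tab$n <- report$design$n
  if (!is.null(report$design$p)) tab$p <- report$design$p
  writeLines(provenance_header(seed, unclass(report$design)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
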