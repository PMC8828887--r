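#' Configuration for reference-station gap imputation
#'
#' @param n_references number of nearest reference stations used as
#'   predictors for each imputed site (default 5).
#' @param transform default distribution-normalising transform
#'   (`"quantile-normal"`); see [fit_transform()].
#' @param transform_map named character vector overriding the transform per
#'   measurement; by default pressure uses the `"power"` (Yeo-Johnson)
#'   transform because quantile clipping is too harsh for its outliers.
#' @param max_iterations round-robin iterations before giving up.
#' @param tolerance convergence threshold: maximum absolute change of any
#'   imputed entry, on the normalised scale (default 1e-3).
#' @param impute_so2 impute SO2 series? Off by default: with sparse SO2
#'   networks the imputation is unreliable, so SO2 gaps are passed through
#'   (the option remains available).
#' @param use_model_covariates include a site's model-forecast channels
#'   (`<pollutant>_EMEP` columns) as predictors when co-imputing pollutants.
#' @param n_quantiles quantile-grid size for the quantile-normal transform.
#' @param min_obs minimum non-missing points required to fit a transform.
#' @param seed seed for any stochastic component.
#' @return an object of class `imputation_config`.
#' @export
imputation_config <- function(n_references = 5,
                              transform = "quantile-normal",
                              transform_map = c(pressure = "power"),
                              max_iterations = 10,
                              tolerance = 1e-3,
                              impute_so2 = FALSE,
                              use_model_covariates = TRUE,
                              n_quantiles = 1000,
                              min_obs = 10,
                              seed = 42) {
  stopifnot(n_references >= 1, tolerance > 0, max_iterations >= 1)
  structure(list(n_references = n_references, transform = transform,
                 transform_map = transform_map,
                 max_iterations = max_iterations, tolerance = tolerance,
                 impute_so2 = impute_so2,
                 use_model_covariates = use_model_covariates,
                 n_quantiles = n_quantiles, min_obs = min_obs, seed = seed),
            class = "imputation_config")
}

transform_method_for <- function(config, name) {
  base <- sub("_(mean|max)$", "", name)
  if (!is.null(config$transform_map) && base %in% names(config$transform_map)) {
    unname(config$transform_map[base])
  } else {
    config$transform
  }
}

# Round-robin regression imputation of an aligned numeric matrix.
# Columns are series sharing one time index; `methods` gives the transform
# per column. Observed entries are returned bit-identical.
impute_matrix <- function(M, config = imputation_config(), methods = NULL) {
  M <- as.matrix(M)
  p <- ncol(M)
  if (is.null(methods)) {
    methods <- vapply(colnames(M) %||% as.character(seq_len(p)),
                      function(nm) transform_method_for(config, nm), character(1))
  }
  obs <- !is.na(M)
  usable <- colSums(obs) >= config$min_obs
  fillable <- usable & colSums(!obs) > 0
  if (!any(fillable)) {
    return(list(values = M, imputed = !obs & FALSE, converged = TRUE, n_iter = 0L))
  }
  trs <- vector("list", p)
  Z <- M
  for (j in seq_len(p)) {
    if (!usable[j]) next
    trs[[j]] <- fit_transform(M[, j], methods[j], n_quantiles = config$n_quantiles)
    Z[, j] <- transform_forward(trs[[j]], M[, j])
  }
  # initialise gaps at the column mean of the transformed observations
  for (j in which(fillable)) {
    Z[!obs[, j], j] <- mean(Z[obs[, j], j])
  }
  predictors <- which(usable)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    delta <- 0
    for (j in which(fillable)) {
      others <- setdiff(predictors, j)
      if (!length(others)) next
      X <- Z[, others, drop = FALSE]
      fit <- bayes_ridge(X[obs[, j], , drop = FALSE], Z[obs[, j], j])
      pred <- predict(fit, X[!obs[, j], , drop = FALSE])
      delta <- max(delta, max(abs(pred - Z[!obs[, j], j])))
      Z[!obs[, j], j] <- pred
    }
    n_iter <- it
    if (delta < config$tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("imputation did not converge within ", config$max_iterations,
            " iterations (last change ", signif(delta, 3), ")")
  }
  out <- M
  for (j in which(fillable)) {
    filled <- transform_inverse(trs[[j]], Z[!obs[, j], j])
    out[!obs[, j], j] <- filled
  }
  list(values = out, imputed = !obs & !is.na(out),
       converged = converged, n_iter = n_iter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative multivariate imputation of one series against its covariates
#'
#' Fills gaps in a target series using aligned covariate series (typically
#' the site's nearest reference stations, plus co-measured channels for
#' pollutants). All series are mapped to a normal scale, then each series
#' with gaps is regressed in turn on all the others with [bayes_ridge()] and
#' its missing entries replaced by predictions, round-robin, until the
#' largest change of any imputed entry drops below `config$tolerance` or
#' `config$max_iterations` is reached (non-convergence warns, it does not
#' fail). Observed values are returned exactly as supplied.
#'
#' @param target numeric vector with gaps (`NA`).
#' @param covariates data.frame or matrix of covariate series aligned with
#'   `target` (same time index, same length); covariates may have gaps too.
#' @param config an [imputation_config()].
#' @param methods optional character vector of transform methods for
#'   `c(target, covariates)` columns.
#' @return list with `values` (filled target), `imputed` (logical mask,
#'   `TRUE` exactly on filled entries), `converged`, `n_iter`.
#' @export
iterative_impute <- function(target, covariates, config = imputation_config(),
                             methods = NULL) {
  covariates <- as.matrix(covariates)
  stopifnot(length(target) == nrow(covariates))
  M <- cbind(.target = target, covariates)
  res <- impute_matrix(M, config, methods = methods)
  list(values = unname(res$values[, 1]), imputed = unname(res$imputed[, 1]),
       converged = res$converged, n_iter = res$n_iter)
}

# wide matrix (time x site) for one measurement from long readings
wide_series <- function(data, measurement, times, sites) {
  M <- matrix(NA_real_, length(times), length(sites),
              dimnames = list(NULL, sites))
  idx <- cbind(match(format_timestamps(data$timestamp), times),
               match(data$site_id, sites))
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  M[idx[ok, , drop = FALSE]] <- data[[measurement]][ok]
  M
}

#' Impute gaps across a whole sensor network
#'
#' Orchestrates gap filling for every measurement: per measurement,
#' reference sites (coverage at least `criteria$reference_days`) with gaps
#' are imputed first against their nearest fellow references, so downstream
#' regressions have complete predictors; then every retained
#' (`criteria$retain_days`) non-reference site is imputed from its
#' `config$n_references` nearest reference stations. Meteorological
#' measurements are imputed independently of each other; with
#' `co_impute = TRUE` (pollutants) each site's measurements are imputed
#' jointly, together with its model-forecast channels (`<m>_EMEP` columns)
#' when `config$use_model_covariates` is set. SO2 is passed through
#' untouched unless `config$impute_so2` is `TRUE`. Sites below retention
#' coverage are skipped and logged.
#'
#' @param data hourly readings data.frame (`site_id`, `timestamp`,
#'   measurement columns).
#' @param sites site metadata (`site_id`, `longitude`, `latitude`).
#' @param measurements measurement columns to impute; model-covariate
#'   (`*_EMEP`) columns are predictors only, never imputation targets.
#' @param config an [imputation_config()].
#' @param criteria a [coverage_criteria()].
#' @param co_impute impute a site's measurements jointly (pollutant mode)?
#' @return list with `data` (filled readings), `mask` (aligned logical
#'   data.frame, `TRUE` where imputed) and `log` (data.frame of per-site
#'   actions).
#' @export
impute_network <- function(data, sites, measurements = NULL,
                           config = imputation_config(),
                           criteria = coverage_criteria(),
                           co_impute = FALSE) {
  set.seed(config$seed)
  if (is.null(measurements)) {
    measurements <- setdiff(names(data), c("site_id", "timestamp"))
    measurements <- measurements[vapply(data[measurements], is.numeric, logical(1))]
    measurements <- measurements[!grepl("_EMEP$", measurements)]
  }
  times <- sort(unique(format_timestamps(data$timestamp)))
  site_ids <- sites$site_id
  sel <- select_sites(data, measurements, criteria)
  cov <- sel$coverage
  mask <- data[c("site_id", "timestamp")]
  for (m in measurements) mask[[m]] <- FALSE
  log <- list()
  note <- function(site, measurement, action, n = NA_integer_) {
    log[[length(log) + 1L]] <<- data.frame(site_id = site, measurement = measurement,
                                           action = action, n_filled = n,
                                           stringsAsFactors = FALSE)
  }

  mats <- lapply(stats::setNames(measurements, measurements),
                 function(m) wide_series(data, m, times, site_ids))
  emep_cols <- grep("_EMEP$", names(data), value = TRUE)
  emep <- lapply(stats::setNames(emep_cols, emep_cols),
                 function(m) wide_series(data, m, times, site_ids))

  targets <- measurements
  if (!config$impute_so2) targets <- setdiff(targets, "SO2")

  ref_ids <- function(m) {
    d <- cov[cov$measurement == m, ]
    sort(d$site_id[d$reference])
  }
  retained_ids <- function(m) {
    d <- cov[cov$measurement == m, ]
    d$site_id[d$retained]
  }

  # pass 1: complete the reference stations, per measurement
  for (m in targets) {
    refs <- ref_ids(m)
    for (sid in refs) {
      col <- mats[[m]][, sid]
      if (!anyNA(col)) next
      others <- setdiff(refs, sid)
      if (!length(others)) { note(sid, m, "reference-unfillable"); next }
      near <- nearest_references(sites[sites$site_id == sid, ],
                                 sites[sites$site_id %in% others, ],
                                 config$n_references)
      res <- iterative_impute(col, mats[[m]][, near, drop = FALSE], config,
                              methods = rep(transform_method_for(config, m),
                                            length(near) + 1L))
      mats[[m]][, sid] <- res$values
      sel_rows <- mask$site_id == sid
      t_idx <- match(format_timestamps(mask$timestamp[sel_rows]), times)
      mask[[m]][sel_rows] <- res$imputed[t_idx]
      note(sid, m, "reference-imputed", sum(res$imputed))
    }
  }

  # pass 2: retained non-reference sites
  impute_site <- function(sid, ms) {
    cols <- list()
    methods <- character()
    for (m in ms) {
      cols[[paste0("t_", m)]] <- wide_series(data, m, times, site_ids)[, sid]
      methods <- c(methods, transform_method_for(config, m))
    }
    if (co_impute && config$use_model_covariates) {
      for (e in emep_cols) {
        cols[[e]] <- emep[[e]][, sid]
        methods <- c(methods, transform_method_for(config, e))
      }
    }
    for (m in ms) {
      refs <- setdiff(ref_ids(m), sid)
      if (!length(refs)) next
      near <- nearest_references(sites[sites$site_id == sid, ],
                                 sites[sites$site_id %in% refs, ],
                                 config$n_references)
      for (r in near) {
        nm <- paste0("ref_", m, "_", r)
        cols[[nm]] <- mats[[m]][, r]
        methods <- c(methods, transform_method_for(config, m))
      }
    }
    M <- do.call(cbind, cols)
    res <- impute_matrix(M, config, methods = methods)
    for (m in ms) {
      j <- match(paste0("t_", m), colnames(M))
      mats[[m]][, sid] <<- res$values[, j]
      sel_rows <- mask$site_id == sid
      t_idx <- match(format_timestamps(mask$timestamp[sel_rows]), times)
      mask[[m]][sel_rows] <<- mask[[m]][sel_rows] | res$imputed[t_idx, j]
      note(sid, m, "imputed", sum(res$imputed[, j]))
    }
  }

  for (sid in site_ids) {
    ms <- targets[vapply(targets, function(m) {
      sid %in% retained_ids(m) && !sid %in% ref_ids(m) &&
        anyNA(mats[[m]][, sid])
    }, logical(1))]
    skipped <- targets[vapply(targets, function(m) {
      !sid %in% retained_ids(m) && anyNA(wide_series(data, m, times, sid)[, 1])
    }, logical(1))]
    for (m in skipped) note(sid, m, "skipped-below-retention")
    if (!length(ms)) next
    if (co_impute) {
      impute_site(sid, ms)
    } else {
      for (m in ms) impute_site(sid, m)
    }
  }

  # write the filled matrices back into the long frame
  out <- data
  t_idx <- match(format_timestamps(out$timestamp), times)
  s_idx <- match(out$site_id, site_ids)
  for (m in measurements) {
    out[[m]] <- mats[[m]][cbind(t_idx, s_idx)]
  }
  log_df <- if (length(log)) do.call(rbind, log)
            else data.frame(site_id = character(), measurement = character(),
                            action = character(), n_filled = integer())
  list(data = out, mask = mask, log = log_df)
}
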