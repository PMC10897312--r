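#' Fit the LAI multiple linear regression
#'
#' Ordinary least squares of ground-measured LAI on the UAV predictors via
#' [stats::lm()], with fit statistics on the training data. The design must
#' be full rank; collinear columns are reported rather than silently
#' dropped. RMSE uses the 1/n convention (no degrees-of-freedom
#' adjustment), so fit and cross-validated RMSE are directly comparable.
#'
#' @param table Tibble with the predictor columns and a `lai_mean` response
#'   column (e.g. from [predictor_table()]).
#' @param predictors Character vector of predictor column names; defaults to
#'   every [predictor_names()] column present in `table`.
#' @param response Response column name.
#' @return Object of class `lai_model`: the `lm` fit plus `r2_fit`,
#'   `rmse_fit` and bookkeeping; extend with [loocv()] and
#'   [lmg_importance()] via [fit_lai_model()].
#' @export
fit_ols <- function(table, predictors = NULL, response = "lai_mean") {
  table <- tibble::as_tibble(table)
  if (is.null(predictors)) {
    predictors <- intersect(predictor_names(), names(table))
  }
  miss <- setdiff(c(predictors, response), names(table))
  if (length(miss)) {
    stop("table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table); p <- length(predictors)
  if (n <= p + 1) {
    stop("need more than ", p + 1, " rows to fit ", p, " predictors; got ",
         n, call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(table[predictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  y <- table[[response]]
  dat <- as.data.frame(table[c(predictors, response)])
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = response)
  fit <- stats::lm(fml, data = dat)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  structure(
    list(fit = fit,
         predictor_names = predictors,
         response = response,
         coefficients = stats::coef(fit),
         n = n,
         r2_fit = 1 - sse / sstot,
         rmse_fit = sqrt(sse / n),
         r2_loocv = NA_real_, rmse_loocv = NA_real_,
         importance_pct = NULL,
         data = tibble::as_tibble(dat)),
    class = "lai_model"
  )
}

#' Leave-one-out cross-validation of the LAI regression
#'
#' Each observation is predicted from a model fitted to the other `n - 1`
#' rows. For OLS the held-out residual equals `e_i / (1 - h_ii)` with
#' `h_ii` the hat-matrix leverage, so no explicit refitting is needed; the
#' identity is exercised against explicit refits in the test suite.
#' `r2_loocv` is computed against the total sum of squares of the full
#' response so it is comparable with the training-fit R-squared.
#'
#' @inheritParams fit_ols
#' @return Named list with `r2_loocv` and `rmse_loocv`.
#' @export
loocv <- function(table, predictors = NULL, response = "lai_mean") {
  m <- fit_ols(table, predictors, response)
  h <- stats::lm.influence(m$fit, do.coef = FALSE)$hat
  if (any(h >= 1 - 1e-12)) {
    stop("fold ", which(h >= 1 - 1e-12)[1],
         " is rank deficient when left out (leverage 1)", call. = FALSE)
  }
  press_res <- stats::residuals(m$fit) / (1 - h)
  y <- m$data[[response]]
  sstot <- sum((y - mean(y))^2)
  list(r2_loocv = 1 - sum(press_res^2) / sstot,
       rmse_loocv = sqrt(mean(press_res^2)))
}

# R^2 of y on the centred predictor subset, from precomputed covariances.
subset_r2 <- function(Sxx, Sxy, Syy, idx) {
  if (!length(idx)) return(0)
  b <- solve(Sxx[idx, idx, drop = FALSE], Sxy[idx])
  sum(b * Sxy[idx]) / Syy
}

#' LMG relative importance of the regression predictors
#'
#' Decomposes the full-model R-squared over predictors by the LMG
#' (Lindeman-Merenda-Gold) rule: a predictor's contribution is its average
#' increase in R-squared over all orders in which it can enter the model.
#' Computed exactly by enumerating all `2^p` predictor subsets with the
#' standard ordering weights `|S|! (p - |S| - 1)! / p!`, then normalized to
#' percentages of the full-model R-squared so the shares sum to 100.
#'
#' @inheritParams fit_ols
#' @param max_p Enumeration bound on the predictor count (default 20).
#' @return Tibble with columns `predictor`, `lmg_r2` (absolute R-squared
#'   share) and `importance_pct` (normalized percentage).
#' @export
lmg_importance <- function(table, predictors = NULL, response = "lai_mean",
                           max_p = 20) {
  m <- fit_ols(table, predictors, response)  # validates rank and columns
  predictors <- m$predictor_names
  p <- length(predictors)
  if (p > max_p) {
    stop("LMG enumerates 2^p subsets; p = ", p, " exceeds ", max_p,
         " - prune predictors first", call. = FALSE)
  }
  X <- as.matrix(m$data[predictors])
  y <- m$data[[m$response]]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  Sxx <- crossprod(Xc); Sxy <- drop(crossprod(Xc, yc)); Syy <- sum(yc^2)

  r2 <- numeric(2^p)  # R^2 of every subset, indexed by bitmask + 1
  for (s in 0:(2^p - 1)) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1))) != 0L)
    r2[s + 1] <- subset_r2(Sxx, Sxy, Syy, idx)
  }
  wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
              lfactorial(p))
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(2^p - 1)) {
      if (bitwAnd(s, bit) == 0L) {
        k <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1))) != 0L)
        shares[j] <- shares[j] + wt[k + 1] * (r2[bitwOr(s, bit) + 1] - r2[s + 1])
      }
    }
  }
  tibble::tibble(
    predictor = predictors,
    lmg_r2 = shares,
    importance_pct = shares / sum(shares) * 100
  )
}

#' Fit the full LAI model: OLS, LOOCV and LMG importance
#'
#' One-stop fit used by the pipeline: ordinary least squares plus
#' leave-one-out statistics and the LMG importance decomposition.
#'
#' @inheritParams fit_ols
#' @return An object of class `lai_model` with all statistics filled.
#' @export
fit_lai_model <- function(table, predictors = NULL, response = "lai_mean") {
  m <- fit_ols(table, predictors, response)
  cv <- loocv(table, m$predictor_names, response)
  m$r2_loocv <- cv$r2_loocv
  m$rmse_loocv <- cv$rmse_loocv
  m$importance_pct <- lmg_importance(table, m$predictor_names, response)
  m
}

#' @export
print.lai_model <- function(x, ...) {
  cat(sprintf("<lai_model> %d predictors, n = %d\n",
              length(x$predictor_names), x$n))
  cat(sprintf("  fit:   R2 = %.3f, RMSE = %.3f\n", x$r2_fit, x$rmse_fit))
  if (is.finite(x$r2_loocv)) {
    cat(sprintf("  LOOCV: R2 = %.3f, RMSE = %.3f\n",
                x$r2_loocv, x$rmse_loocv))
  }
  if (!is.null(x$importance_pct)) {
    top <- x$importance_pct[order(-x$importance_pct$importance_pct), ][1, ]
    cat(sprintf("  top importance: %s (%.2f%%)\n",
                top$predictor, top$importance_pct))
  }
  invisible(x)
}

#' Tidy the LAI model coefficients
#'
#' @param x A `lai_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, and (when importances were computed) `importance_pct`.
#' @export
tidy.lai_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
  if (!is.null(x$importance_pct)) {
    imp <- x$importance_pct
    out$importance_pct <- imp$importance_pct[match(out$term, imp$predictor)]
  }
  out
}

#' One-row summary of the LAI model fit
#'
#' @param x A `lai_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `r2_fit`, `rmse_fit`, `r2_loocv`,
#'   `rmse_loocv`.
#' @export
glance.lai_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = length(x$predictor_names),
    r2_fit = x$r2_fit, rmse_fit = x$rmse_fit,
    r2_loocv = x$r2_loocv, rmse_loocv = x$rmse_loocv
  )
}

#' Predict a wall-to-wall LAI map from a fitted model
#'
#' Per-pixel linear combination of the predictor layers; negative
#' predictions are clamped to zero (LAI is non-negative by definition) and
#' NoData in any predictor propagates.
#'
#' @param model A `lai_model`.
#' @param stack A [band_stack()].
#' @param chm Canopy-height [mf_grid()].
#' @return LAI [mf_grid()] (m2 m-2).
#' @export
predict_lai_map <- function(model, stack, chm) {
  layers <- predictor_layers(stack, chm)
  miss <- setdiff(model$predictor_names, names(layers))
  if (length(miss)) {
    stop("missing predictor layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pred <- matrix(model$coefficients[["(Intercept)"]],
                 nrow = dim(layers[[1]]$values)[1],
                 ncol = dim(layers[[1]]$values)[2])
  for (nm in model$predictor_names) {
    pred <- pred + model$coefficients[[nm]] * layers[[nm]]$values
  }
  pred <- pmax(pred, 0)
  mf_grid(pred, stack$origin, stack$pixel_size, stack$crs)
}

#' Serialize / restore a fitted LAI model as JSON
#'
#' Stores names, coefficients, fit and cross-validation statistics,
#' importances and sample size; enough to predict and report, not the raw
#' training data.
#'
#' @param model A `lai_model`.
#' @param path JSON path.
#' @return `write_lai_model()` the path, invisibly; `read_lai_model()` a
#'   reduced `lai_model` usable by [predict_lai_map()].
#' @export
write_lai_model <- function(model, path) {
  obj <- list(
    predictor_names = model$predictor_names,
    coefficients = as.list(model$coefficients),
    n = model$n,
    r2_fit = model$r2_fit, rmse_fit = model$rmse_fit,
    r2_loocv = model$r2_loocv, rmse_loocv = model$rmse_loocv,
    importance_pct = model$importance_pct,
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("mangroveflux"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lai_model
#' @export
read_lai_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(fit = NULL,
         predictor_names = x$predictor_names,
         response = "lai_mean",
         coefficients = unlist(x$coefficients),
         n = x$n,
         r2_fit = x$r2_fit, rmse_fit = x$rmse_fit,
         r2_loocv = x$r2_loocv, rmse_loocv = x$rmse_loocv,
         importance_pct = if (!is.null(x$importance_pct))
           tibble::as_tibble(x$importance_pct),
         data = NULL),
    class = "lai_model"
  )
}
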