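# Shared fixtures and independent oracles for the test suite.

# Band stack with constant reflectance per band.
const_stack <- function(b475 = 0.05, b560 = 0.08, b668 = 0.1, b717 = 0.3,
                        b842 = 0.5, nrow = 4, ncol = 4, pixel_size = 1) {
  vals <- list(`475` = b475, `560` = b560, `668` = b668, `717` = b717,
               `842` = b842)
  band_stack(lapply(vals, function(v) matrix(v, nrow, ncol)),
             origin = c(0, nrow * pixel_size), pixel_size = pixel_size)
}

# Random band stack with reflectances in (0, 1).
random_stack <- function(nrow = 6, ncol = 6) {
  bands <- lapply(stats::setNames(1:5, c("475", "560", "668", "717", "842")),
                  function(i) matrix(stats::runif(nrow * ncol, 0.01, 0.9),
                                     nrow, ncol))
  band_stack(bands, origin = c(0, nrow), pixel_size = 1)
}

# Minimal model object for predict_lai_map: named coefficients only.
stub_model <- function(coefs, intercept = 0) {
  structure(
    list(coefficients = c(`(Intercept)` = intercept, coefs),
         predictor_names = names(coefs),
         response = "lai_mean"),
    class = "lai_model"
  )
}

# Independent R^2 oracle through lm on a plain data.frame.
r2_lm <- function(X, y) {
  if (is.null(dim(X)) || ncol(as.matrix(X)) == 0) return(0)
  df <- data.frame(as.matrix(X), y = y)
  summary(stats::lm(y ~ ., data = df))$r.squared
}

# All permutations of 1..p (p small).
all_perms <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (i in seq_len(p)) {
    for (rest in all_perms(p - 1L)) {
      tail <- setdiff(seq_len(p), i)[rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

# Brute-force LMG oracle: average R^2 increments over every ordering.
brute_lmg <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  shares <- numeric(p)
  perms <- all_perms(p)
  for (ord in perms) {
    prev <- 0
    for (pos in seq_len(p)) {
      cur <- r2_lm(X[, ord[seq_len(pos)], drop = FALSE], y)
      shares[ord[pos]] <- shares[ord[pos]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(perms)
}

# Explicit leave-one-out refits through lm, the definitional oracle.
explicit_loocv <- function(table, predictors, response = "lai_mean") {
  n <- nrow(table)
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = response)
  errs <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(fml, data = as.data.frame(table[-i, ]))
    table[[response]][i] -
      stats::predict(fit, newdata = as.data.frame(table[i, ]))
  }, numeric(1))
  y <- table[[response]]
  list(r2_loocv = 1 - sum(errs^2) / sum((y - mean(y))^2),
       rmse_loocv = sqrt(mean(errs^2)))
}

# Small scene for pipeline-level tests: quick to generate, still big
# enough to hold a 13-predictor fit on 30 plots.
small_scene_config <- function(seed = 11, ...) {
  scene_config(seed = seed, rows = 240, cols = 240, n_patches = 6,
               patch_radius_m = 30, n_plots = 30, ...)
}
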