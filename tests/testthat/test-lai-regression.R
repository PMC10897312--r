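test_that("OLS reproduces hand-solved single-predictor fits", {
  # exact line: intercept 1, slope 2, R^2 = 1
  t1 <- tibble::tibble(NDVI = c(0, 1, 2), lai_mean = c(1, 3, 5))
  m1 <- fit_ols(t1, "NDVI")
  expect_equal(unname(m1$coefficients), c(1, 2))
  expect_equal(m1$r2_fit, 1)
  expect_equal(m1$rmse_fit, 0)

  # hand normal-equations solve: slope 3/2, intercept -1/6, R^2 = 27/28
  t2 <- tibble::tibble(NDVI = c(0, 1, 2), lai_mean = c(0, 1, 3))
  m2 <- fit_ols(t2, "NDVI")
  expect_equal(unname(m2$coefficients), c(-1 / 6, 3 / 2))
  expect_equal(m2$r2_fit, 27 / 28)
  expect_equal(m2$r2_fit, 0.964286, tolerance = 1e-6)
  expect_equal(m2$rmse_fit, sqrt((1 / 6) / 3))  # RMSE on the 1/n convention

  # degenerate designs are rejected with names
  t3 <- tibble::tibble(NDVI = c(0, 1, 2, 3), CHM = 2,
                       lai_mean = c(0, 1, 3, 4))
  expect_error(fit_ols(t3, c("NDVI", "CHM")), "rank deficient.*CHM")
  expect_error(fit_ols(t2[1:2, ], "NDVI"), "rows")
})

test_that("OLS matches an independent normal-equations oracle", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(15:40, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    tab <- tibble::as_tibble(as.data.frame(X))
    tab$lai_mean <- y
    m <- fit_ols(tab, colnames(X))
    Xd <- cbind(1, X)
    beta <- solve(crossprod(Xd), crossprod(Xd, y))
    expect_equal(unname(m$coefficients), unname(drop(beta)), tolerance = 1e-8)
  }
})

test_that("LOOCV reproduces hand-computed two-point refits", {
  t2 <- tibble::tibble(NDVI = c(0, 1, 2), lai_mean = c(0, 1, 3))
  cv <- loocv(t2, "NDVI")
  # held-out errors 1, -1/2, 1 from the three explicit refits
  expect_equal(cv$rmse_loocv, sqrt(2.25 / 3))
  expect_equal(cv$rmse_loocv, 0.866025, tolerance = 1e-6)
  expect_equal(cv$r2_loocv, 1 - 2.25 / (14 / 3))
  expect_equal(cv$r2_loocv, 0.517857, tolerance = 1e-6)

  # perfectly collinear response: every fold reproduces the line
  t0 <- tibble::tibble(NDVI = 0:3, lai_mean = 2 * (0:3))
  cv0 <- loocv(t0, "NDVI")
  expect_equal(cv0$rmse_loocv, 0)
  expect_equal(cv0$r2_loocv, 1)

  # permutation invariance
  set.seed(5)
  tp <- tibble::tibble(NDVI = rnorm(12), CHM = rnorm(12),
                       lai_mean = rnorm(12))
  cv_a <- loocv(tp, c("NDVI", "CHM"))
  cv_b <- loocv(tp[sample(12), ], c("NDVI", "CHM"))
  expect_equal(cv_a, cv_b)
})

test_that("hat-matrix LOOCV equals explicit refits on random designs", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(12:30, 1); p <- sample(2:4, 1)
    tab <- tibble::as_tibble(
      stats::setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                      paste0("v", 1:p)))
    tab$lai_mean <- rnorm(n)
    got <- loocv(tab, paste0("v", 1:p))
    want <- explicit_loocv(tab, paste0("v", 1:p))
    expect_equal(got$rmse_loocv, want$rmse_loocv, tolerance = 1e-10)
    expect_equal(got$r2_loocv, want$r2_loocv, tolerance = 1e-10)
  }
})

test_that("LMG importance matches closed-form and brute-force oracles", {
  # single predictor takes the whole share
  t1 <- tibble::tibble(NDVI = c(0, 1, 2, 4), lai_mean = c(0.1, 1, 2.2, 4))
  imp1 <- lmg_importance(t1, "NDVI")
  expect_equal(imp1$importance_pct, 100)

  # orthogonal design with y = 2 x1 + x2: marginal R^2 0.8 and 0.2
  t2 <- tibble::tibble(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1))
  t2$lai_mean <- 2 * t2$x1 + t2$x2
  imp2 <- lmg_importance(t2, c("x1", "x2"))
  expect_equal(imp2$importance_pct, c(80, 20))
  expect_equal(imp2$lmg_r2, c(0.8, 0.2))

  # subset enumeration equals averaging over all p! orderings
  set.seed(404)
  for (p in 2:5) {
    n <- 25
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + 0.5 * X[, 2]  # induce correlation
    colnames(X) <- paste0("v", 1:p)
    y <- X %*% rnorm(p) + rnorm(n)
    tab <- tibble::as_tibble(as.data.frame(X)); tab$lai_mean <- drop(y)
    got <- lmg_importance(tab, colnames(X))
    want <- brute_lmg(X, drop(y))
    expect_equal(got$lmg_r2, want, tolerance = 1e-10)
    expect_equal(sum(got$importance_pct), 100, tolerance = 1e-9)
    expect_true(all(got$lmg_r2 >= -1e-12))
  }
})

test_that("LMG shares are invariant to positive rescaling of predictors", {
  set.seed(505)
  n <- 30
  tab <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$lai_mean <- tab$a + 2 * tab$b - tab$c + rnorm(n, 0, 0.5)
  base <- lmg_importance(tab, c("a", "b", "c"))
  tab2 <- dplyr::mutate(tab, a = a * 1000, c = c * 0.003)
  scaled <- lmg_importance(tab2, c("a", "b", "c"))
  expect_equal(scaled$importance_pct, base$importance_pct,
               tolerance = 1e-8)
})

test_that("full fit bundles OLS, LOOCV and importances coherently", {
  scene <- generate_scene(small_scene_config(seed = 21))
  plots <- sample_plots(scene)
  tab <- predictor_table(scene$stack, compute_chm(scene$dsm, scene$dtm),
                         plots)
  m <- fit_lai_model(tab)
  g <- glance(m)
  expect_equal(g$p, 13)
  expect_equal(g$n, nrow(tab))
  expect_lte(g$r2_loocv, g$r2_fit)
  expect_gte(g$rmse_loocv, g$rmse_fit)
  expect_equal(sum(m$importance_pct$importance_pct), 100,
               tolerance = 1e-9)
  td <- tidy(m)
  expect_equal(nrow(td), 14)  # intercept + 13 predictors
  expect_true(all(c("estimate", "std.error", "importance_pct") %in%
                    names(td)))

  # JSON round trip preserves what prediction needs
  path <- withr::local_tempfile(fileext = ".json")
  write_lai_model(m, path)
  m2 <- read_lai_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$r2_loocv, m$r2_loocv)
})

test_that("LAI map prediction combines layers, clamps and propagates NA", {
  s <- const_stack(b842 = 0.5, b668 = 0.1, nrow = 3, ncol = 3)
  chm <- mf_grid(matrix(1, 3, 3), origin = c(0, 3), pixel_size = 1)

  flat <- stub_model(c(NDVI = 0), intercept = 1.5)
  expect_equal(predict_lai_map(flat, s, chm)$values, matrix(1.5, 3, 3))

  ndvi_only <- stub_model(c(NDVI = 5))
  got <- predict_lai_map(ndvi_only, s, chm)$values
  expect_equal(got[2, 2], 5 * (0.4 / 0.6), tolerance = 1e-12)
  expect_equal(got[2, 2], 3.333333, tolerance = 1e-6)

  neg <- stub_model(c(NDVI = 0.3), intercept = -0.4)  # raw -0.2
  expect_equal(predict_lai_map(neg, s, chm)$values, matrix(0, 3, 3))

  s_na <- s; s_na$bands[["668"]][1, 1] <- NA
  expect_true(is.na(predict_lai_map(ndvi_only, s_na, chm)$values[1, 1]))

  bad <- stub_model(c(SAVI = 1))
  expect_error(predict_lai_map(bad, s, chm), "missing predictor")
})
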