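test_that("density transform and its inverse round-trip", {
  expect_equal(transform_density(0), 0)
  expect_equal(transform_density(exp(1) - 1), 1)
  expect_equal(transform_density(9, base = 10), 1)
  set.seed(3)
  x <- runif(50, 0, 100)
  expect_equal(inverse_density(transform_density(x)), x, tolerance = 1e-12)
  expect_error(transform_density(-1), ">= 0")
})

test_that("pseudo-R2 equals 1 - oob MSE over population variance", {
  y <- c(0, 1, 2)
  expect_equal(pseudo_r2(y, y), 1)
  expect_equal(pseudo_r2(rep(mean(y), 3), y), 0)
  expect_equal(pseudo_r2(c(0, 1, 1), y), 0.5)   # 1 - (1/3)/(2/3)
  expect_error(pseudo_r2(c(1, 1), c(2, 2)), "variance")
  expect_error(pseudo_r2(1, c(1, 2)), "lengths")
})

test_that("forest fits are reproducible under a master seed", {
  d <- make_forest_table(n = 40, seed = 5)
  f1 <- grow_forest(d, "response", paste0("x", 1:4), mtry = 2, ntree = 50, seed = 9)
  f2 <- grow_forest(d, "response", paste0("x", 1:4), mtry = 2, ntree = 50, seed = 9)
  expect_identical(f1$oob_pred, f2$oob_pred)
  expect_identical(f1$inbag, f2$inbag)
  f3 <- grow_forest(d, "response", paste0("x", 1:4), mtry = 2, ntree = 50, seed = 10)
  expect_false(identical(f1$oob_pred, f3$oob_pred))
})

test_that("tuning selects the minimal mean oob cell with deterministic ties", {
  d <- make_forest_table(n = 40, seed = 2)
  tn <- tune_forest(d, "response", paste0("x", 1:4), mtry_values = 2,
                    ntree_values = 60, reseeds = 2, seed = 4)
  expect_equal(tn$selected$mtry, 2)
  expect_equal(tn$selected$ntree, 60)
  expect_equal(nrow(tn$surface), 2)
  expect_equal(tn$selected$oob_mse, mean(tn$surface$oob_mse))

  tn2 <- tune_forest(d, "response", paste0("x", 1:4), mtry_values = c(1, 3),
                     ntree_values = c(50, 100), reseeds = 2, seed = 4)
  expect_equal(tn2$selected$oob_mse, min(tn2$summary$oob_mse))
  # reproducibility of the whole surface
  tn3 <- tune_forest(d, "response", paste0("x", 1:4), mtry_values = c(1, 3),
                     ntree_values = c(50, 100), reseeds = 2, seed = 4)
  expect_identical(tn2$surface, tn3$surface)
  # over-large mtry clipped with warning
  expect_warning(tune_forest(d, "response", "x1", mtry_values = 1:3,
                             ntree_values = 30, reseeds = 1, seed = 1),
                 "clipped")
})

test_that("null tuning lands near the response variance", {
  d <- make_forest_table(n = 120, p = 3, seed = 8, signal = FALSE)
  tn <- tune_forest(d, "response", paste0("x", 1:3), mtry_values = c(1, 2),
                    ntree_values = 100, reseeds = 3, seed = 3)
  # pure noise: best achievable oob MSE is the response variance (within MC
  # spread)
  v <- var(d$response)
  expect_lt(abs(tn$selected$oob_mse - v), 2 * v / sqrt(50))
})

test_that("group bootstrap keeps groups together and reduces to row bootstrap", {
  d <- make_forest_table(n = 24, seed = 6)
  g <- rep(1:2, each = 12)
  f <- fit_repeated_measures_forest(d, "response", paste0("x", 1:4),
                                    mtry = 2, ntree = 40, seed = 3, groups = g)
  # audit: within a tree, all rows of one group have the same inbag count,
  # counts across groups sum to the number of group draws
  for (t in seq_len(40)) {
    cnt <- f$inbag[, t]
    expect_length(unique(cnt[g == 1]), 1)
    expect_length(unique(cnt[g == 2]), 1)
    expect_equal(cnt[1] + cnt[13], 2)    # 2 groups drawn with replacement
  }
  # every-row-its-own-group equals the default forest under the same seed
  f1 <- fit_repeated_measures_forest(d, "response", paste0("x", 1:4),
                                     mtry = 2, ntree = 40, seed = 3,
                                     groups = seq_len(24))
  f2 <- grow_forest(d, "response", paste0("x", 1:4), mtry = 2, ntree = 40, seed = 3)
  expect_identical(f1$oob_pred, f2$oob_pred)
  expect_error(fit_repeated_measures_forest(d, "response", "x1", 1, 10,
                                            groups = rep(1, 24)),
               "at least 2 groups")
  expect_error(fit_repeated_measures_forest(d, "response", "x1", 1, 10),
               "requires a grouping")
})

test_that("group-level oob error exceeds row-level error under group effects", {
  # strong group effects make rows within a group informative about each
  # other; holding out whole groups removes that leakage, so the honest
  # (group) oob error is larger on average
  set.seed(20)
  diffs <- replicate(10, {
    n <- 80; ngr <- 8
    g <- rep(seq_len(ngr), each = n / ngr)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$response <- rnorm(ngr, 0, 2)[g] + 0.3 * d$x1 + rnorm(n, 0, 0.2)
    sd <- sample.int(1e6, 1)
    fg <- grow_forest(d, "response", c("x1", "x2"), mtry = 1, ntree = 80,
                      seed = sd, groups = g)
    fr <- grow_forest(d, "response", c("x1", "x2"), mtry = 1, ntree = 80,
                      seed = sd)
    fg$oob_mse - fr$oob_mse
  })
  expect_gt(mean(diffs), 0)
})

test_that("permutation importance finds planted signal and ignores noise", {
  d <- make_forest_table(n = 80, p = 4, seed = 12, signal = TRUE)
  f <- grow_forest(d, "response", paste0("x", 1:4), mtry = 2, ntree = 150, seed = 2)
  imp <- importance_pct_inc_mse(f, seed = 5)
  expect_equal(sort(imp$rank), 1:4)
  expect_equal(imp$predictor[1], "x1")
  expect_gt(imp$pct_inc_mse[1], imp$pct_inc_mse[2] * 2)

  # column order of the input table does not change the values
  d2 <- d[, c("x3", "x1", "x4", "x2", "response")]
  f2 <- grow_forest(d2, "response", paste0("x", 1:4), mtry = 2, ntree = 150, seed = 2)
  imp2 <- importance_pct_inc_mse(f2, seed = 5)
  expect_equal(imp2$predictor[1], "x1")
  expect_error(importance_pct_inc_mse(f, nperm = 0), "nperm")
})

test_that("importance of a predictor unrelated to the response sits near zero", {
  set.seed(31)
  vals <- replicate(12, {
    d <- make_forest_table(n = 60, p = 3, seed = sample.int(1e6, 1),
                           signal = FALSE)
    f <- grow_forest(d, "response", paste0("x", 1:3), mtry = 1, ntree = 100,
                     seed = sample.int(1e6, 1))
    importance_pct_inc_mse(f, seed = 1)$pct_inc_mse
  })
  # null importances scatter around zero rather than being systematically high
  expect_lt(abs(mean(vals)), 1)
})

test_that("partial dependence equals the brute-force definition", {
  d <- make_forest_table(n = 25, p = 3, seed = 9)
  f <- grow_forest(d, "response", paste0("x", 1:3), mtry = 2, ntree = 60, seed = 7)
  grid <- seq(-2, 2, length.out = 7)
  pd <- partial_dependence(f, "x1", grid = grid)
  expect_equal(pd$yhat, oracle_partial_dependence(f, "x1", grid),
               tolerance = 1e-12)
  expect_error(partial_dependence(f, "nope"), "unknown predictor")
  expect_error(partial_dependence(f, "x1", grid = numeric(0)), "empty")

  # constant response gives a flat curve at the constant
  dc <- d; dc$response <- 3.5
  fc <- grow_forest(dc, "response", paste0("x", 1:3), mtry = 1, ntree = 30, seed = 1)
  pdc <- partial_dependence(fc, "x1", grid = grid)
  expect_equal(pdc$yhat, rep(3.5, 7))

  # single-row table: curve equals that row's prediction swept over the grid
  d1 <- d[1, ]
  pd1 <- vapply(grid, function(v) {
    row <- f$x[1, , drop = FALSE]; row$x1 <- v
    predict(f$fit, row, num.threads = 1)$predictions
  }, numeric(1))
  f1 <- f; f1$x <- f$x[1, , drop = FALSE]
  expect_equal(partial_dependence(f1, "x1", grid = grid)$yhat, pd1)
})

test_that("suitability windows are read off curves correctly", {
  # triangular curve peaking mid-domain: half-height window is symmetric
  curve <- structure(data.frame(value = 0:10,
                                yhat = c(0:5, 4:0)),
                     class = c("pd_curve", "data.frame"))
  w <- suitability_window(curve, fraction = 0.5)
  expect_equal(mean(w), 5)
  expect_equal(w, c(3, 7))
  # monotone curve abuts the domain edge
  mono <- structure(data.frame(value = 0:10, yhat = 0:10),
                    class = c("pd_curve", "data.frame"))
  expect_equal(suitability_window(mono)[2], 10)
  # flat curve warns and returns the whole domain
  flat <- structure(data.frame(value = 0:10, yhat = rep(1, 11)),
                    class = c("pd_curve", "data.frame"))
  expect_warning(wf <- suitability_window(flat), "flat")
  expect_equal(wf, c(0, 10))
  expect_error(suitability_window(curve, fraction = 1.5), "fraction")
})
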