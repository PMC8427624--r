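#' Density transform
#'
#' `log(x + 1)` transform applied to raw mussel densities before modelling,
#' focusing model fit on the ecologically informative lower range of counts.
#' Natural log by default; `base = 10` available.
#'
#' @param x raw densities, nonnegative.
#' @param base logarithm base.
#' @return transformed values; [inverse_density()] undoes the transform.
#' @export
transform_density <- function(x, base = exp(1)) {
  if (any(!is.finite(x)) || any(x < 0)) stop_invalid("densities must be >= 0")
  log(x + 1, base = base)
}

#' @rdname transform_density
#' @param y transformed values.
#' @export
inverse_density <- function(y, base = exp(1)) base^y - 1

#' Out-of-bag variance explained
#'
#' `pseudo_R2 = 1 - MSE_oob / Var(y)` with the population variance
#' (denominator n). May be negative when the model is worse than the mean.
#'
#' @param pred out-of-bag predictions (NAs allowed; those rows are skipped).
#' @param y response, same length.
#' @return variance explained on the unit scale (multiply by 100 for percent).
#' @export
pseudo_r2 <- function(pred, y) {
  if (length(pred) != length(y)) stop_invalid("lengths differ")
  v <- mean((y - mean(y))^2)
  if (v == 0) stop_invalid("response variance is zero; pseudo-R2 undefined")
  ok <- is.finite(pred)
  1 - mean((pred[ok] - y[ok])^2) / v
}

# Group-bootstrap in-bag counts: one integer vector per tree, length n.
# Groups are resampled with replacement; every row of a sampled group enters
# the tree once per draw of its group. With each row its own group this is the
# ordinary row bootstrap.
make_inbag <- function(groups, ntree) {
  g <- as.integer(factor(groups))
  ng <- max(g)
  if (ng < 2) stop_invalid("need at least 2 groups for the bootstrap")
  lapply(seq_len(ntree), function(t) {
    draws <- tabulate(sample.int(ng, ng, replace = TRUE), ng)
    draws[g]
  })
}

#' Fit a regression forest with explicit out-of-bag bookkeeping
#'
#' Grows a random forest for the (transformed) density response with a
#' bootstrap the package controls: per tree, *groups* of rows are resampled
#' with replacement and every row of a sampled group enters together. With the
#' default grouping (each row its own group) this is the ordinary random
#' forest; with a grouping column it is the repeated-measures variant, where a
#' row is out-of-bag for a tree iff its group was not sampled. Out-of-bag
#' predictions aggregate only over trees for which the row's group is
#' out-of-bag.
#'
#' Tree growing is delegated to \pkg{ranger} (with the in-bag counts supplied
#' per tree); the bootstrap scheme, out-of-bag aggregation, error estimates,
#' permutation importance and partial dependence are implemented in this
#' package.
#'
#' @param data data frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param mtry predictors tried per split.
#' @param ntree number of trees.
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @param groups optional vector (length nrow(data)) of group labels for the
#'   repeated-measures bootstrap, or a column name in `data`.
#' @return object of class `mussel_forest` with elements `fit` (the ranger
#'   object), `inbag` (n x ntree count matrix), `oob_pred`, `oob_mse`,
#'   `pseudo_r2`, `n_oob_none` (rows never out-of-bag), and the call settings.
#' @export
grow_forest <- function(data, response, predictors, mtry = max(1, floor(length(predictors) / 3)),
                        ntree = 500, seed = 1, groups = NULL) {
  if (!response %in% names(data)) stop_invalid("response column not found")
  if (!all(predictors %in% names(data))) stop_invalid("predictor column(s) not found")
  if (any(!is.finite(data[[response]]))) stop_invalid("missing response values")
  if (length(groups) == 1 && is.character(groups) && groups %in% names(data))
    groups <- data[[groups]]
  n <- nrow(data)
  if (is.null(groups)) groups <- seq_len(n)
  if (length(groups) != n) stop_invalid("groups must label every row")
  mtry <- min(mtry, length(predictors))
  set.seed(derive_seed(seed, "inbag"))
  inbag <- make_inbag(groups, ntree)
  x <- data[, predictors, drop = FALSE]
  y <- data[[response]]
  fit <- ranger::ranger(x = x, y = y, num.trees = ntree, mtry = mtry,
                        inbag = inbag, seed = derive_seed(seed, "ranger"),
                        num.threads = 1, oob.error = FALSE)
  ib <- matrix(unlist(inbag), nrow = n)
  pred_all <- predict(fit, x, predict.all = TRUE, num.threads = 1)$predictions
  oob <- ib == 0
  n_oob_trees <- rowSums(oob)
  oob_pred <- ifelse(n_oob_trees > 0, rowSums(pred_all * oob) / n_oob_trees, NA_real_)
  ok <- n_oob_trees > 0
  structure(list(fit = fit, data = data, x = x, y = y,
                 response = response, predictors = predictors,
                 mtry = mtry, ntree = ntree, seed = seed, groups = groups,
                 inbag = ib, oob = oob, pred_all = pred_all,
                 oob_pred = oob_pred,
                 oob_mse = mean((oob_pred[ok] - y[ok])^2),
                 pseudo_r2 = if (var(y) > 0) pseudo_r2(oob_pred, y) else NA_real_,
                 n_oob_none = sum(!ok)),
            class = "mussel_forest")
}

#' @export
print.mussel_forest <- function(x, ...) {
  cat("Random forest (", x$ntree, " trees, mtry = ", x$mtry, ")\n", sep = "")
  cat("  n = ", length(x$y), ", predictors = ", length(x$predictors), "\n", sep = "")
  cat("  oob MSE = ", signif(x$oob_mse, 4),
      ", pseudo-R2 = ", signif(100 * x$pseudo_r2, 4), "%\n", sep = "")
  invisible(x)
}

#' Repeated-measures random forest
#'
#' Convenience wrapper around [grow_forest()] that requires a grouping
#' variable (the random-effect unit): per-tree bootstrap samples are drawn at
#' the group level so that non-independent rows enter or leave a tree
#' together.
#'
#' @inheritParams grow_forest
#' @export
fit_repeated_measures_forest <- function(data, response, predictors, mtry, ntree,
                                         seed = 1, groups) {
  if (missing(groups) || is.null(groups))
    stop_invalid("repeated-measures forest requires a grouping variable")
  grow_forest(data, response, predictors, mtry = mtry, ntree = ntree,
              seed = seed, groups = groups)
}

#' Out-of-bag tuning over an mtry/ntree grid
#'
#' Fits a forest for every (mtry, ntree) cell, rerunning each cell `reseeds`
#' times under derived seeds, and records the out-of-bag MSE. The selected
#' cell minimizes the mean oob MSE across reseeds; ties are broken by the
#' smaller mtry, then the smaller ntree. Fully reproducible under the master
#' seed.
#'
#' @inheritParams grow_forest
#' @param mtry_values candidate mtry values (clipped to the number of
#'   predictors, with a warning, if needed).
#' @param ntree_values candidate tree counts.
#' @param reseeds forests grown per cell under different derived seeds.
#' @return list with `surface` (one row per cell x reseed), `summary` (mean
#'   oob MSE per cell), and `selected` (mtry, ntree, mean oob MSE).
#' @export
tune_forest <- function(data, response, predictors,
                        mtry_values = seq_along(predictors),
                        ntree_values = c(200, 300, 400, 500, 600, 800, 1000),
                        reseeds = 5, seed = 1, groups = NULL) {
  p <- length(predictors)
  if (any(mtry_values > p)) {
    warning("mtry values above the predictor count were clipped", call. = FALSE)
    mtry_values <- unique(pmin(mtry_values, p))
  }
  if (reseeds < 1) stop_invalid("reseeds must be >= 1")
  grid <- expand.grid(mtry = mtry_values, ntree = ntree_values,
                      reseed = seq_len(reseeds))
  grid$oob_mse <- vapply(seq_len(nrow(grid)), function(i) {
    cell_seed <- derive_seed(seed, "tune",
                             grid$mtry[i] * 1e6 + grid$ntree[i] * 10 + grid$reseed[i])
    grow_forest(data, response, predictors, mtry = grid$mtry[i],
                ntree = grid$ntree[i], seed = cell_seed, groups = groups)$oob_mse
  }, numeric(1))
  agg <- aggregate(oob_mse ~ mtry + ntree, data = grid, FUN = mean)
  agg <- agg[order(agg$oob_mse, agg$mtry, agg$ntree), ]
  sel <- agg[1, ]
  list(surface = grid, summary = agg,
       selected = list(mtry = sel$mtry, ntree = sel$ntree, oob_mse = sel$oob_mse))
}

#' Permutation importance (%IncMSE)
#'
#' For each predictor: its values are permuted within each tree's out-of-bag
#' rows, the tree's out-of-bag MSE is recomputed, and the per-tree increase
#' over the unpermuted out-of-bag MSE is recorded. The reported `%IncMSE` is
#' the mean per-tree increase divided by its standard error across trees (the
#' classic randomForest scaling); the raw mean increase is also reported.
#' Ranks are descending in `%IncMSE`.
#'
#' @param forest a [grow_forest()] fit.
#' @param nperm permutation rounds per tree (averaged).
#' @param seed integer seed for the permutations.
#' @return data frame with columns `predictor`, `pct_inc_mse`, `raw_inc_mse`,
#'   `rank`, ordered by rank.
#' @export
importance_pct_inc_mse <- function(forest, nperm = 1, seed = 1) {
  stopifnot(inherits(forest, "mussel_forest"))
  if (nperm < 1) stop_invalid("nperm must be >= 1")
  ntree <- forest$ntree
  oob_idx <- lapply(seq_len(ntree), function(t) which(forest$oob[, t]))
  use_tree <- which(lengths(oob_idx) >= 2)
  trees <- extract_trees(forest$fit, use_tree)
  xmat <- as.matrix(forest$x)
  # per-tree baseline oob MSE
  mse0 <- vapply(seq_along(use_tree), function(k) {
    idx <- oob_idx[[use_tree[k]]]
    mean((forest$pred_all[idx, use_tree[k]] - forest$y[idx])^2)
  }, numeric(1))
  res <- lapply(seq_along(forest$predictors), function(j) {
    pj <- forest$predictors[j]
    set.seed(derive_seed(seed, paste0("perm-", pj)))
    delta <- matrix(NA_real_, length(use_tree), nperm)
    for (r in seq_len(nperm)) {
      for (k in seq_along(use_tree)) {
        idx <- oob_idx[[use_tree[k]]]
        xp <- xmat[idx, , drop = FALSE]
        xp[, j] <- sample(xp[, j])          # permute within the tree's oob rows
        tr <- trees[[k]]
        pred <- tree_traverse(tr$left, tr$right, tr$splitvar, tr$splitval,
                              tr$value, xp)
        delta[k, r] <- mean((pred - forest$y[idx])^2) - mse0[k]
      }
    }
    dbar <- rowMeans(delta)
    se <- sd(dbar) / sqrt(length(dbar))
    data.frame(predictor = pj,
               pct_inc_mse = if (se > 0) mean(dbar) / se else 0,
               raw_inc_mse = mean(dbar))
  })
  out <- do.call(rbind, res)
  out$rank <- rank(-out$pct_inc_mse, ties.method = "first")
  out[order(out$rank), ]
}

# flatten ranger trees (treeInfo layout) into traversal arrays; splitvar ids
# are 0-based column positions in the model matrix
extract_trees <- function(fit, which_trees) {
  lapply(which_trees, function(t) {
    ti <- ranger::treeInfo(fit, t)
    list(left = as.integer(ti$leftChild),
         right = as.integer(ti$rightChild),
         splitvar = ifelse(is.na(ti$splitvarID), -1L, as.integer(ti$splitvarID)),
         splitval = ifelse(is.na(ti$splitval), 0, as.numeric(ti$splitval)),
         value = as.numeric(ti$prediction))
  })
}

#' Reseed-averaged permutation importance
#'
#' Grows `reseeds` forests under derived seeds at fixed (mtry, ntree) and
#' averages the per-forest `%IncMSE` per predictor — the protocol of rerunning
#' each model several times under different random seeds before reading the
#' importance ranking.
#'
#' @inheritParams grow_forest
#' @param reseeds number of reseeded forests (default 5).
#' @return data frame `predictor`, `pct_inc_mse` (mean across reseeds),
#'   `rank`, ordered by rank; the last fitted forest is attached as attribute
#'   `forest`.
#' @export
importance_reseeded <- function(data, response, predictors, mtry, ntree,
                                seed = 1, reseeds = 5, groups = NULL) {
  stopifnot(reseeds >= 1)
  acc <- NULL
  f <- NULL
  for (r in seq_len(reseeds)) {
    f <- grow_forest(data, response, predictors, mtry = mtry, ntree = ntree,
                     seed = derive_seed(seed, "reseed", r), groups = groups)
    imp <- importance_pct_inc_mse(f, seed = derive_seed(seed, "reseed-imp", r))
    imp <- imp[order(imp$predictor), ]
    acc <- if (is.null(acc)) imp$pct_inc_mse else acc + imp$pct_inc_mse
  }
  out <- data.frame(predictor = sort(predictors), pct_inc_mse = acc / reseeds)
  out$rank <- rank(-out$pct_inc_mse, ties.method = "first")
  out <- out[order(out$rank), ]
  attr(out, "forest") <- f
  out
}

#' Partial dependence of the forest prediction on one predictor
#'
#' For each grid value v, the predictor is set to v for *all* rows and the
#' ensemble prediction is averaged over rows — the brute-force definition,
#' computed exactly.
#'
#' @param forest a [grow_forest()] fit.
#' @param predictor predictor name.
#' @param grid numeric grid; default is `ngrid` equally spaced values across
#'   the observed range.
#' @param ngrid grid size when `grid` is NULL.
#' @return data frame of class `pd_curve` with columns `value`, `yhat`.
#' @export
partial_dependence <- function(forest, predictor, grid = NULL, ngrid = 25) {
  stopifnot(inherits(forest, "mussel_forest"))
  if (!predictor %in% forest$predictors) stop_invalid("unknown predictor")
  if (is.null(grid)) {
    r <- range(forest$x[[predictor]])
    grid <- seq(r[1], r[2], length.out = ngrid)
  }
  if (length(grid) == 0) stop_invalid("empty partial-dependence grid")
  yhat <- vapply(grid, function(v) {
    xv <- forest$x
    xv[[predictor]] <- v
    mean(predict(forest$fit, xv, num.threads = 1)$predictions)
  }, numeric(1))
  structure(data.frame(value = grid, yhat = yhat),
            class = c("pd_curve", "data.frame"))
}

#' Suitability window from a partial-dependence curve
#'
#' Returns the contiguous grid interval, containing the curve maximum, on
#' which the curve stays at or above `min + fraction * (max - min)`. Used to
#' read habitat suitability ranges (e.g. the suitable mean-grain-size window)
#' off partial-dependence curves.
#'
#' @param curve a [partial_dependence()] result.
#' @param fraction height fraction in (0, 1); default 0.5 (half-range).
#' @return numeric `c(lower, upper)` on the predictor scale.
#' @export
suitability_window <- function(curve, fraction = 0.5) {
  if (!nrow(curve)) stop_invalid("empty curve")
  if (fraction <= 0 || fraction >= 1) stop_invalid("fraction must be in (0,1)")
  y <- curve$yhat
  if (diff(range(y)) == 0) {
    warning("flat partial-dependence curve; returning the whole domain",
            call. = FALSE)
    return(range(curve$value))
  }
  thr <- min(y) + fraction * (max(y) - min(y))
  above <- y >= thr
  peak <- which.max(y)
  lo <- peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  c(curve$value[lo], curve$value[hi])
}
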