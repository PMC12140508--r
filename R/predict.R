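#' Fit an elastic-net model of segment RT on chromatin features
#'
#' Columns are centered and scaled (constant columns are zeroed with a
#' warning), then an elastic net is fit over a grid of mixing parameters
#' (0, 0.1, ..., 1) crossed with a geometric penalty path, selecting the
#' pair minimizing mean cross-validated RMSE over `repeats` repetitions of
#' `folds`-fold CV with seed-reproducible fold assignments. The final model
#' is refit on all data; weights are reported on the standardized scale
#' (signal per predictor-sd), with unstandardized weights derivable from the
#' stored column sds.
#'
#' @param x Wide feature matrix tibble (`segment_id` plus numeric feature
#'   columns) or a plain numeric matrix.
#' @param y Numeric target per row of `x` (segment RT or delta-RT).
#' @param mixing Grid of elastic-net mixing parameters (1 = lasso,
#'   0 = ridge).
#' @param folds,repeats Cross-validation scheme (default 5 x 5).
#' @param lambda Optional fixed penalty path; default lets glmnet choose.
#' @param seed Seed for fold assignment.
#' @return An object of class `rt_enet_fit` with elements `weights` (tibble
#'   `feature`, `weight`, `weight_unstandardized`), `intercept`, `mixing`,
#'   `lambda`, `cv` (grid of mean RMSE), `predicted`, `observed`,
#'   `spearman`, and the CV scheme record.
#' @export
fit_elastic_net <- function(x, y, mixing = seq(0, 1, by = 0.1),
                            folds = 5, repeats = 5, lambda = NULL, seed = 1) {
  if (is.data.frame(x)) {
    feats <- setdiff(names(x), "segment_id")
    xm <- as.matrix(x[, feats, drop = FALSE])
  } else {
    xm <- as.matrix(x)
    feats <- colnames(xm)
    if (is.null(feats)) feats <- paste0("x", seq_len(ncol(xm)))
  }
  n <- nrow(xm)
  fixed <- length(mixing) == 1 && !is.null(lambda) && length(lambda) == 1
  if (!fixed && n <= folds) abort("need more rows than CV folds")
  if (length(y) != n) abort("x rows and y length differ")
  sds <- apply(xm, 2, sd)
  mus <- colMeans(xm)
  constant <- sds == 0
  if (any(constant)) {
    warn(paste0("constant column(s) zeroed: ",
                paste(feats[constant], collapse = ", ")))
    sds[constant] <- 1
  }
  xs <- sweep(sweep(xm, 2, mus), 2, sds, "/")
  xs[, constant] <- 0
  fold_ids <- with_seed(child_seed(seed, "enet-folds"), {
    lapply(seq_len(repeats), function(r) sample(rep(seq_len(folds), length.out = n)))
  })
  full_paths <- lapply(mixing, function(a) {
    glmnet::glmnet(xs, y, alpha = a, lambda = lambda,
                   standardize = FALSE, nlambda = 50, thresh = 1e-10)
  })
  grid <- if (fixed) {
    tibble::tibble(mixing = mixing, lambda = lambda, rmse = NA_real_)
  } else purrr::map_dfr(seq_along(mixing), function(ai) {
    lam <- full_paths[[ai]]$lambda
    sse <- matrix(0, length(lam), 1)
    for (r in seq_len(repeats)) {
      fid <- fold_ids[[r]]
      for (f in seq_len(folds)) {
        test <- fid == f
        fit <- glmnet::glmnet(xs[!test, , drop = FALSE], y[!test],
                              alpha = mixing[ai], lambda = lam,
                              standardize = FALSE)
        pred <- predict(fit, xs[test, , drop = FALSE], s = lam)
        sse <- sse + colSums((pred - y[test])^2)
      }
    }
    tibble::tibble(mixing = mixing[ai], lambda = lam,
                   rmse = sqrt(sse[, 1] / (n * repeats)))
  })
  best <- if (fixed) grid else grid[which.min(grid$rmse), ]
  final <- glmnet::glmnet(xs, y, alpha = best$mixing, standardize = FALSE,
                          lambda = full_paths[[match(best$mixing, mixing)]]$lambda,
                          thresh = 1e-12)
  beta <- as.numeric(predict(final, type = "coefficients", s = best$lambda))
  names(beta) <- c("(Intercept)", feats)
  pred <- as.numeric(predict(final, xs, s = best$lambda))
  rho <- suppressWarnings(cor(pred, y, method = "spearman"))
  structure(list(
    weights = tibble::tibble(
      feature = feats,
      weight = unname(beta[-1]),
      weight_unstandardized = unname(beta[-1] / sds)
    ),
    intercept = beta[1],
    mixing = best$mixing,
    lambda = best$lambda,
    cv = grid,
    scheme = list(folds = folds, repeats = repeats, seed = seed),
    predicted = pred,
    observed = y,
    spearman = rho,
    column_means = mus,
    column_sds = sds
  ), class = "rt_enet_fit")
}

#' @export
#' @method print rt_enet_fit
print.rt_enet_fit <- function(x, ...) {
  cat("Elastic-net RT model\n")
  cat(sprintf("  mixing = %.2f, lambda = %.5g (CV over %d x %d folds)\n",
              x$mixing, x$lambda, x$scheme$repeats, x$scheme$folds))
  cat(sprintf("  Spearman(predicted, observed) = %.3f\n", x$spearman))
  top <- x$weights[order(-abs(x$weights$weight)), ][1:min(5, nrow(x$weights)), ]
  cat("  top weights:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-10s %+.3f\n", top$feature[i], top$weight[i]))
  }
  invisible(x)
}

#' Tidy the per-feature weights of an elastic-net RT fit
#'
#' @param x An `rt_enet_fit`.
#' @param ... Unused.
#' @return Tibble `feature`, `weight`, `weight_unstandardized`, ordered by
#'   decreasing |weight|.
#' @export
tidy.rt_enet_fit <- function(x, ...) {
  w <- x$weights
  w[order(-abs(w$weight)), ]
}

#' One-row model summary of an elastic-net RT fit
#'
#' @param x An `rt_enet_fit`.
#' @param ... Unused.
#' @return Tibble with `mixing`, `lambda`, `spearman`, `n`, `n_nonzero`.
#' @export
glance.rt_enet_fit <- function(x, ...) {
  tibble::tibble(mixing = x$mixing, lambda = x$lambda,
                 spearman = x$spearman, n = length(x$observed),
                 n_nonzero = sum(x$weights$weight != 0))
}

#' Ordinary least-squares R-squared of y on one predictor
#'
#' @param x Predictor vector.
#' @param y Response vector.
#' @return R-squared with intercept.
#' @examples
#' univariate_r2(c(0, 1, 2), c(0, 1, 1))  # 0.75
#' @export
univariate_r2 <- function(x, y) {
  summary(lm(y ~ x))$r.squared
}

#' R-squared of a two-predictor OLS fit
#'
#' Always at least the better univariate R-squared (up to numerical noise).
#'
#' @param x1,x2 Predictor vectors.
#' @param y Response vector.
#' @return R-squared of `y ~ x1 + x2`.
#' @export
pairwise_r2 <- function(x1, x2, y) {
  summary(lm(y ~ x1 + x2))$r.squared
}

#' Regression of genotype differences in RT change on feature and RNA changes
#'
#' Fits the two-predictor OLS of the genotype difference in delta-RT
#' (mutant-relative-to-control) on the corresponding differences in the
#' coupled chromatin feature and in transcription, over jointly non-missing
#' bins, returning standardized coefficients.
#'
#' @param delta_delta_rt,delta_delta_feature,delta_delta_rna Bin-track
#'   tibbles on the same binning.
#' @return A tibble `term`, `estimate` (standardized), `p`.
#' @export
coupled_change_regression <- function(delta_delta_rt, delta_delta_feature,
                                      delta_delta_rna) {
  assert_same_bins(delta_delta_rt, delta_delta_feature)
  assert_same_bins(delta_delta_rt, delta_delta_rna)
  ok <- !is.na(delta_delta_rt$value) & !is.na(delta_delta_feature$value) &
    !is.na(delta_delta_rna$value)
  f <- delta_delta_feature$value[ok]
  r <- delta_delta_rna$value[ok]
  if (sd(f) == 0 && sd(r) == 0) abort("both predictors are constant")
  d <- data.frame(y = scale(delta_delta_rt$value[ok])[, 1],
                  feature = scale(f)[, 1],
                  rna = scale(r)[, 1])
  fit <- summary(lm(y ~ feature + rna, data = d))
  co <- fit$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 p = unname(co[, 4]))
}
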