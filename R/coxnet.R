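#' Fit a cross-validated Cox elastic-net model
#'
#' Features are standardised to zero mean / unit variance internally (the
#' scaler is stored and reapplied at prediction time), then a penalised Cox
#' model is fit along a lambda path with `glmnet`, mixing parameter `alpha`
#' (0.8 by default: mostly lasso with a ridge stabiliser). The penalty is
#' chosen by `folds`-fold cross-validation maximising the mean CV partial
#' likelihood (equivalently minimising partial-likelihood deviance); the
#' nonzero-coefficient features constitute the model. Alternatively a target
#' support size may be requested, in which case the lambda on the CV path
#' whose support size is closest to the target is used (ties go to the
#' sparser model).
#'
#' @param features data.frame/matrix of numeric features (an `id` column is
#'   dropped; rows must align with `surv`).
#' @param surv a `survival_table` (or data.frame with `time`, `event`).
#' @param alpha elastic-net mixing parameter in (0, 1\].
#' @param folds number of CV folds.
#' @param seed integer seed fixing the fold assignment.
#' @param target_size optional requested number of selected features.
#' @param ln_volumes if `TRUE`, volume-unit features (per the catalogue
#'   dictionary) are ln-transformed before standardisation; zero volumes are
#'   offset by half a voxel-scale epsilon.
#' @return A `cox_model`: `support` (selected names), `beta` (coefficients
#'   on the standardised scale), `center`/`scale`, `alpha`, `lambda`,
#'   `lambda_path`, `cvm`, `foldid`, `seed`, `ln_features`.
#' @export
fit_cox_elasticnet <- function(features, surv, alpha = 0.8, folds = 10,
                               seed = NULL, target_size = NULL,
                               ln_volumes = FALSE) {
  x <- as.data.frame(features)
  x$id <- NULL
  x <- as.matrix(x)
  stopifnot(nrow(x) == nrow(surv))
  if (sum(surv$event) < 2) stop("need at least 2 events to fit a Cox model")
  ln_feats <- character(0)
  if (ln_volumes) {
    dict <- feature_dictionary()
    vol_names <- intersect(dict$name[dict$units == "cm3"], colnames(x))
    for (v in vol_names) x[, v] <- log(pmax(x[, v], 1e-6))
    ln_feats <- vol_names
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
  }
  xs <- scale(x, center = ctr, scale = scl)
  y <- survival::Surv(surv$time, surv$event)
  set_seed_if(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(xs, y, family = "cox", alpha = alpha,
                          foldid = foldid, standardize = FALSE)
  if (is.null(target_size)) {
    lambda <- cv$lambda.min
  } else {
    dfs <- cv$glmnet.fit$df
    best <- which.min(abs(dfs - target_size))  # first index = largest lambda
    lambda <- cv$glmnet.fit$lambda[best]
  }
  cf <- as.vector(stats::coef(cv$glmnet.fit, s = lambda))
  names(cf) <- colnames(xs)
  support <- names(cf)[cf != 0]
  structure(list(features = colnames(xs),
                 support = support,
                 beta = cf[support],
                 center = ctr, scale = scl,
                 alpha = alpha, lambda = lambda,
                 lambda_path = cv$lambda, cvm = cv$cvm,
                 nfolds = folds, foldid = foldid, seed = seed,
                 ln_features = ln_feats),
            class = "cox_model")
}

#' Risk scores (linear predictor) from a fitted Cox elastic-net model
#'
#' Applies the stored ln transform and training-set standardisation, then
#' returns `x' beta` over the selected support.
#'
#' @param object a `cox_model`.
#' @param newdata data.frame/matrix with at least the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of risk scores (higher = higher hazard).
#' @export
predict.cox_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  x$id <- NULL
  missing_cols <- setdiff(object$features, colnames(x))
  if (length(missing_cols))
    stop("newdata lacks feature(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(x[, object$features, drop = FALSE])
  for (v in intersect(object$ln_features, colnames(x)))
    x[, v] <- log(pmax(x[, v], 1e-6))
  xs <- scale(x, center = object$center, scale = object$scale)
  if (length(object$support) == 0) return(rep(0, nrow(xs)))
  as.vector(xs[, object$support, drop = FALSE] %*% object$beta)
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("<cox_model> alpha = %.2f, lambda = %.4g, %d/%d features selected\n",
              x$alpha, x$lambda, length(x$support), length(x$features)))
  if (length(x$support)) {
    b <- sort(x$beta, decreasing = TRUE)
    print(round(b, 4))
  }
  invisible(x)
}
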