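test_that("mRMR returns k features and defers duplicated information", {
  set.seed(5)
  n <- 300
  ev <- rbinom(n, 1, 0.5)
  inf <- ev + rnorm(n, 0, 0.7)
  X <- data.frame(inf1 = inf, inf2 = inf, matrix(rnorm(n * 20), n))
  sel <- mrmr_select(X, ev, k = 5)
  expect_length(sel, 5)
  expect_true(sel[1] %in% c("inf1", "inf2"))
  expect_false(sel[2] %in% c("inf1", "inf2"))  # redundancy 1 demotes the twin

  # identity case: k equal to the feature count returns everything
  sel_all <- mrmr_select(X, ev, k = ncol(X))
  expect_setequal(sel_all, colnames(X))

  X$const <- 1
  expect_warning(s2 <- mrmr_select(X, ev, k = 3), "const")
  expect_false("const" %in% s2)
  expect_error(mrmr_select(X[, 1:3], ev, k = 10), "exceeds")
})

test_that("the elastic net recovers strong true features", {
  beta <- setNames(rep(1, 5), paste0("f", 1:5))
  so <- simulate_survival(simsurv_spec(n = 500, p = 50, beta = beta,
                                       seed = 111))
  m <- fit_cox_elasticnet(so$features, so$surv, seed = 211)
  expect_true(all(names(beta) %in% m$support))
  # signs of the recovered coefficients match the truth
  expect_true(all(m$beta[names(beta)] > 0))
})

test_that("a null truth keeps the CV-optimal support small", {
  so <- simulate_survival(simsurv_spec(n = 500, p = 50, beta = c(f1 = 0),
                                       seed = 21))
  m <- fit_cox_elasticnet(so$features, so$surv, seed = 22)
  expect_lte(length(m$support), 8)
})

test_that("pure lasso keeps at most one of two duplicated columns", {
  beta <- c(f1 = 1)
  so <- simulate_survival(simsurv_spec(n = 300, p = 10, beta = beta,
                                       seed = 41))
  so$features$f1dup <- so$features$f1
  m <- fit_cox_elasticnet(so$features, so$surv, alpha = 1, seed = 42)
  # the exact lasso solution puts all weight on one twin; allow the
  # coordinate-descent crumb on the other
  pair <- abs(c(f1 = m$beta["f1"], f1dup = m$beta["f1dup"]))
  pair[is.na(pair)] <- 0
  expect_lt(min(pair), 0.05 * max(pair))
})

test_that("a target support size picks the nearest lambda on the path", {
  beta <- setNames(rep(0.8, 5), paste0("f", 1:5))
  so <- simulate_survival(simsurv_spec(n = 400, p = 30, beta = beta,
                                       seed = 51))
  m <- fit_cox_elasticnet(so$features, so$surv, seed = 52, target_size = 5)
  expect_lte(abs(length(m$support) - 5), 2)
})

test_that("concordance handles the degenerate orderings", {
  surv <- validate_survival_table(
    data.frame(id = letters[1:8], time = c(5, 3, 9, 1, 7, 2, 8, 4),
               event = rep(1, 8)))
  expect_equal(concordance_index(-surv$time, surv), 1)
  expect_equal(concordance_index(rep(1, 8), surv), 0.5)
})

test_that("concordance equals the brute-force pair count", {
  # 6-subject hand-built table with censoring and a risk tie
  surv <- validate_survival_table(
    data.frame(id = letters[1:6],
               time = c(2, 4, 4, 7, 9, 9),
               event = c(1, 1, 0, 1, 0, 0)))
  risk <- c(3.0, 2.0, 2.0, 1.0, 0.5, 4.0)
  expect_equal(concordance_index(risk, surv),
               brute_force_cindex(risk, surv$time, surv$event))

  # property: exact agreement on random 20-subject tables
  set.seed(14)
  for (i in 1:100) {
    n <- 20
    tb <- validate_survival_table(
      data.frame(id = paste0("s", 1:n),
                 time = sample(1:12, n, replace = TRUE),
                 event = rbinom(n, 1, 0.6)))
    r <- sample(1:6, n, replace = TRUE)  # deliberate risk ties
    expect_equal(concordance_index(r, tb),
                 brute_force_cindex(r, tb$time, tb$event))
  }
})

test_that("the null-model AIC matches the closed-form partial likelihood", {
  surv <- validate_survival_table(
    data.frame(id = letters[1:5], time = c(2, 4, 6, 8, 10),
               event = c(1, 1, 0, 1, 0)))
  # with no covariates each event contributes -log(risk-set size)
  ll0 <- -(log(5) + log(4) + log(2))
  expect_equal(cox_aic(NULL, surv), -2 * ll0)
  # determinism
  set.seed(1); x <- data.frame(z = rnorm(5))
  expect_identical(cox_aic(x, surv), cox_aic(x, surv))
})

test_that("a pure-noise feature increases AIC in expectation", {
  set.seed(77)
  deltas <- replicate(100, {
    so <- simulate_survival(simsurv_spec(
      features = data.frame(f1 = rnorm(60), f2 = rnorm(60)),
      beta = c(f1 = 0.8), seed = sample.int(1e6, 1)))
    cox_aic(so$features[, c("f1", "f2")], so$surv) -
      cox_aic(so$features[, "f1", drop = FALSE], so$surv)
  })
  expect_gt(mean(deltas), 0)
})

test_that("time-dependent AUC behaves at the extremes", {
  surv <- validate_survival_table(
    data.frame(id = paste0("s", 1:20), time = 1:20,
               event = rep(1, 20)))
  expect_equal(auc_at_time(-(1:20), surv, 10.5), 1)  # perfect ordering
  expect_error(auc_at_time(1:20, surv, 0.5), "events")
  expect_error(auc_at_time(1:20, surv, 25), "at risk")
})

test_that("without censoring AUC(t) equals the binary Mann-Whitney AUC", {
  set.seed(23)
  n <- 300
  so <- simulate_survival(simsurv_spec(n = n, p = 1, beta = c(f1 = 0.8),
                                       t_max = Inf, seed = 24))
  r <- rnorm(n) + so$features$f1
  t0 <- median(so$surv$time)
  lab <- so$surv$time <= t0
  wilcox <- mean(outer(r[lab], r[!lab], ">") + 0.5 * outer(r[lab], r[!lab], "=="))
  expect_equal(auc_at_time(r, so$surv, t0), wilcox)
})

test_that("NRI is zero for identical models and decomposes exactly", {
  so <- simulate_survival(simsurv_spec(n = 200, p = 2, beta = c(f1 = 1),
                                       seed = 61))
  r <- so$features$f1
  nri0 <- nri_categorical(r, r, so$surv, t = 600, B = 0)
  expect_equal(nri0$nri, 0)
  expect_equal(nri0$nri_event, 0)
  expect_equal(nri0$nri_nonevent, 0)

  # informative reclassification: true predictor vs noise
  nri1 <- nri_categorical(so$features$f2, so$truth$linear_predictor,
                          so$surv, t = 600, B = 200, seed = 62)
  expect_gt(nri1$nri, 0)
  expect_equal(nri1$nri, nri1$nri_event + nri1$nri_nonevent)
  expect_true(nri1$ci[1] <= nri1$nri && nri1$nri <= nri1$ci[2])
  expect_error(nri_categorical(r, r, so$surv, t = 1e9), "follow-up")
})

test_that("KM stratification matches the hand product-limit formula", {
  # two identical 5-subject strata
  time <- c(2, 4, 4, 7, 9); event <- c(1, 1, 0, 1, 0)
  surv <- validate_survival_table(
    data.frame(id = paste0("s", 1:10), time = rep(time, 2),
               event = rep(event, 2)))
  km <- km_stratify(rep(c(0, 1), each = 5), surv, split = 0.5)
  expect_gt(km$logrank_p, 0.99)
  expect_equal(km$hr, 1, tolerance = 1e-6)
  oracle <- hand_km(time, event)
  expect_equal(oracle$surv, c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2))
  for (g in 1:2) {
    sel <- seq(5 * (g - 1) + 1, 5 * g)
    fit_t <- km$fit$time[km$fit$strata[g] * (g - 1) + seq_len(km$fit$strata[g])]
    fit_s <- km$fit$surv[km$fit$strata[g] * (g - 1) + seq_len(km$fit$strata[g])]
    got <- fit_s[match(oracle$time, fit_t)]
    expect_equal(got, oracle$surv)
  }
})

test_that("median-split stratification recovers a designed group hazard ratio", {
  # two-group exponential with true HR 2.4; check the Monte-Carlo mean
  hrs <- vapply(1:12, function(s) {
    set.seed(70 + s)
    n <- 400
    grp <- rep(0:1, each = n / 2)
    lam <- log(2) / 600 * 2.4^grp
    t_ev <- rexp(n) / lam
    cens <- runif(n, 0, 2190)
    surv <- validate_survival_table(
      data.frame(id = paste0("s", 1:n), time = pmin(t_ev, cens),
                 event = as.integer(t_ev <= cens)))
    km_stratify(grp + rnorm(n, 0, 1e-9), surv, split = 0.5)$hr
  }, numeric(1))
  expect_true(mean(hrs) > 1.9 && mean(hrs) < 3.0)

  set.seed(71)
  n <- 400; grp <- rep(0:1, each = n / 2)
  t_ev <- rexp(n) / (log(2) / 600 * 2.4^grp)
  cens <- runif(n, 0, 2190)
  surv <- validate_survival_table(
    data.frame(id = paste0("s", 1:n), time = pmin(t_ev, cens),
               event = as.integer(t_ev <= cens)))
  km <- km_stratify(grp + rnorm(n, 0, 1e-9), surv, split = 0.5)
  expect_lt(km$logrank_p, 0.001)
})

test_that("the likelihood-ratio test is calibrated and powered", {
  so <- simulate_survival(simsurv_spec(n = 300, p = 3, beta = c(f1 = 1),
                                       seed = 81))
  a <- so$features[, "f2", drop = FALSE]
  same <- likelihood_ratio_test(a, a, so$surv)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  # adding the true predictor: overwhelming evidence
  strong <- likelihood_ratio_test(a, so$features[, c("f2", "f1")], so$surv)
  expect_lt(strong$p, 0.001)
  # non-nested comparison refuses the chi-squared calibration
  expect_warning(
    nn <- likelihood_ratio_test(so$features[, "f2", drop = FALSE],
                                so$features[, "f3", drop = FALSE], so$surv),
    "nested")
  expect_true(is.na(nn$p))
})

test_that("the true linear predictor dominates single noise features", {
  beta <- setNames(rep(0.7, 3), paste0("f", 1:3))
  so <- simulate_survival(simsurv_spec(n = 1000, p = 10, beta = beta,
                                       seed = 91))
  c_true <- concordance_index(so$truth$linear_predictor, so$surv)
  for (j in paste0("f", 4:10))
    expect_gt(c_true, concordance_index(so$features[[j]], so$surv))
})

test_that("model prediction applies the stored standardisation", {
  beta <- c(f1 = 1, f2 = -1)
  so <- simulate_survival(simsurv_spec(n = 300, p = 5, beta = beta,
                                       seed = 95))
  m <- fit_cox_elasticnet(so$features, so$surv, seed = 96)
  r_all <- predict(m, so$features)
  r_sub <- predict(m, so$features[7:9, ])
  expect_equal(r_sub, r_all[7:9])
  expect_error(predict(m, so$features[, 1:2]), "lacks")
})
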