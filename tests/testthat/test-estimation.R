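# map a free-parameter vector (fit_model naming) back to a bws_params,
# used to cross-check the fitter's internal gradient against the public
# likelihood implementation
par2params <- function(est, interactions = NULL, scale_covars = character()) {
  est <- unlist(est)
  labs <- level_labels()
  beta <- est[intersect(names(est), labs)]
  pb <- pw <- numeric(7)
  for (r in 2:7) {
    if (paste0("pos", r, "_B") %in% names(est)) pb[r] <- est[[paste0("pos", r, "_B")]]
    if (paste0("pos", r, "_W") %in% names(est)) pw[r] <- est[[paste0("pos", r, "_W")]]
  }
  scale <- numeric()
  if (length(scale_covars))
    scale <- stats::setNames(exp(unlist(est[scale_covars])), scale_covars)
  inter <- NULL
  if (!is.null(interactions)) {
    inter <- interactions[, c("level", "covariate")]
    inter$delta <- unlist(est[paste0(inter$level, ":", inter$covariate)])
  }
  bws_params(beta = beta, pos_best = pb, pos_worst = pw, scale = scale,
             interactions = inter)
}

test_that("internal gradient agrees with the public likelihood by finite differences", {
  w <- small_world(n_resp = 10, seed = 29, model = "II")
  inter <- data.frame(level = c("occu3", "soci1"),
                      covariate = c("renter", "noreligion"))
  sc <- c("hgood", "learning")
  dat <- ascotbws:::build_model_data(w$choices, w$cohort, sc, inter)
  nms <- c(colnames(dat$M), colnames(dat$Z))
  par <- withr::with_seed(5, rnorm(length(nms), 0, 0.25))
  names(par) <- nms
  ev <- ascotbws:::smnl_eval(par, dat, hessian = TRUE)
  ll_pub <- dataset_loglik(par2params(as.list(par), inter, sc),
                           w$choices, w$cohort)
  expect_equal(ev$ll, ll_pub, tolerance = 1e-10)
  h <- 1e-5
  idx <- c(1, 8, 27, which(nms == "pos4_W"), which(nms == "occu3:renter"),
           which(nms == "hgood"), which(nms == "learning"))
  for (j in idx) {
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    gfd <- (dataset_loglik(par2params(as.list(pp), inter, sc), w$choices, w$cohort) -
            dataset_loglik(par2params(as.list(pm), inter, sc), w$choices, w$cohort)) / (2 * h)
    expect_equal(unname(ev$grad[j]), gfd, tolerance = 1e-5)
  }
  # Hessian column against finite differences of the analytic gradient
  j <- which(nms == "hgood")
  pp <- par; pp[j] <- pp[j] + h
  pm <- par; pm[j] <- pm[j] - h
  hcol <- (ascotbws:::smnl_eval(pp, dat)$grad -
           ascotbws:::smnl_eval(pm, dat)$grad) / (2 * h)
  expect_equal(unname(ev$H[, j]), unname(hcol), tolerance = 1e-4)
})

test_that("MNL recovers the generating coefficients on simulated data", {
  w <- small_world(n_resp = 150, seed = 23, model = "I")
  fit <- fit_model(w$choices, model = "mnl")
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
  labs <- setdiff(level_labels(), "cont4")
  est <- fit$estimates[labs]
  se <- fit$se[labs]
  truth <- w$truth$beta[labs]
  z <- abs(est - truth) / se
  expect_gt(mean(z < 3), 0.9)
  expect_gt(cor(est, truth), 0.99)
  expect_gt(fit$loglik, fit$loglik_null)
})

test_that("the optimum is independent of the starting point", {
  w <- small_world(n_resp = 25, seed = 31, model = "I")
  f0 <- fit_model(w$choices, model = "mnl")
  start <- withr::with_seed(7, rnorm(length(f0$estimates), 0, 0.5))
  names(start) <- names(f0$estimates)
  f1 <- fit_model(w$choices, model = "mnl", start = start)
  expect_lt(max(abs(f0$estimates - f1$estimates)), 1e-6)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-10)
})

test_that("S-MNL on scale-free data estimates unit scale factors", {
  w <- small_world(n_resp = 150, seed = 23, model = "I")
  fit <- fit_model(w$choices, w$cohort, model = "smnl")
  expect_true(fit$converged)
  expect_true(all(abs(fit$gamma$gamma - 1) < 3.5 * fit$gamma$se + 0.02))
})

test_that("nested model ordering holds on common data", {
  w <- small_world(n_resp = 40, seed = 11)
  f_mnl <- fit_model(w$choices, model = "mnl")
  f_smnl <- fit_model(w$choices, w$cohort, model = "smnl")
  expect_gte(f_smnl$loglik, f_mnl$loglik - 1e-6)
  lr <- lr_test(f_mnl, f_smnl)
  expect_equal(lr$df, 4)
  expect_gte(lr$statistic, 0)
})

test_that("likelihood-ratio arithmetic reproduces the published test", {
  lr <- lr_test(list(loglik = -38475.50, df = 43),
                list(loglik = -38469.54, df = 47))
  expect_equal(lr$statistic, 11.92, tolerance = 1e-9)
  expect_equal(lr$df, 4)
  expect_equal(round(lr$p_value, 3), 0.018)
  same <- list(loglik = -100, df = 10)
  lr0 <- lr_test(same, same)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_equal(round(lr_test(list(loglik = -101.92, df = 1),
                             list(loglik = -100, df = 2))$p_value, 3), 0.05)
  expect_error(lr_test(list(loglik = -99, df = 10), list(loglik = -100, df = 12)),
               "nesting")
})

test_that("pseudo-R2 against the exploded uniform null", {
  ll0_task <- -(log(7) + log(6) + log(5) + log(4))
  expect_equal(pseudo_r2(list(loglik = -38685.26, loglik_null = 8040 * ll0_task)),
               0.285)
  expect_equal(pseudo_r2(list(loglik = -5, loglik_null = -5)), 0)
  expect_equal(pseudo_r2(list(loglik = 0, loglik_null = -5)), 1)
})

test_that("cluster sandwich matches the hand-computed binary-logit case", {
  # two respondents, one two-alternative occasion each (occu1 vs the cont4
  # reference): a one-parameter logit with MLE 0, per-cluster scores +-1/2,
  # Hessian -1/2 -> sandwich variance 2
  mk <- function(id, pick) data.frame(
    respondent_id = id, task = 1L, stage = "best",
    attribute = c("occu", "cont"), level = c(1L, 4L), row = c(1L, 1L),
    available = 1L, chosen = c(pick, 1L - pick))
  ch <- rbind(mk(1L, 1L), mk(2L, 0L))
  fit <- fit_model(ch, model = "mnl")
  expect_equal(length(fit$estimates), 1L)
  expect_equal(unname(fit$estimates["occu1"]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$vcov[1, 1]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$vcov_hessian[1, 1]), 2, tolerance = 1e-6)
})

test_that("duplicating every cluster halves the robust covariance", {
  w <- small_world(n_resp = 20, seed = 37, model = "I")
  ch <- w$choices
  ch2 <- rbind(ch, transform(ch, respondent_id = respondent_id + 1000L))
  f1 <- fit_model(ch, model = "mnl")
  f2 <- fit_model(ch2, model = "mnl")
  expect_lt(max(abs(f1$estimates - f2$estimates)), 1e-5)
  ratio <- diag(f2$vcov) / diag(f1$vcov)
  expect_equal(unname(ratio), rep(0.5, length(ratio)), tolerance = 1e-3)
})

test_that("robust and inverse-Hessian SEs agree under correct specification", {
  # with every occasion its own cluster and a correctly specified model the
  # information-matrix equality applies
  w <- small_world(n_resp = 150, seed = 23, model = "I")
  fit <- fit_model(w$choices, model = "mnl")
  occ_id <- paste(w$choices$respondent_id, w$choices$task, w$choices$stage)
  V <- sandwich_covariance(fit, w$choices, cluster = occ_id)
  ratio <- sqrt(diag(V)) / sqrt(diag(fit$vcov_hessian))
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("collinear interaction columns raise a singularity error", {
  w <- small_world(n_resp = 10, seed = 29, model = "II")
  coh <- w$cohort
  coh$always <- 1L
  inter <- data.frame(level = "occu1", covariate = "always")
  expect_error(fit_model(w$choices, coh, model = "mnl", interactions = inter),
               "singular|collinear")
})

test_that("fitted_params round-trips the estimates into a parameter set", {
  w <- small_world(n_resp = 25, seed = 31, model = "I")
  fit <- fit_model(w$choices, model = "mnl")
  p <- fitted_params(fit)
  expect_equal(dataset_loglik(p, w$choices), fit$loglik, tolerance = 1e-8)
})
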