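test_that("exploding a task yields shrinking sets 7/6/5/4 with valid picks", {
  occ <- one_task()
  sizes <- table(factor(occ$stage,
                        levels = c("best", "worst", "second_best", "second_worst")))
  expect_equal(unname(as.integer(sizes)), c(7L, 6L, 5L, 4L))
  expect_equal(unname(tapply(occ$chosen, occ$stage, sum)), rep(1, 4),
               ignore_attr = TRUE)
  # picked items are removed from later sets
  expect_false("occu" %in% occ$attribute[occ$stage == "worst"])
  expect_error(explode_task(rep(1, 7), picks = c(1, 1, 2, 3)), "malformed")
  expect_error(explode_task(rep(1, 7), picks = c(1, 2, 3, 9)), "malformed")
  expect_error(explode_task(rep(5, 7), picks = c(1, 2, 3, 4)), "malformed")
})

test_that("respondent scale multiplies the published factors of active covariates", {
  p <- finnish_carer_estimates("III*")
  expect_equal(respondent_scale(p, list(hgood = 0, eduhigh = 0, tmlong = 0), 1), 1)
  expect_equal(respondent_scale(p, list(hgood = 1, eduhigh = 0, tmlong = 1), 2),
               1.120 * 1.240)
  expect_equal(respondent_scale(p, list(hgood = 0, eduhigh = 0, tmlong = 0), 5),
               1.069)
  # alternative sequence split: with a 6-task first sequence, task 5 is "early"
  expect_equal(respondent_scale(p, list(hgood = 0, eduhigh = 0, tmlong = 0), 5,
                                first_seq_len = 6), 1)
  expect_error(respondent_scale(p, list(hgood = 1), 1), "eduhigh")
})

test_that("stage utilities follow the sign convention and position constants", {
  p <- finnish_carer_estimates("III*")
  ref <- list(hgood = 0, eduhigh = 0, tmlong = 0)
  occ <- explode_task(c(1, 4, 1, 1, 1, 1, 1), picks = c(1, 2, 3, 4))
  best <- occ[occ$stage == "best", ]
  su <- stage_utilities(p, best, ref)
  expect_equal(su$lambda, 1)
  # cont4 (reference beta) displayed in row 2: only the position constant
  expect_equal(su$V[best$attribute == "cont"], p$pos_best[2])
  # occu1 in row 1: beta alone
  expect_equal(su$V[best$attribute == "occu"], 3.353)

  # occu1 in display row 3 at the best stage: beta + pos3_B
  ord <- c(3, 1, 2, 4, 5, 6, 7)
  occ3 <- explode_task(c(1, 4, 1, 1, 1, 1, 1), picks = c(1, 2, 3, 4),
                       display_order = ord)
  b3 <- occ3[occ3$stage == "best", ]
  expect_equal(b3$row[b3$attribute == "occu"], 3L)
  expect_equal(stage_utilities(p, b3, ref)$V[b3$attribute == "occu"],
               3.353 - 0.109)

  # worst stage flips the preference sign: occu1 in row 1 -> -beta
  occw <- explode_task(c(1, 4, 1, 1, 1, 1, 1), picks = c(2, 1, 3, 4))
  w <- occw[occw$stage == "worst", ]
  expect_equal(stage_utilities(p, w, ref)$V[w$attribute == "occu"], -3.353)
})

test_that("occasion probabilities are a proper softmax", {
  expect_equal(occasion_probability(rep(0, 7)), rep(1 / 7, 7))
  expect_equal(occasion_probability(c(log(2), 0)), c(2 / 3, 1 / 3))
  withr::with_seed(21, {
    for (i in 1:25) {
      V <- rnorm(sample(3:8, 1), sd = 3)
      p <- occasion_probability(V)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  })
  expect_error(occasion_probability(c(1, NaN)), "non-finite")
})

test_that("uniform-parameter log-likelihood matches the closed form", {
  occ <- one_task()
  p0 <- bws_params()
  expect_equal(dataset_loglik(p0, occ),
               -(log(7) + log(6) + log(5) + log(4)), tolerance = 1e-9)
  # lambda is irrelevant when all systematic utilities are zero
  coh1 <- data.frame(id = 1L, hgood = 1L, eduhigh = 1L, tmlong = 1L)
  pl <- bws_params(scale = c(hgood = 2.5))
  expect_equal(dataset_loglik(pl, occ, coh1), -(log(7) + log(6) + log(5) + log(4)))
  expect_equal(dataset_loglik(p0, occ[0, ]), 0)
})

test_that("null log-likelihood depends only on set sizes", {
  occ <- one_task()
  expect_equal(null_loglik(occ), -(log(7) + log(6) + log(5) + log(4)))
  expect_equal(null_loglik(occ[occ$stage == "second_worst", ]), -log(4))
  expect_equal(null_loglik(occ[0, ]), 0)
})

test_that("non-finite utilities raise an error naming the occasion", {
  occ <- one_task()
  p <- bws_params()
  p$beta["occu1"] <- Inf
  expect_error(dataset_loglik(p, occ), "respondent 1 task 1")
})

test_that("exploded likelihood factorises over the 840 pick sequences", {
  # enumerating all orderings of (best, worst, 2nd-best, 2nd-worst), the
  # sequence probabilities must sum to one: the explosion is a proper
  # distribution over partial rankings
  p <- finnish_carer_estimates("I")
  profile <- c(2, 3, 1, 4, 2, 1, 3)
  total <- 0
  for (b in 1:7) for (w in setdiff(1:7, b))
    for (sb in setdiff(1:7, c(b, w))) for (sw in setdiff(1:7, c(b, w, sb))) {
      occ <- explode_task(profile, c(b, w, sb, sw))
      total <- total + exp(dataset_loglik(p, occ))
    }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("unit scale factors reduce the S-MNL likelihood to the MNL exactly", {
  w <- small_world()
  p <- finnish_carer_estimates("I")
  p1 <- bws_params(beta = p$beta, pos_best = p$pos_best,
                   pos_worst = p$pos_worst,
                   scale = c(hgood = 1, eduhigh = 1, tmlong = 1, learning = 1))
  ll_mnl <- dataset_loglik(p, w$choices)
  ll_smnl <- dataset_loglik(p1, w$choices, w$cohort)
  expect_equal(ll_smnl, ll_mnl, tolerance = 1e-12)
})

test_that("probabilities are invariant to a common shift of all beta", {
  p <- finnish_carer_estimates("I")
  occ <- one_task()
  ll1 <- dataset_loglik(p, occ)
  p2 <- p
  p2$beta <- p$beta + 1.7
  ll2 <- dataset_loglik(p2, occ)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})
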