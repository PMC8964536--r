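test_that("normalisation divides by the largest coefficient", {
  beta <- finnish_carer_estimates("III*")$beta
  nv <- normalize_weights(beta)
  expect_equal(unname(nv["cont1"]), 1)
  expect_equal(unname(nv["cont4"]), 0)
  expect_equal(round(unname(nv["occu1"]), 3), 0.976)
  expect_error(normalize_weights(setNames(rep(0, 3), c("a", "b", "c"))),
               "degenerate")
  expect_error(normalize_weights(c(a = -1, b = -2)), "degenerate")
})

test_that("anchoring pins best-state sum to 1 and worst-state sum to 0", {
  beta <- finnish_carer_estimates("III*")$beta
  v <- anchor_index(beta)
  att <- sub("[1-4]$", "", names(v))
  expect_equal(sum(tapply(v, att, max)), 1, tolerance = 1e-9)
  expect_equal(sum(tapply(v, att, min)), 0, tolerance = 1e-9)
  expect_equal(round(unname(v["cont4"]), 3), -0.027)
  expect_equal(round(unname(v["cont1"]), 3), 0.168)
  expect_error(anchor_index(setNames(rep(2, 28), level_labels())),
               "degenerate")
})

test_that("anchoring is affine-equivariant and order-preserving", {
  beta <- finnish_carer_estimates("III*")$beta
  v <- anchor_index(beta)
  v2 <- anchor_index(3.1 * beta + 0.7)
  expect_equal(as.vector(v2), as.vector(v), tolerance = 1e-12)
  # within-attribute ordering preserved by both transforms
  nv <- normalize_weights(beta)
  for (a in unique(sub("[1-4]$", "", names(beta)))) {
    idx <- grep(paste0("^", a), names(beta))
    expect_equal(order(beta[idx]), order(v[idx]))
    expect_equal(order(beta[idx]), order(nv[idx]))
  }
})

test_that("the published weight tables are reproduced to +-0.001", {
  w <- preference_weights(finnish_carer_estimates("III*")$beta)
  pub_idx <- published_index()
  pub_norm <- published_normalized_switched()
  for (a in names(pub_idx)) {
    got <- w$table$index[w$table$attribute == a]
    expect_lt(max(abs(got - pub_idx[[a]])), 0.001 + 1e-9)
  }
  got_norm <- setNames(w$table$normalized, w$table$label)
  # labels keep instrument positions; values were switched for PERC 1/2
  expect_lt(max(abs(got_norm[names(pub_norm)] - pub_norm)), 0.001 + 1e-9)
})

test_that("level switching exchanges published values and is an involution", {
  beta <- finnish_carer_estimates("III*")$beta
  w0 <- preference_weights(beta, switch_pairs = list())
  expect_equal(round(w0$table$normalized[w0$table$label == "perc1"], 3), 0.802)
  expect_equal(round(w0$table$normalized[w0$table$label == "perc2"], 3), 0.810)
  w1 <- apply_level_switch(w0, list(c("PERC", 1, 2)))
  expect_equal(round(w1$table$normalized[w1$table$label == "perc1"], 3), 0.810)
  expect_equal(round(w1$table$normalized[w1$table$label == "perc2"], 3), 0.802)
  w2 <- apply_level_switch(w1, list(c("PERC", 1, 2)))
  expect_equal(w2$table, w0$table)
  expect_error(apply_level_switch(w0, list(c("PERC", 1, 9))), "unknown level")
})

test_that("state scoring is additive over unrounded internal weights", {
  w <- preference_weights(finnish_carer_estimates("III*")$beta)
  expect_equal(score_state(w, "3442434"), 0.204)
  expect_equal(score_state(w, "1231321"), 0.808)
  expect_equal(score_state(w, "1111111"), 1)
  expect_equal(score_state(w, "4444444"), 0)
  expect_equal(score_state(w, "1111111", scale = "normalized"),
               round(sum(tapply(w$table$normalized, w$table$attribute, max)), 3))
  d <- score_state(w, "1111111", digits = NA) - score_state(w, "4444444", digits = NA)
  expect_equal(d, 1, tolerance = 1e-9)
  expect_error(score_state(w, "123"), "7-character")
  expect_error(score_state(w, "12x4567"), "position 3")
})

test_that("post-stratification adjustment follows the fixed-weight formula", {
  # hand-built fit object: one level with one interaction
  labs <- level_labels()
  est <- c(occu1 = 1.000, `occu1:renter` = 0.500)
  V <- matrix(c(0.04, 0, 0, 0.09), 2, 2,
              dimnames = list(names(est), names(est)))
  fit <- list(estimates = est, vcov = V,
              options = list(interactions = data.frame(
                level = "occu1", covariate = "renter")))
  m <- data.frame(subgroup = "renter", population = 0.274)
  adj <- adjust_for_population(fit, m)
  expect_equal(unname(adj$beta["occu1"]), 1 + 0.274 * 0.5)
  m2 <- data.frame(subgroup = "renter", population = 0.5)
  adj2 <- adjust_for_population(fit, m2)
  expect_equal(unname(adj2$se["occu1"]), sqrt(0.04 + 0.25 * 0.09))
  # untouched levels pass through, missing shares error
  expect_equal(unname(adj$beta["cont4"]), 0)
  expect_error(adjust_for_population(fit, data.frame(subgroup = "lowedu",
                                                     population = 0.2)),
               "renter")
  # no interactions: identity on the free coefficients
  fit0 <- list(estimates = est["occu1"],
               vcov = V[1, 1, drop = FALSE],
               options = list(interactions = NULL))
  adj0 <- adjust_for_population(fit0, m)
  expect_equal(unname(adj0$beta["occu1"]), 1)
})

test_that("radar export reports per-attribute values of both states", {
  w <- preference_weights(finnish_carer_estimates("III*")$beta)
  rd <- radar_data(w, "3442434", "1231321")
  expect_equal(nrow(rd), 7)
  expect_equal(round(sum(rd$value_a), 3), 0.204)
  expect_equal(round(sum(rd$value_b), 3), 0.808)
})
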