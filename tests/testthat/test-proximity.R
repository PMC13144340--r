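make_cov <- function(ids, ...) {
  data.frame(participant_id = ids, ..., stringsAsFactors = FALSE)
}

test_that("proximity columns are negative absolute score differences", {
  ids <- c("a", "b", "c", "d")
  cov <- make_cov(ids, score = c(0, 1, 4, 9))
  pairs <- participant_pairs(ids)
  des <- build_proximity_design(cov, pairs, "score", standardize = FALSE)
  # pairs in order ab, ac, ad, bc, bd, cd
  expect_equal(unname(des$X[, "proximity_score"]),
               c(-1, -4, -9, -3, -8, -5))
  expect_true(all(des$X[, "proximity_score"] <= 0))
  # x_i = 3 vs x_j = 5 gives -2; equal scores give the maximum 0
  cov2 <- make_cov(c("a", "b"), score = c(3, 5))
  des2 <- build_proximity_design(cov2, participant_pairs(c("a", "b")),
                                 "score", standardize = FALSE)
  expect_equal(unname(des2$X[, "proximity_score"]), -2)
  cov3 <- make_cov(c("a", "b"), score = c(4, 4))
  expect_error(build_proximity_design(cov3, participant_pairs(c("a", "b")),
                                      "score"), "zero variance")
})

test_that("proximity is invariant to shifting all covariate scores", {
  ids <- sprintf("p%d", 1:5)
  x <- c(2, 7, 1, 9, 4)
  pairs <- participant_pairs(ids)
  d1 <- build_proximity_design(make_cov(ids, s = x), pairs, "s")
  d2 <- build_proximity_design(make_cov(ids, s = x + 100), pairs, "s")
  expect_equal(d1$X[, "proximity_s"], d2$X[, "proximity_s"])
})

test_that("missing participants or values are explicit errors", {
  ids <- c("a", "b", "c")
  pairs <- participant_pairs(ids)
  expect_error(build_proximity_design(make_cov(c("a", "b"), s = 1:2),
                                      pairs, "s"), "missing from")
  cov <- make_cov(ids, s = c(1, NA, 3))
  expect_error(build_proximity_design(cov, pairs, "s"), "missing values.*b",
               perl = TRUE)
  expect_error(build_proximity_design(make_cov(ids, s = 1:3), pairs, "t"),
               "missing columns")
})

# shared fixture: cohort with synchrony decaying in pvv-attitude distance
prox_fixture <- function() {
  cached("prox_fixture", {
    cfg <- tiny_config(n_participants = 8, n_stimuli = 4,
                       segment_duration_s = 60, gamma_proximity = 1,
                       seed = 77)
    co <- simulate_cohort(cfg)
    pre <- preprocess_cohort(co)
    pm_seg <- all_pair_maps(pre$series_by_participant, pre$segments,
                            pre$voxel_ids)
    bl <- all_baseline_maps(pre$series_by_participant, seed = 77)
    pm <- average_by_condition(subtract_baseline(pm_seg, bl))
    des <- build_proximity_design(co$covariates, pm$pairs,
                                  c("pvv_attitude", "authoritarianism"))
    list(co = co, pre = pre, pm = pm, des = des)
  })
}

test_that("the observed proximity t map equals a per-voxel lm oracle", {
  fx <- prox_fixture()
  reg <- isc_proximity_regression(fx$pm, fx$des, fx$co$mask,
                                  variables = "pvv_attitude",
                                  conditions = "threat", n_perm = 60,
                                  seed = 5)
  r <- reg$threat$pvv_attitude
  g <- match("threat", fx$pm$scope$condition)
  y <- t(fx$pm$z[, , g])
  x <- fx$des$X
  oracle_t <- vapply(seq_len(ncol(y)), function(v) {
    fit <- lm(y[, v] ~ x - 1)
    summary(fit)$coefficients["xproximity_pvv_attitude", "t value"]
  }, numeric(1))
  expect_lt(max(abs(r$observed_stat - oracle_t)), 1e-8)
  # positive coupling decay: proximity coefficient positive at signal voxels
  sig <- signal_rows(fx$co, fx$pre$voxel_ids)
  expect_gt(mean(r$observed_beta[sig] > 0), 0.9)
})

test_that("proximity permutation inference is deterministic and respects the
          baseline requirement", {
  fx <- prox_fixture()
  a <- isc_proximity_regression(fx$pm, fx$des, fx$co$mask,
                                variables = "pvv_attitude",
                                conditions = "threat", n_perm = 50, seed = 9)
  b <- isc_proximity_regression(fx$pm, fx$des, fx$co$mask,
                                variables = "pvv_attitude",
                                conditions = "threat", n_perm = 50, seed = 9)
  expect_identical(a$threat$pvv_attitude$p_fwe, b$threat$pvv_attitude$p_fwe)
  raw <- average_by_condition(all_pair_maps(fx$pre$series_by_participant,
                                            fx$pre$segments,
                                            fx$pre$voxel_ids))
  expect_error(isc_proximity_regression(raw, fx$des, fx$co$mask),
               "baseline")
  expect_silent(isc_proximity_regression(raw, fx$des, fx$co$mask,
                                         variables = "pvv_attitude",
                                         conditions = "neutral", n_perm = 20,
                                         seed = 1, require_baseline = FALSE))
})

test_that("across-regressor FWE is never more liberal than within", {
  fx <- prox_fixture()
  reg <- isc_proximity_regression(fx$pm, fx$des, fx$co$mask,
                                  conditions = "blame", n_perm = 50, seed = 3)
  for (v in names(reg$blame)) {
    r <- reg$blame[[v]]
    expect_true(all(r$p_fwe_across >= r$p_fwe - 1e-12))
  }
})

test_that("constant maps yield zero proximity effect and p = 1", {
  fx <- prox_fixture()
  pm_const <- fx$pm
  pm_const$z[] <- 0.3
  reg <- isc_proximity_regression(pm_const, fx$des, fx$co$mask,
                                  variables = "pvv_attitude",
                                  conditions = "threat", n_perm = 30,
                                  seed = 2)
  r <- reg$threat$pvv_attitude
  expect_lt(max(abs(r$observed_beta)), 1e-12)
  expect_lt(max(abs(r$observed_stat)), 1e-6)
  # the intercept reproduces the constant map value exactly
  g <- match("threat", pm_const$scope$condition)
  beta <- qr.coef(qr(fx$des$X), t(pm_const$z[, , g]))
  expect_equal(unname(beta["(intercept)", 1]), 0.3, tolerance = 1e-12)
})

test_that("condition moderation is antisymmetric and zero for identical
          conditions", {
  fx <- prox_fixture()
  ab <- condition_moderation(fx$pm, fx$des, "blame", "threat", fx$co$mask,
                             variables = "pvv_attitude", n_perm = 40,
                             seed = 11)
  ba <- condition_moderation(fx$pm, fx$des, "threat", "blame", fx$co$mask,
                             variables = "pvv_attitude", n_perm = 40,
                             seed = 11)
  expect_equal(ab$pvv_attitude$observed_stat,
               -ba$pvv_attitude$observed_stat, tolerance = 1e-10)
  pm_same <- fx$pm
  pm_same$z[, , match("threat", pm_same$scope$condition)] <-
    pm_same$z[, , match("blame", pm_same$scope$condition)]
  same <- condition_moderation(pm_same, fx$des, "blame", "threat",
                               fx$co$mask, variables = "pvv_attitude",
                               n_perm = 30, seed = 4)
  expect_equal(max(abs(same$pvv_attitude$observed_stat)), 0)
  expect_error(condition_moderation(fx$pm, fx$des, "blame", "sarcasm",
                                    fx$co$mask), "condition missing")
})
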