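test_that("composite scores are item-set means", {
  mapping <- panas_mapping()
  items <- c(mapping$negative_items, mapping$positive_items)
  # all items equal: every composite equals that value
  row_const <- as.data.frame(as.list(setNames(rep(7, 12), items)))
  out <- composite_scores(row_const, mapping)
  expect_equal(out$negative_affect, 7)
  expect_equal(out$positive_affect, 7)
  expect_equal(out$fear, 7)
  expect_equal(out$anger, 7)
  # negative at scale max, positive at min
  row_split <- as.data.frame(as.list(c(setNames(rep(20, 6),
                                                mapping$negative_items),
                                       setNames(rep(0, 6),
                                                mapping$positive_items))))
  out2 <- composite_scores(row_split, mapping)
  expect_equal(out2$negative_affect, 20)
  expect_equal(out2$positive_affect, 0)
  # fixed 12-value row against hand-computed means
  vals <- setNames(c(3, 5, 9, 11, 2, 6, 1, 4, 8, 10, 12, 0), items)
  out3 <- composite_scores(as.data.frame(as.list(vals)), mapping)
  expect_equal(out3$negative_affect, mean(vals[mapping$negative_items]))
  expect_equal(out3$fear, mean(vals[mapping$fear]))
  expect_equal(out3$anger, mean(vals[mapping$anger]))
  # missing item is an error
  expect_error(composite_scores(row_const[, -1], mapping), "missing emotion")
})

test_that("framing model matches a normal-equations oracle on a fixture", {
  set.seed(21)
  n <- 12
  tab <- data.frame(frame = rep(c("neutral", "threat", "blame"), 4),
                    age = rnorm(n, 50, 10),
                    y = rnorm(n))
  fit <- fit_framing_model(tab, "y", covariates = "age")
  # releveled factor orders the dummies blame, threat after the intercept
  x <- cbind(1, tab$frame == "blame", tab$frame == "threat", tab$age)
  oracle <- ols_oracle(x, tab$y)
  expect_lt(max(abs(fit$coefficients$estimate - oracle$beta)), 1e-8)
  expect_lt(max(abs(fit$coefficients$se - oracle$se)), 1e-8)
  # CI = estimate +/- t * se
  expect_equal(fit$coefficients$ci_hi - fit$coefficients$estimate,
               qt(0.975, oracle$df) * fit$coefficients$se, tolerance = 1e-10)
})

test_that("a constant outcome yields zero frame effects", {
  tab <- data.frame(frame = rep(c("neutral", "threat", "blame"), 5), y = 2)
  fit <- suppressWarnings(fit_framing_model(tab, "y"))  # perfect-fit warning
  fr <- fit$coefficients[grepl("^frame", fit$coefficients$term), ]
  expect_equal(fr$estimate, rep(0, 2), tolerance = 1e-12)
})

test_that("within-subject fit equals the participant-demeaned oracle", {
  set.seed(22)
  n_sub <- 15; n_rep <- 6
  tab <- data.frame(
    participant_id = rep(sprintf("s%02d", 1:n_sub), each = n_rep),
    frame = rep(c("neutral", "threat", "blame"), n_sub * 2))
  subj_eff <- rnorm(n_sub, 0, 3)[rep(1:n_sub, each = n_rep)]
  tab$y <- subj_eff + 1.2 * (tab$frame == "blame") + rnorm(nrow(tab))
  fit <- fit_framing_model(tab, "y", within_subject = TRUE)
  # oracle: demean y and frame dummies within participant, then OLS
  dm <- function(v) v - ave(v, tab$participant_id)
  xd <- cbind(dm(as.numeric(tab$frame == "threat")),
              dm(as.numeric(tab$frame == "blame")))
  yd <- dm(tab$y)
  beta_oracle <- drop(solve(crossprod(xd), crossprod(xd, yd)))
  got <- fit$coefficients
  expect_equal(got$estimate[got$term == "frameblame"], beta_oracle[2],
               tolerance = 1e-10)
  expect_equal(got$estimate[got$term == "framethreat"], beta_oracle[1],
               tolerance = 1e-10)
  # participant dummies are absorbed, not reported
  expect_false(any(grepl("participant_id", got$term)))
})

test_that("reference-level switching changes dummies but not fitted values", {
  set.seed(23)
  tab <- data.frame(frame = rep(c("neutral", "threat", "blame"), 10))
  tab$y <- rnorm(30) + (tab$frame == "threat")
  f1 <- fit_framing_model(tab, "y")
  tab2 <- tab
  tab2$frame <- relevel(factor(tab2$frame), ref = "blame")
  f2 <- lm(y ~ frame, data = tab2)
  expect_equal(unname(fitted(f1$fit)), unname(fitted(f2)),
               tolerance = 1e-10)
})

test_that("interaction models enforce marginality and are centering
          invariant", {
  set.seed(24)
  n <- 300
  tab <- data.frame(frame = sample(c("neutral", "threat", "blame"), n, TRUE),
                    importance = rnorm(n, 10, 3),
                    negative_affect = rnorm(n, 8, 2))
  tab$y <- rnorm(n) - 0.1 * tab$importance * (tab$frame == "blame") *
    tab$negative_affect
  expect_error(interaction_model(tab, "y",
                                 c("importance", "frame",
                                   "importance:frame:negative_affect")),
               "without its margins")
  fit <- interaction_model(tab, "y", "importance*frame*negative_affect")
  co <- fit$coefficients
  three <- co[grepl("importance:frameblame:negative_affect", co$term), ]
  expect_equal(nrow(three), 1)
  # centering the continuous predictors leaves the three-way term unchanged
  tab_c <- tab
  tab_c$importance <- tab_c$importance - mean(tab_c$importance)
  tab_c$negative_affect <- tab_c$negative_affect - mean(tab_c$negative_affect)
  fit_c <- interaction_model(tab_c, "y", "importance*frame*negative_affect")
  co_c <- fit_c$coefficients
  three_c <- co_c[grepl("importance:frameblame:negative_affect", co_c$term), ]
  expect_equal(three$estimate, three_c$estimate, tolerance = 1e-8)
})

test_that("injected survey effects are recovered by the framing model", {
  sv <- simulate_survey(n = 1800, seed = 31)
  sv <- composite_scores(sv)
  truth <- attr(sv, "truth")$composite_effects
  fit <- fit_framing_model(sv, "anger", covariates = c("age", "gender"))
  co <- fit$coefficients
  for (fr in c("threat", "blame")) {
    row <- co[co$term == paste0("frame", fr), ]
    expect_lt(abs(row$estimate - truth$anger[fr]), 3 * row$se)
  }
})
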