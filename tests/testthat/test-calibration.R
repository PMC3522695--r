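# Four-step calibration: normalisation, per-step parameter recovery,
# combination prediction, end-to-end behaviour.

test_that("normalisation divides by the day-0 value and guards misuse", {
  s <- mean_series("control", c(0, 7), c(158, 316))
  n <- normalize_series(s)
  expect_true(n$normalized)
  expect_equal(n$data$volume, c(1, 2))
  expect_error(normalize_series(n), "already normalized")

  flat <- normalize_series(mean_series("combination", c(0, 7), c(109, 109)))
  expect_equal(flat$data$volume, c(1, 1))

  # SEM scales with the same factor
  s2 <- normalize_series(mean_series("control", c(0, 7), c(158, 316),
                                     sem = c(15.8, 31.6)))
  expect_equal(s2$data$sem, c(0.1, 0.2))

  expect_error(tumor_series("control",
                            data.frame(animal_id = "m1", day = 5,
                                       volume = 100)),
               "day-0")
  expect_error(tumor_series("control",
                            data.frame(animal_id = "m1", day = c(0, 5),
                                       volume = c(100, -3))),
               "positive")
})

test_that("step 1 recovers (T, K*) from noiseless control data", {
  truth <- model_params(7, 0.11)
  fit <- fit_step1(model_series("control", truth))
  expect_equal(fit$fitted$T_days, 7, tolerance = 0.01)
  expect_equal(fit$fitted$k_star, 0.11, tolerance = 0.01)
  expect_lt(fit$loss, 1e-8)
})

test_that("step 1 pushes K* to the lower bound on exactly exponential data", {
  days <- c(0, 5, 7, 11, 15)
  s <- tumor_series("control",
                    data.frame(animal_id = "mean", day = days,
                               volume = exp(days / 7), sem = NA_real_),
                    normalized = TRUE)
  fit <- fit_step1(s)
  expect_lt(fit$fitted$k_star, 1e-3)
  expect_equal(fit$fitted$T_days, 7, tolerance = 0.02)
})

test_that("step 1 refuses underdetermined fits (two free parameters)", {
  s <- normalize_series(mean_series("control", c(0, 7), c(158, 316)))
  expect_error(fit_step1(s), "at least 3")
  # three points in the full window but only two in the early window
  s3 <- normalize_series(mean_series("control", c(0, 7, 15),
                                     c(158, 316, 700)))
  expect_error(fit_step1(s3, fit_config(window = "early")), "at least 3")
})

test_that("steps 2 and 3 recover their single free parameter", {
  cases <- list(c(k = 0.09), c(k = 0.15))
  for (cs in cases) {
    s <- model_series("as_bcl2", model_params(7, cs[["k"]]))
    fit <- fit_step2(s, T_days = 7)
    expect_equal(fit$fitted$k_prime, cs[["k"]], tolerance = 0.01)
  }
  for (kg in c(3.5, 2)) {
    s <- model_series("anti_cd20", model_params(7, 0.11, k_kill = kg, g = 1))
    fit <- fit_step3(s, T_days = 7, k_star = 0.11)
    expect_equal(fit$fitted$k_killg, kg, tolerance = 0.01)
  }
  # ineffective antibody: recovered kill term at the lower bound
  s0 <- model_series("anti_cd20", model_params(7, 0.11))
  expect_lt(fit_step3(s0, 7, 0.11)$fitted$k_killg, 1e-3)
})

test_that("early-window fits use only days 0-7 and recover early truths", {
  # data follow K' = 0.15 up to day 7, then regrow at K' = 0.09: the
  # early-window fit must see only the first phase
  sched <- regime_schedule(list(model_params(7, 0.15), model_params(7, 0.09)),
                           start = c(0, 1))
  days <- c(0, 3, 5, 7, 11, 15, 19, 23)
  v <- simulate_regimes(sched, days / 7)$n_star
  s <- tumor_series("as_bcl2", data.frame(animal_id = "mean", day = days,
                                          volume = v, sem = NA_real_),
                    normalized = TRUE)
  fe <- fit_step2(s, 7, fit_config(window = "early"))
  expect_equal(fe$fitted$k_prime, 0.15, tolerance = 0.01)
  expect_equal(unname(fe$window), c(0, 7))
})

test_that("K' lower bound is respected on aggressively growing data", {
  days <- c(0, 5, 7, 11)
  s <- tumor_series("as_bcl2",
                    data.frame(animal_id = "mean", day = days,
                               volume = exp(2 * days / 7), sem = NA_real_),
                    normalized = TRUE)
  fit <- fit_step2(s, 7)
  expect_gte(fit$fitted$k_prime, 0)
  expect_lt(fit$fitted$k_prime, 1e-6)
})

test_that("reported loss beats every grid-search candidate", {
  set.seed(5)
  noisy <- model_series("control", model_params(7, 0.11))
  noisy$data$volume <- noisy$data$volume *
    exp(c(0, rnorm(nrow(noisy$data) - 1, 0, 0.1)))
  fit <- fit_step1(noisy)
  w <- rep(1, nrow(noisy$data))
  for (T_try in c(3, 5, 7, 9, 12, 20)) {
    for (k_try in c(0, 0.05, 0.11, 0.2, 0.5, 1)) {
      cand <- logistic_solution(model_params(T_try, k_try),
                                noisy$data$day / T_try)$n_star
      loss <- sum(w * (log(pmax(cand, 1e-12)) - log(noisy$data$volume))^2)
      expect_lte(fit$loss, loss + 1e-12)
    }
  }
})

test_that("combination prediction composes single-agent parameters", {
  days <- c(0, 5, 7, 11, 15, 19, 23)
  # mode (a): K' = 0.15, K''g = 3.5 gives slow growth (net rate 0.325)
  pred <- predict_combination(7, 0.15, 3.5, days)
  ref <- logistic_solution(model_params(7, 0.15, k_kill = 3.5, g = 1),
                           days / 7)
  expect_equal(pred$n_star, ref$n_star, tolerance = 1e-12)
  expect_true(all(diff(pred$n_star) > 0))
  expect_lt(pred$n_star[length(days)], exp(23 / 7))  # far below untreated

  # no antibody reduces the prediction to the as-bcl-2 model exactly
  pred0 <- predict_combination(7, 0.15, 0, days)
  expect_equal(pred0$n_star,
               logistic_solution(model_params(7, 0.15), days / 7)$n_star,
               tolerance = 1e-12)

  # two-phase mode with identical phases equals the single-regime mode
  pred2 <- predict_combination(7, 0.15, 3.5, days, switch_day = 7,
                               late = list(k_prime = 0.15, k_killg = 3.5))
  expect_equal(pred2$n_star, pred$n_star, tolerance = 1e-12)

  # a genuinely different late phase departs only after the switch
  pred3 <- predict_combination(7, 0.15, 3.5, days, switch_day = 7,
                               late = list(k_prime = 0.09, k_killg = 2))
  expect_equal(pred3$n_star[days <= 7], pred$n_star[days <= 7],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pred3$n_star[days > 7],
                                pred$n_star[days > 7])))
})

test_that("fit_all runs the four steps end to end on noiseless fixtures", {
  for (window in c("early", "full")) {
    fx <- dohh2_fixture(window)
    truth <- dohh2_params(window)
    fit <- fit_all(fx)
    expect_equal(fit$params$T_days, 7, tolerance = 0.01)
    expect_equal(fit$params$k_star, 0.11, tolerance = 0.01)
    expect_equal(fit$params$k_prime, truth$as_bcl2$k_star, tolerance = 0.01)
    expect_equal(fit$params$k_killg,
                 truth$anti_cd20$k_kill * truth$anti_cd20$g,
                 tolerance = 0.01)
    obs <- fit$observed_combination$volume
    expect_lt(max(abs(fit$prediction$n_star - obs) / obs), 1e-4)
    expect_length(fit$steps, 4)
    expect_length(fit$steps$step4$fitted, 0)
  }
})

test_that("fit_all names missing arms and is invariant to row order", {
  fx <- dohh2_fixture("early")
  expect_error(fit_all(fx$series["control"]), "as_bcl2.*anti_cd20")
  shuffled <- lapply(fx$series, function(s) {
    set.seed(1)
    tumor_series(s$group, s$data[sample(nrow(s$data)), ], s$normalized)
  })
  f1 <- fit_all(fx)
  f2 <- fit_all(shuffled)
  expect_identical(f1$params, f2$params)
})

test_that("identical data and configuration give bit-identical results", {
  fx <- dohh2_fixture("full")
  f1 <- fit_all(fx, fit_config(window = "full"))
  f2 <- fit_all(fx, fit_config(window = "full"))
  expect_identical(f1$steps, f2$steps)
})

test_that("two-phase prediction restarts from the carried day-7 state", {
  fx <- dohh2_fixture("early")
  fit <- fit_all(fx, predict_mode = "two_phase", switch_day = 7)
  days <- fit$observed_combination$day
  # early phase identical to the single-regime early prediction
  single <- predict_combination(fit$params$T_days,
                                0.15, 3.5, days)$n_star
  expect_equal(fit$prediction$n_star[days <= 7], single[days <= 7],
               tolerance = 1e-3)
  expect_true(all(fit$prediction$n_star >= 0))
})
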