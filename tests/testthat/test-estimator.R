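make_linear_trials <- function(n = 60, beta = c(0.04, 0.01, -0.005, 0.02, 1e-4),
                               intercept = 0.1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- cbind(n_total = rpois(n, 5), n_0_100 = rpois(n, 2),
             n_100_200 = rpois(n, 2), n_200_300 = rpois(n, 2),
             timing_variance = runif(n, 0, 8000))
  y <- intercept + X %*% beta + rnorm(n, 0, noise_sd)
  out <- tibble::as_tibble(as.data.frame(X))
  out$saliva_g <- pmax(0, as.numeric(y))
  out$subject_id <- rep(sprintf("S%02d", 1:12), length.out = n)
  out
}

test_that("near-zero penalty recovers the generating coefficients", {
  trials <- make_linear_trials(noise_sd = 0)
  m <- fit_ridge(trials, alpha = 1e-8)
  beta_raw <- m$coefficients / m$feature_scales
  expect_equal(unname(beta_raw), c(0.04, 0.01, -0.005, 0.02, 1e-4),
               tolerance = 1e-6)
  expect_equal(predict_saliva(m, trials), trials$saliva_g, tolerance = 1e-6)
})

test_that("the closed form matches direct minimization of the penalized objective", {
  trials <- make_linear_trials(noise_sd = 0.02, seed = 3)
  alpha <- 10
  m <- fit_ridge(trials, alpha = alpha)
  X <- as.matrix(trials[m$features])
  Z <- scale(X)
  yc <- trials$saliva_g - mean(trials$saliva_g)
  obj <- function(b) sum((yc - Z %*% b)^2) + alpha * sum(b^2)
  opt <- optim(rep(0, 5), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(m$coefficients), opt$par, tolerance = 1e-5)
})

test_that("shrinkage is monotone in alpha and the penalty limit is the mean", {
  trials <- make_linear_trials(noise_sd = 0.02, seed = 5)
  alphas <- c(0.01, 1, 10, 100, 1e4)
  norms <- vapply(alphas, function(a) {
    sqrt(sum(fit_ridge(trials, alpha = a)$coefficients^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  big <- fit_ridge(trials, alpha = 1e10)
  expect_equal(predict_saliva(big, trials),
               rep(mean(trials$saliva_g), nrow(trials)), tolerance = 1e-5)
})

test_that("duplicating every trial leaves the fit unchanged", {
  trials <- make_linear_trials(n = 30, noise_sd = 0.02, seed = 7)
  a <- fit_ridge(trials, alpha = 10)
  b <- fit_ridge(dplyr::bind_rows(trials, trials), alpha = 20)
  # doubling the data doubles the loss term; doubling alpha restores the
  # same standardized solution up to the n-1 vs n scale factor, so compare
  # predictions which absorb the standardization constants
  expect_equal(predict_saliva(a, trials), predict_saliva(b, trials),
               tolerance = 0.02)
})

test_that("features at the training means predict the intercept exactly", {
  trials <- make_linear_trials(seed = 9)
  m <- fit_ridge(trials, alpha = 10)
  at_means <- tibble::as_tibble(as.list(m$feature_means))
  expect_equal(predict_saliva(m, at_means), m$intercept)
})

test_that("LOOCV predictions match a hand-rolled oracle and ignore row order", {
  trials <- make_linear_trials(n = 12, noise_sd = 0.03, seed = 11)
  fitted <- loocv_ridge(trials, alpha = 10)
  for (i in c(1, 5, 12)) {
    expect_equal(fitted$.pred[i],
                 oracle_ridge_predict(trials[-i, ], trials[i, ], alpha = 10),
                 tolerance = 1e-10)
  }
  perm <- sample(nrow(trials))
  shuffled <- loocv_ridge(trials[perm, ], alpha = 10)
  expect_equal(shuffled$.pred, fitted$.pred[perm], tolerance = 1e-12)
  const <- trials
  const$saliva_g <- 0.2
  expect_equal(loocv_ridge(const, alpha = 10)$.pred, rep(0.2, 12),
               tolerance = 1e-9)
  expect_error(loocv_ridge(trials[1:2, ]), class = "salivaflow_too_few")
})

test_that("r and MAE follow their formulas, including degenerate cases", {
  m <- compute_metrics(c(0.1, 0.2), c(0.15, 0.25))
  expect_equal(m$mae, 0.05)
  expect_equal(m$r, 1)            # equal offsets are perfectly correlated
  exact <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$mae, 0)
  expect_equal(exact$r, 1)
  anti <- compute_metrics(-c(1, 2, 3) + 5, c(1, 2, 3))
  expect_equal(anti$r, -1)
  expect_warning(z <- compute_metrics(c(1, 1), c(1, 2)),
                 class = "salivaflow_r_undefined")
  expect_true(is.na(z$r))
})

test_that("moving-average MAE matches brute-force binning", {
  pred <- c(0.10, 0.14, 0.22, 0.19, 0.31, 0.27)
  truth <- c(0.12, 0.13, 0.20, 0.24, 0.28, 0.30)
  got <- moving_average_mae(pred, truth)
  want <- oracle_moving_mae(pred, truth)
  expect_equal(got$bin_center_g, want$bin_center_g)
  expect_equal(got$mae_g, want$mae_g)
  expect_equal(got$n, want$n)
  # all truths in one bin -> single point equal to the global MAE
  one <- moving_average_mae(c(0.11, 0.12), c(0.101, 0.102),
                            window_g = 0.05, overlap_g = 0.025)
  expect_equal(nrow(one), 1)
  expect_equal(one$mae_g, mean(abs(c(0.11, 0.12) - c(0.101, 0.102))))
  perfect <- moving_average_mae(truth, truth)
  expect_true(all(perfect$mae_g == 0))
  expect_error(moving_average_mae(pred, truth, window_g = 0.05,
                                  overlap_g = 0.05),
               class = "salivaflow_bad_window")
})

test_that("the half split sorts by truth and sends the median low", {
  pred <- c(0.3, 0.1, 0.4, 0.2)
  truth <- c(0.35, 0.05, 0.45, 0.15)
  hs <- split_half_mae(pred, truth)
  expect_equal(hs$mae_g[hs$half == "low"],
               mean(abs(c(0.1, 0.2) - c(0.05, 0.15))))
  expect_equal(hs$mae_g[hs$half == "high"],
               mean(abs(c(0.3, 0.4) - c(0.35, 0.45))))
  odd <- split_half_mae(c(1, 2, 3), c(1, 2, 3))
  expect_equal(odd$n, c(2, 1))
  expect_equal(split_half_mae(truth, truth)$mae_g, c(0, 0))
})

test_that("subject variability matches brute-force formulas", {
  trials <- make_linear_trials(n = 36, noise_sd = 0.05, seed = 13)
  v <- subject_variability(trials)
  by_subject <- tapply(trials$saliva_g, trials$subject_id, stats::sd)
  expect_equal(v$within_subject_sd, mean(by_subject))
  expect_equal(v$overall_sd, stats::sd(trials$saliva_g))
  const <- trials
  const$saliva_g <- 0.2
  vc <- subject_variability(const)
  expect_equal(c(vc$within_subject_sd, vc$overall_sd), c(0, 0))
  two <- tibble::tibble(subject_id = c("A", "A", "B", "B"),
                        saliva_g = c(0.1, 0.1, 0.3, 0.3))
  vt <- subject_variability(two)
  expect_equal(vt$within_subject_sd, 0)
  expect_gt(vt$overall_sd, 0)
  single <- dplyr::bind_rows(two, tibble::tibble(subject_id = "C",
                                                 saliva_g = 0.5))
  expect_warning(vs <- subject_variability(single),
                 class = "salivaflow_single_trial_subject")
  expect_equal(vs$n_subjects, 2)
})

test_that("evaluate_estimator assembles a coherent report", {
  trials <- generate_trials(n_subjects = 6, trials_per_subject = 4, seed = 31)
  ev <- evaluate_estimator(trials)
  expect_s3_class(ev, "saliva_eval")
  expect_true(ev$metrics$r >= -1 && ev$metrics$r <= 1)
  expect_gte(min(ev$mae_curve$mae_g), 0)
  expect_equal(sum(ev$half_mae$n), nrow(trials))
  g <- glance(ev)
  expect_equal(g$mae, ev$metrics$mae)
  expect_equal(nrow(tidy(ev)), nrow(trials))
})
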