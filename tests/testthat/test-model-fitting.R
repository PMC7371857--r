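# Three-stage fitting of the PAL regulation models, model selection, and
# the response-type taxonomy.

test_that("noiseless receptor-model centroids are recovered", {
  drn <- regimen_drn("acute")
  tt <- test_design()$timepoints_h
  true <- pal_model_params("receptor", ks = 1, kd = 0.2, IC50_PAL = 50)
  centroid <- simulate_pal_receptor(true, drn, tt)$PAL
  fit <- fit_pal_model(centroid, tt, "receptor", 1, drn, seed = 2,
                       affine = "none", control = fast_fit_control)
  expect_lt(fit$rss, 1e-6)
  expect_lt(abs(fit$params[["ks"]] - 1), 0.05)
  expect_lt(abs(fit$params[["kd"]] - 0.2) / 0.2, 0.05)
  expect_lt(abs(fit$params[["IC50_PAL"]] - 50) / 50, 0.05)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("a flat baseline centroid fits with (near) zero RSS", {
  tt <- seq(0, 72, 4)
  centroid <- rep(5, length(tt))
  fit <- fit_pal_model(centroid, tt, "receptor", 1, drn = 0, seed = 1,
                       affine = "fit", control = fast_fit_control)
  expect_lt(fit$rss, 1e-10)
  expect_true(is.finite(fit$a) && fit$a != 0)
})

test_that("model selection prefers the generating mechanism", {
  drn <- regimen_drn("chronic")
  tt <- make_design("chronic", replicates = 3)$timepoints_h

  # receptor-generated centroid -> receptor-mediated ranked first
  r_true <- pal_model_params("receptor", ks = 0.5, kd = 0.1, IC50_PAL = 30)
  c_r <- simulate_pal_receptor(r_true, drn, tt)$PAL
  rk <- select_model(c_r, tt, drn, seed = 3, control = fast_fit_control)
  expect_identical(rk[[1]]$model_type, "receptor")

  # biosignal tolerance-shaped centroid (excursion + full return under
  # sustained DRN) -> biosignal ranked first
  b_true <- pal_model_params("biosignal", ks = 1, kd = 0.2, IC50_PAL = 20,
                             ke = 0.05, S = 1 / 20, gamma = 1,
                             drn_sign = 1, bs_sign = -1)
  c_b <- simulate_pal_biosignal(b_true, drn, tt)$PAL
  rk2 <- select_model(c_b, tt, drn, seed = 4, control = fast_fit_control)
  expect_identical(rk2[[1]]$model_type, "biosignal")

  # single candidate returned unconditionally
  one <- select_model(c_r, tt, drn, seed = 5, control = fast_fit_control,
                      candidates = list(list(model_type = "biosignal",
                                             sign_variant = c(1, -1))))
  expect_length(one, 1)
  expect_identical(one[[1]]$model_type, "biosignal")
  expect_error(select_model(c_r, tt, drn, candidates = list()),
               class = "paldyn_usage_error")
})

test_that("response taxonomy labels constructed trajectories correctly", {
  tt <- seq(0, 170, 1)
  # flat -> persistent with zero-effect flag
  lab <- classify_response(rep(3, length(tt)), tt, "chronic")
  expect_identical(as.character(lab), "persistent")
  expect_true(attr(lab, "zero_effect"))

  # chronic excursion with full return -> tolerance
  exc <- 3 + 2 * (exp(-tt / 20) - exp(-tt / 5))
  expect_identical(classify_response(exc, tt, "chronic"), "tolerance")
  # the same shape under a bolus regimen -> transient
  expect_identical(classify_response(exc, tt, "acute"), "transient")

  # baseline crossing with a large opposite-side extremum -> rebound
  reb <- 3 + sin(tt / 18) * exp(-tt / 60)
  expect_identical(classify_response(reb, tt, "acute"), "rebound")

  # settles far from baseline, flat at horizon -> new steady state
  nss <- 3 + 2 * (1 - exp(-tt / 15))
  expect_identical(classify_response(nss, tt, "chronic"), "new_steady_state")

  # labels are invariant to affine rescaling
  for (traj in list(exc, reb, nss)) {
    l0 <- classify_response(traj, tt, "chronic")
    expect_identical(classify_response(7 - 4 * traj, tt, "chronic"), l0)
  }
})

test_that("classify_fit labels a fitted acute receptor model transient", {
  drn <- regimen_drn("acute")
  tt <- test_design()$timepoints_h
  true <- pal_model_params("receptor", ks = 1, kd = 0.2, IC50_PAL = 50)
  centroid <- simulate_pal_receptor(true, drn, tt)$PAL
  fit <- fit_pal_model(centroid, tt, "receptor", 1, drn, seed = 6,
                       affine = "none", control = fast_fit_control)
  expect_identical(classify_fit(fit, drn, seq(0, 72, 0.5), "acute"),
                   "transient")
})
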