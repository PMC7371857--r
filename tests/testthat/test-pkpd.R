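# PK, receptor and PAL ODE models against closed-form / fixed-point oracles.

test_that("acute bolus PK matches the matrix-exponential closed form", {
  pk <- pk_params("acute"); reg <- dose_regimen("acute")
  tt <- seq(0, 12, by = 0.25)
  sim <- simulate_pk(pk, reg, tt)
  M <- matrix(c(-(pk$k12 + pk$CL / pk$Vp), pk$k21, pk$k12, -pk$k21),
              2, 2, byrow = TRUE)
  oracle <- t(sapply(tt, function(t)
    as.numeric(Matrix::expm(M * t) %*% c(50, 0))))
  expect_lt(max(abs(sim$Ap - oracle[, 1]) / pmax(abs(oracle[, 1]), 1e-300)),
            1e-6)
  expect_lt(max(abs(sim$At[-1] - oracle[-1, 2]) / abs(oracle[-1, 2])), 1e-6)
  expect_equal(sim$C_MPL, 0.43 * sim$Ap / pk$Vp)
})

test_that("zero dose gives identically zero PK; mass balance holds at CL = 0", {
  pk <- pk_params("acute")
  reg0 <- structure(list(label = "acute", bolus_amount = 0, k0 = 0,
                         horizon_h = 24), class = "dose_regimen")
  sim <- simulate_pk(pk, reg0, seq(0, 24, 1))
  expect_true(all(sim$Ap == 0) && all(sim$At == 0))

  pk_nc <- pk_params("acute", CL = 1e-300)  # no clearance, no input
  sim2 <- simulate_pk(pk_nc, dose_regimen("acute"), seq(0, 24, 0.5))
  expect_equal(sim2$Ap + sim2$At, rep(50, nrow(sim2)), tolerance = 1e-8)

  expect_error(pk_params("acute", CL = -1), class = "paldyn_validation_error")
})

test_that("chronic infusion converges to k0 Vp / CL", {
  pk <- pk_params("chronic"); reg <- dose_regimen("chronic")
  sim <- simulate_pk(pk, reg, c(0, 10, 50, 170))
  ss <- 220 * 0.82 / 5.61
  expect_lt(abs(sim$Ap[3] - ss) / ss, 0.001)
  expect_lt(abs(sim$Ap[4] - ss) / ss, 1e-6)
})

test_that("drug-free receptor system holds the analytic baseline", {
  for (regimen in c("acute", "chronic")) {
    rp <- receptor_params(regimen)
    rec <- simulate_receptor(rp, 0, seq(0, 100, 2))
    expect_equal(rec$Rm, rep(rp$ksRm / rp$kdRm, nrow(rec)), tolerance = 1e-9)
    expect_equal(rec$R, rep(rp$ksR * rp$ksRm / rp$kdRm / rp$kdR, nrow(rec)),
                 tolerance = 1e-9)
    expect_true(all(rec$DR == 0) && all(rec$DRN == 0))
  }
  expect_equal(unname(receptor_baseline(receptor_params("acute"))["Rm"]),
               3.15 / 0.122)
  expect_error(simulate_receptor(receptor_params("acute"), NaN, 0:10),
               class = "paldyn_input_error")
})

test_that("constant drug drives the receptor system to the algebraic fixed point", {
  rp <- receptor_params("chronic")
  cc <- 16  # constant C_MPL
  # oracle: reduce the 4-equation steady state to a 1-D root in DRN
  res_fun <- function(drn) {
    rm <- rp$ksRm / rp$kdRm * (1 - drn / (rp$IC50Rm + drn))
    r <- (rp$ksR * rm + rp$Rf * rp$kre * drn) / (rp$kon * cc + rp$kdR)
    rp$kon * cc * r / rp$kre - drn     # DRN balance
  }
  drn_star <- stats::uniroot(res_fun, c(1e-6, 1e6), tol = 1e-12)$root
  rates <- c(rp$kdRm, rp$kdR, rp$kre, rp$kT, rp$kon * cc)
  t_eq <- 10 / min(rates)
  rec <- simulate_receptor(rp, cc, c(0, t_eq))
  expect_lt(abs(rec$DRN[2] - drn_star) / drn_star, 0.005)
  # remaining states at their implied fixed points
  rm_star <- rp$ksRm / rp$kdRm * (1 - drn_star / (rp$IC50Rm + drn_star))
  expect_lt(abs(rec$Rm[2] - rm_star) / rm_star, 0.005)
  expect_lt(abs(rec$DR[2] - rp$kre * drn_star / rp$kT) /
              (rp$kre * drn_star / rp$kT), 0.005)
})

test_that("receptor moieties are conserved in the closed limit", {
  # no synthesis, no degradation, full recycling: R + DR + DRN constant
  rp <- receptor_params("acute", ksR = 0, kdR = 0, Rf = 1)
  init <- c(Rm = 0, R = 100, DR = 0, DRN = 0)
  rec <- simulate_receptor(rp, 20, seq(0, 50, 1), init = init)
  tot <- rec$R + rec$DR + rec$DRN
  expect_equal(tot, rep(100, length(tot)), tolerance = 1e-8)
  expect_true(all(rec$DRN >= 0))
})

test_that("receptor-mediated PAL model has the right baseline and limits", {
  pp <- pal_model_params("receptor", ks = 1, kd = 0.2, IC50_PAL = 50)
  flat <- simulate_pal_receptor(pp, 0, seq(0, 72, 1))
  expect_equal(flat$PAL, rep(5, nrow(flat)), tolerance = 1e-10)

  # inhibitory, DRN >> IC50: production ~0, decay at rate kd toward 0
  ppi <- pal_model_params("receptor", ks = 1, kd = 0.2, IC50_PAL = 1,
                          drn_sign = -1)
  dec <- simulate_pal_receptor(ppi, 1e7, seq(0, 40, 1))
  expect_lt(dec$PAL[41], 5e-3 * 5 + 5 * exp(-0.2 * 40) * 1.01)
  expect_equal(dec$PAL[11] / dec$PAL[1], exp(-0.2 * 10), tolerance = 1e-3)

  # acute DRN: excursion then return to within 1% of baseline
  drn <- regimen_drn("acute")
  pal <- simulate_pal_receptor(pp, drn, seq(0, 72, 0.5))
  expect_gt(max(pal$PAL), 5 * 1.05)
  peak_drn <- max(drn$DRN)
  t_dec <- min(drn$time[drn$time > 1 & drn$DRN < 1e-3 * peak_drn])
  expect_lt(abs(pal$PAL[nrow(pal)] - 5) / 5, 0.01)
  expect_lt(t_dec, 72)

  # stimulatory PAL bounded by 2 ks/kd
  expect_lte(max(pal$PAL), 2 * 5)
  expect_error(simulate_pal_biosignal(pp, drn, 0:10),
               class = "paldyn_usage_error")
})

test_that("biosignal kinetics: first-order lag, fast-ke limit, tolerance algebra", {
  # constant DRN: BS(t) = d (1 - exp(-ke t))
  pp <- pal_model_params("biosignal", ks = 1, kd = 0.2, IC50_PAL = 20,
                         ke = 0.15, S = 0, gamma = 1, drn_sign = 1,
                         bs_sign = -1)
  d0 <- 30
  sim <- simulate_pal_biosignal(pp, d0, seq(0, 60, 1))
  expect_equal(sim$BS, d0 * (1 - exp(-0.15 * sim$time)), tolerance = 1e-7)

  # ke -> large: converges to the instantaneous-biosignal (receptor-type,
  # inhibitory) limit within 2%
  drn <- regimen_drn("chronic")
  tt <- seq(0, 170, 1)
  fast <- pal_model_params("biosignal", ks = 1, kd = 0.2, IC50_PAL = 20,
                           ke = 100, S = 0, gamma = 1, bs_sign = -1)
  lim <- pal_model_params("receptor", ks = 1, kd = 0.2, IC50_PAL = 20,
                          drn_sign = -1)
  a <- simulate_pal_biosignal(fast, drn, tt)$PAL
  b <- simulate_pal_receptor(lim, drn, tt)$PAL
  expect_lt(max(abs(a - b)) / 5, 0.02)

  # steady-state algebra: gamma = 1, S = 1/IC50 makes PAL(inf) = ks/kd
  # exactly -> an excursion that returns to baseline under sustained drug
  tol <- pal_model_params("biosignal", ks = 1, kd = 0.2, IC50_PAL = 20,
                          ke = 0.05, S = 1 / 20, gamma = 1,
                          drn_sign = 1, bs_sign = -1)
  sim2 <- simulate_pal_biosignal(tol, drn, seq(0, 1200, 2))
  expect_gt(max(abs(sim2$PAL - 5)), 0.2)       # a real excursion
  expect_lt(abs(sim2$PAL[nrow(sim2)] - 5) / 5, 0.01)  # full return

  expect_error(pal_model_params("biosignal", ks = 1, kd = 0.2, IC50_PAL = 1,
                                gamma = -1),
               class = "paldyn_validation_error")
})
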