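# MPL pharmacokinetics (two-compartment), glucocorticoid receptor dynamics,
# and the two pathway-activity regulation models, as coupled ODEs solved by
# the compiled adaptive RK45 core.

#' Two-compartment PK parameters for MPL
#'
#' Published population values: acute 50 mg/kg intravenous bolus and chronic
#' 0.3 mg/kg/h infusion studies in adrenalectomized rats (the chronic
#' zero-order input constant is used verbatim as tabulated, k0 = 220
#' mg/kg/h, despite the nominal infusion description — an inconsistency in
#' the source that is documented, not resolved).
#'
#' @param regimen `"acute"` or `"chronic"` (selects the default column).
#' @param k0 zero-order infusion rate into plasma, mg/(kg h).
#' @param CL clearance, L/(h kg).
#' @param Vp central volume of distribution, L/kg.
#' @param k12,k21 intercompartmental distribution rate constants, 1/h.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(regimen = c("acute", "chronic"),
                      k0 = NULL, CL = NULL, Vp = NULL, k12 = NULL, k21 = NULL) {
  regimen <- match.arg(regimen)
  def <- if (regimen == "acute")
    list(k0 = 0,   CL = 3.48, Vp = 0.73, k12 = 0.98, k21 = 1.78)
  else
    list(k0 = 220, CL = 5.61, Vp = 0.82, k12 = 0.32, k21 = 0.68)
  p <- list(k0 = k0 %||% def$k0, CL = CL %||% def$CL, Vp = Vp %||% def$Vp,
            k12 = k12 %||% def$k12, k21 = k21 %||% def$k21)
  if (any(unlist(p) < 0) || p$Vp <= 0 || p$CL <= 0)
    paldyn_stop("paldyn_validation_error",
                "PK parameters must be non-negative with Vp, CL > 0")
  structure(c(p, list(regimen = regimen)), class = "pk_params")
}

#' Glucocorticoid receptor model parameters
#'
#' Published fifth-generation receptor model values for acute and chronic
#' MPL administration.  `free_fraction` is the fraction of plasma drug
#' considered free, entering `C_MPL = free_fraction * Ap / Vp`.
#'
#' @param regimen `"acute"` or `"chronic"`.
#' @param ... named overrides of any parameter
#'   (`ksRm, kdRm, IC50Rm, ksR, kre, kon, kdR, kT, Rf, free_fraction`).
#' @return object of class `receptor_params`.
#' @export
receptor_params <- function(regimen = c("acute", "chronic"), ...) {
  regimen <- match.arg(regimen)
  p <- list(ksRm = if (regimen == "acute") 3.15 else 0.45,
            kdRm = 0.122, IC50Rm = 123.7,
            ksR = if (regimen == "acute") 0.84 else 3.63,
            kre = 0.402, kon = 0.019, kdR = 0.0403, kT = 58.1,
            Rf = 0.69, free_fraction = 0.43)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  if (any(unlist(p) < 0) || p$Rf > 1 || p$IC50Rm <= 0)
    paldyn_stop("paldyn_validation_error",
                "receptor rates must be >= 0, 0 <= Rf <= 1, IC50Rm > 0")
  structure(c(p, list(regimen = regimen)), class = "receptor_params")
}

#' Dosing regimen
#'
#' @param label `"acute"` or `"chronic"`.
#' @param bolus_amount intravenous bolus, mg/kg (acute default 50).
#' @param k0 zero-order infusion rate, mg/(kg h) (chronic default 220, the
#'   tabulated PK value).
#' @param horizon_h simulation horizon, hours.
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(label = c("acute", "chronic"),
                         bolus_amount = NULL, k0 = NULL, horizon_h = NULL) {
  label <- match.arg(label)
  bolus_amount <- bolus_amount %||% if (label == "acute") 50 else 0
  k0 <- k0 %||% if (label == "acute") 0 else 220
  horizon_h <- horizon_h %||% if (label == "acute") 72 else 170
  if (horizon_h <= 0)
    paldyn_stop("paldyn_validation_error", "horizon must be positive")
  if (sum(c(bolus_amount > 0, k0 > 0)) != 1)
    paldyn_stop("paldyn_validation_error",
                "exactly one of bolus_amount > 0 or k0 > 0 for a canonical regimen")
  structure(list(label = label, bolus_amount = bolus_amount, k0 = k0,
                 horizon_h = horizon_h), class = "dose_regimen")
}

# internal: coerce a driving signal into the forcing spec the C++ core
# understands.  x may be a single number, a two-column data.frame
# (time, value), a function of t (sampled on a dense grid), or an already
# built forcing list.
.as_forcing <- function(x, tmax, value_col = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$mode)) return(x)
  if (is.numeric(x) && length(x) == 1) return(list(mode = 0L, value = x))
  if (is.function(x)) {
    tt <- seq(0, tmax, length.out = 4001)
    return(list(mode = 1L, t = tt, v = vapply(tt, x, 1.0)))
  }
  if (is.data.frame(x)) {
    vc <- value_col %||% setdiff(names(x), "time")[1]
    return(list(mode = 1L, t = x$time, v = x[[vc]]))
  }
  paldyn_stop("paldyn_input_error", "cannot interpret driving signal")
}

#' Closed-form description of the plasma concentration forcing
#'
#' Diagonalizes the linear two-compartment system and returns the exact
#' biexponential-plus-steady-state form of `C_MPL(t)`, used to drive the
#' receptor ODEs without interpolation error.
#'
#' @param pk a [pk_params()] object.
#' @param regimen a [dose_regimen()] object.
#' @return forcing spec (internal list) usable as the `cmpl` argument of
#'   [simulate_receptor()].
#' @export
pk_forcing <- function(pk, regimen) {
  M <- matrix(c(-(pk$k12 + pk$CL / pk$Vp), pk$k21,
                pk$k12, -pk$k21), 2, 2, byrow = TRUE)
  k0 <- regimen$k0
  yss <- if (k0 > 0) c(k0 * pk$Vp / pk$CL, k0 * pk$k12 * pk$Vp / (pk$CL * pk$k21))
         else c(0, 0)
  y0 <- c(regimen$bolus_amount, 0)
  ev <- eigen(M)
  a <- solve(ev$vectors, y0 - yss)
  scale <- 0.43 / pk$Vp  # C_MPL = 0.43 * Ap / Vp
  list(mode = 2L,
       c1 = Re(ev$vectors[1, 1] * a[1]) * scale, l1 = Re(ev$values[1]),
       c2 = Re(ev$vectors[1, 2] * a[2]) * scale, l2 = Re(ev$values[2]),
       css = yss[1] * scale)
}

#' Simulate MPL two-compartment pharmacokinetics
#'
#' Solves `dAp/dt = k0 + k21 At - (k12 + CL/Vp) Ap`,
#' `dAt/dt = k12 Ap - k21 At` with `Ap(0)` equal to the bolus amount, and
#' reports the free plasma concentration `C_MPL = 0.43 Ap / Vp`.
#'
#' @param pk a [pk_params()] object.
#' @param regimen a [dose_regimen()] object.
#' @param times output time grid (hours), starting at 0.
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `Ap`, `At`, `C_MPL`.
#' @export
#' @examples
#' simulate_pk(pk_params("acute"), dose_regimen("acute"), seq(0, 12, 0.5))
simulate_pk <- function(pk, regimen, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pk, "pk_params"), inherits(regimen, "dose_regimen"))
  if (times[1] != 0)
    paldyn_stop("paldyn_validation_error", "time grid must start at 0")
  y0 <- c(regimen$bolus_amount, 0)
  pars <- c(regimen$k0, pk$CL, pk$Vp, pk$k12, pk$k21)
  out <- .ode_solve(1L, y0, times, pars, list(mode = 0L, value = 0),
                    rtol = rtol, atol = atol)
  data.frame(time = times, Ap = out[, 1], At = out[, 2],
             C_MPL = 0.43 * out[, 1] / pk$Vp)
}

#' Drug-free steady state of the receptor model
#' @param rp a [receptor_params()] object.
#' @return named vector `(Rm, R, DR, DRN)` with `Rm = ksRm/kdRm`,
#'   `R = ksR*Rm/kdR`, `DR = DRN = 0`.
#' @export
receptor_baseline <- function(rp) {
  Rm0 <- rp$ksRm / rp$kdRm
  c(Rm = Rm0, R = rp$ksR * Rm0 / rp$kdR, DR = 0, DRN = 0)
}

#' Simulate glucocorticoid receptor dynamics
#'
#' Solves the receptor mRNA / free receptor / cytosolic complex / nuclear
#' complex system driven by the free drug concentration `C_MPL(t)`.
#' Initial conditions default to the drug-free steady state, so with
#' `C_MPL = 0` every state stays constant.
#'
#' @param rp a [receptor_params()] object.
#' @param cmpl driving concentration: a constant, a data.frame with columns
#'   `time` and `C_MPL`, a function of time, or a [pk_forcing()] spec
#'   (exact, recommended).
#' @param times output time grid (hours).
#' @param init optional initial state `(Rm, R, DR, DRN)`.
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `Rm`, `R`, `DR`, `DRN`.
#' @export
simulate_receptor <- function(rp, cmpl, times, init = NULL,
                              rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(rp, "receptor_params"))
  if (is.numeric(cmpl) && any(!is.finite(cmpl)))
    paldyn_stop("paldyn_input_error", "C_MPL input must be finite")
  forcing <- .as_forcing(cmpl, max(times), value_col = "C_MPL")
  if (forcing$mode == 1L && any(!is.finite(forcing$v)))
    paldyn_stop("paldyn_input_error", "C_MPL input must be finite")
  y0 <- init %||% receptor_baseline(rp)
  pars <- c(rp$ksRm, rp$kdRm, rp$IC50Rm, rp$ksR, rp$kre, rp$kon, rp$kdR,
            rp$kT, rp$Rf)
  out <- .ode_solve(2L, y0, times, pars, forcing, rtol = rtol, atol = atol)
  data.frame(time = times, Rm = out[, 1], R = out[, 2], DR = out[, 3],
             DRN = out[, 4])
}

#' Pathway-activity model parameters
#'
#' @param model_type `"receptor"` (saturable DRN-driven indirect response)
#'   or `"biosignal"` (DRN-driven intermediate biosignal with Hill-type
#'   opposing action).
#' @param ks activation rate of pathway activity (activity/h).
#' @param kd deactivation rate (1/h).
#' @param IC50_PAL driver level for half-maximal modulation (> 0).
#' @param drn_sign +1 (stimulatory DRN term) or -1 (inhibitory).
#' @param bs_sign the opposing biosignal sign (defaults to `-drn_sign`).
#' @param ke biosignal turnover rate (1/h; biosignal model only).
#' @param S stimulation constant for DRN (biosignal model only).
#' @param gamma Hill amplification factor (>= 0; biosignal model only).
#' @return object of class `pal_model_params`.
#' @export
pal_model_params <- function(model_type = c("receptor", "biosignal"),
                             ks, kd, IC50_PAL, drn_sign = 1,
                             bs_sign = -drn_sign,
                             ke = NULL, S = NULL, gamma = NULL) {
  model_type <- match.arg(model_type)
  if (ks <= 0 || kd <= 0 || IC50_PAL <= 0)
    paldyn_stop("paldyn_validation_error", "ks, kd, IC50_PAL must be > 0")
  if (!drn_sign %in% c(-1, 1))
    paldyn_stop("paldyn_validation_error", "drn_sign must be +1 or -1")
  if (model_type == "biosignal") {
    ke <- ke %||% 0.1; S <- S %||% 0; gamma <- gamma %||% 1
    if (ke <= 0) paldyn_stop("paldyn_validation_error", "ke must be > 0")
    if (gamma < 0) paldyn_stop("paldyn_validation_error", "gamma must be >= 0")
    if (!bs_sign %in% c(-1, 1))
      paldyn_stop("paldyn_validation_error", "bs_sign must be +1 or -1")
  }
  structure(list(model_type = model_type, ks = ks, kd = kd,
                 IC50_PAL = IC50_PAL, drn_sign = drn_sign, bs_sign = bs_sign,
                 ke = ke, S = S, gamma = gamma),
            class = "pal_model_params")
}

#' Simulate the receptor-mediated PAL model
#'
#' `dPAL/dt = ks (1 +/- DRN/(IC50_PAL + DRN)) - kd PAL`, starting from the
#' drug-free baseline `PAL(0) = ks/kd`.
#'
#' @param pal_params a [pal_model_params()] with `model_type = "receptor"`.
#' @param drn driving DRN signal: constant, data.frame (`time`, `DRN`),
#'   function, or forcing spec.
#' @param times output time grid.
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `PAL`.
#' @export
simulate_pal_receptor <- function(pal_params, drn, times,
                                  rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pal_params, "pal_model_params"))
  if (pal_params$model_type != "receptor")
    paldyn_stop("paldyn_usage_error",
                "simulate_pal_receptor requires model_type = 'receptor'")
  forcing <- .as_forcing(drn, max(times), value_col = "DRN")
  pars <- c(pal_params$ks, pal_params$kd, pal_params$IC50_PAL,
            pal_params$drn_sign)
  y0 <- pal_params$ks / pal_params$kd
  out <- .ode_solve(3L, y0, times, pars, forcing, rtol = rtol, atol = atol)
  data.frame(time = times, PAL = out[, 1])
}

#' Simulate the biosignal-mediated PAL model
#'
#' `dBS/dt = ke (DRN - BS)`;
#' `dPAL/dt = ks (1 +/- S DRN) (1 -/+ BS^gamma/(IC50^gamma + BS^gamma)) - kd PAL`,
#' with `BS(0) = 0` and `PAL(0) = ks/kd`.  All four sign combinations are
#' supported via `drn_sign` / `bs_sign`.
#'
#' @param pal_params a [pal_model_params()] with `model_type = "biosignal"`.
#' @inheritParams simulate_pal_receptor
#' @return data.frame with columns `time`, `BS`, `PAL`.
#' @export
simulate_pal_biosignal <- function(pal_params, drn, times,
                                   rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pal_params, "pal_model_params"))
  if (pal_params$model_type != "biosignal")
    paldyn_stop("paldyn_usage_error",
                "simulate_pal_biosignal requires model_type = 'biosignal'")
  if (pal_params$gamma < 0)
    paldyn_stop("paldyn_validation_error", "gamma must be >= 0")
  forcing <- .as_forcing(drn, max(times), value_col = "DRN")
  pars <- c(pal_params$ks, pal_params$kd, pal_params$IC50_PAL,
            pal_params$ke, pal_params$S, pal_params$gamma,
            pal_params$drn_sign, pal_params$bs_sign)
  y0 <- c(0, pal_params$ks / pal_params$kd)
  out <- .ode_solve(4L, y0, times, pars, forcing, rtol = rtol, atol = atol)
  data.frame(time = times, BS = out[, 1], PAL = out[, 2])
}
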