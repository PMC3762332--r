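# 1:1 Langmuir kinetic analysis of label-free (OIRD-style) sensorgrams.
# Association: S(t) = S_eq (1 - exp(-(k_on C + k_off) t)), with
# S_eq = S_max C / (C + K_D) and K_D = k_off / k_on.
# Dissociation (after the buffer wash): S(t) = S_0 exp(-k_off t).
# Fitting is two-stage for identifiability: k_off first from the wash
# phase, then the observed rate k_obs = k_on C + k_off and the plateau
# from the association phase with k_off held fixed.

#' Association-phase signal of the 1:1 Langmuir model
#'
#' @param t time since analyte injection, s (>= 0).
#' @param kOn association rate constant, 1/(M s) (> 0).
#' @param kOff dissociation rate constant, 1/s (>= 0).
#' @param conc analyte concentration, M (> 0).
#' @param sMax maximal binding signal.
#' @return signal S(t) = S_eq (1 - exp(-(k_on C + k_off) t)) with
#'   S_eq = S_max C / (C + k_off/k_on).
#' @examples
#' modelAssociation(1e6, 1e4, 1e-3, 1e-7, 1)  # -> S_eq = 0.5
#' @export
modelAssociation <- function(t, kOn, kOff, conc, sMax) {
  if (kOn <= 0 || kOff < 0 || conc <= 0)
    stop("rate constants must satisfy k_on > 0, k_off >= 0, C > 0")
  stopifnot(all(t >= 0))
  kD <- kOff / kOn
  sEq <- sMax * conc / (conc + kD)
  sEq * (1 - exp(-(kOn * conc + kOff) * t))
}

#' Dissociation-phase signal of the 1:1 Langmuir model
#'
#' @param t time since the buffer wash, s (>= 0).
#' @param s0 signal at the wash time.
#' @param kOff dissociation rate constant, 1/s (>= 0).
#' @return signal S(t) = S_0 exp(-k_off t).
#' @export
modelDissociation <- function(t, s0, kOff) {
  if (kOff < 0) stop("k_off must be >= 0")
  stopifnot(all(t >= 0))
  s0 * exp(-kOff * t)
}

failedFit <- function(conc, msg) {
  new("KineticFit", kOn = NA_real_, kOff = NA_real_, kD = NA_real_,
      sMax = NA_real_, concentration = conc, rms = NA_real_,
      converged = FALSE, message = msg)
}

#' Fit a sensorgram with the 1:1 Langmuir model
#'
#' Two-stage nonlinear least squares: (1) k_off from the dissociation
#' phase (t >= `tWash`), initialized by log-linear regression of the
#' decay; (2) with k_off fixed, the association phase (t <= `tWash`) is
#' fit as S = A (1 - exp(-k_obs t)) with k_obs >= k_off, initialized from
#' the plateau and the 63%-rise time. Then k_on = (k_obs - k_off)/C,
#' K_D = k_off/k_on and S_max = A (C + K_D)/C. A signal that never rises
#' above the noise (no binding, the "NB" case) or a non-converging
#' optimization yields a fit-failure result carrying diagnostics, never a
#' silent number. Points at t < 0, if present, are treated as
#' pre-injection baseline and their mean is subtracted.
#'
#' @param times sampling times, s (association starts at t = 0).
#' @param signals measured signals.
#' @param conc analyte concentration, M.
#' @param tWash time of dissociation onset (buffer wash), s.
#' @param joint if `TRUE`, refine all parameters jointly over both phases
#'   after the two-stage fit.
#' @param weighting `"proportional"` (default) weights residuals by
#'   1/signal^2, the correct inverse-variance weighting when measurement
#'   noise scales with the signal (as it does for reflectivity readouts);
#'   weights are floored at 5% of the phase maximum to keep near-zero
#'   points from dominating. `"none"` gives ordinary least squares.
#' @return a [KineticFit-class].
#' @export
fitSensorgram <- function(times, signals, conc, tWash, joint = FALSE,
                          weighting = c("proportional", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(times) == length(signals), conc > 0)
  ord <- order(times)
  times <- times[ord]; signals <- signals[ord]
  pre <- times < 0
  if (any(pre)) {
    signals <- signals - mean(signals[pre])
    times <- times[!pre]; signals <- signals[!pre]
  }
  assoc <- times <= tWash
  dissoc <- times >= tWash
  if (sum(assoc) < 5L || sum(dissoc) < 5L)
    return(failedFit(conc, "need >= 5 points in each phase"))
  ta <- times[assoc]; sa <- signals[assoc]
  td <- times[dissoc] - tWash; sd_ <- signals[dissoc]
  amp <- max(sa) - min(sa)
  if (!is.finite(amp) || amp <= 0)
    return(failedFit(conc, "no binding: flat signal"))

  # stage 1: k_off from the dissociation decay
  pos <- sd_ > 0
  if (sum(pos) < 5L)
    return(failedFit(conc, "no binding: non-positive dissociation signal"))
  init <- stats::coef(stats::lm(log(sd_[pos]) ~ td[pos]))
  koffInit <- max(-init[[2L]], 1e-8)
  s0Init <- exp(init[[1L]])
  wts <- function(y) {
    if (weighting == "none") return(rep(1, length(y)))
    1 / pmax(y, 0.05 * max(y))^2
  }
  dfit <- tryCatch(
    minpack.lm::nlsLM(y ~ s0 * exp(-koff * x),
                      data = data.frame(x = td, y = sd_),
                      start = list(s0 = s0Init, koff = koffInit),
                      weights = wts(sd_),
                      lower = c(s0 = 0, koff = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(dfit)) return(failedFit(conc, "dissociation fit failed"))
  koff <- stats::coef(dfit)[["koff"]]

  # stage 2: association with k_off fixed
  aInit <- mean(utils::tail(sa, max(3L, length(sa) %/% 10L)))
  if (aInit <= 0) return(failedFit(conc, "no binding: no association rise"))
  t63 <- ta[which(sa >= (1 - exp(-1)) * aInit)[1L]]
  kobsInit <- if (is.na(t63) || t63 <= 0) koff + 1 / max(ta) else 1 / t63
  kobsInit <- max(kobsInit, koff * (1 + 1e-6) + 1e-9)
  afit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-kobs * x)),
                      data = data.frame(x = ta, y = sa),
                      start = list(a = aInit, kobs = kobsInit),
                      weights = wts(sa),
                      lower = c(a = 0, kobs = koff + 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(afit)) return(failedFit(conc, "association fit failed"))
  a <- stats::coef(afit)[["a"]]
  kobs <- stats::coef(afit)[["kobs"]]

  if (joint) {
    jfit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ ifelse(x <= tWash,
                   a * (1 - exp(-kobs * x)),
                   a * (1 - exp(-kobs * tWash)) *
                     exp(-koff * (x - tWash))),
        data = data.frame(x = times, y = signals),
        weights = wts(signals),
        start = list(a = a, kobs = kobs, koff = koff),
        lower = c(a = 0, kobs = 1e-12, koff = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(jfit)) {
      a <- stats::coef(jfit)[["a"]]
      kobs <- stats::coef(jfit)[["kobs"]]
      koff <- stats::coef(jfit)[["koff"]]
    }
  }

  kon <- (kobs - koff) / conc
  if (!is.finite(kon) || kon <= 0)
    return(failedFit(conc, "k_obs did not exceed k_off: k_on unresolved"))
  kd <- koff / kon
  sMax <- a * (conc + kd) / conc
  pred <- c(a * (1 - exp(-kobs * ta)),
            a * (1 - exp(-kobs * tWash)) * exp(-koff * td))
  obs <- c(sa, sd_)
  rms <- sqrt(mean((obs - pred)^2))
  new("KineticFit", kOn = kon, kOff = koff, kD = kd, sMax = sMax,
      concentration = conc, rms = rms, converged = TRUE,
      message = "ok")
}

#' Average K_D over fits at two analyte concentrations
#'
#' The reported affinity is the arithmetic mean of the per-concentration
#' K_D estimates. A discordance ratio (max/min) above `discordanceLimit`
#' raises a warning flag; if one fit failed, the surviving estimate is
#' reported flagged `single_concentration`.
#'
#' @param fitA,fitB [KineticFit-class] objects at different
#'   concentrations.
#' @param discordanceLimit ratio beyond which the two estimates are
#'   flagged discordant (default 3).
#' @return list with `kD` (averaged, `NA` if both failed), `kDs`
#'   (per-concentration values), `discordance` (max/min ratio),
#'   `flags` (character vector).
#' @export
averageKd <- function(fitA, fitB, discordanceLimit = 3) {
  stopifnot(is(fitA, "KineticFit"), is(fitB, "KineticFit"))
  fits <- list(fitA, fitB)
  okv <- vapply(fits, function(f) f@converged, logical(1L))
  kds <- vapply(fits, function(f) f@kD, numeric(1L))
  flags <- character()
  if (!any(okv))
    return(list(kD = NA_real_, kDs = kds, discordance = NA_real_,
                flags = "no_converged_fit"))
  if (!all(okv)) {
    flags <- c(flags, "single_concentration")
    return(list(kD = kds[okv], kDs = kds, discordance = NA_real_,
                flags = flags))
  }
  disc <- max(kds) / min(kds)
  if (disc > discordanceLimit) flags <- c(flags, "discordant")
  list(kD = mean(kds), kDs = kds, discordance = disc, flags = flags)
}
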