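## BLI-like dissociation kinetics and the CTP retention model.

#' Construct a SensorTrace
#' @param time numeric, seconds.
#' @param signal numeric, sensor signal.
#' @param phase character per point: "baseline", "association",
#'   "dissociation".
#' @param metadata list.
#' @return a \linkS4class{SensorTrace}.
#' @export
sensorTrace <- function(time, signal, phase, metadata = list()) {
  new("SensorTrace", time = as.numeric(time), signal = as.numeric(signal),
      phase = as.character(phase), metadata = metadata)
}

setMethod("show", "SensorTrace", function(object) {
  cat(sprintf("SensorTrace: %d points (%s)\n", length(object@time),
              paste(unique(object@phase), collapse = ", ")))
})

#' Fit the apparent dissociation rate of a sensor trace
#'
#' Fits \eqn{A e^{-k_{app} t} + c} to the dissociation phase (time
#' re-zeroed to the phase start) by Levenberg-Marquardt least squares.
#' The baseline offset \code{c} is estimated, not assumed zero. A trace
#' that does not decay returns \code{kApp = 0} with \code{zeroRate = TRUE}
#' rather than an error.
#'
#' @param trace a \linkS4class{SensorTrace} whose dissociation phase has
#'   >= 10 points and positive initial amplitude.
#' @return list: \code{kApp} (1/s), \code{se}, \code{amplitude},
#'   \code{offset}, \code{converged}, \code{zeroRate}.
#' @export
fitOffRate <- function(trace) {
  stopifnot(is(trace, "SensorTrace"))
  sel <- trace@phase == "dissociation"
  if (sum(sel) < 10)
    stop("dissociation phase needs >= 10 points")
  t <- trace@time[sel]; y <- trace@signal[sel]
  t <- t - t[1]
  a0 <- y[1] - min(y)
  if (a0 <= 0 || y[1] <= min(y) + .Machine$double.eps)
    return(list(kApp = 0, se = NA_real_, amplitude = 0, offset = mean(y),
                converged = TRUE, zeroRate = TRUE))
  ## log-linear start for k on the upper half of the decay
  c0 <- min(y)
  pos <- y - c0 > a0 * 0.05
  k0 <- if (sum(pos) >= 2)
    max(-stats::coef(stats::lm(log(y[pos] - c0 + a0 * 1e-3) ~ t[pos]))[2],
        1e-6) else 1 / max(t)
  fit <- minpack.lm::nls.lm(
    par = c(A = a0, k = k0, c = c0),
    fn = function(p) p["A"] * exp(-p["k"] * t) + p["c"] - y,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 500))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("off-rate fit did not converge (nls.lm info ", fit$info, ")")
  k <- fit$par[["k"]]
  if (k < 0) return(list(kApp = 0, se = NA_real_,
                         amplitude = fit$par[["A"]],
                         offset = fit$par[["c"]],
                         converged = converged, zeroRate = TRUE))
  se <- tryCatch(sqrt(diag(vcov(fit)))[2], error = function(e) NA_real_)
  list(kApp = k, se = unname(se), amplitude = fit$par[["A"]],
       offset = fit$par[["c"]], converged = converged, zeroRate = FALSE)
}

#' Apparent unloading rate under CTP re-capture (retention model)
#'
#' After CTP hydrolysis a loaded clamp either re-binds CTP before opening
#' (and stays on DNA) or opens and unloads. With fast nucleotide exchange
#' the re-capture probability is \eqn{[CTP]/([CTP] + K_{d,CTP})}, so the
#' apparent unloading rate is
#' \deqn{k_{app} = k_h \frac{K_{d,CTP}}{[CTP] + K_{d,CTP}}.}
#' It equals \eqn{k_h} without CTP, halves at \eqn{[CTP] = K_{d,CTP}}
#' (half-maximal retention at the CTP affinity), and decreases strictly
#' with CTP, bounded in \eqn{(0, k_h]}.
#'
#' @param ctp CTP concentration (uM), >= 0; vectorized.
#' @param kH hydrolysis rate (1/s or 1/min; output inherits the unit).
#' @param kdCTP CTP dissociation constant (uM), > 0.
#' @return apparent unloading rate, same unit as \code{kH}.
#' @export
retentionModel <- function(ctp, kH, kdCTP) {
  stopifnot(all(ctp >= 0), kH >= 0, kdCTP > 0)
  kH * kdCTP / (ctp + kdCTP)
}

#' CTP concentration of half-maximal retention
#'
#' Solves \code{retentionModel(ctp, kH, kdCTP) == kH / 2} for the CTP
#' concentration numerically (monotone bisection via \code{uniroot}).
#'
#' @param kH hydrolysis rate.
#' @param kdCTP CTP dissociation constant (uM).
#' @param upper search upper bound (uM).
#' @return CTP concentration (uM) at which the apparent unloading rate is
#'   half of \code{kH}.
#' @export
retentionHalfMax <- function(kH, kdCTP, upper = 1e4) {
  stopifnot(kH > 0, kdCTP > 0)
  f <- function(ctp) retentionModel(ctp, kH, kdCTP) - kH / 2
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-10)$root
}
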