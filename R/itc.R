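## ITC: the 1:1 Wiseman isotherm, the displaced-volume injection heats,
## and Levenberg-Marquardt refinement of (K, dH).

#' Cumulative binding heat of a 1:1 isotherm
#'
#' Evaluates the closed-form total heat content of the cell for a 1:1
#' binding model,
#' \deqn{Q = \frac{M_t \Delta H V_o}{2}\left[1 + \frac{X_t}{M_t} +
#'   \frac{1}{K M_t} - \sqrt{\left(1 + \frac{X_t}{M_t} +
#'   \frac{1}{K M_t}\right)^2 - \frac{4 X_t}{M_t}}\right]}
#' which equals \eqn{\Delta H V_o [\mathrm{complex}]} with the complex
#' concentration from the binding quadratic. The discriminant is clipped
#' at zero against round-off; a genuinely negative discriminant is a
#' parameter error.
#'
#' @param K association constant (1/uM), > 0.
#' @param dH molar heat of binding (kcal/mol of ligand).
#' @param Mt cell macromolecule concentration (uM), > 0.
#' @param Xt cumulative ligand concentration (uM), >= 0. Vectorized over
#'   \code{Mt}/\code{Xt}.
#' @param Vo cell volume (uL).
#' @return heat content in kcal * uM * uL / 1e9 units consistent with the
#'   inputs (callers normalize per mole of injectant; only ratios matter
#'   for fitting).
#' @export
wisemanHeat <- function(K, dH, Mt, Xt, Vo) {
  stopifnot(K > 0, all(Mt > 0), all(Xt >= 0), Vo > 0)
  r <- 1 + Xt / Mt + 1 / (K * Mt)
  disc <- r^2 - 4 * Xt / Mt
  if (any(disc < -1e-8))
    stop("negative discriminant: inconsistent (K, Mt, Xt) parameterization")
  disc <- pmax(disc, 0)
  Mt * dH * Vo / 2 * (r - sqrt(disc))
}

## dilution recursion for a perfusion (constant-volume) cell:
## each injection of dv displaces a fraction dv/Vo of the cell content
.itcSchedule <- function(vo, dvi, m0, xsyringe) {
  n <- length(dvi)
  mt <- xt <- numeric(n)
  m <- m0; x <- 0
  for (i in seq_len(n)) {
    d <- dvi[i] / vo
    m <- m * (1 - d)
    x <- x * (1 - d) + xsyringe * d
    mt[i] <- m; xt[i] <- x
  }
  list(mt = mt, xt = xt)
}

#' Model per-injection heats for a titration
#'
#' Applies the displaced-volume correction
#' \deqn{\Delta Q(i) = Q(i) + \frac{dV_i}{V_o}\,
#'   \frac{Q(i) + Q(i-1)}{2} - Q(i-1), \qquad Q(0) = 0,}
#' to the cumulative heats of \code{\link{wisemanHeat}} evaluated at the
#' experiment's per-injection (diluted) concentrations, then normalizes
#' per mole of injectant so the result is comparable to Wiseman-plot
#' heats in kcal/mol.
#'
#' @param exp a \linkS4class{TitrationExperiment} (its \code{mt}, \code{xt},
#'   \code{dvi}, \code{vo} and \code{xsyringe} define the schedule).
#' @param K association constant (1/uM).
#' @param dH molar heat (kcal/mol injectant).
#' @param normalize divide by moles of injectant (Wiseman convention)?
#'   With \code{FALSE} the raw corrected heats \eqn{\Delta Q(i)} are
#'   returned (useful for degenerate diagnostic schedules with
#'   \code{dvi = 0}, where the per-mole normalization is undefined).
#' @return numeric vector of model heats (kcal/mol injectant, or raw
#'   heat units when \code{normalize = FALSE}).
#' @export
injectionHeats <- function(exp, K, dH, normalize = TRUE) {
  stopifnot(is(exp, "TitrationExperiment"))
  Q <- wisemanHeat(K, dH, exp@mt, exp@xt, exp@vo)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q + (exp@dvi / exp@vo) * (Q + Qprev) / 2 - Qprev
  if (!normalize) return(dQ)
  ## per mole of injected ligand: dvi * xsyringe (volume * concentration)
  dQ / (exp@dvi * exp@xsyringe)
}

#' Construct a TitrationExperiment
#'
#' Builds the injection schedule by the constant-volume dilution
#' recursion and attaches observed heats (if any).
#'
#' @param vo cell volume (uL).
#' @param dvi injection volumes (uL); a scalar is recycled.
#' @param m0 initial cell macromolecule concentration (uM).
#' @param xsyringe syringe ligand concentration (uM).
#' @param nInjections number of injections when \code{dvi} is scalar.
#' @param heats observed per-injection heats (kcal/mol injectant);
#'   defaults to NA.
#' @param metadata list.
#' @return a \linkS4class{TitrationExperiment}.
#' @export
titrationExperiment <- function(vo = 280, dvi = 2, m0 = 100,
                                xsyringe = 2000, nInjections = 20,
                                heats = NULL, metadata = list()) {
  if (length(dvi) == 1L) dvi <- rep(dvi, nInjections)
  sched <- .itcSchedule(vo, dvi, m0, xsyringe)
  if (is.null(heats)) heats <- rep(NA_real_, length(dvi))
  new("TitrationExperiment", vo = as.numeric(vo), dvi = as.numeric(dvi),
      mt = sched$mt, xt = sched$xt, heats = as.numeric(heats),
      xsyringe = as.numeric(xsyringe),
      metadata = c(metadata, list(m0 = m0)))
}

setMethod("show", "TitrationExperiment", function(object) {
  n <- length(object@dvi)
  cat(sprintf(
    "TitrationExperiment: %d injections, Vo = %g uL, cell %g -> %g uM, ligand up to %g uM\n",
    n, object@vo, object@mt[1], object@mt[n], object@xt[n]))
  if (!all(is.na(object@heats)))
    cat(sprintf("  heats: %g .. %g kcal/mol injectant\n",
                object@heats[1], object@heats[n]))
})

#' Fit a 1:1 binding isotherm to titration heats
#'
#' Levenberg-Marquardt (damped iterative least squares) refinement of the
#' association constant K and molar heat dH against the observed
#' per-injection heats, with the model of \code{\link{injectionHeats}}.
#' Deterministic initialization: dH from the first-injection heat, K from
#' the inflection injection (steepest heat change). K is optimized on a
#' log scale to keep it positive. Iterations stop when the relative loss
#' change falls below \code{ftol} or after \code{maxIter} iterations;
#' non-convergence is flagged, never silent.
#'
#' @param exp a \linkS4class{TitrationExperiment} with >= 5 observed heats
#'   spanning the transition.
#' @param ftol relative loss-change convergence tolerance.
#' @param maxIter iteration cap.
#' @return list: \code{K} (1/uM), \code{Kd} (uM), \code{dH} (kcal/mol),
#'   \code{se} (asymptotic SEs for K and dH), \code{converged},
#'   \code{residuals}, \code{fitted}.
#' @export
fitITC <- function(exp, ftol = 1e-10, maxIter = 500) {
  stopifnot(is(exp, "TitrationExperiment"))
  obs <- exp@heats
  if (sum(is.finite(obs)) < 5)
    stop("need >= 5 observed injection heats")
  dH0 <- obs[1]
  infl <- which.max(abs(diff(obs))) + 1L
  K0 <- 2 / exp@mt[infl]            # Kd guess: half the cell concentration
  resid <- function(par) {
    injectionHeats(exp, exp(par[1]), par[2]) - obs
  }
  fit <- minpack.lm::nls.lm(
    par = c(logK = log(K0), dH = dH0), fn = resid,
    control = minpack.lm::nls.lm.control(ftol = ftol, maxiter = maxIter))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("ITC fit did not converge (nls.lm info ", fit$info, "): ",
            fit$message)
  K <- exp(fit$par[["logK"]])
  dH <- fit$par[["dH"]]
  ## delta method for K = exp(logK)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  list(K = K, Kd = 1 / K, dH = dH,
       se = c(K = unname(se[1]) * K, dH = unname(se[2])),
       converged = converged, iterations = fit$niter,
       residuals = fit$fvec, fitted = obs - fit$fvec)
}
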