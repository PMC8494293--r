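## Exact stochastic simulation (direct method) and trajectory summaries.

## md5 of the serialized object; enough to fingerprint a network
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Simulate a reaction network exactly (direct method)
#'
#' Draws a statistically exact sample path of the network's Markov jump
#' process: exponential waiting times from the total propensity, reaction
#' choice proportional to individual propensities. The trajectory records
#' the event log (up to \code{maxStore} events), per-reaction firing
#' counts, time-averaged species means after \code{burnIn} with batch
#' means for standard errors, and the post-burn-in hydrolysis event count.
#' The same (seed, network) pair always yields the same trajectory.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param tEnd simulated time (s), > 0.
#' @param seed integer seed (mandatory).
#' @param burnIn time excluded from the averages; default 10x the slowest
#'   network timescale (capped at \code{tEnd / 2}).
#' @param maxStore cap on stored events (the simulation itself always runs
#'   to \code{tEnd}); 0 disables event storage.
#' @param nBatch number of batches for standard-error estimation.
#' @return a \linkS4class{Trajectory}.
#' @export
simulateNetwork <- function(network, tEnd, seed, burnIn = NULL,
                            maxStore = 1e6, nBatch = 20L) {
  stopifnot(is(network, "ReactionNetwork"), tEnd > 0)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (is.null(burnIn)) {
    pos <- network@rates[network@rates > 0]
    burnIn <- if (length(pos)) min(10 / min(pos), tEnd / 2) else 0
  }
  stopifnot(burnIn >= 0, burnIn < tEnd)
  res <- .withSeed(seed, .ssa_direct(
    unname(network@species), network@reactants, network@products,
    network@rates, tEnd, burnIn, network@hydrolysisReactions,
    as.integer(maxStore), as.integer(nBatch)))
  sn <- names(network@species)
  tavg <- res$tavg; names(tavg) <- sn
  batch <- res$batch; colnames(batch) <- sn
  fin <- res$final; names(fin) <- sn
  new("Trajectory",
      times = res$times, reactionIds = res$reaction,
      initialState = network@species, finalState = fin,
      firedTotal = res$fired_total, firedPost = res$fired_post,
      tavgMean = tavg, batchMeans = batch,
      hydrolysisCount = res$hydrolysis_post, tEnd = tEnd, burnIn = burnIn,
      metadata = list(seed = as.integer(seed),
                      networkHash = .hashObject(network),
                      nEvents = res$n_events, truncated = res$truncated,
                      conserved = network@conserved,
                      hydrolysisReactions = network@hydrolysisReactions,
                      volumeFactor = network@volumeFactor,
                      reactionNames = network@reactionNames))
}

## evaluate an expression under a temporary RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Monte Carlo standard errors of the time-averaged species means
#' @param trajectory a \linkS4class{Trajectory}.
#' @return named numeric vector (batch-means standard errors).
#' @export
tavgSE <- function(trajectory) {
  b <- trajectory@batchMeans
  apply(b, 2, stats::sd) / sqrt(nrow(b))
}

setMethod("speciesNames", "Trajectory", function(x) names(x@initialState))

#' Reconstruct the species copy-number series from the event log
#'
#' @param trajectory a \linkS4class{Trajectory} whose event log was not
#'   truncated.
#' @param network the \linkS4class{ReactionNetwork} it was simulated from.
#' @return data.frame: time, reaction id, then one column per species.
#' @export
trajectoryStates <- function(trajectory, network) {
  if (isTRUE(trajectory@metadata$truncated))
    stop("event log was truncated; rerun with a larger maxStore")
  if (!identical(trajectory@metadata$networkHash, .hashObject(network)))
    stop("trajectory was not simulated from this network")
  S <- network@products - network@reactants
  n <- length(trajectory@times)
  out <- matrix(0, nrow = n + 1L, ncol = nrow(S))
  out[1L, ] <- network@species
  if (n > 0) {
    inc <- t(S[, trajectory@reactionIds, drop = FALSE])
    out[-1L, ] <- apply(inc, 2, cumsum) + rep(network@species,
                                              each = n)
  }
  df <- data.frame(time = c(0, trajectory@times),
                   reaction = c(NA_integer_, trajectory@reactionIds))
  st <- as.data.frame(out)
  names(st) <- names(network@species)
  cbind(df, st)
}

#' Hydrolysis flux of a trajectory
#'
#' Post-burn-in cumulative hydrolysis events divided by the number of ParB
#' copies and by the elapsed time: the per-enzyme turnover rate the
#' malachite-green CTPase assay measures (1/s; multiply by 60 for 1/min).
#'
#' @param x a \linkS4class{Trajectory}.
#' @param burnIn burn-in time; defaults to the trajectory's own. A
#'   different value requires a complete event log.
#' @param ... unused.
#' @return numeric(1), hydrolysis events per ParB per second.
#' @export
setMethod("hydrolysisFlux", "Trajectory", function(x, burnIn = NULL, ...) {
  co <- x@metadata$conserved
  if (is.null(co$ParB)) stop("network reports no conserved ParB moiety")
  nParB <- sum(co$ParB * x@initialState[names(co$ParB)])
  if (nParB == 0) stop("no ParB copies in the network")
  if (is.null(burnIn) || isTRUE(all.equal(burnIn, x@burnIn))) {
    span <- x@tEnd - x@burnIn
    if (span <= 0) stop("zero post-burn-in duration")
    return(x@hydrolysisCount / nParB / span)
  }
  if (burnIn >= x@tEnd) stop("zero post-burn-in duration")
  if (isTRUE(x@metadata$truncated))
    stop("event log truncated: cannot recount with a different burn-in")
  ## recount from the event log
  isH <- x@reactionIds %in% x@metadata$hydrolysisReactions
  sum(isH & x@times > burnIn) / nParB / (x@tEnd - burnIn)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %.0f events over %g s (burn-in %g s), seed %d\n",
              object@metadata$nEvents, object@tEnd, object@burnIn,
              object@metadata$seed))
  cat("time-averaged copy numbers (post burn-in):\n")
  print(signif(object@tavgMean, 4))
})

#' Write a trajectory event table (TSV: time, reaction id, reaction name)
#' @param trajectory a \linkS4class{Trajectory}.
#' @param file path.
#' @export
writeTrajectory <- function(trajectory, file) {
  df <- data.frame(
    time = trajectory@times,
    reaction = trajectory@reactionIds,
    name = trajectory@metadata$reactionNames[trajectory@reactionIds])
  writeTSV(df, file, comment = c(
    sprintf("seed=%d network=%s tEnd=%g burnIn=%g",
            trajectory@metadata$seed, trajectory@metadata$networkHash,
            trajectory@tEnd, trajectory@burnIn),
    "time: s; reaction: index into the network reaction list"))
}
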