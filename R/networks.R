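## Builders for the stochastic reaction networks: the coarse clamp cycle
## and the nucleotide-resolved (detailed) scheme.

.mkNetwork <- function(species, reactions, volumeFactor, conserved) {
  ## reactions: list of list(name, from = named counts, to = named counts,
  ##            rate, hydrolysis = FALSE)
  ns <- length(species); nr <- length(reactions)
  Sr <- matrix(0L, ns, nr, dimnames = list(names(species), NULL))
  Sp <- matrix(0L, ns, nr, dimnames = list(names(species), NULL))
  rates <- numeric(nr); nm <- character(nr); hyd <- integer(0)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    for (s in names(rx$from)) Sr[s, j] <- as.integer(rx$from[[s]])
    for (s in names(rx$to)) Sp[s, j] <- as.integer(rx$to[[s]])
    rates[j] <- rx$rate
    nm[j] <- rx$name
    if (isTRUE(rx$hydrolysis)) hyd <- c(hyd, j)
  }
  new("ReactionNetwork", species = species, reactants = Sr, products = Sp,
      rates = rates, reactionNames = nm, hydrolysisReactions = hyd,
      volumeFactor = volumeFactor, conserved = conserved)
}

#' Build the coarse clamp-cycle network for stochastic simulation
#'
#' Integer-copy-number version of the simplified scheme solved by
#' \code{\link{steadyState}}: four ParB species (open/closed x free/bound)
#' plus free DNA. Only the open form binds or releases DNA; hydrolysis
#' converts closed to open both off DNA and (keeping the clamp loaded) on
#' DNA. \code{volumeFactor} converts concentrations to copies: a
#' second-order rate \code{kOn} (1/(uM s)) becomes the stochastic constant
#' \code{kOn / volumeFactor}.
#'
#' @param rates a \linkS4class{RateSet}; \code{kOn} is required (or the
#'   \code{\link{defaultKon}} default is taken).
#' @param parbCopies,dnaCopies initial copy numbers (all ParB starts open
#'   and free; all DNA starts free).
#' @param volumeFactor copies per uM (default 100).
#' @return a \linkS4class{ReactionNetwork}.
#' @export
buildCoarseNetwork <- function(rates, parbCopies = 500L, dnaCopies = 100L,
                               volumeFactor = 100) {
  stopifnot(is(rates, "RateSet"), parbCopies >= 0, dnaCopies >= 0)
  kon <- .konOrDefault(rates)$kOn
  koff <- kon * rates@kdOpen
  species <- c(parb_open_free = as.integer(parbCopies),
               parb_closed_free = 0L,
               parb_open_bound = 0L, parb_closed_bound = 0L,
               dna_free = as.integer(dnaCopies))
  rx <- list(
    list(name = "closure_free", from = c(parb_open_free = 1),
         to = c(parb_closed_free = 1), rate = rates@kOC),
    list(name = "opening_free", from = c(parb_closed_free = 1),
         to = c(parb_open_free = 1), rate = rates@kCO),
    list(name = "hydrolysis_free", from = c(parb_closed_free = 1),
         to = c(parb_open_free = 1), rate = rates@kH, hydrolysis = TRUE),
    list(name = "closure_bound", from = c(parb_open_bound = 1),
         to = c(parb_closed_bound = 1), rate = rates@kOCdna),
    list(name = "opening_bound", from = c(parb_closed_bound = 1),
         to = c(parb_open_bound = 1), rate = rates@kCOdna),
    list(name = "hydrolysis_bound", from = c(parb_closed_bound = 1),
         to = c(parb_open_bound = 1), rate = rates@kH, hydrolysis = TRUE),
    list(name = "bind", from = c(parb_open_free = 1, dna_free = 1),
         to = c(parb_open_bound = 1), rate = kon / volumeFactor),
    list(name = "unbind", from = c(parb_open_bound = 1),
         to = c(parb_open_free = 1, dna_free = 1), rate = koff)
  )
  conserved <- list(
    ParB = c(parb_open_free = 1L, parb_closed_free = 1L,
             parb_open_bound = 1L, parb_closed_bound = 1L),
    DNA = c(dna_free = 1L, parb_open_bound = 1L, parb_closed_bound = 1L)
  )
  .mkNetwork(species, rx, volumeFactor, conserved)
}

## required entries of the detailed-network parameter table, with the
## reaction-scheme step each one drives
.DETAILED_REQUIRED <- c(
  ctp = "step 1-2 (CTP concentration, uM)",
  ctpOn = "step 1-2 (CTP on-rate, 1/(uM s))",
  ctpOff = "step 1-2 (CTP off-rate, 1/s)",
  untether = "step 3 (N-M untethering rate, 1/s)",
  retether = "step 3 (N-M retethering rate, 1/s)",
  closureFree = "step 4 (clamp closure off DNA, 1/s)",
  closureParS = "step 4' (clamp closure on parS, 1/s)",
  kH = "step 5/5' (CTP hydrolysis rate, 1/s)",
  kdCTP = "step 5' (CTP dissociation constant for the retention split, uM)",
  kOn = "parS binding by untethered ParB (1/(uM s))",
  kdOpen = "parS dissociation constant of untethered ParB (uM)"
)

#' Build the nucleotide-resolved (detailed) ParB network
#'
#' The detailed scheme resolves the clamp cycle into nucleotide binding,
#' N-M untethering, closure, and hydrolysis: apo ParB binds CTP (steps
#' 1-2), the N and M domains untether (step 3, reversible), the untethered
#' dimer closes slowly off DNA (step 4) or rapidly on parS (step 4'), and
#' hydrolysis recycles closed clamps (steps 5/5'). After an on-DNA
#' hydrolysis event the clamp is retained (nucleotide exchange without
#' unloading) with probability
#' \code{pRetain = ctp / (ctp + kdCTP)}, or unloads and reverts to the
#' autoinhibited apo dimer otherwise; the CDP micro-steps are folded into
#' this split. Only the untethered (open) form binds or releases DNA.
#'
#' @param params named list or vector with entries \code{ctp}, \code{ctpOn},
#'   \code{ctpOff}, \code{untether}, \code{retether}, \code{closureFree},
#'   \code{closureParS}, \code{kH}, \code{kdCTP}, \code{kOn}, \code{kdOpen}
#'   (units as in \code{ParBcycle:::.DETAILED_REQUIRED}); missing entries
#'   raise an error naming the reaction step. Optional: \code{nsCopies}
#'   (nonspecific DNA copies, default 0), \code{kdOpenNS} (uM, default
#'   \code{kdOpen}), \code{pRetain} (overrides the CTP competition split).
#' @param parbCopies,parsCopies initial copies (ParB starts apo and free).
#' @param volumeFactor copies per uM.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
buildDetailedNetwork <- function(params, parbCopies = 500L, parsCopies = 10L,
                                 volumeFactor = 100) {
  params <- as.list(params)
  missing <- setdiff(names(.DETAILED_REQUIRED), names(params))
  if (length(missing))
    stop("missing detailed-network rate(s): ",
         paste(sprintf("'%s' [%s]", missing, .DETAILED_REQUIRED[missing]),
               collapse = ", "))
  p <- lapply(params, as.numeric)
  pRetain <- if (!is.null(p$pRetain)) p$pRetain else
    p$ctp / (p$ctp + p$kdCTP)
  stopifnot(pRetain >= 0, pRetain <= 1)
  nsCopies <- if (!is.null(p$nsCopies)) as.integer(p$nsCopies) else 0L
  kdOpenNS <- if (!is.null(p$kdOpenNS)) p$kdOpenNS else p$kdOpen
  koff <- p$kOn * p$kdOpen

  species <- c(parb_intra_apo = as.integer(parbCopies),
               parb_intra_ctp = 0L, parb_untethered = 0L,
               parb_closed_free = 0L,
               parb_open_parS = 0L, parb_closed_parS = 0L,
               parS_free = as.integer(parsCopies))
  rx <- list(
    list(name = "ctp_binding", from = c(parb_intra_apo = 1),
         to = c(parb_intra_ctp = 1), rate = p$ctpOn * p$ctp),
    list(name = "ctp_release", from = c(parb_intra_ctp = 1),
         to = c(parb_intra_apo = 1), rate = p$ctpOff),
    list(name = "untether", from = c(parb_intra_ctp = 1),
         to = c(parb_untethered = 1), rate = p$untether),
    list(name = "retether", from = c(parb_untethered = 1),
         to = c(parb_intra_ctp = 1), rate = p$retether),
    list(name = "parS_bind",
         from = c(parb_untethered = 1, parS_free = 1),
         to = c(parb_open_parS = 1), rate = p$kOn / volumeFactor),
    list(name = "parS_release", from = c(parb_open_parS = 1),
         to = c(parb_untethered = 1, parS_free = 1), rate = koff),
    list(name = "closure_free", from = c(parb_untethered = 1),
         to = c(parb_closed_free = 1), rate = p$closureFree),
    list(name = "closure_parS", from = c(parb_open_parS = 1),
         to = c(parb_closed_parS = 1), rate = p$closureParS),
    list(name = "hydrolysis_free", from = c(parb_closed_free = 1),
         to = c(parb_intra_apo = 1), rate = p$kH, hydrolysis = TRUE),
    list(name = "hydrolysis_retain", from = c(parb_closed_parS = 1),
         to = c(parb_closed_parS = 1), rate = p$kH * pRetain,
         hydrolysis = TRUE),
    list(name = "hydrolysis_unload", from = c(parb_closed_parS = 1),
         to = c(parb_intra_apo = 1, parS_free = 1),
         rate = p$kH * (1 - pRetain), hydrolysis = TRUE)
  )
  conservedParB <- c(parb_intra_apo = 1L, parb_intra_ctp = 1L,
                     parb_untethered = 1L, parb_closed_free = 1L,
                     parb_open_parS = 1L, parb_closed_parS = 1L)
  conserved <- list(
    ParB = conservedParB,
    parS = c(parS_free = 1L, parb_open_parS = 1L, parb_closed_parS = 1L)
  )

  if (nsCopies > 0L) {
    species <- c(species,
                 c(parb_open_ns = 0L, parb_closed_ns = 0L,
                   ns_free = nsCopies))
    rx <- c(rx, list(
      list(name = "ns_bind", from = c(parb_untethered = 1, ns_free = 1),
           to = c(parb_open_ns = 1), rate = p$kOn / volumeFactor),
      list(name = "ns_release", from = c(parb_open_ns = 1),
           to = c(parb_untethered = 1, ns_free = 1),
           rate = p$kOn * kdOpenNS),
      list(name = "closure_ns", from = c(parb_open_ns = 1),
           to = c(parb_closed_ns = 1), rate = p$closureFree),
      list(name = "hydrolysis_retain_ns", from = c(parb_closed_ns = 1),
           to = c(parb_closed_ns = 1), rate = p$kH * pRetain,
           hydrolysis = TRUE),
      list(name = "hydrolysis_unload_ns", from = c(parb_closed_ns = 1),
           to = c(parb_intra_apo = 1, ns_free = 1),
           rate = p$kH * (1 - pRetain), hydrolysis = TRUE)
    ))
    conserved$ParB <- c(conservedParB,
                        c(parb_open_ns = 1L, parb_closed_ns = 1L))
    conserved$NS <- c(ns_free = 1L, parb_open_ns = 1L, parb_closed_ns = 1L)
  }
  net <- .mkNetwork(species, rx, volumeFactor, conserved)
  attr(net, "pRetain") <- pRetain
  net
}

#' Evaluate conserved moieties of a network on a state
#' @param network a \linkS4class{ReactionNetwork}.
#' @param state named integer vector (defaults to the initial state).
#' @return named numeric vector of moiety totals.
#' @export
conservedTotals <- function(network, state = network@species) {
  vapply(network@conserved, function(co) {
    sum(co * state[names(co)])
  }, numeric(1))
}

setMethod("speciesNames", "ReactionNetwork", function(x) names(x@species))

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions (volumeFactor %g copies/uM)\n",
              length(object@species), length(object@rates),
              object@volumeFactor))
  cat("conserved moieties:", paste(names(object@conserved), collapse = ", "),
      "\n")
  for (j in seq_along(object@rates)) {
    lhs <- .sideString(object@reactants[, j])
    rhs <- .sideString(object@products[, j])
    cat(sprintf("  [%d] %-18s %s -> %s  @ %g%s\n", j,
                object@reactionNames[j], lhs, rhs, object@rates[j],
                if (j %in% object@hydrolysisReactions) "  (hydrolysis)" else ""))
  }
})

.sideString <- function(stoich) {
  nz <- which(stoich > 0)
  if (!length(nz)) return("0")
  paste(ifelse(stoich[nz] > 1, paste0(stoich[nz], " "), ""),
        names(stoich)[nz], sep = "", collapse = " + ")
}

#' Write a human-readable reaction list
#' @param network a \linkS4class{ReactionNetwork}.
#' @param file path.
#' @export
writeNetwork <- function(network, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(capture.output(show(network)), con)
  invisible(file)
}
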