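# Forward WB-PBPK simulator. All amounts are ug per kg body weight;
# volumes ml/kg, flows/clearances ml/min/kg, rate constants /min, time min,
# so every concentration is ug/ml. Metabolite mass is counted 1:1 in
# dose-equivalents (no molecular-weight correction), matching how the
# objective data are normalized to the administered CPT-11 amount.

nSpecies <- function() 5L
nCompartments <- function() 23L

stateNames <- function() {
  as.vector(t(outer(speciesNames(), compartmentNames(), paste, sep = ".")))
}

# parameter vector handed to the compiled right-hand side
packParms <- function(phys, params, rate, tstop) {
  c(unname(phys$volume), unname(phys$flow), unname(as.numeric(params)),
    rate, tstop)
}

#' Assemble the model's state-derivative function
#'
#' Returns the right-hand side of the coupled ODE system for the five
#' compounds over 23 compartments as a plain R closure
#' \code{function(t, state)}. The production integrator uses an equivalent
#' compiled routine; this closure is the reference implementation of the
#' model equations, convenient for inspection and for testing single terms.
#'
#' The model is perfusion-limited: each organ exchanges with blood at
#' \code{Q * (C_in - C_tissue/Kp)}, with the lung in series between the
#' venous and arterial pools and the splanchnic organs (spleen, pancreas,
#' stomach, intestines) draining into the liver inlet together with the
#' hepatic artery. Renal elimination acts on kidney outflow plasma,
#' biliary and metabolic clearances on liver outflow plasma. Biliary
#' output passes three transit compartments into the small-intestine
#' lumen, from which drug is either reabsorbed into the liver
#' (enterohepatic circulation; lumenal SN-38G re-enters as SN-38 after
#' bacterial deconjugation) or passed to the large-intestine lumen and on
#' to feces.
#'
#' @param phys A \code{\link{buildPhysiology}} object.
#' @param params A \code{\link{drugParameterSet}} (or numeric vector of
#'   length 105).
#' @param infusion_rate Zero-order CPT-11 infusion rate into venous blood
#'   (ug/kg/min); applied while \code{t < infusion_stop}.
#' @param infusion_stop End of the infusion (min).
#' @return \code{function(t, state)} mapping a time and a state vector of
#'   115 amounts (5 species x 23 compartments, species-major) to the
#'   115 derivatives.
#' @export
assembleRHS <- function(phys, params, infusion_rate = 0,
                        infusion_stop = phys$infusion_duration) {
  V <- unname(phys$volume)
  Q <- unname(phys$flow)
  dp <- unname(as.numeric(params))
  stopifnot(length(dp) == 105L)
  kp <- matrix(dp[1:70], nrow = 5)          # kp[species, organ]
  clr <- dp[71:75]; clbile <- dp[76:80]
  cl_ces1 <- dp[81]; cl_ces2 <- dp[82]
  cl_3a4_1 <- dp[83]; cl_3a4_2 <- dp[84]; cl_ugt <- dp[85]
  kbile <- dp[86:90]; ka <- dp[91:95]; kli <- dp[96:100]; kfec <- dp[101:105]

  VEN <- 1L; ART <- 2L; LUNG <- 3L; KID <- 10L; SPL <- 11L; LIV <- 16L
  B1 <- 17L; B2 <- 18L; B3 <- 19L; SIL <- 20L; LIL <- 21L; UR <- 22L; FE <- 23L
  nc <- 23L

  function(t, state) {
    stopifnot(length(state) == 115L)
    A <- matrix(state, nrow = nc)           # A[compartment, species]
    dA <- matrix(0, nrow = nc, ncol = 5)
    cliv <- A[LIV, ] / (V[LIV] * kp[, 14])
    for (s in 1:5) {
      cven <- A[VEN, s] / V[VEN]
      cart <- A[ART, s] / V[ART]
      cout <- A[LUNG:LIV, s] / (V[LUNG:LIV] * kp[s, ])
      names(cout) <- NULL
      co <- function(organ) cout[organ - 2L]    # organ compartment index
      dA[LUNG, s] <- Q[1] * (cven - co(LUNG))
      venret <- 0; artout <- 0
      for (c in 4:KID) {                        # heart..kidney
        q <- Q[c - 2L]
        dA[c, s] <- q * (cart - co(c))
        venret <- venret + q * co(c)
        artout <- artout + q
      }
      el <- clr[s] * co(KID)
      dA[KID, s] <- dA[KID, s] - el
      dA[UR, s] <- el
      livin <- Q[15] * cart                     # hepatic artery
      artout <- artout + Q[15]
      for (c in SPL:(LIV - 1L)) {
        q <- Q[c - 2L]
        dA[c, s] <- q * (cart - co(c))
        livin <- livin + q * co(c)
        artout <- artout + q
      }
      dA[LIV, s] <- livin - Q[14] * cliv[s] - clbile[s] * cliv[s]
      venret <- venret + Q[14] * cliv[s]
      dA[VEN, s] <- venret - Q[1] * cven
      dA[ART, s] <- Q[1] * co(LUNG) - artout * cart
      dA[B1, s] <- clbile[s] * cliv[s] - kbile[s] * A[B1, s]
      dA[B2, s] <- kbile[s] * (A[B1, s] - A[B2, s])
      dA[B3, s] <- kbile[s] * (A[B2, s] - A[B3, s])
      dA[SIL, s] <- kbile[s] * A[B3, s] - (ka[s] + kli[s]) * A[SIL, s]
      dA[LIL, s] <- kli[s] * A[SIL, s] - kfec[s] * A[LIL, s]
      dA[FE, s] <- kfec[s] * A[LIL, s]
    }
    # enterohepatic reabsorption; lumenal SN-38G returns as hepatic SN-38
    for (s in 1:5) {
      flux <- ka[s] * A[SIL, s]
      target <- if (s == 3L) 2L else s
      dA[LIV, target] <- dA[LIV, target] + flux
    }
    f_ces1 <- cl_ces1 * cliv[1]; f_3a41 <- cl_3a4_1 * cliv[1]
    f_3a42 <- cl_3a4_2 * cliv[1]; f_ces2 <- cl_ces2 * cliv[4]
    f_ugt <- cl_ugt * cliv[2]
    dA[LIV, 1] <- dA[LIV, 1] - (f_ces1 + f_3a41 + f_3a42)
    dA[LIV, 2] <- dA[LIV, 2] + f_ces1 + f_ces2 - f_ugt
    dA[LIV, 3] <- dA[LIV, 3] + f_ugt
    dA[LIV, 4] <- dA[LIV, 4] + f_3a42 - f_ces2
    dA[LIV, 5] <- dA[LIV, 5] + f_3a41
    if (infusion_rate > 0 && t < infusion_stop) {
      dA[VEN, 1] <- dA[VEN, 1] + infusion_rate
    }
    as.vector(dA)
  }
}

defaultOutputTimes <- function(tinf, horizon) {
  fine_end <- min(4 * tinf, horizon)
  fine <- seq(0, fine_end, by = 1)
  if (horizon > fine_end) {
    tail <- exp(seq(log(fine_end), log(horizon), length.out = 40L))[-1]
    sort(unique(c(fine, tinf, tail, horizon)))
  } else {
    sort(unique(c(fine, tinf)))
  }
}

#' Simulate the irinotecan WB-PBPK model for one patient
#'
#' Integrates the stiff ODE system with \pkg{deSolve} (lsoda, compiled
#' right-hand side), split at the infusion stop time so the zero-order
#' input discontinuity never degrades step control. The output grid is
#' 1-min spaced through four infusion durations (resolving every Cmax) and
#' log-spaced out to the horizon, where cumulative urinary and fecal
#' recovery is read.
#'
#' @param phys A \code{\link{buildPhysiology}} object.
#' @param params A \code{\link{drugParameterSet}} or numeric vector of
#'   length 105.
#' @param horizon Simulation end (min). Default 30240 (21 days), by which
#'   terminal excretion flux is negligible for plausible parameters.
#' @param rtol,atol Integrator tolerances; \code{atol} defaults to
#'   \code{1e-9 * dose}.
#' @param times Optional explicit output grid (min).
#' @param maxsteps lsoda step budget per output interval.
#' @return Object of class \code{pbpk_result}: list with \code{times},
#'   \code{state} (time x 115 amounts matrix), \code{dose}, \code{status}
#'   (\code{"ok"} or \code{"failed"}), \code{phys_id}.
#' @export
#' @examples
#' \donttest{
#' p1 <- studyPatients()[[1]]
#' theta <- drugParameterSet(parameterTable()$min * 2)
#' res <- simulatePBPK(p1, theta)
#' computeObservables(res)
#' }
simulatePBPK <- function(phys, params, horizon = 30240, rtol = 1e-6,
                         atol = 1e-9 * max(phys$dose, 1), times = NULL,
                         maxsteps = 10000L) {
  tinf <- phys$infusion_duration
  if (horizon < tinf) stop("horizon must cover the infusion")
  if (is.null(times)) times <- defaultOutputTimes(tinf, horizon)
  times <- sort(unique(c(0, tinf, times)))
  y0 <- rep(0, 115L)
  rate <- phys$dose / tinf

  run_piece <- function(y, tt, rate_now) {
    parms <- packParms(phys, params, rate_now, tinf)
    out <- try(suppressWarnings(
      deSolve::ode(y = y, times = tt, func = "pbpk_derivs",
                   parms = parms, dllname = "pbpkcnm",
                   initfunc = "pbpk_initmod", method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)
    ), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) return(NULL)
    if (nrow(out) < length(tt) || anyNA(out)) return(NULL)
    out
  }

  t1 <- times[times <= tinf]
  t2 <- times[times >= tinf]
  out1 <- run_piece(y0, t1, rate)
  if (is.null(out1)) return(failedResult(phys, times))
  state <- out1[, -1, drop = FALSE]
  if (length(t2) > 1L) {
    out2 <- run_piece(unname(state[nrow(state), ]), t2, 0)
    if (is.null(out2)) return(failedResult(phys, times))
    state <- rbind(state, out2[-1, -1, drop = FALSE])
    tfull <- c(t1, t2[-1])
  } else {
    tfull <- t1
  }
  colnames(state) <- stateNames()
  structure(list(times = tfull, state = state, dose = phys$dose,
                 infusion_duration = tinf, status = "ok",
                 venous_volume = unname(phys$volume["venous_blood"]),
                 phys_id = phys$patient_id),
            class = "pbpk_result")
}

failedResult <- function(phys, times) {
  structure(list(times = times, state = NULL, dose = phys$dose,
                 infusion_duration = phys$infusion_duration,
                 status = "failed", phys_id = phys$patient_id),
            class = "pbpk_result")
}

#' @export
print.pbpk_result <- function(x, ...) {
  cat("<pbpk_result>", x$phys_id, "status:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  %d output times to %g min, dose %g ug/kg\n",
                length(x$times), max(x$times), x$dose))
  }
  invisible(x)
}

stateColumn <- function(species, compartment) {
  s <- match(species, speciesNames())
  c <- match(compartment, compartmentNames())
  (s - 1L) * 23L + c
}

#' Names of the 13 objective observables
#'
#' Order: urinary elimination ratio (% of dose) of CPT-11, SN-38, SN-38G,
#' NPC, APC; fecal elimination ratio (%) of CPT-11, SN-38 + SN-38G, NPC,
#' APC; Cmax (ug/ml, venous blood) of CPT-11, SN-38, SN-38G, APC.
#'
#' @return Character vector of length 13.
#' @export
observableNames <- function() {
  c("urine_CPT11", "urine_SN38", "urine_SN38G", "urine_NPC", "urine_APC",
    "feces_CPT11", "feces_SN38_SN38G", "feces_NPC", "feces_APC",
    "cmax_CPT11", "cmax_SN38", "cmax_SN38G", "cmax_APC")
}

#' Extract the 13 objective observables from a simulation
#'
#' Urinary and fecal recoveries are the cumulative amounts at the final
#' output time expressed as % of the administered dose; fecal SN-38 and
#' SN-38G are reported jointly (only their sum is observable in feces).
#' Cmax is the maximum of the venous-blood concentration trace; NPC has no
#' Cmax objective.
#'
#' @param result A \code{pbpk_result} with status \code{"ok"}.
#' @return Named numeric vector of length 13 (see
#'   \code{\link{observableNames}}).
#' @export
computeObservables <- function(result) {
  if (!inherits(result, "pbpk_result")) stop("not a pbpk_result")
  if (result$status != "ok") stop("cannot compute observables of a failed simulation")
  st <- result$state
  last <- nrow(st)
  dose <- result$dose
  if (dose == 0) {
    return(structure(rep(0, 13L), names = observableNames()))
  }
  sp <- speciesNames()
  urine <- vapply(sp, function(s) st[last, stateColumn(s, "urine")], 0)
  feces <- vapply(sp, function(s) st[last, stateColumn(s, "feces")], 0)
  cmax <- vapply(c("CPT-11", "SN-38", "SN-38G", "APC"), function(s) {
    max(st[, stateColumn(s, "venous_blood")])
  }, 0)
  structure(
    c(100 * urine / dose,
      100 * c(feces[1], feces[2] + feces[3], feces[4], feces[5]) / dose,
      cmax / result$venous_volume),
    names = observableNames()
  )
}

#' Mass-balance residual of a simulation
#'
#' Total drug amount in every compartment (circulatory, transit, lumen,
#' urine, feces, all species) minus the cumulatively infused amount, at
#' each output time. Metabolic conversion is 1:1 in dose-equivalent mass,
#' so this is zero up to integrator tolerance.
#'
#' @param result An ok \code{pbpk_result}.
#' @return Numeric vector (one residual per output time, ug/kg).
#' @export
massBalanceResidual <- function(result) {
  if (result$status != "ok") stop("failed simulation")
  infused <- result$dose * pmin(result$times, result$infusion_duration) /
    result$infusion_duration
  rowSums(result$state) - infused
}
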