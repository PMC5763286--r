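# Layout of the 105 drug-related parameters and their prior ranges.
#
# IDs 1-70   Kp, tissue-plasma partition coefficients: 14 perfused organs x 5
#            compounds, organ-major (ids (o-1)*5 + s).
# IDs 71-75  renal clearance CLr per compound (ml/min/kg)
# IDs 76-80  biliary clearance CLbile per compound (ml/min/kg)
# IDs 81-85  hepatic metabolic clearances CL_CES1, CL_CES2, CL_3A4_1,
#            CL_3A4_2, CL_UGT (ml/min/kg)
# IDs 86-90  k_bile, biliary transit rate constant per compound (/min)
# IDs 91-95  k_a, intestinal absorption rate constant per compound (/min)
# IDs 96-100 k_LI, small-to-large-intestine lumen transit per compound (/min)
# IDs 101-105 k_feces, large-intestine-to-feces rate per compound (/min)

#' Names of the five modelled compounds
#'
#' Irinotecan (CPT-11) and its metabolites, in the fixed order used
#' everywhere in the package: CPT-11, SN-38, SN-38G, NPC, APC.
#' The metabolic cascade is CPT-11 -> SN-38 (CES2), CPT-11 -> APC (CYP3A4),
#' CPT-11 -> NPC (CYP3A4), NPC -> SN-38 (CES2), SN-38 -> SN-38G (UGT1A).
#'
#' @return Character vector of length 5.
#' @export
speciesNames <- function() {
  c("CPT-11", "SN-38", "SN-38G", "NPC", "APC")
}

#' Names of the 14 perfused organs carrying a partition coefficient
#'
#' Order matches the Kp block of the parameter table (ids 1-70); the two
#' blood pools (venous, arterial) carry no Kp.
#'
#' @return Character vector of length 14.
#' @export
kpOrganNames <- function() {
  c("lung", "heart", "brain", "muscle", "adipose", "skin", "bone",
    "kidney", "spleen", "pancreas", "stomach", "small_intestine",
    "large_intestine", "liver")
}

#' Full table of the 105 drug-related parameters
#'
#' One row per parameter id: name, group, organ (Kp rows only), compound
#' (where the parameter is per-compound), unit, and the lower/upper bounds
#' of the prior range sampled by the Cluster Newton Method.
#'
#' @return A data.frame with columns \code{id}, \code{name}, \code{group},
#'   \code{organ}, \code{species}, \code{unit}, \code{min}, \code{max}.
#' @export
#' @examples
#' tab <- parameterTable()
#' nrow(tab)        # 105
#' tab[71, ]        # renal clearance of CPT-11
parameterTable <- function() {
  sp <- speciesNames()
  org <- kpOrganNames()
  kp <- data.frame(
    id = 1:70,
    name = paste0("Kp_", rep(org, each = 5), "_", rep(sp, 14)),
    group = "Kp",
    organ = rep(org, each = 5),
    species = rep(sp, 14),
    unit = "-",
    min = 0.1, max = 10,
    stringsAsFactors = FALSE
  )
  clr <- data.frame(
    id = 71:75,
    name = paste0("CLr_", sp),
    group = "CLr", organ = NA_character_, species = sp,
    unit = "ml/min/kg",
    min = c(0.1, rep(0.01, 4)),
    max = c(10, rep(1, 4)),
    stringsAsFactors = FALSE
  )
  clb <- data.frame(
    id = 76:80,
    name = paste0("CLbile_", sp),
    group = "CLbile", organ = NA_character_, species = sp,
    unit = "ml/min/kg", min = 0.1, max = 10,
    stringsAsFactors = FALSE
  )
  met <- data.frame(
    id = 81:85,
    name = c("CL_CES1", "CL_CES2", "CL_3A4_1", "CL_3A4_2", "CL_UGT"),
    group = "CLmet", organ = NA_character_,
    species = NA_character_,
    unit = "ml/min/kg", min = 0.1, max = 10,
    stringsAsFactors = FALSE
  )
  rates <- function(ids, tag, lo, hi) {
    data.frame(
      id = ids, name = paste0(tag, "_", sp),
      group = tag, organ = NA_character_, species = sp,
      unit = "/min", min = lo, max = hi,
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(
    kp, clr, clb, met,
    rates(86:90, "kbile", 0.001, 0.1),
    rates(91:95, "ka", 1e-4, 0.01),
    rates(96:100, "kLI", 1e-4, 0.01),
    rates(101:105, "kfeces", 1e-4, 0.01)
  )
  rownames(tab) <- NULL
  tab
}

#' Indices of the Kp block
#'
#' @return Integer vector 1:70, named by parameter name.
#' @export
kpIndices <- function() {
  tab <- parameterTable()
  structure(tab$id[tab$group == "Kp"], names = tab$name[tab$group == "Kp"])
}

#' Construct a validated drug-parameter vector
#'
#' @param values Numeric vector of length 105 in parameter-id order
#'   (see \code{\link{parameterTable}}); all entries must be strictly
#'   positive.
#' @return Named numeric vector of class \code{drug_parameter_set}.
#' @export
drugParameterSet <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 105L) {
    stop("a drug parameter set has exactly 105 entries, got ", length(values))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)[1]
    stop("parameter ", bad, " (", parameterTable()$name[bad],
         ") must be strictly positive and finite")
  }
  structure(values, names = parameterTable()$name,
            class = "drug_parameter_set")
}

#' Box bounds for a parameter vector
#'
#' @param lower,upper Numeric vectors of equal length with
#'   \code{0 < lower < upper} elementwise.
#' @return A list of class \code{bound_box} with elements \code{lower},
#'   \code{upper}.
#' @export
boundBox <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) stop("lower/upper length mismatch")
  if (any(lower <= 0)) stop("all lower bounds must be strictly positive")
  if (any(lower >= upper)) stop("need lower < upper for every parameter")
  structure(list(lower = lower, upper = upper), class = "bound_box")
}

#' Default bounds over the 105 drug-related parameters
#'
#' @return A \code{\link{boundBox}} built from \code{\link{parameterTable}}.
#' @export
defaultBounds <- function() {
  tab <- parameterTable()
  boundBox(tab$min, tab$max)
}

#' Fix a subset of parameters at given values
#'
#' A constraint mask marks coordinates that every Cluster Newton operation
#' must leave untouched (used to hold Kp at its across-patient medians in
#' the second, constrained estimation stage).
#'
#' @param indices Integer parameter ids to fix.
#' @param values Numeric values, one per fixed index.
#' @return A list of class \code{constraint_mask} with elements
#'   \code{indices}, \code{values}.
#' @export
constraintMask <- function(indices, values) {
  indices <- as.integer(indices)
  values <- as.numeric(values)
  if (length(indices) != length(values)) stop("indices/values length mismatch")
  if (anyDuplicated(indices)) stop("duplicated fixed indices")
  if (any(values <= 0)) stop("fixed values must be strictly positive")
  structure(list(indices = indices, values = values),
            class = "constraint_mask")
}

#' @export
print.drug_parameter_set <- function(x, ...) {
  cat("<drug_parameter_set> 105 parameters\n")
  cat("  Kp range      :", format(range(x[1:70]), digits = 3), "\n")
  cat("  CLr CPT-11    :", format(x[71], digits = 3), "ml/min/kg\n")
  cat("  CLbile CPT-11 :", format(x[76], digits = 3), "ml/min/kg\n")
  invisible(x)
}
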