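# Patient physiology: per-kg organ volumes and blood flows for the 16
# circulatory compartments, plus demographics and the dosing regimen.

#' Names of the 16 circulatory compartments
#'
#' Two blood pools plus 14 perfused organs, in state order.
#'
#' @return Character vector of length 16.
#' @export
circulatoryNames <- function() {
  c("venous_blood", "artery_blood", kpOrganNames())
}

#' Names of all 23 model compartments (per compound)
#'
#' The 16 circulatory compartments followed by the elimination chain:
#' three biliary transit compartments, the small- and large-intestine
#' lumen, urine and feces.
#'
#' @return Character vector of length 23.
#' @export
compartmentNames <- function() {
  c(circulatoryNames(),
    "bile_transit_1", "bile_transit_2", "bile_transit_3",
    "si_lumen", "li_lumen", "urine", "feces")
}

flowNames <- function() {
  c("lung", "heart", "brain", "muscle", "adipose", "skin", "bone",
    "kidney", "spleen", "pancreas", "stomach", "small_intestine",
    "large_intestine", "liver_total", "liver_artery")
}

splanchnicOrgans <- function() {
  c("spleen", "pancreas", "stomach", "small_intestine", "large_intestine")
}

#' Build and validate a patient-physiology object
#'
#' Takes one patient record (demographics, dose, per-kg organ volumes in
#' ml/kg and blood flows in ml/min/kg) and returns a validated object.
#' Validation checks strict positivity of every volume and flow, that the
#' hepatic-artery flow is below the total liver flow, and two flow-balance
#' identities: total liver flow = hepatic artery + splanchnic venous flows,
#' and lung flow = sum of all venous returns. Printed per-kg tables carry
#' rounding error, so both identities are checked to \code{flow_tol}.
#'
#' @param record A list or one-row data.frame with elements
#'   \code{patient_id}, \code{sex}, \code{age}, \code{height} (cm),
#'   \code{weight} (kg), \code{dose} (ug/kg), \code{infusion_duration}
#'   (min), \code{volume} (named numeric, ml/kg, one entry per circulatory
#'   compartment) and \code{flow} (named numeric, ml/min/kg, one entry per
#'   name in lung...large_intestine, liver_total, liver_artery).
#' @param flow_tol Tolerance (ml/min/kg) for the two flow-balance checks.
#' @return An object of class \code{patient_physiology}.
#' @export
#' @examples
#' p <- studyPatients()[[1]]
#' bmi(p)                      # 37.1 kg/m^2 for patient 1
#' portalFlow(p)               # liver_total - liver_artery
buildPhysiology <- function(record, flow_tol = 1.0) {
  need <- c("patient_id", "sex", "age", "height", "weight", "dose",
            "infusion_duration", "volume", "flow")
  miss <- setdiff(need, names(record))
  if (length(miss)) stop("patient record missing field(s): ",
                         paste(miss, collapse = ", "))
  vol <- unlist(record$volume)[circulatoryNames()]
  flo <- unlist(record$flow)[flowNames()]
  if (any(is.na(vol))) {
    stop("missing organ volume: ",
         paste(setdiff(circulatoryNames(), names(record$volume)), collapse = ", "))
  }
  if (any(is.na(flo))) {
    stop("missing organ flow: ",
         paste(setdiff(flowNames(), names(record$flow)), collapse = ", "))
  }
  if (any(vol <= 0)) {
    stop("non-positive volume for organ: ",
         paste(names(vol)[vol <= 0], collapse = ", "))
  }
  if (any(flo <= 0)) {
    stop("non-positive flow for organ: ",
         paste(names(flo)[flo <= 0], collapse = ", "))
  }
  for (f in c("age", "height", "weight", "infusion_duration")) {
    if (!is.finite(record[[f]]) || record[[f]] <= 0) {
      stop("non-positive value for ", f)
    }
  }
  if (!is.finite(record$dose) || record$dose < 0) {
    stop("negative or non-finite dose")
  }
  if (flo["liver_artery"] >= flo["liver_total"]) {
    stop("hepatic artery flow must be below total liver flow")
  }
  splanchnic <- sum(flo[splanchnicOrgans()])
  if (abs(flo["liver_total"] - (flo["liver_artery"] + splanchnic)) > flow_tol) {
    stop("flow balance violated at liver: total ", flo["liver_total"],
         " vs artery + splanchnic ", flo["liver_artery"] + splanchnic)
  }
  venous_return <- sum(flo[c("heart", "brain", "muscle", "adipose", "skin",
                             "bone", "kidney", "liver_total")])
  if (abs(flo["lung"] - venous_return) > flow_tol) {
    stop("flow balance violated at lung: lung flow ", flo["lung"],
         " vs venous returns ", venous_return)
  }
  structure(
    list(
      patient_id = as.character(record$patient_id),
      sex = as.character(record$sex),
      age = as.numeric(record$age),
      height = as.numeric(record$height),
      weight = as.numeric(record$weight),
      dose = as.numeric(record$dose),
      infusion_duration = as.numeric(record$infusion_duration),
      volume = vol,
      flow = flo
    ),
    class = "patient_physiology"
  )
}

#' Body-mass index of a patient
#'
#' @param phys A \code{patient_physiology}.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(phys) {
  phys$weight / (phys$height / 100)^2
}

#' Portal (gut-derived) inflow to the liver
#'
#' @param phys A \code{patient_physiology}.
#' @return Flow in ml/min/kg: total liver flow minus hepatic-artery flow.
#' @export
portalFlow <- function(phys) {
  unname(phys$flow["liver_total"] - phys$flow["liver_artery"])
}

#' @export
print.patient_physiology <- function(x, ...) {
  cat("<patient_physiology>", x$patient_id, "\n")
  cat(sprintf("  %s, %g y, %g cm, %g kg (BMI %.1f)\n",
              x$sex, x$age, x$height, x$weight, bmi(x)))
  cat(sprintf("  dose %g ug/kg over %g min infusion\n",
              x$dose, x$infusion_duration))
  cat(sprintf("  cardiac output (lung flow) %.1f ml/min/kg, liver total %.1f\n",
              x$flow[["lung"]], x$flow[["liver_total"]]))
  invisible(x)
}

#' The seven study patients
#'
#' Loads the packaged physiology fixture (demographics, dose, per-kg organ
#' volumes and flows for the seven analyzed colorectal-cancer patients) and
#' builds validated \code{patient_physiology} objects.
#'
#' @return Named list of 7 \code{patient_physiology} objects.
#' @export
studyPatients <- function() {
  path <- system.file("extdata", "patients.csv", package = "pbpkcnm",
                      mustWork = TRUE)
  readPatientsCSV(path)
}
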