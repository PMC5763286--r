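# Synthetic studies: virtual patients, ground-truth parameter sets, and
# noisy objective vectors produced by forward simulation, so the whole
# three-step analysis can be exercised and scored with a known answer.

#' Across-patient mean per-kg physiology
#'
#' Mean per-kg organ volumes and flows over the packaged seven-patient
#' table; the anchor around which virtual patients are drawn.
#'
#' @return List with numeric vectors \code{volume} and \code{flow}.
#' @export
meanPhysiology <- function() {
  pats <- studyPatients()
  vol <- rowMeans(vapply(pats, function(p) p$volume,
                         numeric(length(circulatoryNames()))))
  flo <- rowMeans(vapply(pats, function(p) p$flow,
                         numeric(length(flowNames()))))
  list(volume = vol, flow = flo)
}

#' Generate a virtual patient
#'
#' Per-kg organ volumes and flows are drawn around the across-patient
#' means with multiplicative lognormal variation (CV
#' \code{variation_cv}), then the dependent flows are rebuilt so the flow
#' balances hold exactly: total liver flow = hepatic artery + splanchnic
#' flows, lung flow = sum of venous returns. A 90-min zero-order infusion
#' is attached.
#'
#' @param seed Optional integer seed.
#' @param weight Body weight, kg (30-200).
#' @param height Height, cm (120-220).
#' @param sex \code{"M"} or \code{"F"}.
#' @param age Age in years.
#' @param dose Dose in ug/kg.
#' @param variation_cv Lognormal coefficient of variation of each per-kg
#'   value around its mean (default 0.15; 0 reproduces the means).
#' @param patient_id Identifier.
#' @return A validated \code{patient_physiology}.
#' @export
makeVirtualPatient <- function(seed = NULL, weight = 75, height = 170,
                               sex = "M", age = 60, dose = 1400,
                               variation_cv = 0.15,
                               patient_id = "virtual") {
  if (weight < 30 || weight > 200) stop("implausible weight: ", weight, " kg")
  if (height < 120 || height > 220) stop("implausible height: ", height, " cm")
  if (!is.null(seed)) set.seed(seed)
  anchor <- meanPhysiology()
  sdlog <- sqrt(log(1 + variation_cv^2))
  perturb <- function(x) {
    if (variation_cv == 0) return(x)
    x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
  }
  vol <- perturb(anchor$volume)
  flo <- perturb(anchor$flow)
  names(vol) <- circulatoryNames(); names(flo) <- flowNames()
  # rebuild the dependent flows so balance is exact
  flo["liver_total"] <- flo["liver_artery"] + sum(flo[splanchnicOrgans()])
  flo["lung"] <- sum(flo[c("heart", "brain", "muscle", "adipose", "skin",
                           "bone", "kidney", "liver_total")])
  buildPhysiology(list(
    patient_id = patient_id, sex = sex, age = age, height = height,
    weight = weight, dose = dose, infusion_duration = 90,
    volume = vol, flow = flo), flow_tol = 1e-6)
}

#' Draw an interior ground-truth parameter set
#'
#' Log-uniform draw from the central 80% (in log space) of each parameter
#' range, so the truth is strictly inside the bounds the estimator
#' samples.
#'
#' @param bounds A \code{\link{boundBox}} (default the packaged ranges).
#' @param seed Optional integer seed.
#' @return A \code{\link{drugParameterSet}}.
#' @export
makeTruthParameters <- function(bounds = defaultBounds(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  llo <- log(bounds$lower); lhi <- log(bounds$upper)
  margin <- 0.1 * (lhi - llo)
  drugParameterSet(exp(stats::runif(length(llo), llo + margin,
                                    lhi - margin)))
}

#' Simulate noisy objective vectors from a known truth
#'
#' Runs the forward model at the truth parameters and multiplies each of
#' the 13 observables by independent lognormal noise with coefficient of
#' variation \code{noise_cv} (mean 1); \code{noise_cv = 0} returns the
#' exact forward observables.
#'
#' @param phys A \code{patient_physiology}.
#' @param truth A \code{\link{drugParameterSet}}.
#' @param noise_cv Observation-noise CV (default 0.1).
#' @param seed Optional integer seed for the noise draw.
#' @return Named numeric vector of 13 positive targets.
#' @export
forwardObjectives <- function(phys, truth, noise_cv = 0.1, seed = NULL) {
  res <- simulatePBPK(phys, truth)
  if (res$status != "ok") {
    stop("forward simulation failed at the truth parameters; redraw the truth")
  }
  obs <- computeObservables(res)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    obs <- obs * exp(stats::rnorm(13L, -sdlog^2 / 2, sdlog))
  }
  obs
}

#' Generate a complete synthetic study
#'
#' Virtual patients with anthropometrics drawn in realistic adult ranges,
#' one interior truth parameter set per patient, and objective vectors
#' simulated from the truth with optional multiplicative noise.
#'
#' @param n_patients Number of virtual patients.
#' @param noise_cv Objective-noise CV (0 = noiseless).
#' @param seed Integer seed; the study is fully reproducible from it.
#' @param bounds Parameter bounds (packaged ranges by default).
#' @return List of class \code{synthetic_study}: \code{inputs} (a
#'   \code{\link{studyInputs}}), \code{truth} (list of parameter sets),
#'   \code{noise_cv}, \code{seed}.
#' @export
makeSyntheticStudy <- function(n_patients = 1L, noise_cv = 0, seed = 1L,
                               bounds = defaultBounds()) {
  set.seed(seed)
  patients <- vector("list", n_patients)
  truth <- vector("list", n_patients)
  objectives <- matrix(NA_real_, n_patients, 13L)
  for (i in seq_len(n_patients)) {
    phys <- makeVirtualPatient(
      weight = stats::runif(1, 50, 110),
      height = stats::runif(1, 150, 195),
      sex = sample(c("M", "F"), 1L),
      age = round(stats::runif(1, 45, 80)),
      dose = round(stats::runif(1, 1000, 2200)),
      patient_id = sprintf("synthetic_%d", i))
    for (attempt in 1:10) {
      th <- makeTruthParameters(bounds)
      obs <- tryCatch(forwardObjectives(phys, th, noise_cv = noise_cv),
                      error = function(e) NULL)
      if (!is.null(obs) && all(obs > 0)) break
      th <- NULL
    }
    if (is.null(th)) stop("could not find a simulable truth for patient ", i)
    patients[[i]] <- phys
    truth[[i]] <- th
    objectives[i, ] <- obs
  }
  structure(list(inputs = studyInputs(patients, objectives, bounds),
                 truth = truth, noise_cv = noise_cv, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d virtual patient(s), noise CV %g, seed %d\n",
              length(x$inputs$patients), x$noise_cv, x$seed))
  invisible(x)
}

#' Run the full pipeline on a synthetic study and score recovery
#'
#' Executes the three-step analysis on the synthetic inputs and reports,
#' per patient: minimum stage-1 SSR, stage-1 and stage-2 CV of every
#' parameter, and the ratio of the stage-2 cluster median to the known
#' truth.
#'
#' @param study A \code{\link{makeSyntheticStudy}} result.
#' @param config1,config2 Stage configs (reduced preset by default; stage
#'   2 inherits with 15 iterations).
#' @param ssr_threshold,cv_threshold Pipeline thresholds.
#' @return List of class \code{recovery_report}: \code{pipeline},
#'   \code{min_ssr} (per patient), \code{cv1}, \code{cv2} (patients x 105),
#'   \code{ratio} (patients x 105 matrix of stage-2 median / truth).
#' @export
recoveryExperiment <- function(study,
                               config1 = cnmPreset("reduced", stage = 1L,
                                                   seed = study$seed),
                               config2 = NULL,
                               ssr_threshold = 0.03, cv_threshold = 0.3) {
  pipe <- runPipeline(study$inputs, config1, config2,
                      ssr_threshold = ssr_threshold,
                      cv_threshold = cv_threshold)
  ids <- names(study$inputs$patients)
  min_ssr <- vapply(pipe$stage1, function(h) {
    min(h$final$ssr, na.rm = TRUE)
  }, 0)
  ratio <- matrix(NA_real_, length(ids), 105L,
                  dimnames = list(ids, parameterTable()$name))
  for (i in seq_along(ids)) {
    cl <- pipe$stage2[[i]]$final
    ok <- cl$status == "ok" & !is.na(cl$ssr)
    med <- apply(cl$points[ok, , drop = FALSE], 2, stats::median)
    ratio[i, ] <- med / as.numeric(study$truth[[i]])
  }
  structure(list(pipeline = pipe, min_ssr = min_ssr,
                 cv1 = pipe$cv1$cv, cv2 = pipe$cv2$cv, ratio = ratio),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n  min stage-1 SSR:",
      paste(sprintf("%.3g", x$min_ssr), collapse = ", "), "\n")
  key <- c(71L, 76L, 83L)
  cat("  stage-2 median/truth for ids 71/76/83:\n")
  print(round(x$ratio[, key, drop = FALSE], 3))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline input dialect
#'
#' Writes \code{patients.csv}, \code{objectives.csv}, \code{bounds.csv}
#' (loadable with \code{\link{loadStudy}}) plus \code{truth.csv} with one
#' row per patient for scoring.
#'
#' @param study A \code{synthetic_study}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSyntheticStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- study$inputs$patients
  df <- do.call(rbind, lapply(pats, function(p) {
    row <- data.frame(patient_id = p$patient_id, sex = p$sex, age = p$age,
                      height_cm = p$height, weight_kg = p$weight,
                      dose_ug_kg = p$dose, infusion_min = p$infusion_duration,
                      stringsAsFactors = FALSE)
    vol <- as.data.frame(t(p$volume)); names(vol) <- paste0("v_", names(p$volume))
    flo <- as.data.frame(t(p$flow))
    names(flo) <- c(paste0("q_", flowNames()[1:13]), "q_liver_total",
                    "q_liver_artery")
    cbind(row, vol, flo)
  }))
  utils::write.csv(df, file.path(dir, "patients.csv"), row.names = FALSE,
                   quote = FALSE)
  obj <- data.frame(patient_id = rownames(study$inputs$objectives),
                    study$inputs$objectives, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(obj, file.path(dir, "objectives.csv"), row.names = FALSE,
                   quote = FALSE)
  tab <- parameterTable()
  utils::write.csv(tab[, c("id", "name", "group", "organ", "species",
                           "unit", "min", "max")],
                   file.path(dir, "bounds.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- do.call(rbind, lapply(study$truth, function(t) {
    as.data.frame(t(as.numeric(t)))
  }))
  names(tr) <- tab$name
  tr <- cbind(patient_id = names(pats), tr)
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
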