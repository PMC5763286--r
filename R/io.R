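# Readers/writers for the study-input and cluster CSV dialects.
# All CSVs: '.' decimal, comma separator, UTF-8, header row.

physCSVColumns <- function() {
  c("patient_id", "sex", "age", "height_cm", "weight_kg", "dose_ug_kg",
    "infusion_min",
    paste0("v_", circulatoryNames()),
    paste0("q_", flowNames()[1:13]), "q_liver_total", "q_liver_artery")
}

#' Read a patient-physiology CSV
#'
#' One row per patient; columns \code{patient_id, sex, age, height_cm,
#' weight_kg, dose_ug_kg, infusion_min}, then per-kg volumes
#' \code{v_<compartment>} (ml/kg) and flows \code{q_<organ>},
#' \code{q_liver_total}, \code{q_liver_artery} (ml/min/kg).
#'
#' @param path CSV file.
#' @param flow_tol Passed to \code{\link{buildPhysiology}}.
#' @return Named list of \code{patient_physiology} objects.
#' @export
readPatientsCSV <- function(path, flow_tol = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(physCSVColumns(), names(df))
  if (length(miss)) {
    stop("patients file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    vol <- as.numeric(row[paste0("v_", circulatoryNames())])
    names(vol) <- circulatoryNames()
    flo <- as.numeric(row[c(paste0("q_", flowNames()[1:13]),
                            "q_liver_total", "q_liver_artery")])
    names(flo) <- flowNames()
    buildPhysiology(list(
      patient_id = row$patient_id, sex = row$sex, age = row$age,
      height = row$height_cm, weight = row$weight_kg,
      dose = row$dose_ug_kg, infusion_duration = row$infusion_min,
      volume = vol, flow = flo), flow_tol = flow_tol)
  })
  names(out) <- df$patient_id
  out
}

#' Read an objectives CSV
#'
#' One row per patient: \code{patient_id} plus the 13 observable columns
#' in \code{\link{observableNames}} order.
#'
#' @param path CSV file.
#' @return Numeric matrix (patients x 13) with patient-id rownames.
#' @export
readObjectivesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", observableNames())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("objectives file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    stop("objectives file ", path, " has unexpected column(s): ",
         paste(extra, collapse = ", "))
  }
  m <- as.matrix(df[, observableNames()])
  rownames(m) <- df$patient_id
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("objectives file ", path, ": non-positive value at row ",
         bad[1, 1], ", column ", observableNames()[bad[1, 2]])
  }
  m
}

#' Read a parameter-bounds CSV
#'
#' Columns \code{id, name, min, max} (extra descriptive columns are
#' allowed); ids must be exactly 1..105 in order and match the package's
#' parameter layout.
#'
#' @param path CSV file.
#' @return A \code{\link{boundBox}}.
#' @export
readBoundsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "min", "max")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("bounds file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) != 105L || !identical(as.integer(df$id), 1:105)) {
    stop("bounds file ", path, " must enumerate parameter ids 1..105")
  }
  if (!identical(df$name, parameterTable()$name)) {
    stop("bounds file ", path, " parameter names do not match the ",
         "package layout (see parameterTable())")
  }
  boundBox(df$min, df$max)
}

#' Bundle validated study inputs
#'
#' @param patients List of \code{patient_physiology}.
#' @param objectives Patients x 13 matrix of positive targets.
#' @param bounds A \code{\link{boundBox}} over the 105 parameters.
#' @return A list of class \code{study_inputs}.
#' @export
studyInputs <- function(patients, objectives, bounds) {
  if (!all(vapply(patients, inherits, TRUE, "patient_physiology"))) {
    stop("patients must be patient_physiology objects")
  }
  objectives <- as.matrix(objectives)
  if (ncol(objectives) != 13L) stop("objectives must have 13 columns")
  if (nrow(objectives) != length(patients)) {
    stop("one objective row per patient required")
  }
  if (any(objectives <= 0)) stop("all objective entries must be positive")
  ids <- unname(vapply(patients, function(p) p$patient_id, ""))
  rownames(objectives) <- ids
  colnames(objectives) <- observableNames()
  names(patients) <- ids
  structure(list(patients = patients, objectives = objectives,
                 bounds = bounds), class = "study_inputs")
}

#' Load study inputs from a directory
#'
#' Expects \code{patients.csv}, \code{objectives.csv} and
#' \code{bounds.csv} in the dialects of \code{\link{readPatientsCSV}},
#' \code{\link{readObjectivesCSV}} and \code{\link{readBoundsCSV}}.
#'
#' @param dir Directory path.
#' @param flow_tol Passed to the physiology validator.
#' @return A \code{\link{studyInputs}} object.
#' @export
loadStudy <- function(dir, flow_tol = 1.0) {
  paths <- file.path(dir, c("patients.csv", "objectives.csv", "bounds.csv"))
  for (p in paths) if (!file.exists(p)) stop("missing study file: ", p)
  patients <- readPatientsCSV(paths[1], flow_tol = flow_tol)
  objectives <- readObjectivesCSV(paths[2])
  if (!identical(sort(rownames(objectives)),
                 sort(names(patients)))) {
    stop("objectives.csv patient ids do not match patients.csv")
  }
  objectives <- objectives[names(patients), , drop = FALSE]
  studyInputs(patients, objectives, readBoundsCSV(paths[3]))
}

#' Load the packaged seven-patient study
#'
#' The fixtures reproduce the printed patient characteristics, objective
#' values and parameter ranges used throughout the package.
#'
#' @return A \code{\link{studyInputs}} object with 7 patients.
#' @export
loadPackagedStudy <- function() {
  loadStudy(system.file("extdata", package = "pbpkcnm", mustWork = TRUE))
}

#' Write / read a cluster as CSV
#'
#' Exactly 107 columns: the 105 parameters named by
#' \code{\link{parameterTable}}, then \code{ssr} and \code{status}.
#' Full double precision is preserved, so \code{readCluster(writeCluster())}
#' round-trips exactly. Observables are not stored; re-evaluate if needed.
#'
#' @param cluster A \code{cnm_cluster}.
#' @param path Output CSV path.
#' @return \code{writeCluster}: the path, invisibly. \code{readCluster}:
#'   a \code{cnm_cluster} (with unevaluated observables).
#' @export
writeCluster <- function(cluster, path) {
  df <- as.data.frame(cluster$points)
  names(df) <- parameterTable()$name
  df$ssr <- cluster$ssr
  df$status <- cluster$status
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCluster
#' @export
readCluster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(parameterTable()$name, "ssr", "status")
  if (!identical(names(df), need)) {
    stop("corrupted cluster file ", path,
         ": expected the 105 parameter columns followed by ssr, status")
  }
  cl <- newCluster(as.matrix(df[, parameterTable()$name]))
  cl$ssr <- as.numeric(df$ssr)
  cl$status <- as.character(df$status)
  cl
}

#' Write a run manifest
#'
#' JSON sidecar capturing what is needed to re-run a pipeline identically:
#' seed, full configuration, package version, input/output paths.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param configs Named list of \code{cnm_config}s (e.g. stage1, stage2).
#' @param paths Named list/character of input and output locations.
#' @param extra Optional named list of additional fields.
#' @return The path, invisibly (file written atomically via rename).
#' @export
writeRunManifest <- function(path, seed, configs, paths = list(),
                             extra = list()) {
  strip <- function(cfg) cfg[setdiff(names(cfg), "forward")]
  manifest <- c(list(
    package = "pbpkcnm",
    version = as.character(utils::packageVersion("pbpkcnm")),
    seed = seed,
    configs = lapply(configs, strip),
    paths = paths,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}
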