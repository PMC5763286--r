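# Three-step constraint-based perturbation analysis:
#   stage 1: unconstrained CNM per patient (all 105 parameters free);
#   fix Kp: pool parameter sets with SSR <= 0.03 across patients, take the
#           per-Kp median, freeze the 70 Kp coordinates;
#   stage 2: CNM per patient with Kp fixed (35 free parameters);
#   screen:  coefficient of variation per parameter over the final cluster,
#            parameters with CV <= 0.3 converge strongly.

patientSeed <- function(base, i) {
  if (is.null(base)) NULL else as.integer(base + i)
}

#' Stage 1: unconstrained per-patient CNM
#'
#' Runs the Cluster Newton Method independently for every patient with all
#' 105 drug-related parameters free. Patient runs do not interact; each
#' uses seed \code{config$seed + patient index} so results are independent
#' of ordering.
#'
#' @param inputs A \code{\link{studyInputs}}.
#' @param config A \code{\link{cnmConfig}} (10 iterations by default).
#' @param verbose Print per-iteration SSR quantiles.
#' @return Named list of \code{cnm_history}, one per patient.
#' @export
runStage1 <- function(inputs, config = cnmConfig(iterations = 10L),
                      verbose = FALSE) {
  out <- vector("list", length(inputs$patients))
  names(out) <- names(inputs$patients)
  for (i in seq_along(inputs$patients)) {
    cfg <- config
    cfg$seed <- patientSeed(config$seed, i)
    out[[i]] <- runCNM(patientForward(inputs$patients[[i]]),
                       inputs$objectives[i, ], inputs$bounds,
                       mask = NULL, config = cfg, verbose = verbose)
  }
  out
}

#' Pool low-SSR parameter sets across patients
#'
#' Selects, from each patient's final cluster, the points whose SSR is at
#' or below the threshold ("0.03 or less" is inclusive), tagged with the
#' patient id.
#'
#' @param histories List of \code{cnm_history} (or \code{cnm_cluster}),
#'   one per patient.
#' @param threshold SSR selection threshold (default 0.03).
#' @return List with \code{points} (pooled matrix), \code{ssr},
#'   \code{patient} (id per row).
#' @export
selectLowSSR <- function(histories, threshold = 0.03) {
  finals <- lapply(histories, function(h) {
    if (inherits(h, "cnm_history")) h$final else h
  })
  ids <- names(finals)
  if (is.null(ids)) ids <- as.character(seq_along(finals))
  picked <- lapply(seq_along(finals), function(i) {
    cl <- finals[[i]]
    keep <- cl$status == "ok" & !is.na(cl$ssr) & cl$ssr <= threshold
    list(points = cl$points[keep, , drop = FALSE],
         ssr = cl$ssr[keep],
         patient = rep(ids[i], sum(keep)))
  })
  points <- do.call(rbind, lapply(picked, `[[`, "points"))
  if (is.null(points) || nrow(points) == 0L) {
    stop("no parameter sets with SSR <= ", threshold,
         "; run more iterations or loosen the threshold")
  }
  list(points = points,
       ssr = unlist(lapply(picked, `[[`, "ssr")),
       patient = unlist(lapply(picked, `[[`, "patient")))
}

#' Median tissue-plasma partition coefficients as a constraint mask
#'
#' Per-Kp-coordinate median over the pooled selected parameter sets
#' (pooling across patients), returned as the constraint mask fixing all
#' 70 Kp coordinates for the second, constrained CNM.
#'
#' @param selected Result of \code{\link{selectLowSSR}} (or any matrix of
#'   parameter rows).
#' @param per_patient If TRUE, take per-patient medians first and then the
#'   median across patients (requires the \code{patient} tags).
#' @return A \code{\link{constraintMask}} over parameter ids 1..70.
#' @export
medianKp <- function(selected, per_patient = FALSE) {
  pts <- if (is.matrix(selected)) selected else selected$points
  if (nrow(pts) == 0L) stop("no selected parameter sets")
  kp_ids <- unname(kpIndices())
  if (per_patient && !is.matrix(selected)) {
    by_pat <- split(seq_len(nrow(pts)), selected$patient)
    pat_med <- t(vapply(by_pat, function(rows) {
      apply(pts[rows, kp_ids, drop = FALSE], 2, stats::median)
    }, numeric(length(kp_ids))))
    med <- apply(pat_med, 2, stats::median)
  } else {
    med <- apply(pts[, kp_ids, drop = FALSE], 2, stats::median)
  }
  constraintMask(kp_ids, med)
}

#' Stage 2: Kp-constrained per-patient CNM
#'
#' Re-estimates the 35 non-Kp parameters per patient with the 70 Kp
#' coordinates frozen at the mask values; 15 iterations by default, same
#' cluster size and dS as stage 1.
#'
#' @param inputs A \code{\link{studyInputs}}.
#' @param mask A \code{\link{constraintMask}} covering exactly the 70 Kp
#'   ids.
#' @param config A \code{\link{cnmConfig}}.
#' @param init \code{"fresh"} (default): sample a new cluster within
#'   bounds; \code{"stage1"}: start from the supplied stage-1 final
#'   clusters (\code{stage1} argument) with Kp overwritten by the mask.
#' @param stage1 Stage-1 histories, needed when \code{init = "stage1"}.
#' @param verbose Print progress.
#' @return Named list of \code{cnm_history}, one per patient.
#' @export
runStage2 <- function(inputs, mask, config = cnmConfig(iterations = 15L),
                      init = c("fresh", "stage1"), stage1 = NULL,
                      verbose = FALSE) {
  init <- match.arg(init)
  if (!setequal(mask$indices, unname(kpIndices()))) {
    stop("stage-2 mask must cover exactly the 70 Kp parameter ids")
  }
  out <- vector("list", length(inputs$patients))
  names(out) <- names(inputs$patients)
  for (i in seq_along(inputs$patients)) {
    cfg <- config
    cfg$seed <- patientSeed(config$seed, i)
    init_cluster <- NULL
    if (init == "stage1") {
      if (is.null(stage1)) stop("init = 'stage1' needs the stage1 histories")
      pts <- stage1[[i]]$final$points
      pts[, mask$indices] <- matrix(mask$values, nrow(pts),
                                    length(mask$indices), byrow = TRUE)
      init_cluster <- newCluster(pts)
      if (!is.null(cfg$seed)) set.seed(cfg$seed)
      cfg$seed <- NULL
    }
    out[[i]] <- runCNM(patientForward(inputs$patients[[i]]),
                       inputs$objectives[i, ], inputs$bounds,
                       mask = mask, config = cfg, init = init_cluster,
                       verbose = verbose)
  }
  out
}

#' Coefficient of variation of each parameter over a cluster
#'
#' Sample standard deviation (n-1 denominator) divided by mean, per
#' parameter column, over the ok points of the final cluster; computed on
#' the linear scale. Columns held constant by a mask have CV exactly 0.
#'
#' @param cluster A \code{cnm_cluster} or \code{cnm_history}.
#' @return Named numeric vector of 105 CVs.
#' @export
computeCV <- function(cluster) {
  if (inherits(cluster, "cnm_history")) cluster <- cluster$final
  ok <- cluster$status == "ok" & !is.na(cluster$ssr)
  if (sum(ok) < 2L) stop("need at least 2 ok points to compute a CV")
  pts <- cluster$points[ok, , drop = FALSE]
  cv <- apply(pts, 2, stats::sd) / colMeans(pts)
  names(cv) <- parameterTable()$name
  cv
}

#' CV report across patients
#'
#' @param histories Per-patient list of \code{cnm_history}/clusters.
#' @param threshold Strong-convergence CV threshold (default 0.3,
#'   inclusive).
#' @return List of class \code{cv_report}: \code{cv} (patients x 105
#'   matrix), \code{selected} (logical, cv <= threshold),
#'   \code{threshold}.
#' @export
cvReport <- function(histories, threshold = 0.3) {
  cv <- t(vapply(histories, computeCV, numeric(105L)))
  rownames(cv) <- names(histories)
  structure(list(cv = cv, selected = cv <= threshold,
                 threshold = threshold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  all_pat <- which(apply(x$selected, 2, all))
  cat(sprintf("<cv_report> %d patients, CV threshold %.2f\n",
              nrow(x$cv), x$threshold))
  cat("  parameters converging strongly in every patient:",
      if (length(all_pat)) paste(colnames(x$cv)[all_pat], collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Strong-convergence selection table
#'
#' @param report A \code{\link{cvReport}} result.
#' @param threshold CV threshold; \code{"0.3 or less"} is inclusive.
#' @return List: \code{selected} (patients x 105 logical),
#'   \code{all_patients} (ids of parameters selected in every patient).
#' @export
selectStrong <- function(report, threshold = report$threshold) {
  sel <- report$cv <= threshold
  list(selected = sel,
       all_patients = which(apply(sel, 2, all)))
}

#' Pooled parameter distributions by age group
#'
#' Splits the patients at the age cutoff (below vs at-or-over) and pools
#' the requested parameter columns of each group's final clusters,
#' reporting median and quartiles — the basis for contrasting the
#' constrained and unconstrained estimates across age groups.
#'
#' @param patients List of \code{patient_physiology}.
#' @param histories Matching per-patient \code{cnm_history}/clusters.
#' @param params Parameter ids to summarize (default the three strongly
#'   converging ones: 71, 76, 83).
#' @param cutoff Age cutoff in years (default 70; upper group is
#'   \code{age >= cutoff}).
#' @return List of class \code{age_group_summary} with \code{groups}
#'   (patient ids per group) and \code{summary} (long data.frame: group,
#'   parameter, q25, median, q75, n).
#' @export
ageGroupSummary <- function(patients, histories, params = c(71L, 76L, 83L),
                            cutoff = 70) {
  ages <- vapply(patients, function(p) p$age, 0)
  ids <- vapply(patients, function(p) p$patient_id, "")
  upper <- ages >= cutoff
  groups <- list(below = ids[!upper], at_or_over = ids[upper])
  if (any(lengths(groups) == 0L)) {
    warning("an age group is empty at cutoff ", cutoff)
  }
  finals <- lapply(histories, function(h) {
    if (inherits(h, "cnm_history")) h$final else h
  })
  pool <- function(members) {
    idx <- which(ids %in% members)
    do.call(rbind, lapply(finals[idx], function(cl) {
      ok <- cl$status == "ok" & !is.na(cl$ssr)
      cl$points[ok, params, drop = FALSE]
    }))
  }
  rows <- list()
  for (g in names(groups)) {
    pooled <- pool(groups[[g]])
    for (k in seq_along(params)) {
      vals <- if (is.null(pooled) || nrow(pooled) == 0L) numeric(0)
              else pooled[, k]
      q <- if (length(vals)) stats::quantile(vals, c(.25, .5, .75))
           else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter_id = params[k],
        parameter = parameterTable()$name[params[k]],
        q25 = q[1], median = q[2], q75 = q[3], n = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(groups = groups, cutoff = cutoff,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "age_group_summary")
}

#' @export
print.age_group_summary <- function(x, ...) {
  cat(sprintf("<age_group_summary> cutoff %g y: below = {%s}, at/over = {%s}\n",
              x$cutoff, paste(x$groups$below, collapse = ", "),
              paste(x$groups$at_or_over, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Full three-step constraint-based perturbation analysis
#'
#' Stage-1 unconstrained CNM per patient, median-Kp fixing over the pooled
#' low-SSR sets, stage-2 Kp-constrained CNM per patient, and CV screening
#' of strongly converging parameters, plus the age-group contrast of the
#' three all-patient parameters.
#'
#' @param inputs A \code{\link{studyInputs}}.
#' @param config1 Stage-1 \code{\link{cnmConfig}} (10 iterations).
#' @param config2 Stage-2 config; defaults to \code{config1} with 15
#'   iterations.
#' @param ssr_threshold Selection threshold for the Kp pooling (0.03).
#' @param cv_threshold Strong-convergence CV threshold (0.3).
#' @param verbose Print progress.
#' @return List of class \code{pbpk_pipeline}: \code{stage1},
#'   \code{selected}, \code{mask}, \code{stage2}, \code{cv1}, \code{cv2},
#'   \code{strong}, \code{age_summary}.
#' @export
runPipeline <- function(inputs, config1 = cnmPreset("reduced", stage = 1L),
                        config2 = NULL, ssr_threshold = 0.03,
                        cv_threshold = 0.3, verbose = FALSE) {
  if (is.null(config2)) {
    config2 <- config1
    config2$iterations <- 15L
    if (!is.null(config1$seed)) config2$seed <- config1$seed + 500L
  }
  stage1 <- runStage1(inputs, config1, verbose = verbose)
  selected <- selectLowSSR(stage1, ssr_threshold)
  mask <- medianKp(selected)
  stage2 <- runStage2(inputs, mask, config2, verbose = verbose)
  cv1 <- cvReport(stage1, cv_threshold)
  cv2 <- cvReport(stage2, cv_threshold)
  structure(list(stage1 = stage1, selected = selected, mask = mask,
                 stage2 = stage2, cv1 = cv1, cv2 = cv2,
                 strong = selectStrong(cv2),
                 age_summary = ageGroupSummary(inputs$patients, stage2)),
            class = "pbpk_pipeline")
}

#' @export
print.pbpk_pipeline <- function(x, ...) {
  cat("<pbpk_pipeline> three-step constraint-based perturbation analysis\n")
  minssr <- vapply(x$stage1, function(h) min(h$final$ssr, na.rm = TRUE), 0)
  cat("  stage-1 min SSR per patient:",
      paste(sprintf("%s=%.3g", names(minssr), minssr), collapse = ", "), "\n")
  cat("  pooled low-SSR sets:", nrow(x$selected$points), "\n")
  strong <- x$strong$all_patients
  cat("  strongly converging in all patients:",
      if (length(strong)) paste(parameterTable()$name[strong], collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
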