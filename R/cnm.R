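# Cluster Newton Method (CNM) with the dS dividing-point modification.
#
# The method keeps a cloud of parameter points, fits one global affine
# surrogate of the forward map over the cloud, and moves every point by the
# minimum-norm Newton step toward (a per-point randomized copy of) the
# target observables. dS in [0,1] damps the step: the new point divides
# the segment [x, x + s] so that dS = 0 takes the full original-CNM step
# and dS = 1 leaves the point in place.

#' Configuration for a CNM run
#'
#' @param n_points Cluster size (number of virtual samples). Default 1000.
#' @param iterations Number of cluster iterations (10 for the first,
#'   unconstrained stage; 15 for the Kp-constrained second stage).
#' @param ds Dividing-point parameter in [0, 1]; each point moves by
#'   \code{(1 - ds)} of its full Newton step. Default 0.2.
#' @param eta Half-width of the multiplicative uniform perturbation applied
#'   per point to the target vector (keeps the cluster diverse). Default
#'   0.05, placing the induced objective-space diversity
#'   (\code{13 * eta^2 / 3} in relative SSR units) just below the 0.03
#'   selection threshold used downstream.
#' @param svd_cutoff Relative singular-value cutoff of the pseudoinverse
#'   (default 0.01). The slope matrix is a regression estimate, so its
#'   smallest singular values are fit noise; truncating them keeps the
#'   minimum-norm step from exploding along poorly identified directions.
#' @param sampling Initial sampling of each free coordinate within its
#'   bounds: \code{"log"}-uniform (default; ranges span decades) or
#'   \code{"linear"}.
#' @param space Coordinate space for the affine fit and Newton step:
#'   \code{"log"} (default; keeps parameters positive, steps are
#'   multiplicative) or \code{"linear"}.
#' @param residual Residual scale of the SSR: \code{"relative"} (default)
#'   or \code{"absolute"}.
#' @param perturb_each_iteration Redraw the per-point target perturbation
#'   every iteration (TRUE) or draw it once at initialization (FALSE, the
#'   default). Draw-once lets each point converge onto its own randomized
#'   copy of the target; redrawing keeps the cloud mixing but floors the
#'   attainable SSR near \code{13 * eta^2 / 3}.
#' @param seed Optional integer seed making the run reproducible.
#' @return A list of class \code{cnm_config}.
#' @export
cnmConfig <- function(n_points = 1000L, iterations = 10L, ds = 0.2,
                      eta = 0.05, svd_cutoff = 1e-2,
                      sampling = c("log", "linear"),
                      space = c("log", "linear"),
                      residual = c("relative", "absolute"),
                      perturb_each_iteration = FALSE, seed = NULL) {
  sampling <- match.arg(sampling)
  space <- match.arg(space)
  residual <- match.arg(residual)
  if (ds < 0 || ds > 1) stop("ds must lie in [0, 1]")
  if (eta < 0) stop("eta must be non-negative")
  n_points <- as.integer(n_points)
  if (n_points < 13L) stop("need at least as many points as objectives")
  structure(list(n_points = n_points, iterations = as.integer(iterations),
                 ds = ds, eta = eta, svd_cutoff = svd_cutoff,
                 sampling = sampling, space = space, residual = residual,
                 perturb_each_iteration = perturb_each_iteration,
                 seed = seed),
            class = "cnm_config")
}

#' Preset CNM configurations
#'
#' \code{"paper"}: 1000 points, 10 first-stage / 15 second-stage
#' iterations, dS = 0.2. \code{"reduced"}: the same schedule with 300
#' points, keeping runs desk-scale.
#'
#' @param name \code{"paper"} or \code{"reduced"}.
#' @param stage 1 (unconstrained) or 2 (Kp-constrained); sets the
#'   iteration count.
#' @param seed Optional seed.
#' @return A \code{\link{cnmConfig}}.
#' @export
cnmPreset <- function(name = c("reduced", "paper"), stage = 1L, seed = NULL) {
  name <- match.arg(name)
  n <- if (name == "paper") 1000L else 300L
  iters <- if (stage == 1L) 10L else 15L
  cnmConfig(n_points = n, iterations = iters, ds = 0.2, seed = seed)
}

freeIndices <- function(n_params, mask) {
  fixed <- if (is.null(mask)) integer(0) else mask$indices
  setdiff(seq_len(n_params), fixed)
}

toSpace <- function(x, space) if (space == "log") log(x) else x
fromSpace <- function(x, space) if (space == "log") exp(x) else x

sampleFree <- function(n, lower, upper, sampling) {
  # one row per draw, one column per free coordinate
  k <- length(lower)
  u <- matrix(stats::runif(n * k), nrow = n, ncol = k)
  if (sampling == "log") {
    exp(sweep(sweep(u, 2, log(upper) - log(lower), "*"), 2, log(lower), "+"))
  } else {
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  }
}

newCluster <- function(points, iteration = 0L) {
  n <- nrow(points)
  structure(list(points = points,
                 observables = matrix(NA_real_, n, 13L,
                                      dimnames = list(NULL, observableNames())),
                 ssr = rep(NA_real_, n),
                 status = rep("ok", n),
                 iteration = as.integer(iteration)),
            class = "cnm_cluster")
}

#' @export
print.cnm_cluster <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("<cnm_cluster> %d points x %d parameters, iteration %d\n",
              nrow(x$points), ncol(x$points), x$iteration))
  if (any(ok & !is.na(x$ssr))) {
    q <- stats::quantile(x$ssr[ok], c(0, .25, .5, .75, 1), na.rm = TRUE)
    cat("  SSR min/median/max:",
        format(q[c(1, 3, 5)], digits = 3), "\n")
  }
  invisible(x)
}

#' Draw the initial CNM cluster
#'
#' Free coordinates are sampled independently (log-uniformly by default)
#' within their bounds; coordinates covered by the constraint mask are set
#' exactly to their fixed values.
#'
#' @param bounds A \code{\link{boundBox}}.
#' @param mask Optional \code{\link{constraintMask}}.
#' @param config A \code{\link{cnmConfig}}; \code{config$seed} (if set and
#'   \code{reseed}) seeds the draw.
#' @param reseed Honour \code{config$seed} (set FALSE when the caller
#'   manages the RNG stream).
#' @return A \code{cnm_cluster} with unevaluated observables.
#' @export
sampleInitialCluster <- function(bounds, mask = NULL, config = cnmConfig(),
                                 reseed = TRUE) {
  np <- length(bounds$lower)
  free <- freeIndices(np, mask)
  if (length(free) == 0L) stop("no free parameters: the mask fixes everything")
  if (reseed && !is.null(config$seed)) set.seed(config$seed)
  pts <- matrix(NA_real_, config$n_points, np)
  pts[, free] <- sampleFree(config$n_points, bounds$lower[free],
                            bounds$upper[free], config$sampling)
  if (!is.null(mask) && length(mask$indices)) {
    pts[, mask$indices] <- matrix(mask$values, config$n_points,
                                  length(mask$indices), byrow = TRUE)
  }
  newCluster(pts)
}

#' Sum of squared residuals between calculated and target observables
#'
#' With relative scaling (default), each residual is
#' \code{(calc - target)/target}, so percent-of-dose recoveries and ug/ml
#' concentrations contribute comparably.
#'
#' @param calculated,target Numeric vectors of equal length.
#' @param residual \code{"relative"} or \code{"absolute"}.
#' @return Scalar SSR.
#' @export
#' @examples
#' ssr(c(1.1, 0.9), c(1, 1))   # 0.02
ssr <- function(calculated, target, residual = "relative") {
  if (length(calculated) != length(target)) {
    stop("calculated/target length mismatch")
  }
  if (residual == "relative") {
    if (any(target <= 0)) stop("relative residuals need strictly positive targets")
    sum(((calculated - target) / target)^2)
  } else {
    sum((calculated - target)^2)
  }
}

evaluateCluster <- function(cluster, forward, targets, residual) {
  for (j in seq_len(nrow(cluster$points))) {
    obs <- forward(cluster$points[j, ])
    if (is.null(obs) || anyNA(obs) || any(!is.finite(obs))) {
      cluster$status[j] <- "failed"
      cluster$ssr[j] <- NA_real_
      cluster$observables[j, ] <- NA_real_
    } else {
      cluster$status[j] <- "ok"
      cluster$observables[j, ] <- obs
      cluster$ssr[j] <- ssr(obs, targets, residual)
    }
  }
  cluster
}

#' Fit the affine surrogate of the forward map over a cluster
#'
#' Least-squares fit of each observable against the free parameter
#' coordinates (in the configured space) over the ok points of the
#' cluster: \code{y ~ A x + b}.
#'
#' @param cluster An evaluated \code{cnm_cluster}.
#' @param mask Optional \code{\link{constraintMask}}.
#' @param config A \code{\link{cnmConfig}} (\code{space} is used).
#' @return List with the slope matrix \code{A} (13 x n_free), intercept
#'   \code{b} (13), \code{free} indices, and \code{space}.
#' @export
fitLinearMap <- function(cluster, mask = NULL, config = cnmConfig()) {
  free <- freeIndices(ncol(cluster$points), mask)
  ok <- cluster$status == "ok" & !is.na(cluster$ssr)
  if (sum(ok) < length(free) + 1L) {
    stop("affine fit needs at least ", length(free) + 1L,
         " ok points; increase the cluster size")
  }
  X <- toSpace(cluster$points[ok, free, drop = FALSE], config$space)
  M <- cbind(1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    stop("rank-deficient design (rank ", qrM$rank, " < ", ncol(M),
         "); increase the cluster size or free-parameter spread")
  }
  B <- qr.coef(qrM, cluster$observables[ok, , drop = FALSE])
  list(A = t(B[-1, , drop = FALSE]), b = as.numeric(B[1, ]),
       free = free, space = config$space)
}

pseudoInverse <- function(A, cutoff) {
  sv <- svd(A)
  keep <- sv$d > cutoff * max(sv$d)
  if (!any(keep)) stop("surrogate slope matrix is numerically zero")
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' One CNM cluster update
#'
#' For each ok point, perturbs the target multiplicatively (uniform on
#' \code{[-eta, eta]} per component), forms the Newton residual between the
#' perturbed target and the point's evaluated observables (falling back to
#' the surrogate prediction where observables are unevaluated), solves the
#' surrogate system by minimum-norm SVD pseudoinverse, and moves the point
#' by \code{(1 - ds)} of that step, clipped to the bounds. With relative
#' residuals the system rows are scaled by \code{1/target}, so the step
#' minimizes the same relative metric the SSR scores. Fixed coordinates
#' are left untouched; failed points are resampled within the bounds.
#'
#' @param cluster Evaluated \code{cnm_cluster}.
#' @param map Surrogate from \code{\link{fitLinearMap}}.
#' @param targets Length-13 target observable vector.
#' @param config A \code{\link{cnmConfig}}.
#' @param mask Optional \code{\link{constraintMask}}.
#' @param bounds A \code{\link{boundBox}}.
#' @param perturbation Optional pre-drawn n x 13 perturbation matrix
#'   (entries in [-eta, eta]); drawn internally when NULL.
#' @return A new, unevaluated \code{cnm_cluster} with incremented
#'   iteration counter.
#' @export
cnmUpdate <- function(cluster, map, targets, config, mask = NULL,
                      bounds, perturbation = NULL) {
  free <- map$free
  n <- nrow(cluster$points)
  ok <- cluster$status == "ok" & !is.na(cluster$ssr)
  if (!any(ok)) stop("all cluster points failed; cannot update")
  lo <- toSpace(bounds$lower[free], map$space)
  hi <- toSpace(bounds$upper[free], map$space)

  X <- toSpace(cluster$points[, free, drop = FALSE], map$space)
  pred <- X %*% t(map$A) + matrix(map$b, n, 13L, byrow = TRUE)
  y <- cluster$observables
  use_pred <- is.na(y)
  y[use_pred] <- pred[use_pred]
  if (is.null(perturbation)) {
    perturbation <- matrix(stats::runif(n * 13L, -config$eta, config$eta),
                           n, 13L)
  }
  ystar <- matrix(targets, n, 13L, byrow = TRUE) * (1 + perturbation)
  resid <- ystar - y
  A <- map$A
  if (config$residual == "relative") {
    A <- A / targets
    resid <- resid / matrix(targets, n, 13L, byrow = TRUE)
  }
  pinvA <- pseudoInverse(A, config$svd_cutoff)          # n_free x 13
  steps <- resid %*% t(pinvA)                           # n x n_free
  Xnew <- X + (1 - config$ds) * steps
  Xnew <- pmin(pmax(Xnew, matrix(lo, n, length(free), byrow = TRUE)),
               matrix(hi, n, length(free), byrow = TRUE))
  if (any(!ok)) {
    Xnew[!ok, ] <- toSpace(
      sampleFree(sum(!ok), bounds$lower[free], bounds$upper[free],
                 config$sampling), map$space)
  }

  pts <- cluster$points
  # second clip in the original space: exp(log(upper)) can overshoot by 1 ulp
  pts[, free] <- pmin(pmax(fromSpace(Xnew, map$space),
                           matrix(bounds$lower[free], n, length(free),
                                  byrow = TRUE)),
                      matrix(bounds$upper[free], n, length(free),
                             byrow = TRUE))
  if (!is.null(mask) && length(mask$indices)) {
    pts[, mask$indices] <- matrix(mask$values, n, length(mask$indices),
                                  byrow = TRUE)
  }
  newCluster(pts, cluster$iteration + 1L)
}

#' Run the Cluster Newton Method
#'
#' Samples an initial cluster, then alternates affine-surrogate fitting,
#' damped minimum-norm updates, and forward re-evaluation for
#' \code{config$iterations} iterations. Evaluation is serial, so a fixed
#' \code{config$seed} makes the whole run bitwise reproducible.
#'
#' @param forward Function mapping a full parameter vector (length of the
#'   bounds) to the 13 observables, or NULL/NA on simulation failure.
#' @param targets Length-13 positive target vector.
#' @param bounds A \code{\link{boundBox}}.
#' @param mask Optional \code{\link{constraintMask}} (fixed coordinates).
#' @param config A \code{\link{cnmConfig}}.
#' @param init Optional pre-built initial \code{cnm_cluster} (e.g. the
#'   final cluster of a previous stage); sampled fresh when NULL.
#' @param verbose Print per-iteration SSR quantiles.
#' @return List of class \code{cnm_history}: \code{clusters} (evaluated
#'   cluster per iteration, element 1 = initial), \code{final} (last
#'   cluster), \code{config}, \code{mask}.
#' @export
runCNM <- function(forward, targets, bounds, mask = NULL,
                   config = cnmConfig(), init = NULL, verbose = FALSE) {
  if (length(targets) != 13L || any(targets <= 0)) {
    stop("targets must be 13 positive observables")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cluster <- if (is.null(init)) {
    sampleInitialCluster(bounds, mask, config, reseed = FALSE)
  } else init
  cluster <- evaluateCluster(cluster, forward, targets, config$residual)
  history <- vector("list", config$iterations + 1L)
  history[[1L]] <- cluster
  perturbation <- NULL
  for (it in seq_len(config$iterations)) {
    map <- fitLinearMap(cluster, mask, config)
    if (config$perturb_each_iteration || is.null(perturbation)) {
      perturbation <- matrix(
        stats::runif(nrow(cluster$points) * 13L, -config$eta, config$eta),
        nrow(cluster$points), 13L)
    }
    cluster <- cnmUpdate(cluster, map, targets, config, mask, bounds,
                         perturbation = perturbation)
    cluster <- evaluateCluster(cluster, forward, targets, config$residual)
    if (all(cluster$status != "ok")) {
      stop("all cluster points failed at iteration ", it)
    }
    if (verbose) {
      q <- stats::quantile(cluster$ssr[cluster$status == "ok"],
                           c(.05, .5, .95), na.rm = TRUE)
      message(sprintf("iter %2d  SSR q05 %.4g  median %.4g  q95 %.4g",
                      it, q[1], q[2], q[3]))
    }
    history[[it + 1L]] <- cluster
  }
  structure(list(clusters = history, final = cluster,
                 config = config, mask = mask),
            class = "cnm_history")
}

#' @export
print.cnm_history <- function(x, ...) {
  cat(sprintf("<cnm_history> %d iterations, %d points\n",
              length(x$clusters) - 1L, nrow(x$final$points)))
  print(x$final)
  invisible(x)
}

#' Forward-map factory for one patient
#'
#' Binds a patient's physiology into a closure suitable for
#' \code{\link{runCNM}}: parameter vector in, 13 observables out, NULL on
#' integrator failure.
#'
#' @param phys A \code{patient_physiology}.
#' @param horizon,rtol Passed to \code{\link{simulatePBPK}}.
#' @return \code{function(theta) -> numeric(13) | NULL}.
#' @export
patientForward <- function(phys, horizon = 30240, rtol = 1e-6) {
  times <- defaultOutputTimes(phys$infusion_duration, horizon)
  function(theta) {
    res <- simulatePBPK(phys, theta, horizon = horizon, rtol = rtol,
                        times = times)
    if (res$status != "ok") return(NULL)
    computeObservables(res)
  }
}
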