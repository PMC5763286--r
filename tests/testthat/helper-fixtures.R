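# Shared fixtures and memoised heavy runs.

# a flat parameter vector: Kp = 1 everywhere, all elimination/metabolism
# and transit rates at `level` (0 allowed: assembleRHS/simulate do not
# require positivity, only the estimator's bounds do)
flatParams <- function(level = 0) {
  c(rep(1, 70), rep(level, 35))
}

testPatient <- function(i = 1L) studyPatients()[[i]]

# a 13-observable affine toy forward map on k parameters
affineToy <- function(k = 2L, seed = 99L) {
  set.seed(seed)
  A <- matrix(stats::rnorm(13L * k), 13L, k)
  b <- stats::rnorm(13L)
  list(A = A, b = b,
       forward = function(theta) as.numeric(A %*% theta + b))
}

# smooth nonlinear toy on the full 105-parameter layout: power-law map of
# three influential coordinates, cheap stand-in for the PBPK forward
toy105 <- function(theta) {
  x <- log(theta[c(71, 76, 83)])
  base <- c(20, 0.5, 3, 0.2, 2, 45, 12, 2, 11, 1.5, 0.05, 0.1, 0.2)
  w <- matrix(c( 0.8, -0.3, -0.2,
                -0.2,  0.5, -0.1,
                 0.3,  0.2, -0.4), 3, 3, byrow = TRUE)
  f <- as.numeric(w %*% x)
  base * exp(c(f[1], f[2], f[3], f[1] / 2, f[2] / 2, -f[1] / 2,
               f[3] / 2, -f[2] / 2, f[1] / 4, f[2] / 4, -f[3] / 2,
               f[1] / 3, f[3] / 3) / 4)
}

# memoised heavy runs shared between acceptance blocks
.heavy <- new.env(parent = emptyenv())

patient1Pipeline <- function() {
  if (is.null(.heavy$p1)) {
    study <- loadPackagedStudy()
    one <- studyInputs(study$patients[1],
                       study$objectives[1, , drop = FALSE], study$bounds)
    # single-patient study: the below-70 age group is legitimately empty
    .heavy$p1 <- suppressWarnings(
      runPipeline(one, cnmPreset("reduced", stage = 1L, seed = 1L)))
  }
  .heavy$p1
}

syntheticRecoveries <- function(seeds = 11:15) {
  key <- paste0("synth_", paste(seeds, collapse = "_"))
  if (is.null(.heavy[[key]])) {
    .heavy[[key]] <- lapply(seeds, function(s) {
      study <- makeSyntheticStudy(n_patients = 1L, noise_cv = 0, seed = s)
      suppressWarnings(recoveryExperiment(study))
    })
  }
  .heavy[[key]]
}
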