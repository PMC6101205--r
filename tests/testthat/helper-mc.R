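# Shared Monte-Carlo replicate cache for the sampling-distribution and
# coverage checks: 1000 reduced-rank refits of the workforce-style scenario
# at n = 2000, with per-replicate plug-in standard errors, computed once per
# test run.

mc_cache_env <- new.env(parent = emptyenv())

workforce_replicates <- function() {
  if (!is.null(mc_cache_env$reps)) {
    return(mc_cache_env$reps)
  }
  sc <- workforce_scenario()
  spec <- sc$spec
  xi0 <- pack_params(sc$true_params)
  n <- 2000
  nrep <- 1000
  set.seed(2026)
  seeds <- sample.int(1e6, nrep)
  E <- matrix(NA_real_, nrep, length(xi0))
  SE <- matrix(NA_real_, nrep, length(xi0))
  for (b in seq_len(nrep)) {
    ds <- simulate_dataset(sc, n = n, seed = seeds[b])
    fr <- tryCatch(
      suppressWarnings(fit_reduced(ds$X, ds$Y, spec)),
      error = function(e) NULL
    )
    if (is.null(fr) || !fr$converged) next
    E[b, ] <- fr$xi
    cv <- avar_reduced(
      estimate_W(ds$X, fr$params, spec),
      build_G(fr$params$C, fr$params$B, spec),
      n = n
    )
    SE[b, ] <- cv$se
  }
  # analytic avar at the true parameters; W from a large predictor draw
  dsW <- simulate_dataset(sc, n = 2e5, seed = 1234)
  W0 <- estimate_W(dsW$X, sc$true_params, spec)
  av0 <- avar_reduced(
    W0, build_G(sc$true_params$C, sc$true_params$B, spec)
  )$avar
  mc_cache_env$reps <- list(
    scenario = sc, n = n, xi0 = xi0, E = E, SE = SE, avar0 = av0,
    ok = stats::complete.cases(E)
  )
  mc_cache_env$reps
}
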