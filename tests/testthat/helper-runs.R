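# Shared scaled evolution runs, computed once per test session and reused
# across the acceptance criteria (they are expensive).

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# Scaled study conditions for the criticality-emergence runs (problem sizes
# chosen for desk-scale compute; see the methods vignette).
scaled_alpha_config <- function(start = c("ordered", "chaotic"), seed) {
  start <- match.arg(start)
  if (start == "ordered")
    evolution_config(M0 = 150L, N0 = 10L, K0 = 1L, p0 = 0.5,
                     total_generations = 2000L, duplication_period = 500L,
                     mutation = mutation_config(mu = 0.01),
                     fitness = fitness_spec("alpha"), seed = seed)
  else
    evolution_config(M0 = 150L, N0 = 10L, K0 = 4L, p0 = 0.5,
                     total_generations = 3000L, duplication_period = 750L,
                     mutation = mutation_config(mu = 0.01),
                     fitness = fitness_spec("alpha"), seed = seed)
}

# Final sensitivity = mean over the trailing 10% of generations (averaging
# damps the generation-to-generation fluctuation of small populations).
final_mean_S <- function(run) {
  k <- max(1L, floor(nrow(run$census) * 0.1))
  mean(tail(run$census$mean_S, k))
}

scaled_alpha_run <- function(start, seed) {
  cached(paste0("alpha_", start, "_", seed),
         run_evolution(scaled_alpha_config(start, seed)))
}

scaled_control_run <- function(start, seed) {
  cfg <- scaled_alpha_config(start, seed)
  cfg$selection <- FALSE
  cfg$total_generations <- 1000L
  cfg$duplication_period <- 250L
  cfg$M0 <- 50L
  cached(paste0("control_", start, "_", seed), run_evolution(cfg))
}

scaled_sfit_run <- function(seed) {
  cached(paste0("sfit_", seed), {
    cfg <- evolution_config(M0 = 100L, N0 = 10L, K0 = 4L, p0 = 0.5,
                            total_generations = 1500L,
                            duplication_period = 500L,
                            mutation = mutation_config(mu = 0.005),
                            fitness = fitness_spec("S"), seed = seed)
    run_evolution(cfg)
  })
}

de_novo_pop <- function(seed = 99L, M = 100L, N = 15L) {
  cached(paste0("denovo_", seed, "_", M, "_", N), {
    set.seed(seed)
    de_novo_critical_ensemble(M, N)
  })
}
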