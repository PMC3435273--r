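# The generation loop: mutation -> ACC -> replication, with periodic
# duplication -> AIC -> fitness replication, lineage tracking and census.

#' Evolution run configuration
#'
#' @param M0 Nominal population size.
#' @param N0 Initial gene count per network.
#' @param K0 Initial in-degree (integer, or range `c(lo, hi)`).
#' @param p0 Initial truth-table bias.
#' @param total_generations Number of generations to run.
#' @param duplication_period Generations between simultaneous
#'   duplication-divergence events (default 2000, giving a per-gene
#'   duplication rate of order `1e-5`).
#' @param N_max Growth cap on network size.
#' @param mutation A [mutation_config()].
#' @param search A [search_config()].
#' @param fitness A [fitness_spec()].
#' @param selection Apply the ACC/AIC filters (`FALSE` gives the unselected
#'   mutagenesis control, in which every network survives).
#' @param strain_check_interval Generations between strain censuses.
#' @param seed Integer seed; whole runs are a pure function of
#'   (config, seed).
#' @return A list of class `rbn_evolution_config`.
#' @export
evolution_config <- function(M0 = 1000L, N0 = 10L, K0 = 2L, p0 = 0.5,
                             total_generations = 10000L,
                             duplication_period = 2000L, N_max = 100L,
                             mutation = mutation_config(),
                             search = search_config(),
                             fitness = fitness_spec("alpha"),
                             selection = TRUE,
                             strain_check_interval = 20L,
                             seed = 1L) {
  stopifnot(M0 >= 1L, N0 >= 2L, total_generations >= 1L,
            duplication_period >= 1L, N_max >= N0)
  structure(list(M0 = as.integer(M0), N0 = as.integer(N0), K0 = as.integer(K0),
                 p0 = p0, total_generations = as.integer(total_generations),
                 duplication_period = as.integer(duplication_period),
                 N_max = as.integer(N_max), mutation = mutation,
                 search = search, fitness = fitness, selection = selection,
                 strain_check_interval = as.integer(strain_check_interval),
                 seed = as.integer(seed)),
            class = "rbn_evolution_config")
}

#' Initial population of random networks
#'
#' Builds `M0` random networks and fully enumerates the attractor landscape
#' of every one (the only generation at which complete enumeration is
#' performed; thereafter tracked landscapes change only through conservation
#' updates and search additions). Strains are labelled `1..M0`.
#'
#' @param cfg An [evolution_config()]; `N0` must be below the exhaustive
#'   enumeration bound.
#' @return An object of class `rbn_population` with fields `networks`,
#'   `landscapes` (tracked, full width), `strains`, `generation`.
#' @export
init_population <- function(cfg) {
  if (cfg$N0 >= cfg$search$exhaustive_below)
    stop("N0 must be below exhaustive_below so initial landscapes can be enumerated")
  nets <- vector("list", cfg$M0)
  lands <- vector("list", cfg$M0)
  for (i in seq_len(cfg$M0)) {
    net <- random_network(cfg$N0, cfg$K0, cfg$p0,
                          k_max = cfg$mutation$k_max,
                          allow_self = cfg$mutation$allow_self)
    net$strain <- i
    nets[[i]] <- net
    lands[[i]] <- cache_alpha(enumerate_attractors(net, cfg$search$exhaustive_below))
  }
  structure(list(networks = nets, landscapes = lands,
                 strains = seq_len(cfg$M0), generation = 0L,
                 S = vapply(nets, annealed_sensitivity, numeric(1))),
            class = "rbn_population")
}

#' @export
print.rbn_population <- function(x, ...) {
  cat("Population:", length(x$networks), "networks, generation",
      x$generation, ",", length(unique(x$strains)), "strains\n")
  invisible(x)
}

population_fitnesses <- function(pop, spec) {
  vapply(seq_along(pop$networks), function(i)
    network_fitness(pop$networks[[i]], pop$landscapes[[i]], spec), numeric(1))
}

apply_replication <- function(pop, cfg, run_env = NULL) {
  m <- length(pop$networks)
  if (m >= cfg$fitness$replication_threshold_fraction * cfg$M0) return(pop)
  f <- population_fitnesses(pop, cfg$fitness)
  rep_out <- replicate_survivors(pop$networks, f, cfg$M0, cfg$fitness,
                                 warn_env = run_env)
  copies <- rep_out$copies
  idx <- rep(seq_len(m), times = copies)
  pop$networks <- pop$networks[idx]
  pop$landscapes <- pop$landscapes[idx]
  pop$strains <- pop$strains[idx]
  pop$S <- pop$S[idx]
  pop
}

#' Run one ordinary (point-mutation) generation
#'
#' Each network is mutated with [mutate_network()]; networks with at least
#' one effective mutation are tested against their tracked landscape by the
#' ACC and removed on failure (unmutated networks pass untouched). If the
#' survivor count falls below the replication threshold, survivors
#' replicate in proportion to fitness.
#'
#' @param pop An `rbn_population`.
#' @param cfg An [evolution_config()].
#' @param run_env Internal environment for once-per-run warnings.
#' @return The next-generation population; signals a condition of class
#'   `rbn_extinction` if no network survives.
#' @export
run_generation <- function(pop, cfg, run_env = NULL) {
  keep <- logical(length(pop$networks))
  for (i in seq_along(pop$networks)) {
    res <- mutate_network(pop$networks[[i]], cfg$mutation)
    if (!records_effective(res$records)) {   # untouched: passes by reflexivity
      keep[i] <- TRUE
      next
    }
    if (!cfg$selection) {
      pop$networks[[i]] <- res$net
      pop$S[i] <- annealed_sensitivity(res$net)
      keep[i] <- TRUE
      next
    }
    ok <- conserve_landscape(pop$landscapes[[i]], res$net)$ok
    if (ok) {
      pop$networks[[i]] <- res$net
      pop$S[i] <- annealed_sensitivity(res$net)
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) signal_extinction(pop$generation + 1L)
  pop$networks <- pop$networks[keep]
  pop$landscapes <- pop$landscapes[keep]
  pop$strains <- pop$strains[keep]
  pop$S <- pop$S[keep]
  pop$generation <- pop$generation + 1L
  attr(pop, "survivors") <- sum(keep)
  apply_replication(pop, cfg, run_env)
}

#' Run a duplication-divergence generation
#'
#' Every network undergoes [duplicate_gene()] (capped networks are skipped
#' and pass through). Under selection, a duplicated network survives only if
#' it satisfies the ACC *and* the attractor search finds at least one new
#' attractor (AIC); its tracked landscape is then re-expressed at full width
#' and extended with the finds, up to the landscape cap. Survivors replicate
#' by fitness under the usual threshold rule.
#'
#' @inheritParams run_generation
#' @return The next-generation population; signals `rbn_extinction` when no
#'   network survives the AIC.
#' @export
run_duplication_generation <- function(pop, cfg, run_env = NULL) {
  keep <- logical(length(pop$networks))
  for (i in seq_along(pop$networks)) {
    net <- pop$networks[[i]]
    if (network_size(net) >= cfg$N_max) {   # growth cap: event is a no-op
      keep[i] <- TRUE
      next
    }
    old_n <- network_size(net)
    dup <- duplicate_gene(net, cfg$mutation, n_max = cfg$N_max)
    if (!cfg$selection) {
      pop$networks[[i]] <- dup$net
      pop$S[i] <- annealed_sensitivity(dup$net)
      keep[i] <- TRUE
      next
    }
    cons <- conserve_landscape(pop$landscapes[[i]], dup$net)
    if (!cons$ok) next
    tracked <- landscape(cons$attractors, complete = FALSE)
    room <- cfg$search$landscape_cap - length(tracked$attractors)
    if (room <= 0L) next                    # cannot innovate past the cap
    scfg <- cfg$search
    scfg$D_max_new <- min(scfg$D_max_new, room)
    found <- search_new_attractors(dup$net, tracked, scfg,
                                   compare_width = old_n)
    if (length(found) == 0L) next           # AIC: innovation required
    pop$networks[[i]] <- dup$net
    pop$S[i] <- annealed_sensitivity(dup$net)
    pop$landscapes[[i]] <- cache_alpha(landscape(c(tracked$attractors, found),
                                                 complete = FALSE))
    keep[i] <- TRUE
  }
  if (!any(keep)) signal_extinction(pop$generation + 1L)
  pop$networks <- pop$networks[keep]
  pop$landscapes <- pop$landscapes[keep]
  pop$strains <- pop$strains[keep]
  pop$S <- pop$S[keep]
  pop$generation <- pop$generation + 1L
  attr(pop, "survivors") <- sum(keep)
  apply_replication(pop, cfg, run_env)
}

signal_extinction <- function(generation) {
  stop(structure(class = c("rbn_extinction", "error", "condition"),
                 list(message = paste0("extinction at generation ", generation),
                      call = NULL)))
}

# alpha_h depends only on the tracked landscape, so it is cached on the
# landscape object (set at creation/update) and only read here.
landscape_alpha_h <- function(ls) {
  if (!is.null(ls$alpha_h)) ls$alpha_h else variability(ls)$alpha_h
}

cache_alpha <- function(ls) {
  ls$alpha_h <- variability(ls)$alpha_h
  ls
}

census_row <- function(pop, cfg, event, survivors) {
  s <- if (!is.null(pop$S)) pop$S
       else vapply(pop$networks, annealed_sensitivity, numeric(1))
  a_h <- if (cfg$selection)
    mean(vapply(pop$landscapes, landscape_alpha_h, numeric(1)))
  else NA_real_
  data.frame(generation = pop$generation, size = length(pop$networks),
             survivors = survivors, mean_S = mean(s), sd_S = sd(s),
             mean_alpha_h = a_h,
             mean_N = mean(vapply(pop$networks, network_size, integer(1))),
             n_strains = length(unique(pop$strains)), event = event,
             stringsAsFactors = FALSE)
}

#' Run a whole evolutionary simulation
#'
#' Executes `total_generations` generations, interleaving a simultaneous
#' duplication-divergence event (with the AIC filter) every
#' `duplication_period` generations, and records a per-generation census,
#' a lineage log (strains checked every `strain_check_interval`
#' generations), and optional checkpoints. Runs are bit-reproducible from
#' `(config, seed)`.
#'
#' @param cfg An [evolution_config()].
#' @param initial_population Optional pre-built `rbn_population` (e.g. from
#'   [seeded_hub_experiment()] construction or a checkpoint); the RNG is
#'   still seeded from `cfg$seed`.
#' @param resume Optional checkpoint (from [save_checkpoint()] /
#'   [read_checkpoint()]) to continue from; overrides `initial_population`
#'   and restores the RNG state.
#' @param out_dir Optional directory; when given, the census CSV and a
#'   checkpoint at every duplication event are written there.
#' @param checkpoint_every Write checkpoints at duplication events when
#'   `out_dir` is set.
#' @return List of class `rbn_run` with `census` (data frame), `lineage`
#'   (closed survival intervals and fixation events), `population`,
#'   `status` (`"completed"` or `"extinct"`), and `config`.
#' @export
run_evolution <- function(cfg, initial_population = NULL, resume = NULL,
                          out_dir = NULL, checkpoint_every = TRUE) {
  run_env <- new.env(parent = emptyenv())
  if (!is.null(resume)) {
    pop <- resume$population
    assign(".Random.seed", resume$rng_state, envir = globalenv())
    lineage <- resume$lineage
    census <- resume$census
    if (is.data.frame(census)) census <- list(census)
  } else {
    set.seed(cfg$seed)
    pop <- if (is.null(initial_population)) init_population(cfg)
           else initial_population
    lineage <- new_lineage_log(pop)
    census <- list()
  }
  status <- "completed"
  g0 <- pop$generation
  for (g in seq.int(g0 + 1L, cfg$total_generations)) {
    is_dup <- g %% cfg$duplication_period == 0L
    res <- tryCatch(
      if (is_dup) run_duplication_generation(pop, cfg, run_env)
      else run_generation(pop, cfg, run_env),
      rbn_extinction = function(e) e)
    if (inherits(res, "rbn_extinction")) {
      status <- "extinct"            # pop keeps the last surviving generation
      attr(status, "generation") <- g
      break
    }
    pop <- res
    census[[length(census) + 1L]] <-
      census_row(pop, cfg, if (is_dup) "duplication" else "mutation",
                 attr(pop, "survivors"))
    if (g %% cfg$strain_check_interval == 0L) {
      upd <- track_strains(pop, lineage, g)
      pop <- upd$population
      lineage <- upd$lineage
    }
    if (!is.null(out_dir) && is_dup && checkpoint_every)
      save_checkpoint(list(population = pop, lineage = lineage,
                           census = census,
                           rng_state = get(".Random.seed", globalenv())),
                      file.path(out_dir, sprintf("checkpoint_g%06d.json", g)))
  }
  census <- do.call(rbind, census)
  run <- structure(list(census = census, lineage = lineage, population = pop,
                        status = status, config = cfg),
                   class = "rbn_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(census, file.path(out_dir, "census.csv"), row.names = FALSE)
  }
  run
}

#' @export
print.rbn_run <- function(x, ...) {
  cat("Evolution run:", x$status, "after",
      max(x$census$generation), "generations; final mean S =",
      round(tail(x$census$mean_S, 1), 4), "\n")
  invisible(x)
}

# ---- lineage tracking ----

new_lineage_log <- function(pop) {
  list(birth = setNames(rep(0L, length(unique(pop$strains))),
                        sort(unique(pop$strains))),
       intervals = data.frame(strain = integer(0), birth = integer(0),
                              death = integer(0), nu = integer(0)),
       fixations = integer(0))
}

#' Census the strains and update the lineage log
#'
#' Records which strain labels survive, closes the survival interval of any
#' label that has disappeared since the previous check (survival time = the
#' check generation minus the birth generation), and on fixation (a single
#' label remaining) records the event and relabels all networks `1..M`.
#'
#' @param pop An `rbn_population`.
#' @param lineage A lineage log (from inside [run_evolution()]).
#' @param generation Current generation index.
#' @return List with updated `population` and `lineage`.
#' @export
track_strains <- function(pop, lineage, generation) {
  alive <- unique(pop$strains)
  dead <- setdiff(as.integer(names(lineage$birth)), alive)
  for (d in dead) {
    nu <- generation - lineage$birth[[as.character(d)]]
    lineage$intervals <- rbind(lineage$intervals,
                               data.frame(strain = d,
                                          birth = lineage$birth[[as.character(d)]],
                                          death = generation, nu = nu))
  }
  lineage$birth <- lineage$birth[as.character(alive)]
  if (length(alive) == 1L) {
    lineage$fixations <- c(lineage$fixations, generation)
    # close the fixed ancestor's interval too: its lineage is relabelled
    lineage$intervals <- rbind(lineage$intervals,
                               data.frame(strain = alive,
                                          birth = lineage$birth[[as.character(alive)]],
                                          death = generation,
                                          nu = generation - lineage$birth[[as.character(alive)]]))
    m <- length(pop$networks)
    pop$strains <- seq_len(m)
    for (i in seq_len(m)) pop$networks[[i]]$strain <- i
    lineage$birth <- setNames(rep(generation, m), seq_len(m))
  }
  list(population = pop, lineage = lineage)
}

#' Survival-time distribution and power-law fit
#'
#' Logarithmically bins the closed strain survival times, fits a power law
#' `P(nu) ~ nu^(-gamma)` by least squares on the log-binned density, and
#' reports the complementary cumulative distribution, a Kolmogorov-Smirnov
#' goodness-of-fit statistic against the fitted law, and a discrete
#' maximum-likelihood exponent as a cross-check.
#'
#' @param nu Integer vector of survival times (or an `rbn_run` / lineage
#'   log, from which closed intervals are taken). At least two distinct
#'   values are required.
#' @param bins_per_decade Logarithmic binning resolution.
#' @return List of class `rbn_survival` with `exponent` (least-squares),
#'   `exponent_ml`, `binned` (data frame `center`, `density`), `ccdf`
#'   (data frame `nu`, `p`), `ks_stat`, `n`.
#' @export
survival_distribution <- function(nu, bins_per_decade = 5) {
  if (inherits(nu, "rbn_run")) nu <- nu$lineage$intervals$nu
  if (is.list(nu) && !is.null(nu$intervals)) nu <- nu$intervals$nu
  nu <- nu[nu > 0]
  if (length(nu) < 2L) stop("need at least two closed survival intervals")
  if (length(unique(nu)) < 2L)
    stop("degenerate survival data: all lifetimes identical, fit refused")
  lo <- min(nu); hi <- max(nu)
  nb <- max(2L, ceiling(log10(hi / lo) * bins_per_decade))
  edges <- lo * (hi / lo)^(seq(0, 1, length.out = nb + 1L))
  edges[1] <- edges[1] * (1 - 1e-9); edges[nb + 1L] <- edges[nb + 1L] * (1 + 1e-9)
  cnt <- tabulate(findInterval(nu, edges, rightmost.closed = TRUE), nbins = nb)
  width <- diff(edges)
  center <- sqrt(edges[-1] * edges[-(nb + 1L)])
  dens <- cnt / width / length(nu)
  use <- cnt > 0
  fit <- lm(log10(dens[use]) ~ log10(center[use]))
  gamma_ls <- -unname(coef(fit)[2])
  xmin <- min(nu)
  gamma_ml <- 1 + length(nu) / sum(log(nu / (xmin - 0.5)))
  # KS against the fitted continuous power law with the same xmin
  srt <- sort(nu)
  emp <- seq_along(srt) / length(srt)
  theo <- 1 - (srt / xmin)^(1 - gamma_ls)
  ks <- max(abs(emp - theo))
  ccdf <- data.frame(nu = srt, p = 1 - (seq_along(srt) - 1L) / length(srt))
  structure(list(exponent = gamma_ls, exponent_ml = gamma_ml,
                 binned = data.frame(center = center[use], density = dens[use]),
                 ccdf = ccdf, ks_stat = ks, n = length(nu)),
            class = "rbn_survival")
}
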