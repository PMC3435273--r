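# Knockouts, robustness assay, de novo controls, serialization.

test_that("de novo critical ensembles sit at sensitivity 1 by construction", {
  set.seed(81)
  pop <- de_novo_critical_ensemble(20, 10)
  for (net in pop$networks) {
    expect_true(all(in_degrees(net) == 2))
  }
  sa <- vapply(pop$networks, function(n) sensitivity(n)$S_annealed, numeric(1))
  expect_lt(abs(mean(sa) - 1), 0.1)   # p is sampled, so 1 in expectation
})

test_that("knockout removes the gene, collapses targets, and respects admissibility", {
  set.seed(82)
  net <- random_network(8, 2, 0.5)
  ko <- knockout(net, 3)
  if (ko$status == "ok") {
    expect_equal(network_size(ko$net), 7)
    expect_silent(validate_network(ko$net))
    expect_false(3 %in% unlist(lapply(ko$net$genes, `[[`, "bs")))
  }
  # a gene with no targets leaves all other genes' tables untouched
  lonely <- boolean_network(list(gene(1, 2, c(0L, 1L)), gene(2, 2, c(1L, 0L)),
                                 gene(3, 2, c(0L, 0L))))
  ko1 <- knockout(lonely, 1)   # gene 1 regulates nothing
  expect_equal(ko1$status, "ok")
  expect_identical(gene_by_id(ko1$net, 2)$tt, gene_by_id(lonely, 2)$tt)
  expect_identical(gene_by_id(ko1$net, 3)$tt, gene_by_id(lonely, 3)$tt)
  # sole-regulator deletion is inadmissible
  ko2 <- knockout(lonely, 2)   # gene 2 is the only regulator of everything
  expect_equal(ko2$status, "inadmissible")
  expect_true(length(ko2$blocked) > 0)
  # clamping alternative keeps N
  ko3 <- knockout(lonely, 2, method = "clamp")
  expect_equal(network_size(ko3$net), 3)
  expect_true(all(gene_by_id(ko3$net, 2)$tt == 0))
})

test_that("knocking out a gene frozen at 0 in an attractor conserves its restriction", {
  # gene 3 is constant 0 and feeds gene 1; the attractor restriction survives
  net <- boolean_network(list(
    gene(1, c(2, 3), c(0L, 1L, 0L, 1L)),  # copies gene 2 when gene 3 = 0
    gene(2, 1, c(0L, 1L)),
    gene(3, 3, c(0L, 0L))))               # frozen at 0
  ls <- enumerate_attractors(net)
  frozen <- vapply(ls$attractors, function(a) all(a$states[, 3] == 0), logical(1))
  expect_true(any(frozen))
  ko <- knockout(net, 3)
  expect_equal(ko$status, "ok")
  enc <- rbnevolve:::compile_network(ko$net)
  for (a in ls$attractors[frozen]) {
    expect_true(rbnevolve:::restricted_conserved(a, 3, enc))
  }
})

test_that("P(q) is a normalized histogram, invariant under population order", {
  set.seed(83)
  pop <- de_novo_critical_ensemble(15, 10)
  rq <- robustness_pq(pop)
  expect_equal(sum(rq$P), 1)
  expect_true(all(rq$q_values >= 0 & rq$q_values <= 100))
  pop_rev <- pop
  pop_rev$networks <- rev(pop$networks)
  pop_rev$landscapes <- rev(pop$landscapes)
  rq2 <- robustness_pq(pop_rev)
  expect_identical(rq$P, rq2$P)
})

test_that("network JSON round trips are bit-exact and schema violations are named", {
  set.seed(84)
  net <- random_network(8, c(1, 3), 0.4)
  net$strain <- 7L
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, p1)
  net2 <- read_network_json(p1)
  expect_identical(net2$genes, net$genes)
  expect_equal(net2$strain, 7)
  write_network_json(net2, p2)
  expect_identical(readLines(p1), readLines(p2))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"meta": {}}', bad)
  expect_error(read_network_json(bad), "genes")
})

test_that("landscape TSV lists one row per state with attractor ids", {
  ls <- enumerate_attractors(copy_ring(3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_landscape_tsv(ls, p)
  tab <- read.delim(p, colClasses = c("integer", "integer", "character"))
  expect_equal(nrow(tab), sum(vapply(ls$attractors, function(a) a$period, integer(1))))
  expect_equal(sort(unique(tab$attractor_id)), seq_along(ls$attractors))
  expect_true(all(nchar(tab$bitstring) == 3))
})

test_that("GraphML export carries topology, out-degrees and persistence", {
  p <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(copy_ring(3), p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_true("out_degree" %in% igraph::vertex_attr_names(g))

  pop <- structure(list(networks = list(copy_ring(3), copy_ring(3)),
                        landscapes = vector("list", 2), strains = 1:2,
                        generation = 0L),
                   class = "rbn_population")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(pop, p2)
  g2 <- igraph::read_graph(p2, format = "graphml")
  expect_true("persistence" %in% igraph::edge_attr_names(g2))
  expect_true(all(igraph::E(g2)$persistence == 1))
})

test_that("checkpoint restore continues to a bit-identical census", {
  cfg <- evolution_config(M0 = 20, N0 = 8, K0 = 2, total_generations = 120,
                          duplication_period = 60,
                          mutation = mutation_config(mu = 0.02), seed = 85)
  full <- run_evolution(cfg)
  half_cfg <- cfg
  half_cfg$total_generations <- 60L
  half <- run_evolution(half_cfg)
  cp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(list(population = half$population, lineage = half$lineage,
                       census = half$census,
                       rng_state = get(".Random.seed", globalenv())), cp)
  resumed <- run_evolution(cfg, resume = read_checkpoint(cp))
  expect_equal(full$census, resumed$census, ignore_attr = TRUE)
  expect_identical(lapply(full$population$networks, `[[`, "genes"),
                   lapply(resumed$population$networks, `[[`, "genes"))
})

test_that("YAML configs map onto evolution configs", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("M0: 50", "N0: 8", "K0: 2", "total_generations: 100",
               "duplication_period: 50",
               "mutation:", "  mu: 0.02", "fitness:", "  mode: S"), y)
  cfg <- evolution_config_from_yaml(y)
  expect_equal(cfg$M0, 50L)
  expect_equal(cfg$mutation$mu, 0.02)
  expect_equal(cfg$fitness$mode, "S")
})

test_that("the seeded hub starts with the prescribed out-degree", {
  cfg <- evolution_config(M0 = 10, N0 = 10, K0 = 2, total_generations = 40,
                          duplication_period = 20,
                          mutation = mutation_config(mu = 0.02), seed = 86)
  rep <- seeded_hub_experiment(cfg, hub_out_fraction = 0.8)
  expect_equal(rep$hub_initial_out, 8)   # 80% of the 9 other genes, rounded up
  expect_length(rep$argmax_out, length(rep$run$population$networks))
  expect_true(all(rep$final_hub_rank >= 1))
})
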