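# ACC, AIC, and fitness-proportional replication.

test_that("ACC is reflexive and strict to single truth-table flips on attractor states", {
  set.seed(51)
  for (r in 1:10) {
    net <- random_network(8, 2, 0.5)
    ls <- enumerate_attractors(net)
    expect_true(acc_check(ls, net))       # unmutated network always passes
  }

  # flipping a truth-table entry that lies on a tracked fixed point breaks it
  net <- constant_zero_net(4)
  ls <- enumerate_attractors(net)         # single all-zero fixed point
  g <- gene_by_id(net, 2)
  g$tt[1] <- 1L                           # output for the all-zero input
  expect_false(acc_check(ls, rbnevolve:::set_gene(net, g)))
  # flipping an entry never visited by the fixed point leaves the ACC intact
  g2 <- gene_by_id(net, 2)
  g2$tt[2] <- 1L                          # input config with regulator = 1
  expect_true(acc_check(ls, rbnevolve:::set_gene(net, g2)))
})

test_that("ACC after duplication compares restrictions to the first N genes", {
  set.seed(52)
  hits <- 0L
  for (r in 1:20) {
    net <- random_network(8, 2, 0.5)
    ls <- enumerate_attractors(net)
    d <- duplicate_gene(net, mutation_config(), divergence_events = 0L)
    ok <- acc_check(ls, d$net)
    if (ok) hits <- hits + 1L
    if (ok) {
      # conserved: each tracked attractor re-expressed at width 9 restricts back
      cons <- rbnevolve:::conserve_landscape(ls, d$net)
      expect_length(cons$attractors, length(ls$attractors))
      for (i in seq_along(ls$attractors))
        expect_identical(restrict_attractor(cons$attractors[[i]], 8)$key,
                         ls$attractors[[i]]$key)
    }
  }
  expect_gt(hits, 0)   # undiverged duplications conserve often (clamp argument)
})

test_that("AIC requires conservation plus at least one genuinely new attractor", {
  net <- constant_zero_net(8)
  ls <- enumerate_attractors(net)
  fake_new <- list(attractor(matrix(1L, 1, 8)))
  g <- gene_by_id(net, 2); g$tt[1] <- 1L       # breaks the tracked fixed point
  broken <- rbnevolve:::set_gene(net, g)
  expect_false(acc_check(ls, broken))
  expect_false(aic_check(ls, broken, fake_new))  # ACC failure dominates
  expect_false(aic_check(ls, net, list()))       # no innovation -> fail
  expect_true(aic_check(ls, net, fake_new))      # conserved + one new -> pass
})

test_that("replication restores the population size with proportional copies", {
  nets <- as.list(seq_len(333))   # stand-ins; replication only rearranges
  out <- replicate_survivors(nets, rep(1, 333), M0 = 1000, fitness_spec("neutral"))
  expect_true(all(out$copies == 3L))
  expect_length(out$networks, 999)

  # above threshold: pass through unchanged
  out2 <- replicate_survivors(as.list(1:600), rep(1, 600), 1000, fitness_spec())
  expect_length(out2$networks, 600)

  # proportionality: double fitness -> double copies (up to rounding)
  set.seed(54)
  for (r in 1:200) {
    m <- sample(5:60, 1)
    f <- runif(m, 0.1, 1)
    out <- replicate_survivors(as.list(seq_len(m)), f, M0 = 1000, fitness_spec())
    lambda <- 1000 / sum(f)
    expect_identical(out$copies, pmax(1L, as.integer(floor(lambda * f + 0.5))))
    expect_lt(abs(length(out$networks) - 1000), m + 1)
  }

  # all-zero fitness under S-mode falls back to neutral with one warning
  expect_warning(
    out3 <- replicate_survivors(as.list(1:10), rep(0, 10), 1000, fitness_spec("S")),
    "zero fitness")
  expect_length(out3$networks, 1000)
})

test_that("extinction is an explicit status, never a silent empty population", {
  expect_equal(extinction_check(list()), "extinct")
  expect_equal(extinction_check(list(1)), "alive")
  cfg <- evolution_config(M0 = 4, N0 = 6, K0 = 2, total_generations = 5,
                          seed = 55)
  set.seed(55)
  pop <- init_population(cfg)
  pop$networks <- pop$networks[0]; pop$landscapes <- pop$landscapes[0]
  pop$strains <- pop$strains[0]; pop$S <- pop$S[0]
  expect_error(rbnevolve:::signal_extinction(3), class = "rbn_extinction")
})

test_that("alpha-fitness refuses empty tracked landscapes", {
  set.seed(56)
  net <- random_network(6, 2, 0.5)
  expect_error(rbnevolve:::network_fitness(net, landscape(list()), fitness_spec("alpha")),
               "empty tracked landscape")
})
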