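# Data model, synchronous dynamics, exhaustive enumeration.

test_that("gene and network invariants are enforced", {
  expect_error(gene(1, integer(0), integer(0)), "binding sites")
  expect_error(gene(1, c(2, 3), c(0, 1)), "truth table")
  expect_error(gene(1, 2, c(0, 2)), "non-binary")
  expect_error(boolean_network(list(gene(1, 1, c(0, 1)), gene(1, 1, c(0, 1)))),
               "duplicated")
  # regulator referencing a gene outside the network
  expect_error(boolean_network(list(gene(1, 5, c(0, 1)))), "absent")
  # multiplicity: two binding sites for one regulator still means k = 1
  g <- gene(1, c(2, 2), c(0, 1))
  expect_identical(regulators(g), 2L)
})

test_that("random networks honour the in-degree spec, bias, and determinism", {
  set.seed(1)
  net <- random_network(10, 2, 0.5)
  expect_true(all(in_degrees(net) == 2L))
  expect_true(all(vapply(net$genes, function(g) length(g$tt), integer(1)) == 4L))

  set.seed(2)
  p0 <- random_network(30, 2, 0)
  expect_true(all(unlist(lapply(p0$genes, `[[`, "tt")) == 0L))
  # forced fixed point at the all-zero state
  expect_identical(network_step(p0, rep(0L, 30)), rep(0L, 30))

  set.seed(3); a <- random_network(50, c(1, 4), 0.5)
  set.seed(3); b <- random_network(50, c(1, 4), 0.5)
  expect_identical(a$genes, b$genes)
  expect_true(all(in_degrees(a) %in% 1:4))

  expect_error(random_network(5, 5, 0.5, allow_self = FALSE), "candidates")
  expect_error(random_network(10, 9, 0.5), "K_max")
})

test_that("synchronous step matches hand evaluation on toy networks", {
  expect_identical(network_step(swap_pair(), c(0L, 1L)), c(1L, 0L))
  # true mutual negation: (0,1) is a fixed point
  expect_identical(network_step(negation_pair(), c(0L, 1L)), c(0L, 1L))
  expect_identical(network_step(constant_zero_net(4), c(1L, 1L, 0L, 1L)),
                   rep(0L, 4))
  expect_identical(network_step(copy_ring(3), c(1L, 0L, 0L)), c(0L, 1L, 0L))
  expect_error(network_step(copy_ring(3), c(1L, 0L)), "length")
})

test_that("trajectories terminate on the correct attractor", {
  tr <- trajectory_to_attractor(constant_zero_net(5), c(1L, 0L, 1L, 1L, 0L))
  expect_equal(tr$attractor$period, 1)
  expect_identical(as.integer(tr$attractor$states), rep(0L, 5))
  expect_lte(tr$transient, 1)

  tr <- trajectory_to_attractor(swap_pair(), c(0L, 1L))
  expect_equal(tr$attractor$period, 2)
  expect_equal(tr$transient, 0)
  expect_identical(tr$attractor$key, attractor(rbind(c(0, 1), c(1, 0)))$key)

  expect_error(trajectory_to_attractor(copy_ring(4), rep(0L, 4), max_steps = 0),
               "max_steps")
  # a period-3 orbit cannot close in 2 steps
  expect_error(trajectory_to_attractor(copy_ring(3), c(1L, 0L, 0L), max_steps = 2),
               "transient-exceeded")
})

test_that("trajectory attractor agrees with full state-graph decomposition", {
  set.seed(11)
  for (rep in 1:5) {
    net <- random_network(10, 2, 0.5)
    keys <- naive_landscape_keys(net)
    s0 <- rbinom(10, 1, 0.5)
    expect_true(trajectory_to_attractor(net, s0)$attractor$key %in% keys)
  }
})

test_that("exhaustive enumeration equals the naive oracle and partitions state space", {
  ls <- enumerate_attractors(constant_zero_net(5))
  expect_length(ls$attractors, 1)
  expect_equal(ls$basin_sizes, 32)

  ls3 <- enumerate_attractors(copy_ring(3))
  expect_length(ls3$attractors, 4)  # 000, 111, and two period-3 cycles
  periods <- sort(vapply(ls3$attractors, function(a) a$period, integer(1)))
  expect_equal(periods, c(1L, 1L, 3L, 3L))

  set.seed(21)
  for (rep in 1:8) {
    net <- random_network(8, sample(1:3, 1), runif(1, 0.2, 0.8))
    ls <- enumerate_attractors(net)
    expect_equal(sum(ls$basin_sizes), 2^8)
    expect_identical(sort(vapply(ls$attractors, function(a) a$key, character(1))),
                     naive_landscape_keys(net))
  }
  expect_error(enumerate_attractors(random_network(10, 2, 0.5),
                                    exhaustive_limit = 10), "too-large")
})

test_that("attractor canonicalization is idempotent and rotation-invariant", {
  cyc <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0))
  a1 <- attractor(cyc)
  a2 <- attractor(cyc[c(2, 3, 1), ])
  a3 <- attractor(a1$states)
  expect_identical(a1$key, a2$key)
  expect_identical(a1$states, a3$states)
})

test_that("attractor restriction projects, collapses, and is identity at full length", {
  fp <- attractor(matrix(c(1, 0, 1), nrow = 1))
  expect_identical(as.integer(restrict_attractor(fp, 2)$states), c(1L, 0L))
  cyc <- attractor(rbind(c(0, 1, 0), c(0, 1, 1)))
  expect_identical(restrict_attractor(cyc, 3)$key, cyc$key)
  # states differing only in the last gene restrict to a fixed point
  r <- restrict_attractor(cyc, 2)
  expect_equal(r$period, 1)
  expect_identical(as.integer(r$states), c(0L, 1L))
  expect_error(restrict_attractor(fp, 4), "exceeds")
})
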