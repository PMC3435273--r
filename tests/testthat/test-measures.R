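# Sensitivity, Derrida maps, variability, degrees, link persistence.

test_that("annealed sensitivity matches the closed form on constructed cases", {
  expect_equal(sensitivity(constant_zero_net(6))$S_annealed, 0)
  # copy ring: K = 1, p = 0.5 -> S_annealed = 0.5, S_exact = 1 exactly
  s <- sensitivity(copy_ring(8))
  expect_equal(s$S_annealed, 0.5)
  expect_equal(s$S_exact, 1)
  # fresh K = 2, p = 0.5 ensembles sit at the phase boundary on average
  set.seed(5)
  sa <- replicate(100, sensitivity(random_network(10, 2, 0.5))$S_annealed)
  expect_lt(abs(mean(sa) - 1), 0.05)
})

test_that("exact sensitivity agrees with the annealed formula on random ensembles", {
  set.seed(6)
  se <- replicate(150, sensitivity(random_network(12, 3, 0.5))$S_exact)
  expect_lt(abs(mean(se) - 1.5), 0.05 * 1.5)
})

test_that("exact sensitivity matches a Monte-Carlo perturbation estimate", {
  set.seed(7)
  net <- random_network(10, 3, 0.3)
  s <- sensitivity(net)$S_exact
  # flip one random input coordinate of one random gene, count output flips
  hits <- 0L; n_mc <- 4000L
  for (r in seq_len(n_mc)) {
    g <- net$genes[[sample.int(10, 1)]]
    k <- length(unique(g$bs))
    idx <- sample.int(length(g$tt), 1) - 1L
    pos <- sample.int(k, 1)
    hits <- hits + (g$tt[idx + 1L] != g$tt[bitwXor(idx, bitwShiftL(1L, pos - 1L)) + 1L])
  }
  k_mean <- mean(in_degrees(net))
  # MC estimates the per-coordinate flip probability; scale by mean k per gene
  est <- mean(vapply(net$genes, function(g) {
    k <- length(unique(g$bs)); k
  }, numeric(1))) * hits / n_mc
  expect_lt(abs(est - s), 0.15)
})

test_that("Derrida maps diagnose the dynamical regime", {
  d <- derrida_map(copy_ring(12), n_pairs = 30)
  # permutation dynamics preserve Hamming distance exactly
  expect_equal(d$points$d_next, d$points$d)
  expect_equal(d$slope_at_origin, 1)

  d0 <- derrida_map(constant_zero_net(10), n_pairs = 30)
  expect_equal(d0$slope_at_origin, 0)
  expect_true(all(d0$points$d_next == 0))

  expect_equal(d$points$d[1], 0)  # curve passes through the origin
  expect_error(derrida_map(copy_ring(4), n_pairs = 0), "n_pairs")
})

test_that("Derrida slope at the origin matches S_annealed for random ensembles", {
  set.seed(8)
  for (k in c(2, 4)) {
    sl <- replicate(6, {
      net <- random_network(25, k, 0.5)
      derrida_map(net, n_pairs = 1000, fit_frac = 0.04)$slope_at_origin
    })
    se <- sd(sl) / sqrt(length(sl))
    expect_lt(abs(mean(sl) - k / 2), 3 * se + 0.05)
  }
})

test_that("variability separates horizontal and vertical structure", {
  fp0 <- landscape(list(attractor(matrix(0L, 1, 6))))
  v <- variability(fp0)
  expect_equal(v$alpha_h, 0)
  expect_equal(v$alpha_v, 0)
  expect_equal(v$n0, 1)

  half <- landscape(list(attractor(matrix(c(1, 1, 1, 0, 0, 0), 1))))
  v2 <- variability(half)
  expect_equal(v2$alpha_h, 0.5)
  expect_equal(v2$alpha_v, 0)    # fixed points have no temporal variation

  # all-ones <-> all-zeros cycle: frozen-looking states, oscillating genes
  blink <- landscape(list(attractor(rbind(rep(1L, 6), rep(0L, 6)))))
  v3 <- variability(blink)
  expect_equal(v3$alpha_h, 0)
  expect_equal(v3$alpha_v, 0.5)

  expect_error(variability(landscape(list())), "empty")
})

test_that("variability is invariant under gene reordering and 0/1 relabeling", {
  set.seed(9)
  for (r in 1:20) {
    st <- matrix(rbinom(24, 1, runif(1)), 4, 6)
    ls <- landscape(list(attractor(st)))
    perm <- sample(6)
    ls_p <- landscape(list(attractor(st[, perm])))
    ls_f <- landscape(list(attractor(1L - st)))
    v <- variability(ls)
    expect_equal(variability(ls_p)$alpha_h, v$alpha_h)
    expect_equal(variability(ls_p)$alpha_v, v$alpha_v)
    expect_equal(variability(ls_f)$alpha_h, v$alpha_h)
    expect_equal(variability(ls_f)$alpha_v, v$alpha_v)
  }
})

test_that("degree statistics count distinct edges and conserve totals", {
  set.seed(10)
  net <- random_network(10, 2, 0.5)
  ds <- degree_stats(net)
  expect_true(all(ds$in_degree == 2))
  expect_equal(names(ds$in_hist), "2")
  expect_equal(sum(ds$in_degree), sum(ds$out_degree))

  # a hub regulating 8 of 10 genes reports out-degree 8
  hub <- boolean_network(c(
    list(gene(1, 1, c(0L, 1L))),
    lapply(2:9, function(i) gene(i, 1, c(0L, 1L))),
    list(gene(10, 10, c(0L, 1L)))))
  expect_equal(unname(degree_stats(hub)$out_degree["1"]), 9 - 1 + 1)
  expect_equal(degree_stats(hub)$max_out_degree, 9)
})

test_that("link persistence reports edge frequencies and ignores network order", {
  net <- copy_ring(3)
  pop <- structure(list(networks = list(net, net, net),
                        landscapes = vector("list", 3),
                        strains = 1:3, generation = 0L),
                   class = "rbn_population")
  f <- link_persistence(pop)
  expect_true(all(f[f > 0] == 1))
  expect_equal(sum(f > 0), 3)

  other <- boolean_network(list(gene(1, 2, c(0L, 1L)), gene(2, 2, c(0L, 1L)),
                                gene(3, 2, c(0L, 1L))))
  mixed <- list(net, net, other)
  f1 <- link_persistence(mixed)
  f2 <- link_persistence(rev(mixed))
  expect_identical(f1, f2)
  expect_equal(f1["2", "3"], 1)      # edge in all three networks
  expect_equal(f1["3", "1"], 2 / 3)  # ring edge absent from `other`
  expect_equal(f1["2", "2"], 1 / 3)  # self-loop only in `other`
})
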