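test_that("gate vocabulary evaluates correctly", {
  net <- boolean_network(list(out = "NAND(a, b)"), target = "out")
  s <- c(a = 0, b = 0, out = 0)
  expect_equal(synchronous_step(net, s)[["out"]], 1)  # NAND(0,0) = 1
  s <- c(a = 1, b = 1, out = 0)
  expect_equal(synchronous_step(net, s)[["out"]], 0)  # NAND(1,1) = 0
  net2 <- boolean_network(list(out = "a AND NOT b OR c"), target = "out")
  s2 <- c(a = 1, b = 0, c = 0, out = 0)
  expect_equal(synchronous_step(net2, s2)[["out"]], 1)
})

test_that("the feed-forward model follows its hand-traced dynamics", {
  net <- build_feedforward_model()
  s <- c(dFOXO = 1, AOP = 0, PNT = 1, lifespan = 0)
  nx <- synchronous_step(net, s)
  expect_equal(nx[["AOP"]], 1)
  expect_equal(nx[["PNT"]], 1)       # NOT AOP(prev=0)
  expect_equal(nx[["lifespan"]], 0)  # NAND(1, 1)
  expect_equal(nx[["dFOXO"]], 1)     # free node holds its value
  # dFOXO = 0 everywhere: PNT stabilizes at 1, lifespan = NAND(0,1) = 1
  s0 <- c(dFOXO = 0, AOP = 0, PNT = 0, lifespan = 0)
  for (i in 1:5) s0 <- synchronous_step(net, s0)
  expect_equal(s0[["PNT"]], 1)
  expect_equal(s0[["lifespan"]], 1)
})

test_that("the linear model is a chain of NOTs from dFOXO", {
  net <- build_linear_model()
  s <- c(dFOXO = 1, AOP = 0, PNT = 1, lifespan = 1)
  expect_equal(synchronous_step(net, s)[["lifespan"]], 0)  # NOT PNT
  # clamped dFOXO = 1 reaches the attractor AOP=1, PNT=0, lifespan=1
  st <- c(dFOXO = 1, AOP = 0, PNT = 0, lifespan = 0)
  for (i in 1:6) st <- synchronous_step(net, st, clamps = c(dFOXO = 1))
  expect_equal(unname(st[c("AOP", "PNT", "lifespan")]), c(1, 0, 1))
})

test_that("synchronous updates agree with the truth-table evaluator on all states", {
  for (net in list(build_feedforward_model(), build_linear_model())) {
    grid <- expand.grid(rep(list(c(0, 1)), 4))
    names(grid) <- net$nodes
    for (r in seq_len(nrow(grid))) {
      st <- unlist(grid[r, ])
      expect_equal(synchronous_step(net, st), brute_step(net, st))
    }
  }
})

test_that("random rule networks match the truth-table evaluator", {
  ops <- c("%s AND %s", "%s OR %s", "NAND(%s, %s)", "NOT %s")
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(3:6, 1)
    nodes <- paste0("n", seq_len(n))
    rules <- lapply(seq_len(n - 1), function(i) {
      op <- sample(ops, 1)
      ins <- sample(nodes, 2)
      if (op == "NOT %s") sprintf(op, ins[1]) else sprintf(op, ins[1], ins[2])
    })
    names(rules) <- nodes[-n]
    net <- boolean_network(rules, target = nodes[n])
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    colnames(grid) <- nodes
    for (r in sample(nrow(grid), 8)) {
      st <- grid[r, ]
      expect_equal(synchronous_step(net, st), brute_step(net, st))
    }
  }
})

test_that("clamps override rules and the clamped target is trivially active", {
  net <- build_feedforward_model()
  s <- c(dFOXO = 1, AOP = 0, PNT = 1, lifespan = 0)
  nx <- synchronous_step(net, s, clamps = c(lifespan = 1))
  expect_equal(nx[["lifespan"]], 1)
  for (m in list(build_feedforward_model(), build_linear_model())) {
    r <- simulate_probability(m, clamps = c(lifespan = 1), mode = "exact")
    expect_equal(r$probability_target_active, 1)
  }
})

test_that("exact clamping probabilities match enumeration-derived values", {
  ff <- build_feedforward_model()
  expect_equal(simulate_probability(ff, clamps = c(dFOXO = 1, PNT = 1))$
                 probability_target_active, 0)
  expect_equal(simulate_probability(ff, clamps = c(dFOXO = 1))$
                 probability_target_active, 1)
  expect_equal(simulate_probability(ff, clamps = c(PNT = 1))$
                 probability_target_active, 0.5)
  lin <- build_linear_model()
  expect_equal(simulate_probability(lin, clamps = c(PNT = 1))$
                 probability_target_active, 0)
  expect_equal(simulate_probability(lin, clamps = c(dFOXO = 1, PNT = 1))$
                 probability_target_active, 0)
})

test_that("probability at 1000 transitions equals any post-transient horizon", {
  for (m in list(build_feedforward_model(), build_linear_model())) {
    for (cl in list(c(dFOXO = 1), c(PNT = 1), c(dFOXO = 1, PNT = 1))) {
      p1000 <- simulate_probability(m, clamps = cl, n_transitions = 1000)
      p16 <- simulate_probability(m, clamps = cl, n_transitions = 16)
      expect_equal(p1000$probability_target_active,
                   p16$probability_target_active)
    }
  }
})

test_that("Monte-Carlo estimates are within 3 standard errors of exact", {
  set.seed(1)
  for (m in list(build_feedforward_model(), build_linear_model())) {
    for (cl in list(c(dFOXO = 1), c(PNT = 1), c(dFOXO = 1, PNT = 1))) {
      ex <- simulate_probability(m, clamps = cl)$probability_target_active
      mc <- simulate_probability(m, clamps = cl, mode = "monte_carlo",
                                 n_runs = 2000, seed = 17)
      tol <- 3 * sqrt(max(ex * (1 - ex), 1e-9) / mc$n_runs)
      expect_lte(abs(mc$probability_target_active - ex), max(tol, 1e-12))
    }
  }
})

test_that("model comparison flags synergy only for the feed-forward circuit", {
  tab <- compare_models()
  ff <- tab[tab$model == "feedforward", ]
  lin <- tab[tab$model == "linear", ]
  expect_equal(c(ff$dFOXO, ff$PNT, ff$both), c(1, 0.5, 0))
  expect_true(ff$synergy)
  expect_equal(lin$PNT, lin$both)
  expect_false(lin$synergy)
  # a constant-lifespan rule shows no synergy
  const <- boolean_network(list(AOP = "dFOXO", PNT = "NOT AOP",
                                lifespan = "1 OR 1"))
  tab2 <- compare_models(models = list(const = const))
  expect_equal(c(tab2$dFOXO, tab2$PNT, tab2$both), c(1, 1, 1))
  expect_false(tab2$synergy)
})

test_that("network text definitions parse and validate", {
  net <- parse_network(c("# feed-forward wiring",
                         "AOP <- dFOXO",
                         "PNT <- NOT AOP",
                         "lifespan <- NAND(dFOXO, PNT)"))
  expect_equal(simulate_probability(net, clamps = c(dFOXO = 1, PNT = 1))$
                 probability_target_active, 0)
  expect_error(parse_network("lifespan NAND dFOXO"), "malformed")
  expect_error(boolean_network(list(a = "b AND"), target = "a"), "parse")
  expect_error(simulate_probability(build_linear_model(),
                                    clamps = c(nope = 1)), "exist")
  expect_error(synchronous_step(build_linear_model(), c(dFOXO = 1)), "every node")
})
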