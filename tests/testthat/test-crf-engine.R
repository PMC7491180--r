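test_that("singleton factors are weighted component likelihoods", {
  m <- toy_model()  # lambda 30, f 1.2, lambda0 1.5, f0 1.2, equal weights
  f <- singleton_factor(list(id = 1, domain = 0:2), C = 30, model = m)
  expect_equal(f$v, 1L)
  expect_equal(f$d, 3L)
  expect_equal((0:2)[which.max(f$x)], 1)  # argmax at the true multiplicity
  expect_equal(f$x, log(1) + sapply(0:2, component_pmf, C = 30, model = m, log = TRUE))
  expect_error(singleton_factor(list(id = 1, domain = 1:2), 10,
                                nb_mixture(30, 1.2, 1, 1.2, c(1, 0, 0))),
               "degenerate")
})

test_that("the 2k rule suppresses singleton factors on short nodes", {
  k <- 3
  # node 2 has exactly 2k k-mers -> no singleton factor; others are longer
  g <- toy_cycle(c(30, 30, 30), c(28, 28, 28), num_kmers = c(10, 2 * k, 10), k = k)
  m <- toy_model()
  crf <- build_crf(g, m, m, extract_neighbourhood(g, 2, 1, "node"))
  # variables: 3 nodes + 3 arcs; factors: 2 node singletons (not node 2),
  # 3 arc singletons, 2 flow factors per node
  expect_length(crf$domains, 6)
  expect_length(crf$factors, 2 + 3 + 6)
  one_var_scopes <- vapply(crf$factors, function(f) length(f$v), 0L) == 1
  short_var <- crf$node_vars[["2"]]
  expect_false(any(vapply(crf$factors[one_var_scopes], function(f) f$v == short_var, TRUE)))
})

test_that("alpha = 0 collapses the domain to a point", {
  g <- toy_cycle(c(30, 30, 30), c(28, 28, 28))
  m <- toy_model()
  p <- infer_element(g, m, m, 1, "node", s = 1, alpha = 0)
  expect_equal(p$domain, 1L)
  expect_equal(p$prob, 1)
})

test_that("flow factors score conservation and violations", {
  nv <- list(id = 1, domain = 0:2)
  avs <- list(list(id = 2, domain = 0:1, coeff = 1),
              list(id = 3, domain = 0:1, coeff = 1))
  f <- flow_factor(nv, avs, eps = 1e-7)
  val <- function(mn, a1, a2) exp(f$x[1 + (mn - 0) + 3 * a1 + 6 * a2])
  expect_equal(val(2, 1, 1), 1)       # 2 = 1 + 1
  expect_equal(val(2, 0, 1), 1e-7)    # 2 != 0 + 1, the default epsilon
  expect_equal(val(0, 0, 0), 1)
  # empty side: the sum over no arcs is 0
  fe <- flow_factor(nv, list(), eps = 1e-7)
  expect_equal(exp(fe$x), c(1, 1e-7, 1e-7))
  # hairpin coefficient 2: node 2 with one arc of coefficient 2
  fh <- flow_factor(nv, list(list(id = 2, domain = 0:1, coeff = 2)), eps = 1e-7)
  expect_equal(exp(fh$x[1 + 2 + 3 * 1]), 1)  # m_n = 2 with arc at 1
  expect_equal(exp(fh$x[1 + 1 + 3 * 1]), 1e-7)
})

test_that("a degree-(2,2) node yields the expected CRF shape", {
  # centre c with two in-arcs and two out-arcs, four long neighbours
  u <- data.frame(seq = strrep("C", 12), cov_sum = 10 * c(60, 30, 30, 30, 30))
  arcs <- data.frame(from = c(2, 3, 1, 1), from_side = "right",
                     to = c(1, 1, 4, 5), to_side = "left",
                     k1mer = "AAAA", cov = 28)
  g <- dbg_graph(3, u, arcs)
  m <- toy_model()
  crf <- build_crf(g, m, m, extract_neighbourhood(g, 1, 1, "node"))
  # 5 node + 4 arc multiplicity variables
  expect_length(crf$domains, 9)
  centre <- crf$node_vars[["1"]]
  flow_scopes <- Filter(function(f) length(f$v) > 1, crf$factors)
  centre_flows <- Filter(function(f) centre %in% f$v, flow_scopes)
  # two cliques for the flow through the centre, each node + 2 arcs
  expect_length(centre_flows, 2)
  expect_true(all(vapply(centre_flows, function(f) length(f$v), 0L) == 3))
})

test_that("a single-variable CRF is the normalised singleton factor", {
  g <- toy_cycle(c(30, 30, 30), c(28, 28, 28))
  m <- toy_model()
  crf <- build_crf(g, m, m, extract_neighbourhood(g, 1, 0, "node"))
  expect_length(crf$domains, 1)
  p <- variable_elimination(crf)
  ref <- exp(crf$factors[[1]]$x - max(crf$factors[[1]]$x))
  expect_equal(p$prob, ref / sum(ref), tolerance = 1e-12)
  expect_equal(sum(p$prob), 1, tolerance = 1e-9)
})

test_that("variable elimination matches brute-force enumeration", {
  set.seed(101)
  for (i in 1:40) {
    crf <- random_crf()
    p <- variable_elimination(crf)
    expect_equal(sum(p$prob), 1, tolerance = 1e-9)
    expect_equal(p$prob, enumerate_marginal(crf), tolerance = 1e-9)
  }
})

test_that("deterministic flow chains propagate evidence end to end", {
  # five binary variables chained by near-hard equality constraints; strong
  # evidence at one end must force the far end
  doms <- rep(list(0:1), 5)
  factors <- list(list(v = 1L, d = 2L, x = c(-20, 0)))  # Y1 = 1
  for (i in 1:4) {
    factors[[length(factors) + 1]] <- flow_factor(
      list(id = i, domain = 0:1),
      list(list(id = i + 1, domain = 0:1, coeff = 1)), eps = 1e-12)
  }
  crf <- structure(list(domains = doms, factors = factors, query = 5L),
                   class = "dbg_crf")
  p <- variable_elimination(crf)
  expect_equal(p$map, 1)
  expect_gt(p$prob[2], 1 - 1e-6)
  expect_equal(p$prob, enumerate_marginal(crf), tolerance = 1e-9)
})

test_that("shrinking epsilon never favours flow-violating configurations", {
  g <- toy_cycle(c(30, 12, 5, 12, 30), c(28, 7, 7, 7, 28))
  m <- nb_mixture(30, 1.5, 1.5, 1.5, c(1000, 1000, 100, 10, 1, 1))
  nbh <- extract_neighbourhood(g, 3, 2, "node")
  prev <- Inf
  for (eps in c(1e-3, 1e-5, 1e-7, 1e-9)) {
    crf <- build_crf(g, m, m, nbh, eps = eps)
    grid <- do.call(expand.grid, lapply(crf$domains, seq_along))
    logp <- enumerate_joint_log(crf, grid)
    post <- exp(logp - max(logp)); post <- post / sum(post)
    # a configuration violates flow iff some flow factor contributes log(eps)
    viol <- rep(FALSE, nrow(grid))
    for (f in Filter(function(f) length(f$v) > 1, crf$factors)) {
      str_ <- cumprod(c(1, f$d))
      idx <- rep(1, nrow(grid))
      for (j in seq_along(f$v)) idx <- idx + (grid[[f$v[j]]] - 1) * str_[j]
      viol <- viol | (f$x[idx] < -1e-9)
    }
    mass <- sum(post[viol])
    expect_lte(mass, prev + 1e-12)
    prev <- mass
  }
})

test_that("s = 0 degenerates to the histogram rule on long nodes", {
  g <- toy_cycle(c(2, 14, 30, 45, 61, 140), rep(10, 6), num_kmers = 20)
  m <- toy_model()
  for (u in 1:6) {
    p <- infer_element(g, m, m, u, "node", s = 0)
    expect_equal(p$map, most_likely_multiplicity(g$unitigs$avg_cov[u], m))
  }
})

test_that("context flips an apparent error to multiplicity one", {
  # low-coverage true node: locally it looks like a sequencing error, but at
  # s >= 2 the high-coverage ring two steps away restores multiplicity 1
  g <- toy_cycle(c(30, 12, 5, 12, 30), c(28, 7, 7, 7, 28))
  m <- nb_mixture(30, 1.5, 1.5, 1.5, c(1000, 1000, 100, 10, 1, 1))
  maps <- vapply(0:3, function(s) infer_element(g, m, m, 3, "node", s = s)$map, 0L)
  expect_equal(maps[1], 0)  # s = 0: coverage alone says error
  expect_equal(maps[3], 1)  # s = 2: context rescues the node
  expect_equal(maps[4], 1)
})

test_that("isolated nodes have s-independent posteriors", {
  g <- dbg_graph(3, data.frame(seq = strrep("ACGT", 5), cov_sum = 28 * 18))
  m <- toy_model()
  p0 <- infer_element(g, m, m, 1, "node", s = 0)
  for (s in c(1, 3, 5)) {
    ps <- infer_element(g, m, m, 1, "node", s = s)
    expect_equal(ps$prob, p0$prob, tolerance = 1e-12)
  }
})

test_that("oversized intermediate tables raise a treewidth error", {
  # densely connected toy: many parallel arcs between two nodes
  u <- data.frame(seq = strrep("G", 12), cov_sum = 10 * c(90, 90))
  arcs <- data.frame(from = 1, from_side = "right", to = 2, to_side = "left",
                     k1mer = "AAAA", cov = 30)[rep(1, 6), ]
  g <- dbg_graph(3, u, arcs)
  m <- toy_model()
  expect_error(infer_element(g, m, m, 1, "node", s = 1, max_table = 100),
               class = "dbgcrf_treewidth_error")
  # infer_elements falls back to smaller s instead
  res <- infer_elements(g, m, m, data.frame(type = "node", id = 1),
                        s = 1, max_table = 100)
  expect_equal(res$s_used, 0L)
})

test_that("arc-centred inference works and posteriors normalise", {
  g <- toy_cycle(c(30, 30, 60, 30), c(28, 29, 31, 27))
  m <- toy_model()
  for (s in 0:2) {
    p <- infer_element(g, m, m, 2, "arc", s = s)
    expect_equal(sum(p$prob), 1, tolerance = 1e-9)
    expect_equal(p$map, 1)
  }
})
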