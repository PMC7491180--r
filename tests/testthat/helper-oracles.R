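# Independent oracles for the CRF engine tests: brute-force enumeration of
# the full joint distribution, and a generator of random CRFs small enough
# to enumerate.

# exact marginal of the query variable by summing the joint over all
# assignments (log-sum-exp); independent of the elimination machinery
enumerate_marginal <- function(crf) {
  doms <- crf$domains
  grid <- do.call(expand.grid, lapply(doms, seq_along))
  logp <- enumerate_joint_log(crf, grid)
  q <- crf$query
  marg <- vapply(seq_along(doms[[q]]), function(i) {
    lp <- logp[grid[[q]] == i]
    mx <- max(lp)
    if (is.finite(mx)) mx + log(sum(exp(lp - mx))) else -Inf
  }, 0)
  p <- exp(marg - max(marg))
  p / sum(p)
}

# joint log-value of every row of an assignment grid (domain indices)
enumerate_joint_log <- function(crf, grid) {
  logp <- numeric(nrow(grid))
  for (f in crf$factors) {
    str_ <- cumprod(c(1, f$d))
    idx <- rep(1, nrow(grid))
    for (j in seq_along(f$v)) idx <- idx + (grid[[f$v[j]]] - 1) * str_[j]
    logp <- logp + f$x[idx]
  }
  logp
}

# random CRF with <= max_vars variables, domains <= 5, a mix of random
# singleton-like factors and deterministic-flavoured flow factors; the
# joint size is kept enumerable
random_crf <- function(max_vars = 12, max_joint = 2e5) {
  repeat {
    nv <- sample(2:max_vars, 1)
    d <- sample(2:5, nv, replace = TRUE, prob = c(0.45, 0.35, 0.12, 0.08))
    if (prod(d) <= max_joint) break
  }
  doms <- lapply(d, function(k) 0:(k - 1))
  factors <- list()
  for (v in sample(nv, max(1, nv %/% 2))) {
    factors[[length(factors) + 1]] <- list(v = v, d = d[v], x = rnorm(d[v], sd = 3))
  }
  for (i in seq_len(sample(1:max(1, nv %/% 2), 1))) {
    sc <- sample(nv, min(nv, sample(2:4, 1)))
    factors[[length(factors) + 1]] <- flow_factor(
      list(id = sc[1], domain = doms[[sc[1]]]),
      lapply(sc[-1], function(a) list(id = a, domain = doms[[a]], coeff = 1)),
      eps = 10^-sample(3:9, 1))
  }
  structure(list(domains = doms, factors = factors, query = sample(nv, 1)),
            class = "dbg_crf")
}
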