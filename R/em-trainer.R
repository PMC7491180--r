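# Expectation-maximisation estimation of the node and arc mixture models.
#
# E-step: multiplicity posteriors for a fixed random subset of nodes and
# arcs, inferred with the current models (through the CRF at s_em >= 1, or
# as plain mixture responsibilities at s_em = 0).  M-step: method-of-moments
# updates of lambda0, lambda, f0, f and the weights, using the posteriors as
# soft assignments.  Convergence: the fraction of subset elements whose MAP
# multiplicity changed between consecutive E-steps drops below
# `conv_fraction`.

#' EM configuration
#'
#' @param subset_nodes,subset_arcs number of nodes/arcs sampled for
#'   parameter estimation (defaults 10000; capped at the graph size).
#' @param conv_fraction convergence threshold on the fraction of subset
#'   elements whose MAP changed between consecutive E-steps (default 0.001).
#' @param max_iters iteration cap (default 25).
#' @param s_em neighbourhood size used during EM (default 1).
#' @param alpha,eps,max_table CRF parameters, see [build_crf()].
#' @param m_max largest explicitly modelled multiplicity (default 5).
#' @param seed seed for the subset sample.
#' @param init_lambda optional user override for the initial lambda.
#' @return list of class `em_config`.
#' @export
em_config <- function(subset_nodes = 10000, subset_arcs = 10000,
                      conv_fraction = 0.001, max_iters = 25, s_em = 1,
                      alpha = 2, eps = 1e-7, max_table = 1e7, m_max = 5,
                      seed = 1, init_lambda = NULL) {
  stopifnot(conv_fraction > 0, conv_fraction <= 1, max_iters >= 1, s_em >= 0)
  structure(list(subset_nodes = subset_nodes, subset_arcs = subset_arcs,
                 conv_fraction = conv_fraction, max_iters = max_iters,
                 s_em = s_em, alpha = alpha, eps = eps, max_table = max_table,
                 m_max = m_max, seed = seed, init_lambda = init_lambda),
            class = "em_config")
}

#' Initialise a mixture model from a coverage histogram
#'
#' `lambda` starts at the highest histogram bin with coverage above 2 (the
#' putative multiplicity-1 mode, skipping the error peak near zero);
#' `lambda0` at `max(0.5, lambda/10)`; both overdispersion factors at 1.5.
#' Weights take the histogram mass closest to each component mean.
#'
#' @param hist a [coverage_histogram()].
#' @param m_max largest modelled multiplicity.
#' @param init_lambda optional override for the detected lambda.
#' @return An [nb_mixture()].
#' @export
em_init <- function(hist, m_max = 5, init_lambda = NULL) {
  if (!nrow(hist)) stop("initialisation failure: empty coverage histogram")
  lam <- init_lambda
  if (is.null(lam)) {
    above <- hist[hist$coverage > 2, ]
    if (!nrow(above) || sum(above$count) == 0)
      stop("initialisation failure: no coverage signal above the error floor")
    lam <- above$coverage[which.max(above$count)]
  }
  lam0 <- max(0.5, lam / 10)
  means <- c(lam0, (1:m_max) * lam)
  comp <- apply(outer(hist$coverage, means, function(c, m) abs(c - m)), 1, which.min)
  w <- vapply(seq_along(means), function(i) sum(hist$count[comp == i]), 0)
  w <- pmax(w, 1e-12)
  nb_mixture(lam = lam, f = 1.5, lam0 = lam0, f0 = 1.5, weights = w)
}

# subset posteriors for one element class; s_em = 0 short-circuits to plain
# mixture responsibilities over the restricted domain
.em_posteriors <- function(graph, model_nodes, model_arcs, ids, type, cfg) {
  model <- if (type == "node") model_nodes else model_arcs
  covs <- if (type == "node") graph$unitigs$avg_cov[ids] else graph$arcs$cov[ids]
  lapply(seq_along(ids), function(i) {
    if (cfg$s_em == 0) {
      dom <- .restrict_domain(covs[i], model, cfg$alpha)
      ll <- base::log(.mix_weight(model, dom)) + .comp_logpmf(dom, covs[i], model)
      p <- exp(ll - max(ll)); p <- p / sum(p)
      structure(list(domain = dom, prob = p, map = dom[which.max(p)],
                     confidence = max(p)), class = "mult_posterior")
    } else {
      tryCatch(
        infer_element(graph, model_nodes, model_arcs, ids[i], type,
                      s = cfg$s_em, alpha = cfg$alpha, eps = cfg$eps,
                      max_table = cfg$max_table),
        dbgcrf_treewidth_error = function(e) NULL)
    }
  })
}

#' E-step: subset multiplicity posteriors under the current models
#'
#' @param graph a `dbg_graph` with coverage.
#' @param model_nodes,model_arcs current [nb_mixture()] models.
#' @param subset list with integer vectors `nodes` and `arcs`.
#' @param cfg an [em_config()].
#' @return list with `nodes` and `arcs`: lists of `mult_posterior` (NULL
#'   where inference failed; such elements are dropped from the M-step).
#' @export
em_e_step <- function(graph, model_nodes, model_arcs, subset, cfg = em_config()) {
  list(nodes = .em_posteriors(graph, model_nodes, model_arcs, subset$nodes, "node", cfg),
       arcs = .em_posteriors(graph, model_nodes, model_arcs, subset$arcs, "arc", cfg))
}

#' M-step: method-of-moments parameter update from soft assignments
#'
#' With `g_im` the posterior of element `i` at multiplicity `m` and `C_i`
#' its coverage:
#' `lambda0 = sum(g_i0 C_i) / sum(g_i0)`,
#' `lambda  = sum_{m>=1} sum_i g_im C_i / sum_{m>=1} sum_i g_im m`,
#' `f0 = sum(g_i0 (C_i - lambda0)^2) / (lambda0 sum(g_i0))`,
#' `f  = sum_{m>=1} g_im (C_i - m lambda)^2 / (lambda sum_{m>=1} g_im m)`,
#' both overdispersion factors floored at `1 + 1e-6`.  Weights are the
#' posterior masses rescaled from the subset to the whole element class.  An
#' empty effective component keeps its previous value with a warning.
#'
#' @param posteriors list of `mult_posterior` (NULLs ignored).
#' @param coverages coverage of each element, aligned with `posteriors`.
#' @param model previous [nb_mixture()] (fallback values).
#' @param n_total total number of elements of this class in the graph.
#' @return An updated [nb_mixture()].
#' @export
em_m_step <- function(posteriors, coverages, model, n_total) {
  ok <- !vapply(posteriors, is.null, TRUE)
  posteriors <- posteriors[ok]
  coverages <- coverages[ok]
  m_max <- model$m_max
  n <- length(posteriors)
  if (!n) { warning("M-step: no usable posteriors; model unchanged"); return(model) }

  # gamma matrix over multiplicities 0..(m_max), clamping domain overshoot
  G <- matrix(0, n, m_max + 1)
  for (i in seq_len(n)) {
    p <- posteriors[[i]]
    mm <- pmin(p$domain, m_max)
    for (j in seq_along(mm)) G[i, mm[j] + 1] <- G[i, mm[j] + 1] + p$prob[j]
  }

  g0 <- G[, 1]
  s0 <- sum(g0)
  if (s0 > 1e-12) {
    lam0 <- sum(g0 * coverages) / s0
    f0 <- max(1 + 1e-6, sum(g0 * (coverages - lam0)^2) / (lam0 * s0))
  } else {
    warning("M-step: empty error component; lambda0, f0 unchanged")
    lam0 <- model$lam0; f0 <- model$f0
  }

  ms <- 1:m_max
  Gm <- G[, -1, drop = FALSE]
  denom <- sum(sweep(Gm, 2, ms, `*`))
  if (denom > 1e-12) {
    lam <- sum(Gm * coverages) / denom
    f <- max(1 + 1e-6, sum(Gm * (outer(coverages, ms * lam, `-`))^2) / (lam * denom))
  } else {
    warning("M-step: empty true component; lambda, f unchanged")
    lam <- model$lam; f <- model$f
  }
  if (lam0 >= lam) lam0 <- lam / 2  # keep the error mean below lambda

  w <- colSums(G) * n_total / n
  w <- pmax(w, 1e-12)
  nb_mixture(lam = lam, f = f, lam0 = max(lam0, 1e-3), f0 = f0, weights = w)
}

#' Fit node and arc mixture models by expectation-maximisation
#'
#' Samples a fixed subset of nodes and arcs once (uniformly without
#' replacement, seeded) and alternates [em_e_step()] / [em_m_step()] on it
#' until the MAP multiplicities stabilise or `max_iters` is reached.
#'
#' @param graph a `dbg_graph` with coverage annotated.
#' @param cfg an [em_config()].
#' @return list with `node_model`, `arc_model`, `iterations`, `converged`,
#'   and `trace` (per-iteration parameter values and changed fraction).
#' @export
run_em <- function(graph, cfg = em_config()) {
  nu <- nrow(graph$unitigs); na <- nrow(graph$arcs)
  hist_nodes <- coverage_histogram(graph$unitigs$avg_cov)
  hist_arcs <- coverage_histogram(graph$arcs$cov)
  node_model <- em_init(hist_nodes, cfg$m_max, cfg$init_lambda)
  arc_model <- em_init(hist_arcs, cfg$m_max, cfg$init_lambda)

  set.seed(cfg$seed)
  subset <- list(nodes = sort(sample(nu, min(cfg$subset_nodes, nu))),
                 arcs = if (na) sort(sample(na, min(cfg$subset_arcs, na))) else integer())
  cov_n <- graph$unitigs$avg_cov[subset$nodes]
  cov_a <- graph$arcs$cov[subset$arcs]

  prev_map <- NULL
  converged <- FALSE
  trace <- NULL
  it <- 0
  frac <- NA_real_
  while (it < cfg$max_iters) {
    it <- it + 1
    post <- em_e_step(graph, node_model, arc_model, subset, cfg)
    maps <- c(vapply(post$nodes, function(p) if (is.null(p)) NA_integer_ else p$map, 0L),
              vapply(post$arcs, function(p) if (is.null(p)) NA_integer_ else p$map, 0L))
    if (!is.null(prev_map)) {
      frac <- mean(maps != prev_map, na.rm = TRUE)
    }
    prev_map <- maps
    node_model <- em_m_step(post$nodes, cov_n, node_model, nu)
    if (na) arc_model <- em_m_step(post$arcs, cov_a, arc_model, na)
    trace <- rbind(trace, data.frame(
      iteration = it, changed_fraction = frac,
      node_lambda = node_model$lam, node_f = node_model$f,
      node_lambda0 = node_model$lam0, node_f0 = node_model$f0,
      arc_lambda = arc_model$lam, arc_f = arc_model$f))
    # conv_fraction >= 1 accepts any assignment, i.e. stop after one E/M pair
    if (cfg$conv_fraction >= 1 || (!is.na(frac) && frac < cfg$conv_fraction)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning(sprintf("EM did not converge within %d iterations", cfg$max_iters))
  list(node_model = node_model, arc_model = arc_model,
       iterations = it, converged = converged, trace = trace)
}
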