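# Conditional random field over a de Bruijn graph neighbourhood, and exact
# marginal inference by log-space variable elimination.
#
# A factor is a list(v, d, x): `v` the ordered integer ids of the variables
# in its scope, `d` their domain sizes, and `x` the log-value table stored as
# a flat vector with the first variable fastest-varying (column-major).  The
# joint conditional P(Y|X) is proportional to the product of all factors;
# the partition function is realised by the final normalisation.

#' Singleton factor tying a multiplicity variable to its observed coverage
#'
#' For each candidate multiplicity `m` in the variable's domain the factor
#' value is `w_m * P_m(C)`: the mixture weight times the density of the
#' corresponding negative-binomial component at the observed coverage.
#'
#' @param var variable description: a list with `id` (integer) and `domain`
#'   (ordered integer candidate multiplicities).
#' @param C observed coverage (non-negative).
#' @param model an [nb_mixture()].
#' @return A factor (list with `v`, `d`, `x` log-values).
#' @export
singleton_factor <- function(var, C, model) {
  stopifnot(C >= 0, length(var$domain) >= 1)
  lw <- base::log(.mix_weight(model, var$domain))
  if (all(!is.finite(lw))) stop("degenerate model: all weights zero on the domain")
  lp <- .comp_logpmf(var$domain, C, model)
  list(v = as.integer(var$id), d = length(var$domain), x = lw + lp)
}

#' Conservation-of-flow factor for one side of a node
#'
#' Scores an assignment 1 when the node's multiplicity equals the
#' coefficient-weighted sum of the multiplicities of the arcs on that side,
#' and a small `eps` otherwise.  Ordinary arcs and self-loops have
#' coefficient 1; a hairpin arc (a side joined to itself) has coefficient 2
#' because it is traversed both entering and leaving the side.  A side with
#' no arcs yields a factor over the node variable alone that is 1 at
#' multiplicity 0 (the empty-sum convention) and `eps` elsewhere.
#'
#' @param node_var list with `id` and `domain` for the node variable.
#' @param arc_vars list of lists with `id`, `domain` and `coeff` for the
#'   side's arc variables.
#' @param eps flow-violation value in (0, 1); default `1e-7`.
#' @return A factor.
#' @export
flow_factor <- function(node_var, arc_vars = list(), eps = 1e-7) {
  stopifnot(eps > 0, eps < 1)
  doms <- c(list(as.integer(node_var$domain)), lapply(arc_vars, function(a) as.integer(a$domain)))
  v <- c(as.integer(node_var$id), vapply(arc_vars, function(a) as.integer(a$id), 0L))
  d <- lengths(doms)
  n <- prod(d)
  t <- 0:(n - 1)
  before <- cumprod(c(1, d))[seq_along(d)]
  nodeval <- doms[[1]][(t %% d[1]) + 1]
  arcsum <- numeric(n)
  for (j in seq_along(arc_vars)) {
    arcsum <- arcsum + arc_vars[[j]]$coeff *
      doms[[j + 1]][((t %/% before[j + 1]) %% d[j + 1]) + 1]
  }
  x <- ifelse(nodeval == arcsum, 0, base::log(eps))
  list(v = v, d = as.integer(d), x = x)
}

# broadcast a factor's log-table to the union scope `uv` with dims `du`
.fexpand <- function(f, uv, du, n) {
  if (length(f$v) == length(uv) && all(f$v == uv)) return(f$x)
  p <- match(f$v, uv)
  before <- cumprod(c(1, du))[seq_along(du)]
  fstr <- cumprod(c(1, f$d))[seq_along(f$d)]
  t <- 0:(n - 1)
  ix <- 0
  for (j in seq_along(p)) {
    ix <- ix + ((t %/% before[p[j]]) %% du[p[j]]) * fstr[j]
  }
  f$x[ix + 1]
}

# factor product in log space
.fprod <- function(f, g) {
  if (length(f$v) == length(g$v) && all(f$v == g$v)) {
    return(list(v = f$v, d = f$d, x = f$x + g$x))
  }
  new <- !(g$v %in% f$v)
  uv <- c(f$v, g$v[new])
  du <- c(f$d, g$d[new])
  n <- prod(du)
  list(v = uv, d = du, x = .fexpand(f, uv, du, n) + .fexpand(g, uv, du, n))
}

# min-neighbours elimination order on the induced variable graph: repeatedly
# pick the non-query variable with the fewest neighbours (ties towards the
# smallest id), connect its neighbours (fill-in) and remove it
.elim_order <- function(scopes, nvar, query) {
  A <- matrix(FALSE, nvar, nvar)
  for (s in scopes) A[s, s] <- TRUE
  diag(A) <- FALSE
  remaining <- setdiff(seq_len(nvar), query)  # ascending, so ties pick min id
  ord <- integer(0)
  while (length(remaining)) {
    deg <- rowSums(A[remaining, , drop = FALSE])
    v <- remaining[which.min(deg)]
    nb <- which(A[v, ])
    if (length(nb) > 1) { A[nb, nb] <- TRUE; diag(A) <- FALSE }
    A[v, ] <- FALSE
    A[, v] <- FALSE
    ord <- c(ord, v)
    remaining <- remaining[remaining != v]
  }
  ord
}

# sum out one variable by log-sum-exp
.fmarg <- function(f, var) {
  pos <- match(var, f$v)
  dv <- f$d[pos]
  if (length(f$v) == 1) {
    mx <- max(f$x)
    tot <- if (is.finite(mx)) mx + base::log(sum(exp(f$x - mx))) else -Inf
    return(list(v = integer(), d = integer(), x = tot))
  }
  a <- f$x
  if (pos != 1) {
    a <- aperm(array(f$x, f$d), c(pos, seq_along(f$d)[-pos]))
  }
  m <- matrix(a, nrow = dv)
  mx <- m[1, ]
  if (dv > 1) for (i in 2:dv) mx <- pmax(mx, m[i, ])
  s <- mx + base::log(colSums(exp(m - rep(mx, each = dv))))
  s[!is.finite(mx)] <- -Inf
  list(v = f$v[-pos], d = f$d[-pos], x = s)
}

#' Build the CRF for a neighbourhood
#'
#' Creates one multiplicity variable per node and per arc in the
#' neighbourhood, with domains restricted to `[max(0, m_opt - alpha),
#' m_opt + alpha]` around the most likely multiplicity given the element's
#' own coverage.  Singleton factors are attached to every arc variable and to
#' node variables whose unitig contains more than `2k` k-mers (the average
#' coverage of shorter nodes is strongly correlated with their adjacent arcs
#' and would double-count evidence).  Two conservation-of-flow factors are
#' added per included node, one per side; boundary arcs are therefore
#' constrained on one side only.  At `s = 0` the CRF degenerates to the
#' centre's own variable and singleton factor.
#'
#' @param graph a `dbg_graph`.
#' @param model_nodes,model_arcs fitted [nb_mixture()] models.
#' @param nbh a [extract_neighbourhood()] result.
#' @param alpha half-width of the candidate-multiplicity window (default 2).
#' @param eps flow-violation value (default 1e-7).
#' @return An object of class `dbg_crf`.
#' @export
build_crf <- function(graph, model_nodes, model_arcs, nbh, alpha = 2, eps = 1e-7) {
  stopifnot(inherits(nbh, "dbg_neighbourhood"))
  if (!length(nbh$nodes) && !length(nbh$arcs)) stop("empty neighbourhood")
  k <- graph$k

  if (nbh$s == 0) {
    if (nbh$type == "node") {
      C <- graph$unitigs$avg_cov[nbh$centre]
      dom <- .restrict_domain(C, model_nodes, alpha)
      factors <- if (.has_singleton(graph, nbh$centre)) {
        list(singleton_factor(list(id = 1L, domain = dom), C, model_nodes))
      } else list()
    } else {
      C <- graph$arcs$cov[nbh$centre]
      dom <- .restrict_domain(C, model_arcs, alpha)
      factors <- list(singleton_factor(list(id = 1L, domain = dom), C, model_arcs))
    }
    return(structure(list(domains = list(dom), factors = factors, query = 1L,
                          node_vars = NULL, arc_vars = NULL, eps = eps),
                     class = "dbg_crf"))
  }

  nn <- length(nbh$nodes)
  na <- length(nbh$arcs)
  domains <- vector("list", nn + na)
  factors <- vector("list", 0)

  for (i in seq_len(nn)) {
    u <- nbh$nodes[i]
    C <- graph$unitigs$avg_cov[u]
    domains[[i]] <- .restrict_domain(C, model_nodes, alpha)
    if (.has_singleton(graph, u)) {
      factors[[length(factors) + 1]] <-
        singleton_factor(list(id = i, domain = domains[[i]]), C, model_nodes)
    }
  }
  for (j in seq_len(na)) {
    a <- nbh$arcs[j]
    C <- graph$arcs$cov[a]
    domains[[nn + j]] <- .restrict_domain(C, model_arcs, alpha)
    factors[[length(factors) + 1]] <-
      singleton_factor(list(id = nn + j, domain = domains[[nn + j]]), C, model_arcs)
  }
  for (i in seq_len(nn)) {
    u <- nbh$nodes[i]
    for (side in c("left", "right")) {
      sa <- .side_arcs(graph, u, side)
      # a side with no arcs (dead end: tip or linear fragment end) is left
      # unconstrained rather than forced to multiplicity 0
      if (!length(sa$arc)) next
      vids <- nn + match(sa$arc, nbh$arcs)
      arc_vars <- lapply(seq_along(sa$arc), function(r) {
        list(id = vids[r], domain = domains[[vids[r]]], coeff = sa$coeff[r])
      })
      factors[[length(factors) + 1]] <-
        flow_factor(list(id = i, domain = domains[[i]]), arc_vars, eps = eps)
    }
  }

  query <- if (nbh$type == "node") match(nbh$centre, nbh$nodes) else
    nn + match(nbh$centre, nbh$arcs)
  structure(list(domains = domains, factors = factors, query = query,
                 node_vars = stats::setNames(seq_len(nn), nbh$nodes),
                 arc_vars = stats::setNames(nn + seq_len(na), nbh$arcs),
                 eps = eps),
            class = "dbg_crf")
}

.restrict_domain <- function(C, model, alpha) {
  m_opt <- most_likely_multiplicity(C, model)
  max(0, m_opt - alpha):(m_opt + alpha)
}

# a node carries its own coverage evidence when it is long (its average is
# then informative beyond its adjacent arcs) or isolated (no arcs exist to
# supply evidence through flow factors)
.has_singleton <- function(graph, u) {
  graph$unitigs$num_kmers[u] > 2 * graph$k ||
    (length(graph$adjacency$left[[u]]) + length(graph$adjacency$right[[u]])) == 0
}

#' Exact posterior by variable elimination
#'
#' Sums out all non-query variables one at a time, choosing at each step the
#' variable with the fewest neighbours in the current induced graph (ties
#' break towards the smallest variable id).  All computation is in log space
#' (log-sum-exp); the final normalisation over the query's domain realises
#' the partition function.  The result is exact: the elimination order
#' affects cost but not the marginal.
#'
#' @param crf a [build_crf()] result.
#' @param max_table cap on any intermediate table size (entries); exceeding
#'   it raises a `dbgcrf_treewidth_error` so the caller can retry with a
#'   smaller neighbourhood.
#' @return An object of class `mult_posterior`: the domain, the normalised
#'   posterior probabilities, the MAP multiplicity (ties towards the smaller
#'   value) and its probability as `confidence`.
#' @export
variable_elimination <- function(crf, max_table = 1e8) {
  factors <- crf$factors
  dsize <- lengths(crf$domains)
  nvar <- length(crf$domains)
  elim_order <- .elim_order(lapply(factors, `[[`, "v"), nvar, crf$query)

  for (best in elim_order) {
    scopes <- lapply(factors, `[[`, "v")
    idx <- which(vapply(scopes, function(s) best %in% s, TRUE))
    if (length(idx)) {
      uv <- unique(unlist(scopes[idx], use.names = FALSE))
      if (prod(dsize[uv]) > max_table) {
        stop(structure(class = c("dbgcrf_treewidth_error", "error", "condition"),
                       list(message = sprintf(
                         "treewidth blowup: intermediate table of %.3g entries exceeds cap %.3g",
                         prod(dsize[uv]), max_table), call = NULL)))
      }
      f <- Reduce(.fprod, factors[idx])
      f <- .fmarg(f, best)
      factors <- factors[-idx]
      if (length(f$v)) factors[[length(factors) + 1]] <- f
    }
  }

  dom <- crf$domains[[crf$query]]
  lx <- numeric(length(dom))
  for (f in factors) if (length(f$v)) lx <- lx + f$x
  mx <- max(lx)
  p <- if (is.finite(mx)) exp(lx - mx) else rep(1, length(dom))
  p <- p / sum(p)
  structure(list(domain = dom, prob = p,
                 map = dom[which.max(p)], confidence = max(p)),
            class = "mult_posterior")
}

#' @export
print.mult_posterior <- function(x, ...) {
  cat(sprintf("multiplicity posterior: MAP=%d (p=%.4f)\n", x$map, x$confidence))
  print(stats::setNames(round(x$prob, 4), x$domain))
  invisible(x)
}

#' Infer the multiplicity posterior of one node or arc
#'
#' Composition of [extract_neighbourhood()], [build_crf()] and
#' [variable_elimination()].
#'
#' @param graph a `dbg_graph` with coverage annotated.
#' @param model_nodes,model_arcs fitted [nb_mixture()] models.
#' @param id unitig id or arc id.
#' @param type `"node"` or `"arc"`.
#' @param s neighbourhood size.
#' @param alpha,eps,max_table see [build_crf()] and [variable_elimination()].
#' @return A `mult_posterior`.
#' @export
infer_element <- function(graph, model_nodes, model_arcs, id,
                          type = c("node", "arc"), s = 3, alpha = 2,
                          eps = 1e-7, max_table = 1e8) {
  type <- match.arg(type)
  nbh <- extract_neighbourhood(graph, id, s, type)
  crf <- build_crf(graph, model_nodes, model_arcs, nbh, alpha = alpha, eps = eps)
  variable_elimination(crf, max_table = max_table)
}

#' Infer multiplicities for many elements
#'
#' Runs [infer_element()] for each requested element.  When an element's CRF
#' exceeds the table cap, the neighbourhood size falls back to `s - 1` (down
#' to 0) and the element is flagged via `s_used`.
#'
#' @param graph a `dbg_graph`.
#' @param model_nodes,model_arcs fitted [nb_mixture()] models.
#' @param elements data frame with columns `type` and `id`; default all
#'   nodes then all arcs.
#' @param s,alpha,eps,max_table inference parameters.
#' @return data frame: `id`, `type`, `coverage`, `map`, `p_map`, `posterior`
#'   (semicolon-separated `m:prob`), `s_used`.
#' @export
infer_elements <- function(graph, model_nodes, model_arcs, elements = NULL,
                           s = 3, alpha = 2, eps = 1e-7, max_table = 1e8) {
  if (is.null(elements)) {
    elements <- rbind(
      data.frame(type = "node", id = graph$unitigs$id),
      data.frame(type = "arc", id = graph$arcs$id))
  }
  n <- nrow(elements)
  map <- integer(n); pmap <- numeric(n); sused <- integer(n)
  poststr <- character(n); cov <- numeric(n)
  for (i in seq_len(n)) {
    ty <- elements$type[i]; id <- elements$id[i]
    cov[i] <- if (ty == "node") graph$unitigs$avg_cov[id] else graph$arcs$cov[id]
    si <- s
    repeat {
      post <- tryCatch(
        infer_element(graph, model_nodes, model_arcs, id, ty, s = si,
                      alpha = alpha, eps = eps, max_table = max_table),
        dbgcrf_treewidth_error = function(e) NULL)
      if (!is.null(post) || si == 0) break
      si <- si - 1L
    }
    if (is.null(post)) stop("inference failed even at s=0")
    map[i] <- post$map; pmap[i] <- post$confidence; sused[i] <- si
    poststr[i] <- paste(sprintf("%d:%.6g", post$domain, post$prob), collapse = ";")
  }
  data.frame(id = elements$id, type = elements$type, coverage = cov,
             map = map, p_map = pmap, posterior = poststr, s_used = sused)
}
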