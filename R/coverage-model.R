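# Negative-binomial mixture model over multiplicities.
#
# The NB is parameterised by its mean lambda and overdispersion factor
# f = variance / mean (f = 1 is the Poisson limit).  In the classical (r, p)
# parameterisation, lambda = p*r/(1-p) and f = 1/(1-p), i.e. p = (f-1)/f and
# r = lambda/(f-1).  The mixture has an error component (multiplicity 0) with
# mean lambda0 and, for every multiplicity m >= 1, a component with mean
# m*lambda; all m >= 1 components share the overdispersion factor f.
# Component weights w_m are expected element counts, not probabilities.

#' Probability that a base call is correct
#'
#' Maps a Phred quality score to the probability `1 - 10^(-phred/10)` that
#' the call is correct, the per-base weight used in q-mer counting.
#'
#' @param phred non-negative integer Phred score(s).
#' @return numeric in `[0, 1]`.
#' @export
qual_weight <- function(phred) {
  stopifnot(all(phred >= 0))
  1 - 10^(-phred / 10)
}

#' q-mer score of one k-mer occurrence
#'
#' The product of the correctness probabilities of the k bases spanned by
#' the occurrence.
#'
#' @param quals numeric vector of per-base correctness probabilities in (0,1].
#' @return the product, in (0, 1].
#' @export
qmer_score <- function(quals) {
  stopifnot(all(quals > 0), all(quals <= 1))
  prod(quals)
}

#' Negative binomial mixture over multiplicities
#'
#' @param lam mean coverage of multiplicity-1 elements (> 0).
#' @param f overdispersion factor (variance/mean) of the m >= 1 components.
#' @param lam0 mean coverage of erroneous (multiplicity-0) elements;
#'   must be smaller than `lam`.
#' @param f0 overdispersion factor of the error component.
#' @param weights numeric vector of component weights for multiplicities
#'   `0..M_max` (expected element counts; need not sum to 1).
#' @return An object of class `nb_mixture`.
#' @export
nb_mixture <- function(lam, f, lam0, f0, weights) {
  stopifnot(lam > 0, lam0 > 0, lam0 < lam, f >= 1, f0 >= 1,
            length(weights) >= 2, all(weights >= 0))
  structure(list(lam = lam, f = f, lam0 = lam0, f0 = f0,
                 weights = as.numeric(weights),
                 m_max = length(weights) - 1L),
            class = "nb_mixture")
}

#' @export
print.nb_mixture <- function(x, ...) {
  cat(sprintf("nb_mixture: lambda=%.3f f=%.3f | lambda0=%.3f f0=%.3f | M_max=%d\n",
              x$lam, x$f, x$lam0, x$f0, x$m_max))
  cat("  weights:", sprintf("%.3g", x$weights), "\n")
  invisible(x)
}

#' Continuous negative binomial density
#'
#' The discrete NB pmf with the factorials replaced by Gamma functions,
#' defined for real `x >= 0` and equal to the classical pmf at integer `x`.
#' Evaluated in log space.  When `f <= 1 + 1e-9` the (Gamma-continuous)
#' Poisson pmf is used instead, the `f -> 1` limit of the NB.
#'
#' @param x non-negative coverage value(s).
#' @param lam mean (> 0).
#' @param f overdispersion factor (>= 1).
#' @param log return the log density.
#' @return density value(s).
#' @export
nb_pmf <- function(x, lam, f, log = FALSE) {
  stopifnot(all(lam > 0), all(x >= 0))
  lp <- .nb_logpmf(x, lam, f)
  if (log) lp else exp(lp)
}

# log density; vectorised over x or over lam (f scalar)
.nb_logpmf <- function(x, lam, f) {
  if (f <= 1 + 1e-9) {
    x * base::log(lam) - lam - lgamma(x + 1)
  } else {
    p <- (f - 1) / f
    r <- lam / (f - 1)
    lgamma(x + r) - lgamma(r) - lgamma(x + 1) + x * base::log(p) + r * log1p(-p)
  }
}

# log component densities for a vector of multiplicities at one coverage
.comp_logpmf <- function(ms, C, model) {
  out <- numeric(length(ms))
  z <- ms == 0
  if (any(z)) out[z] <- .nb_logpmf(C, model$lam0, model$f0)
  if (any(!z)) out[!z] <- .nb_logpmf(C, ms[!z] * model$lam, model$f)
  out
}

#' Mixture component density at a given multiplicity
#'
#' Component `m = 0` is NB(`lam0`, `f0`); component `m >= 1` is
#' NB(`m * lam`, `f`).
#'
#' @param m multiplicity (scalar, >= 0).
#' @param C coverage value(s).
#' @param model an [nb_mixture()].
#' @param log return log density.
#' @return density value(s).
#' @export
component_pmf <- function(m, C, model, log = FALSE) {
  stopifnot(m >= 0)
  if (m == 0) nb_pmf(C, model$lam0, model$f0, log = log)
  else nb_pmf(C, m * model$lam, model$f, log = log)
}

# weight of component m, extending beyond M_max with the last weight
.mix_weight <- function(model, m) {
  model$weights[pmin(m, model$m_max) + 1]
}

#' Most likely multiplicity for an observed coverage
#'
#' The histogram rule: `argmax_m w_m P_m(C)` over multiplicities
#' `0..M_max`.  Coverage above the mean of the largest modelled component is
#' mapped to `min(M_max, round(C/lambda))`, i.e. clamped to `M_max`.  Ties
#' break towards the smaller multiplicity.
#'
#' @param C coverage value(s).
#' @param model an [nb_mixture()].
#' @return integer multiplicity estimate(s).
#' @export
most_likely_multiplicity <- function(C, model) {
  ms <- 0:model$m_max
  lw <- base::log(.mix_weight(model, ms))
  vapply(C, function(ci) {
    if (ci > model$m_max * model$lam) {
      return(min(model$m_max, as.integer(round(ci / model$lam))))
    }
    ll <- lw + .comp_logpmf(ms, ci, model)
    ms[which.max(ll)]  # which.max returns the first (smallest m) maximum
  }, 0L)
}

#' Coverage histogram
#'
#' Counts of coverage values in unit-width bins; real-valued q-mer coverages
#' are floored.  Model fitting uses the raw values, the histogram is for
#' display and EM initialisation.
#'
#' @param values numeric coverage values.
#' @return data frame with columns `coverage` and `count`, class
#'   `coverage_histogram`.
#' @export
coverage_histogram <- function(values) {
  if (!length(values)) {
    h <- data.frame(coverage = integer(), count = integer())
  } else {
    t <- table(floor(values))
    h <- data.frame(coverage = as.integer(names(t)), count = as.integer(t))
  }
  class(h) <- c("coverage_histogram", "data.frame")
  h
}

#' Write a coverage histogram as two-column TSV
#' @param hist a [coverage_histogram()].
#' @param path output path.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(hist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fitted node and arc mixture models to a key-value text file
#'
#' The stage-2 output format: flat `key = value` lines with `node.` and
#' `arc.` prefixes, plus any extra scalar entries (iterations, convergence).
#'
#' @param node_model,arc_model [nb_mixture()] objects.
#' @param path output path.
#' @param extra named list of additional scalar entries.
#' @export
write_model_file <- function(node_model, arc_model, path, extra = list()) {
  fmt <- function(prefix, m) {
    c(sprintf("%s.lambda = %.10g", prefix, m$lam),
      sprintf("%s.f = %.10g", prefix, m$f),
      sprintf("%s.lambda0 = %.10g", prefix, m$lam0),
      sprintf("%s.f0 = %.10g", prefix, m$f0),
      sprintf("%s.w%d = %.10g", prefix, 0:m$m_max, m$weights))
  }
  lines <- c(fmt("node", node_model), fmt("arc", arc_model),
             vapply(names(extra), function(n) sprintf("%s = %s", n, format(extra[[n]])), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model file written by [write_model_file()]
#' @param path model file.
#' @return list with elements `node`, `arc` ([nb_mixture()]) and `extra`.
#' @export
read_model_file <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  grab <- function(prefix) {
    wk <- sort(keys[grepl(sprintf("^%s\\.w\\d+$", prefix), keys)])
    wi <- order(as.integer(sub(sprintf("^%s\\.w", prefix), "", wk)))
    nb_mixture(lam = as.numeric(vals[keys == paste0(prefix, ".lambda")]),
               f = as.numeric(vals[keys == paste0(prefix, ".f")]),
               lam0 = as.numeric(vals[keys == paste0(prefix, ".lambda0")]),
               f0 = as.numeric(vals[keys == paste0(prefix, ".f0")]),
               weights = as.numeric(vals[match(wk[wi], keys)]))
  }
  known <- grepl("^(node|arc)\\.", keys)
  extra <- as.list(vals[!known])
  names(extra) <- keys[!known]
  list(node = grab("node"), arc = grab("arc"), extra = extra)
}
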