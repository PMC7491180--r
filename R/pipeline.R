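# Three-stage pipeline: (1) graph construction / loading and coverage
# annotation, (2) EM model fitting, (3) CRF multiplicity inference.  All
# intermediates are plain text: GFA1 for the graph, TSV for histograms and
# multiplicities, a key-value file for the fitted models.

#' Pipeline configuration
#'
#' @param k k-mer size (default 21).
#' @param abundance_min minimum k-mer count (default 2).
#' @param weighted use quality-weighted q-mer counts (default `TRUE`).
#' @param s neighbourhood size for final inference (default 3).
#' @param alpha candidate-multiplicity window half-width (default 2).
#' @param eps flow-violation factor value (default 1e-7).
#' @param m_max largest modelled multiplicity (default 5).
#' @param max_table intermediate-table cap during stage-3 inference; an
#'   element exceeding it falls back to a smaller `s`.
#' @param em an [em_config()].
#' @param seed RNG seed for subsampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 21, abundance_min = 2, weighted = TRUE,
                            s = 3, alpha = 2, eps = 1e-7, m_max = 5,
                            max_table = 1e7, em = em_config(), seed = 1) {
  structure(list(k = k, abundance_min = abundance_min, weighted = weighted,
                 s = s, alpha = alpha, eps = eps, m_max = m_max,
                 max_table = max_table, em = em, seed = seed),
            class = "pipeline_config")
}

#' Stage 1: build or load the graph and annotate coverage
#'
#' @param reads FASTQ path, character vector of reads, or `list(seq, qual)`;
#'   may be `NULL` when `gfa` is given and q-mer annotation is not wanted.
#' @param gfa optional GFA1 path (e.g. BCALM 2 output); when given the graph
#'   is loaded instead of built and `reads` only serve coverage annotation.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; writes `graph.gfa`,
#'   `nodes.hist.tsv` and `arcs.hist.tsv`.
#' @return the annotated `dbg_graph`.
#' @export
stage1 <- function(reads = NULL, gfa = NULL, config = pipeline_config(),
                   out_dir = NULL) {
  if (is.null(reads) && is.null(gfa)) stop("stage1 needs reads and/or a GFA file")
  graph <- if (!is.null(gfa)) read_gfa(gfa, k = config$k)
           else build_graph(reads, k = config$k, abundance_min = config$abundance_min)
  if (!is.null(reads)) {
    reads <- .as_reads(reads)
    weighted <- config$weighted && !is.null(reads$qual)
    graph <- annotate_coverage(graph, reads, weighted = weighted)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gfa(graph, file.path(out_dir, "graph.gfa"))
    write_histogram(coverage_histogram(graph$unitigs$avg_cov),
                    file.path(out_dir, "nodes.hist.tsv"))
    write_histogram(coverage_histogram(graph$arcs$cov),
                    file.path(out_dir, "arcs.hist.tsv"))
  }
  graph
}

#' Stage 2: estimate the mixture models by EM
#'
#' @param graph annotated `dbg_graph` from [stage1()].
#' @param config a [pipeline_config()]; `config$em` holds the EM settings.
#' @param out_dir optional; writes `model.txt` and `em_trace.tsv`.
#' @param allow_nonconverged return (with a warning) instead of erroring
#'   when EM hits the iteration cap.
#' @return the [run_em()] result.
#' @export
stage2 <- function(graph, config = pipeline_config(), out_dir = NULL,
                   allow_nonconverged = TRUE) {
  fit <- run_em(graph, config$em)
  if (!fit$converged && !allow_nonconverged)
    stop("EM did not converge; rerun with a higher iteration cap or allow_nonconverged")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_file(fit$node_model, fit$arc_model,
                     file.path(out_dir, "model.txt"),
                     extra = list(iterations = fit$iterations,
                                  converged = fit$converged,
                                  subset_nodes = min(config$em$subset_nodes, nrow(graph$unitigs)),
                                  subset_arcs = min(config$em$subset_arcs, nrow(graph$arcs))))
    utils::write.table(fit$trace, file.path(out_dir, "em_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fit
}

#' Stage 3: infer multiplicities for all (or a subset of) elements
#'
#' Elements whose CRF exceeds the table cap are retried at `s - 1` down to
#' 0 and flagged in the `s_used` column of the output.
#'
#' @param graph annotated `dbg_graph`.
#' @param node_model,arc_model fitted [nb_mixture()] models (e.g. from
#'   [stage2()]).
#' @param config a [pipeline_config()].
#' @param subset optional number of elements to sample (seeded with
#'   `config$seed`), mirroring subsampled inference on very large graphs.
#' @param out_dir optional; writes `multiplicities.tsv`.
#' @return data frame as from [infer_elements()], sorted by type and id.
#' @export
stage3 <- function(graph, node_model, arc_model, config = pipeline_config(),
                   subset = NULL, out_dir = NULL) {
  elements <- rbind(data.frame(type = "node", id = graph$unitigs$id),
                    data.frame(type = "arc", id = graph$arcs$id))
  if (!is.null(subset) && subset < nrow(elements)) {
    set.seed(config$seed)
    elements <- elements[sort(sample(nrow(elements), subset)), ]
  }
  res <- infer_elements(graph, node_model, arc_model, elements,
                        s = config$s, alpha = config$alpha, eps = config$eps,
                        max_table = config$max_table)
  res <- res[order(res$type != "node", res$id), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(out_dir, "multiplicities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Conservation-of-flow consistency of an assignment
#'
#' Fraction of node sides at which the assigned node multiplicity equals the
#' coefficient-weighted sum of the assigned multiplicities of the side's
#' arcs.  Sides without arcs (dead ends) are skipped.
#'
#' @param graph a `dbg_graph`.
#' @param assignments data frame from [stage3()] / [infer_elements()]
#'   covering all nodes and arcs.
#' @return fraction in `[0, 1]` (NA when the graph has no arcs).
#' @export
flow_consistency <- function(graph, assignments) {
  an <- assignments[assignments$type == "node", ]
  aa <- assignments[assignments$type == "arc", ]
  nodemap <- an$map[match(graph$unitigs$id, an$id)]
  arcmap <- aa$map[match(graph$arcs$id, aa$id)]
  ok <- 0L; tot <- 0L
  for (u in graph$unitigs$id) {
    for (side in c("left", "right")) {
      sa <- .side_arcs(graph, u, side)
      if (!length(sa$arc)) next
      tot <- tot + 1L
      if (!is.na(nodemap[u]) && !anyNA(arcmap[sa$arc]) &&
          nodemap[u] == sum(sa$coeff * arcmap[sa$arc])) ok <- ok + 1L
    }
  }
  if (!tot) return(NA_real_)
  ok / tot
}

#' Classify k-mers into trusted and untrusted sets
#'
#' A node's k-mers are trusted when its MAP multiplicity is >= 1 and
#' untrusted when it is 0 (sequencing-error artifacts).
#'
#' @param assignments data frame from [stage3()] / [infer_elements()].
#' @param graph the matching `dbg_graph`.
#' @param out_dir optional; writes `trusted.kmers.txt` and
#'   `untrusted.kmers.txt`, one canonical k-mer per line.
#' @return list with character vectors `trusted` and `untrusted`.
#' @export
classify_trusted <- function(assignments, graph, out_dir = NULL) {
  an <- assignments[assignments$type == "node", ]
  expand <- function(ids) {
    if (!length(ids)) return(character())
    unlist(lapply(ids, function(u) {
      s <- graph$unitigs$seq[u]
      n <- graph$unitigs$num_kmers[u]
      km <- substring(s, 1:n, graph$k:(n + graph$k - 1))
      pmin(km, revcomp(km))
    }), use.names = FALSE)
  }
  trusted <- expand(an$id[an$map >= 1])
  untrusted <- expand(an$id[an$map == 0])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(trusted, file.path(out_dir, "trusted.kmers.txt"))
    writeLines(untrusted, file.path(out_dir, "untrusted.kmers.txt"))
  }
  list(trusted = trusted, untrusted = untrusted)
}
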