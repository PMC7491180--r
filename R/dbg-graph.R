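# Compacted bidirected de Bruijn graph: construction, coverage annotation and
# neighbourhood extraction.
#
# Each unitig has a left and a right side.  Arcs join sides: an arc
# (from, from_side) -> (to, to_side) is traversed by exiting `from` through
# `from_side` and entering `to` through `to_side`.  Reading a unitig in its
# stored orientation, the arcs on its left side are its incoming arcs and the
# arcs on its right side its outgoing arcs.  Every arc corresponds to exactly
# one canonical k+1-mer and is stored once.

#' Construct a de Bruijn graph object
#'
#' Low-level constructor used by [build_graph()] and [read_gfa()].  Validates
#' the unitig and arc tables, derives `num_kmers` and `avg_cov`, and builds
#' the side-adjacency index.
#'
#' @param k k-mer size (odd integer).
#' @param unitigs data frame with columns `seq` (DNA string of length >= k)
#'   and optionally `cov_sum` (sum of k-mer counts over the unitig's k-mers).
#' @param arcs data frame with columns `from`, `from_side`, `to`, `to_side`
#'   (sides are `"left"`/`"right"`), `k1mer` (the arc's k+1-mer) and
#'   optionally `cov`.
#' @return An object of class `dbg_graph`.
#' @export
dbg_graph <- function(k, unitigs, arcs = NULL) {
  stopifnot(is.numeric(k), k >= 3, k %% 2 == 1)
  k <- as.integer(k)
  if (is.null(arcs)) {
    arcs <- data.frame(from = integer(), from_side = character(),
                       to = integer(), to_side = character(),
                       k1mer = character(), cov = numeric())
  }
  unitigs <- as.data.frame(unitigs)
  arcs <- as.data.frame(arcs)
  if (!nrow(unitigs)) stop("empty graph: no unitigs")
  if (is.null(unitigs$cov_sum)) unitigs$cov_sum <- 0
  if (is.null(arcs$cov)) arcs$cov <- rep(0, nrow(arcs))

  nchar_seq <- nchar(unitigs$seq)
  if (any(nchar_seq < k)) stop("unitig shorter than k")
  if (any(grepl("[^ACGT]", unitigs$seq))) stop("unitig sequence must be over {A,C,G,T}")
  unitigs$id <- seq_len(nrow(unitigs))
  unitigs$num_kmers <- nchar_seq - k + 1L
  unitigs$avg_cov <- unitigs$cov_sum / unitigs$num_kmers
  unitigs <- unitigs[, c("id", "seq", "num_kmers", "cov_sum", "avg_cov")]

  if (nrow(arcs)) {
    if (!all(arcs$from_side %in% c("left", "right")) ||
        !all(arcs$to_side %in% c("left", "right")))
      stop("arc sides must be 'left' or 'right'")
    if (any(arcs$from < 1 | arcs$from > nrow(unitigs) |
            arcs$to < 1 | arcs$to > nrow(unitigs)))
      stop("arc endpoint does not exist")
    if (any(nchar(arcs$k1mer) != k + 1)) stop("arc k+1-mer of wrong length")
    if (any(arcs$cov < 0)) stop("arc coverage must be non-negative")
    arcs$from <- as.integer(arcs$from)
    arcs$to <- as.integer(arcs$to)
  }
  arcs$id <- seq_len(nrow(arcs))
  arcs <- arcs[, c("id", "from", "from_side", "to", "to_side", "k1mer", "cov")]

  g <- structure(list(k = k, unitigs = unitigs, arcs = arcs), class = "dbg_graph")
  g$adjacency <- .build_adjacency(g)
  g <- .index_graph(g)
  g
}

# navigation caches used by the inference hot path: flow coefficients per
# side and the distinct neighbour nodes of each unitig
.index_graph <- function(g) {
  nu <- nrow(g$unitigs)
  a <- g$arcs
  coeff_of <- function(ids) ifelse(a$from[ids] == a$to[ids] &
                                     a$from_side[ids] == a$to_side[ids], 2, 1)
  g$coeff <- list(left = lapply(g$adjacency$left, coeff_of),
                  right = lapply(g$adjacency$right, coeff_of))
  g$nbrs <- lapply(seq_len(nu), function(u) {
    ids <- c(g$adjacency$left[[u]], g$adjacency$right[[u]])
    unique(c(a$from[ids], a$to[ids]))
  })
  g
}

# side adjacency: for each unitig, the arc ids incident to its left and right
# side.  A hairpin arc (same unitig, same side on both ends) is listed once.
.build_adjacency <- function(g) {
  nu <- nrow(g$unitigs)
  adj <- list(left = vector("list", nu), right = vector("list", nu))
  for (s in c("left", "right")) {
    for (i in seq_len(nu)) adj[[s]][[i]] <- integer()
  }
  a <- g$arcs
  if (nrow(a)) {
    for (j in seq_len(nrow(a))) {
      adj[[a$from_side[j]]][[a$from[j]]] <- c(adj[[a$from_side[j]]][[a$from[j]]], a$id[j])
      hairpin <- a$from[j] == a$to[j] && a$from_side[j] == a$to_side[j]
      if (!hairpin) {
        adj[[a$to_side[j]]][[a$to[j]]] <- c(adj[[a$to_side[j]]][[a$to[j]]], a$id[j])
      }
    }
    adj$left <- lapply(adj$left, unique)
    adj$right <- lapply(adj$right, unique)
  }
  adj
}

# arcs incident to one side of a node, with their flow coefficients:
# 1 for ordinary arcs and self-loops (right -> left of the same unitig, which
# appear in both side sums once), 2 for hairpins (side connected to itself,
# traversed entering and leaving the side).
.side_arcs <- function(g, node, side) {
  list(arc = g$adjacency[[side]][[node]], coeff = g$coeff[[side]][[node]])
}

#' Build a compacted de Bruijn graph from reads
#'
#' Counts canonical k-mers and k+1-mers in the reads, discards k-mers seen
#' fewer than `abundance_min` times, compacts maximal non-branching paths
#' into unitigs and connects them by the observed k+1-mers whose two
#' constituent k-mers both survive.  Coverage is annotated from the same
#' integer counts; use [annotate_coverage()] to switch to quality-weighted
#' (q-mer) counts.
#'
#' @param reads character vector of read sequences, a list with elements
#'   `seq` and `qual`, or the path to a FASTQ file.
#' @param k odd k-mer size between 3 and 31 (default 21).
#' @param abundance_min minimum k-mer count to enter the graph (default 2).
#' @return A `dbg_graph`.  Unitig ids are assigned in canonical-sequence sort
#'   order, so identical inputs yield identical graphs.
#' @export
build_graph <- function(reads, k = 21, abundance_min = 2) {
  reads <- .as_reads(reads)
  if (!length(reads$seq)) stop("reads must be non-empty")
  stopifnot(k >= 3, k %% 2 == 1)
  ktab <- .cpp_kmer_table(reads$seq, character(), k, FALSE)
  k1tab <- .cpp_kmer_table(reads$seq, character(), k + 1L, FALSE)
  parts <- .cpp_build_unitigs(ktab, k1tab, abundance_min)
  unitigs <- data.frame(seq = parts$seq)
  arcs <- data.frame(from = parts$from,
                     from_side = ifelse(parts$from_side == 1, "right", "left"),
                     to = parts$to,
                     to_side = ifelse(parts$to_side == 1, "right", "left"),
                     k1mer = parts$k1mer, cov = parts$cov)
  unitigs$cov_sum <- vapply(.cpp_seq_kmer_counts(ktab, unitigs$seq), sum, 0)
  dbg_graph(k, unitigs, arcs)
}

#' Annotate node and arc coverage from a read set
#'
#' Recomputes `cov_sum`/`avg_cov` of every unitig and `cov` of every arc from
#' the reads.  With `weighted = TRUE` each k-mer occurrence contributes its
#' q-mer score, the product of the correctness probabilities
#' `1 - 10^(-Q/10)` of its bases (quality strings required); otherwise each
#' occurrence contributes 1.  A k-mer and its reverse complement are pooled.
#'
#' @param graph a `dbg_graph`.
#' @param reads as in [build_graph()].
#' @param weighted use q-mer (quality-weighted) counts (default `TRUE`).
#' @return The graph with coverage fields replaced.
#' @export
annotate_coverage <- function(graph, reads, weighted = TRUE) {
  stopifnot(inherits(graph, "dbg_graph"))
  reads <- .as_reads(reads)
  if (weighted && is.null(reads$qual))
    stop("weighted counting requires quality strings")
  quals <- if (weighted) reads$qual else character()
  k <- graph$k
  ktab <- .cpp_kmer_table(reads$seq, quals, k, weighted)
  k1tab <- .cpp_kmer_table(reads$seq, quals, k + 1L, weighted)
  graph$unitigs$cov_sum <- vapply(.cpp_seq_kmer_counts(ktab, graph$unitigs$seq), sum, 0)
  graph$unitigs$avg_cov <- graph$unitigs$cov_sum / graph$unitigs$num_kmers
  if (nrow(graph$arcs))
    graph$arcs$cov <- as.numeric(.cpp_table_counts_of(k1tab, graph$arcs$k1mer))
  graph
}

#' Extract a neighbourhood around a node or arc
#'
#' The neighbourhood of size `s` around a node consists of all nodes
#' reachable from it by traversing at most `s` arcs (in any direction,
#' through either side) together with, for `s >= 1`, every arc incident to an
#' included node -- boundary arcs are included even when their far endpoint
#' is not.  At `s = 0` a node-centred neighbourhood contains no arcs.  An
#' arc-centred neighbourhood seeds both endpoint nodes at distance 0 and
#' always contains the centre arc.
#'
#' @param graph a `dbg_graph`.
#' @param centre unitig id or arc id.
#' @param s neighbourhood size (non-negative integer).
#' @param type `"node"` or `"arc"`.
#' @return An object of class `dbg_neighbourhood` with elements `nodes`
#'   (unitig ids) and `arcs` (arc ids).
#' @export
extract_neighbourhood <- function(graph, centre, s, type = c("node", "arc")) {
  type <- match.arg(type)
  stopifnot(inherits(graph, "dbg_graph"), s >= 0)
  centre <- as.integer(centre)
  if (type == "node") {
    if (centre < 1 || centre > nrow(graph$unitigs)) stop("centre node does not exist")
    seeds <- centre
  } else {
    if (centre < 1 || centre > nrow(graph$arcs)) stop("centre arc does not exist")
    seeds <- unique(c(graph$arcs$from[centre], graph$arcs$to[centre]))
  }
  nodes <- seeds
  frontier <- seeds
  depth <- 0L
  while (depth < s && length(frontier)) {
    nxt <- unique(unlist(graph$nbrs[frontier], use.names = FALSE))
    frontier <- nxt[!(nxt %in% nodes)]
    nodes <- c(nodes, frontier)
    depth <- depth + 1L
  }
  nodes <- sort(nodes)
  if (type == "node" && s == 0) {
    arcs <- integer()
  } else if (s == 0) {
    arcs <- centre
  } else {
    arcs <- sort(unique(unlist(c(graph$adjacency$left[nodes],
                                 graph$adjacency$right[nodes]))))
    if (type == "arc") arcs <- sort(unique(c(arcs, centre)))
  }
  structure(list(centre = centre, type = type, s = as.integer(s),
                 nodes = nodes, arcs = as.integer(arcs)),
            class = "dbg_neighbourhood")
}

# TRUE when no pair of distinct unitigs could still be merged: an arc whose
# two endpoints are distinct and are each the only arc on their side would
# have been compacted away.
.is_compacted <- function(graph) {
  a <- graph$arcs
  if (!nrow(a)) return(TRUE)
  for (j in seq_len(nrow(a))) {
    if (a$from[j] == a$to[j]) next
    d_from <- length(graph$adjacency[[a$from_side[j]]][[a$from[j]]])
    d_to <- length(graph$adjacency[[a$to_side[j]]][[a$to[j]]])
    if (d_from == 1 && d_to == 1) return(FALSE)
  }
  TRUE
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat(sprintf("dbg_graph: k=%d, %d unitigs (%d k-mers), %d arcs\n",
              x$k, nrow(x$unitigs), sum(x$unitigs$num_kmers), nrow(x$arcs)))
  cat(sprintf("  mean node coverage %.2f, mean arc coverage %.2f\n",
              mean(x$unitigs$avg_cov), if (nrow(x$arcs)) mean(x$arcs$cov) else NA))
  invisible(x)
}

#' @export
print.dbg_neighbourhood <- function(x, ...) {
  cat(sprintf("neighbourhood (s=%d) around %s %d: %d nodes, %d arcs\n",
              x$s, x$type, x$centre, length(x$nodes), length(x$arcs)))
  invisible(x)
}

# normalise the accepted read inputs to list(seq=, qual= or NULL)
.as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1 &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    return(read_fastq(reads))
  }
  if (is.character(reads)) return(list(seq = reads, qual = NULL))
  if (is.list(reads) && !is.null(reads$seq)) {
    return(list(seq = reads$seq, qual = reads$qual))
  }
  stop("reads must be a character vector, a list(seq, qual), or a FASTQ path")
}
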