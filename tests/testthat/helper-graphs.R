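# Small graph fixtures built directly through the dbg_graph constructor.
# Sequences are placeholders (the constructor only validates lengths and the
# alphabet); coverages and topology carry the information under test.

# cycle of n unitigs: node i connects right -> left of node i+1 (wrapping)
toy_cycle <- function(node_cov, arc_cov, num_kmers = 10, k = 3) {
  n <- length(node_cov)
  if (length(num_kmers) == 1) num_kmers <- rep(num_kmers, n)
  u <- data.frame(seq = strrep("A", num_kmers + k - 1),
                  cov_sum = node_cov * num_kmers)
  arcs <- data.frame(from = 1:n, from_side = "right",
                     to = c(2:n, 1), to_side = "left",
                     k1mer = "AAAA", cov = arc_cov)
  dbg_graph(k, u, arcs)
}

# open chain: n unitigs, n-1 arcs
toy_chain <- function(node_cov, arc_cov, num_kmers = 10, k = 3) {
  n <- length(node_cov)
  if (length(num_kmers) == 1) num_kmers <- rep(num_kmers, n)
  u <- data.frame(seq = strrep("A", num_kmers + k - 1),
                  cov_sum = node_cov * num_kmers)
  arcs <- data.frame(from = 1:(n - 1), from_side = "right",
                     to = 2:n, to_side = "left",
                     k1mer = "AAAA", cov = arc_cov)
  dbg_graph(k, u, arcs)
}

# reference mixture used across CRF tests
toy_model <- function(lam = 30, f = 1.2, lam0 = 1.5, f0 = 1.2,
                      weights = rep(1, 6)) {
  nb_mixture(lam, f, lam0, f0, weights)
}

# a graph with exact coverages m * lam for every element, from a simulated
# genome with two dispersed repeats; returns graph, truth and genome
perfect_coverage_graph <- function(genome_len = 1e5, lam = 30, seed = 42) {
  gen <- make_genome(genome_len,
                     repeats = list(list(length = 2000, copies = 2, mode = "dispersed"),
                                    list(length = 1000, copies = 3, mode = "dispersed")),
                     seed = seed, circular = TRUE)
  reads <- simulate_reads(gen, depth = 40, read_len = 100, error_rate = 0,
                          f_sim = 1, seed = seed + 1)
  g <- build_graph(reads$seq, k = 21, abundance_min = 2)
  tr <- truth_labels(gen, 21)
  gt <- graph_truth(g, tr)
  stopifnot(!any(gt$nodes$mixed))
  g$unitigs$avg_cov <- gt$nodes$mult * lam
  g$unitigs$cov_sum <- g$unitigs$avg_cov * g$unitigs$num_kmers
  g$arcs$cov <- gt$arcs$mult * lam
  list(graph = g, truth = gt, genome = gen,
       model = nb_mixture(lam, 1.2, 1.5, 1.2, rep(1, 6)))
}
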