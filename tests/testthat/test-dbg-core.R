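test_that("a repeat-free read set collapses to a single unitig", {
  # k=3 over ATTCACGGC: all seven canonical 3-mers are distinct, so the
  # graph is one non-branching path; the read is its own canonical form
  g <- build_graph(rep("ATTCACGGC", 3), k = 3, abundance_min = 2)
  expect_equal(nrow(g$unitigs), 1)
  expect_equal(g$unitigs$seq, "ATTCACGGC")
  expect_equal(g$unitigs$num_kmers, 7L)
  expect_equal(g$unitigs$cov_sum, 21)  # each 3-mer seen once in each of 3 reads
  expect_equal(g$unitigs$avg_cov, 3)
  expect_equal(nrow(g$arcs), 0)
})

test_that("a duplicated genome segment collapses to one repeat unitig", {
  gen <- make_genome(200, repeats = list(list(length = 30, copies = 2, mode = "dispersed")),
                     circular = FALSE, seed = 5)
  g <- build_graph(gen, k = 9, abundance_min = 1)
  tr <- truth_labels(gen, 9, circular = FALSE)
  gt <- graph_truth(g, tr)
  # every distinct canonical genome k-mer appears in exactly one unitig
  expect_equal(sum(g$unitigs$num_kmers), dbgcrf:::.cpp_table_size(tr$ktab))
  # the duplicated interior is a single multiplicity-2 node with two in-paths
  rep_nodes <- gt$nodes$id[!gt$nodes$mixed & gt$nodes$mult == 2]
  expect_gte(length(rep_nodes), 1)
  degs <- vapply(rep_nodes, function(u)
    length(g$adjacency$left[[u]]) + length(g$adjacency$right[[u]]), 0L)
  expect_true(any(degs >= 2))
})

test_that("abundance_min = 1 on error-free reads reproduces the genome k-mer set", {
  for (seed in 1:2) {
    gen <- make_genome(20000, seed = seed, circular = TRUE)
    reads <- simulate_reads(gen, depth = 30, read_len = 100, error_rate = 0,
                            f_sim = 1, seed = seed + 10)
    g <- build_graph(reads$seq, k = 21, abundance_min = 1)
    tr <- truth_labels(gen, 21)
    expect_equal(sum(g$unitigs$num_kmers), dbgcrf:::.cpp_table_size(tr$ktab))
    gt <- graph_truth(g, tr)
    expect_true(all(unlist(gt$node_kmer_mult) >= 1))
    expect_true(dbgcrf:::.is_compacted(g))
  }
})

test_that("an empty surviving k-mer set is an explicit error", {
  expect_error(build_graph(rep("ATTCACGGC", 2), k = 3, abundance_min = 3),
               "empty graph")
})

test_that("non-ACGT read characters break k-mer windows without failing", {
  g1 <- build_graph(rep("ATTCACGGC", 2), k = 3, abundance_min = 1)
  g2 <- build_graph(rep("ATTCANCGGC", 2), k = 3, abundance_min = 1)
  # the N removes the three windows spanning it: 7 k-mers drop to 5
  expect_equal(sum(g1$unitigs$num_kmers), 7L)
  expect_equal(sum(g2$unitigs$num_kmers), 5L)
})

test_that("GFA write/load round trip preserves topology and coverage", {
  gen <- make_genome(30000, repeats = list(list(length = 800, copies = 2, mode = "dispersed")),
                     seed = 11, circular = TRUE)
  reads <- simulate_reads(gen, depth = 25, read_len = 100, error_rate = 0.005,
                          f_sim = 1.3, seed = 12)
  g <- build_graph(reads, k = 21, abundance_min = 2)
  g <- annotate_coverage(g, reads, weighted = TRUE)
  path <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, path)
  g2 <- read_gfa(path)
  expect_equal(g2$k, g$k)
  expect_equal(g2$unitigs$seq, g$unitigs$seq)
  expect_equal(g2$unitigs$cov_sum, g$unitigs$cov_sum, tolerance = 1e-6)
  key <- function(gr) with(gr$arcs, sort(paste(from, from_side, to, to_side, k1mer)))
  expect_equal(key(g2), key(g))
  expect_equal(sort(g2$arcs$cov), sort(g$arcs$cov), tolerance = 1e-6)
})

test_that("BCALM-style S/L lines are interpreted correctly", {
  # KC:i total-count tags, and 'L a + b + 2M' joining right(a) to left(b)
  path <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0",
               "S\ta\tAACG\tKC:i:20",
               "S\tb\tCGTT\tKC:i:12",
               "L\ta\t+\tb\t+\t2M"), path)
  g <- read_gfa(path, k = 3)
  expect_equal(g$unitigs$seq, c("AACG", "CGTT"))
  expect_equal(g$unitigs$cov_sum, c(20, 12))
  expect_equal(g$unitigs$avg_cov, c(10, 6))
  expect_equal(nrow(g$arcs), 1)
  expect_equal(g$arcs$from_side, "right")
  expect_equal(g$arcs$to_side, "left")
  expect_equal(g$arcs$k1mer, "ACGT")
  # the same bidirected arc written from both directions collapses to one
  writeLines(c("S\ta\tAACG\tKC:i:20",
               "S\tb\tCGTT\tKC:i:12",
               "L\ta\t+\tb\t+\t2M",
               "L\tb\t-\ta\t-\t2M"), path)
  g2 <- read_gfa(path, k = 3)
  expect_equal(nrow(g2$arcs), 1)
  expect_equal(g2$arcs$k1mer, "ACGT")
})

test_that("malformed GFA links are format errors", {
  path <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("S\ta\tAACG", "S\tb\tCGTT", "L\ta\t+\tb\t+\t3M"), path)
  expect_error(read_gfa(path, k = 3), "overlap")
  writeLines(c("S\ta\tAACG", "L\ta\t+\tzz\t+\t2M"), path)
  expect_error(read_gfa(path, k = 3), "dangling")
})

test_that("coverage annotation counts k-mers and pools strands", {
  read <- "ATTCACGGC"
  g <- build_graph(rep(read, 2), k = 3, abundance_min = 2)
  g1 <- annotate_coverage(g, read, weighted = FALSE)
  expect_equal(g1$unitigs$avg_cov, 1)          # one pass over the unitig
  # a read and its reverse complement double every canonical count
  g2 <- annotate_coverage(g, c(read, revcomp(read)), weighted = FALSE)
  expect_equal(g2$unitigs$avg_cov, 2)
  # near-certain base calls make the q-mer count match the k-mer count
  gq <- annotate_coverage(g, list(seq = read, qual = strrep("I", nchar(read))),
                          weighted = TRUE)
  expect_equal(gq$unitigs$avg_cov, 1, tolerance = 1e-3)
  # q-mer counts never exceed integer counts
  gq2 <- annotate_coverage(g, list(seq = read, qual = strrep("5", nchar(read))),
                           weighted = TRUE)
  expect_lt(gq2$unitigs$cov_sum, g1$unitigs$cov_sum)
})

test_that("neighbourhood extraction follows the reachability definition", {
  g <- toy_chain(c(10, 10, 10, 10), c(9, 9, 9))
  # s = 0 around a node: the node alone, no arcs
  n0 <- extract_neighbourhood(g, 2, 0, "node")
  expect_equal(n0$nodes, 2L)
  expect_length(n0$arcs, 0)
  # chain a-b-c-d centred on b at s=1: nodes {a,b,c}, arcs incident to them
  n1 <- extract_neighbourhood(g, 2, 1, "node")
  expect_equal(n1$nodes, 1:3)
  expect_equal(n1$arcs, 1:3)  # c-d is incident to c, so included
  # s beyond the diameter: the whole graph
  nall <- extract_neighbourhood(g, 2, 10, "node")
  expect_equal(nall$nodes, 1:4)
  expect_equal(nall$arcs, 1:3)
  # arc centre: both endpoints at distance 0
  a0 <- extract_neighbourhood(g, 2, 0, "arc")
  expect_equal(a0$nodes, 2:3)
  expect_equal(a0$arcs, 2L)
  a1 <- extract_neighbourhood(g, 2, 1, "arc")
  expect_equal(a1$nodes, 1:4)
})

test_that("neighbourhoods are monotone in s", {
  gen <- make_genome(30000, repeats = list(list(length = 500, copies = 3, mode = "dispersed")),
                     seed = 3, circular = TRUE)
  reads <- simulate_reads(gen, depth = 15, read_len = 100, error_rate = 0.01,
                          f_sim = 1.5, seed = 4)
  g <- build_graph(reads, k = 21, abundance_min = 2)
  set.seed(8)
  for (u in sample(nrow(g$unitigs), 10)) {
    prev <- extract_neighbourhood(g, u, 0, "node")
    for (s in 1:4) {
      cur <- extract_neighbourhood(g, u, s, "node")
      expect_true(all(prev$nodes %in% cur$nodes))
      expect_true(all(prev$arcs %in% cur$arcs))
      prev <- cur
    }
  }
})

test_that("reverse-complementing every read leaves the graph invariant", {
  gen <- make_genome(15000, seed = 21, circular = TRUE)
  reads <- simulate_reads(gen, depth = 20, read_len = 80, error_rate = 0,
                          f_sim = 1, seed = 22)
  g1 <- build_graph(reads$seq, k = 21, abundance_min = 2)
  g2 <- build_graph(revcomp(reads$seq), k = 21, abundance_min = 2)
  expect_equal(g1$unitigs$seq, g2$unitigs$seq)
  expect_equal(g1$unitigs$cov_sum, g2$unitigs$cov_sum)
  key <- function(gr) with(gr$arcs, sort(paste(from, from_side, to, to_side)))
  expect_equal(key(g1), key(g2))
})

test_that("built graphs are maximally compacted", {
  for (seed in c(2, 9)) {
    gen <- make_genome(20000, repeats = list(list(length = 400, copies = 2, mode = "dispersed")),
                       seed = seed, circular = TRUE)
    reads <- simulate_reads(gen, depth = 20, read_len = 100, error_rate = 0.01,
                            f_sim = 1.5, seed = seed + 50)
    g <- build_graph(reads, k = 21, abundance_min = 2)
    expect_true(dbgcrf:::.is_compacted(g))
  }
})
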