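# Seeded genome and short-read simulation with exact ground-truth
# multiplicity labels, plus the evaluation harness.
#
# The simulator emulates the structure that drives the inference problem:
# dispersed or tandem repeat blocks create elements of multiplicity >= 2,
# substitution errors create spurious low-coverage elements, and
# negative-binomial read-start clustering reproduces the overdispersed
# coverage of real Illumina runs.  Only substitutions are simulated (no
# indels), which keeps the truth labelling exact.

#' Generate a random genome with controlled repeat structure
#'
#' Draws an i.i.d. random sequence and copies repeat blocks into it:
#' dispersed copies go to random positions, tandem copies directly after the
#' source block.  The returned sequence has exactly `length` bases.
#'
#' @param length total genome length in bp.
#' @param repeats list of repeat specs, each a list with `length` (bp),
#'   `copies` (total copy number >= 2) and `mode` (`"dispersed"` or
#'   `"tandem"`).
#' @param gc GC content (default 0.5).
#' @param circular logical; circular genomes wrap for k-mer counting and
#'   read simulation.
#' @param seed RNG seed (optional).
#' @return character scalar with attributes `circular`.
#' @export
make_genome <- function(length, repeats = list(), gc = 0.5, circular = TRUE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  extra <- sum(vapply(repeats, function(r) (r$copies - 1) * r$length, 0))
  base_len <- length - extra
  if (base_len <= max(c(0, vapply(repeats, `[[`, 0, "length"))))
    stop("infeasible genome spec: repeat content must be smaller than the genome")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), base_len, replace = TRUE, prob = p)
  for (r in repeats) {
    src <- sample.int(base::length(chars) - r$length + 1, 1)
    block <- chars[src:(src + r$length - 1)]
    for (cp in seq_len(r$copies - 1)) {
      at <- if (identical(r$mode, "tandem")) src + cp * r$length
            else sample.int(base::length(chars) + 1, 1)
      chars <- append(chars, block, after = at - 1)
    }
  }
  g <- paste(chars, collapse = "")
  stopifnot(nchar(g) == length)
  attr(g, "circular") <- circular
  g
}

#' Ground-truth multiplicity labels of a genome
#'
#' Exact canonical k-mer and k+1-mer counts over the genome (one occurrence
#' per genomic position, both strands pooled through canonicalisation);
#' circular genomes wrap across the origin.
#'
#' @param genome character scalar (e.g. from [make_genome()]).
#' @param k k-mer size.
#' @param circular wrap over the origin; defaults to the genome's
#'   `circular` attribute (or `TRUE`).
#' @return An object of class `dbg_truth` with count-table handles; query it
#'   with [truth_multiplicity()] or [graph_truth()].
#' @export
truth_labels <- function(genome, k, circular = NULL) {
  if (is.null(circular)) circular <- isTRUE(attr(genome, "circular")) || is.null(attr(genome, "circular"))
  gk <- if (circular) paste0(genome, substr(genome, 1, k - 1)) else genome
  gk1 <- if (circular) paste0(genome, substr(genome, 1, k)) else genome
  structure(list(k = as.integer(k), circular = circular,
                 ktab = .cpp_kmer_table(gk, character(), as.integer(k), FALSE),
                 k1tab = .cpp_kmer_table(gk1, character(), as.integer(k) + 1L, FALSE)),
            class = "dbg_truth")
}

#' True multiplicity of k-mers or k+1-mers
#' @param truth a [truth_labels()] object.
#' @param seqs character vector of k-mers or (k+1)-mers (any orientation).
#' @return integer multiplicities (0 for sequences absent from the genome).
#' @export
truth_multiplicity <- function(truth, seqs) {
  len <- unique(nchar(seqs))
  stopifnot(length(len) <= 1)
  tab <- if (!length(len) || len == truth$k) truth$ktab else truth$k1tab
  as.integer(.cpp_table_counts_of(tab, seqs))
}

#' Label every node and arc of a graph with its true multiplicity
#'
#' A unitig's truth is the shared multiplicity of its constituent k-mers; if
#' they disagree the node is flagged `mixed` (its per-k-mer truths are kept
#' for k-mer-level evaluation).  An arc's truth is the count of its k+1-mer
#' in the genome; spurious arcs get 0.
#'
#' @param graph a `dbg_graph`.
#' @param truth a [truth_labels()] object with matching `k`.
#' @return list with data frames `nodes` (`id`, `mult`, `mixed`,
#'   `num_kmers`), `arcs` (`id`, `mult`) and the list `node_kmer_mult` of
#'   per-k-mer truth vectors.
#' @export
graph_truth <- function(graph, truth) {
  stopifnot(inherits(graph, "dbg_graph"), inherits(truth, "dbg_truth"),
            graph$k == truth$k)
  per_kmer <- lapply(.cpp_seq_kmer_counts(truth$ktab, graph$unitigs$seq), as.integer)
  mult <- vapply(per_kmer, function(v) if (length(unique(v)) == 1) v[1] else NA_integer_, 0L)
  nodes <- data.frame(id = graph$unitigs$id, mult = mult, mixed = is.na(mult),
                      num_kmers = graph$unitigs$num_kmers)
  arcs <- data.frame(id = graph$arcs$id,
                     mult = if (nrow(graph$arcs))
                       as.integer(.cpp_table_counts_of(truth$k1tab, graph$arcs$k1mer))
                     else integer())
  list(nodes = nodes, arcs = arcs, node_kmer_mult = per_kmer)
}

#' Simulate short reads with errors and quality scores
#'
#' Read starts are drawn per genome position from a negative binomial with
#' overdispersion `f_sim` (Poisson when `f_sim = 1`), reproducing the
#' overdispersed per-k-mer coverage of real runs; strands are equiprobable.
#' Substitution errors occur independently at `error_rate`; erroneous bases
#' receive low Phred draws and correct bases high ones (normal draws around
#' `phred_error` resp. `phred_correct`, sd `phred_sd`, clipped to `[2, 40]`).
#'
#' The effective per-k-mer coverage depth of the output is approximately
#' `depth * (read_len - k + 1) / read_len * (1 - error_rate)^k`
#' (see [effective_kmer_depth()]).
#'
#' @param genome character scalar; its `circular` attribute controls
#'   wrapping.
#' @param depth target fold read coverage (> 0).
#' @param read_len read length (default 100).
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param f_sim read-start overdispersion factor (>= 1, default 1.5).
#' @param phred_correct,phred_error,phred_sd quality model (defaults 32, 12, 3).
#' @param seed RNG seed (optional).
#' @return list with `seq` and `qual` character vectors (FASTQ-ready) and
#'   `n_errors` per read.
#' @export
simulate_reads <- function(genome, depth, read_len = 100, error_rate = 0.01,
                           f_sim = 1.5, phred_correct = 32, phred_error = 12,
                           phred_sd = 3, seed = NULL) {
  stopifnot(depth > 0, error_rate >= 0, error_rate <= 0.05, f_sim >= 1)
  L <- nchar(genome)
  if (read_len > L) stop("read length exceeds genome length")
  if (!is.null(seed)) set.seed(seed)
  circular <- isTRUE(attr(genome, "circular")) || is.null(attr(genome, "circular"))

  npos <- if (circular) L else L - read_len + 1
  mu <- L * depth / (read_len * npos)
  counts <- if (f_sim <= 1 + 1e-9) rpois(npos, mu)
            else rnbinom(npos, mu = mu, size = mu / (f_sim - 1))
  starts <- rep.int(seq_len(npos), counts)
  if (!length(starts)) stop("no reads drawn; increase depth")

  template <- if (circular) paste0(genome, substr(genome, 1, read_len - 1)) else genome
  seqs <- substring(template, starts, starts + read_len - 1)
  minus <- runif(length(seqs)) < 0.5
  seqs[minus] <- revcomp(seqs[minus])

  out <- .cpp_apply_read_errors(seqs, error_rate, phred_correct, phred_error, phred_sd)
  list(seq = out$seq, qual = out$qual, n_errors = out$n_errors)
}

#' Expected per-k-mer coverage of a simulated read set
#'
#' A k-mer position is spanned by `read_len - k + 1` of the `read_len`
#' per-base read placements and an occurrence is error-free with probability
#' `(1 - error_rate)^k`.
#'
#' @param depth,read_len,error_rate as in [simulate_reads()].
#' @param k k-mer size.
#' @return expected error-free k-mer coverage depth.
#' @export
effective_kmer_depth <- function(depth, read_len, k, error_rate = 0) {
  depth * (read_len - k + 1) / read_len * (1 - error_rate)^k
}

#' Evaluate multiplicity assignments against the ground truth
#'
#' Node accuracy is the percentage of (non-mixed) evaluated nodes assigned
#' their true multiplicity; k-mer accuracy weighs each node by its number of
#' k-mers and scores mixed nodes per k-mer.  The confusion matrix tabulates
#' estimated against true multiplicities over `0..m_max` and `>m_max`.
#' Trusted/untrusted classification treats a k-mer as untrusted when its
#' node's MAP multiplicity is 0; the positive class is the erroneous k-mers
#' (truth 0), so sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and
#' F1 = 2TP/(2TP+FP+FN).
#'
#' @param assignments data frame as returned by [infer_elements()] (columns
#'   `id`, `type`, `map`).
#' @param gtruth a [graph_truth()] result for the same graph.
#' @param m_max top multiplicity class of the confusion matrix (default 5).
#' @return list with `node_accuracy`, `kmer_accuracy`, `arc_accuracy`
#'   (percentages), `confusion` (matrix), and `classification` (TP, TN, FP,
#'   FN, sensitivity, specificity, f1 for the trusted/untrusted split).
#' @export
evaluate_assignments <- function(assignments, gtruth, m_max = 5) {
  an <- assignments[assignments$type == "node", ]
  aa <- assignments[assignments$type == "arc", ]
  tn <- gtruth$nodes[match(an$id, gtruth$nodes$id), ]
  kt <- gtruth$node_kmer_mult[an$id]

  pure <- !tn$mixed
  node_accuracy <- 100 * mean(an$map[pure] == tn$mult[pure])

  kmer_hits <- sum(vapply(which(pure), function(i)
    tn$num_kmers[i] * (an$map[i] == tn$mult[i]), 0))
  kmer_hits <- kmer_hits + sum(vapply(which(!pure), function(i)
    sum(kt[[i]] == an$map[i]), 0))
  kmer_total <- sum(tn$num_kmers)
  kmer_accuracy <- 100 * kmer_hits / kmer_total

  arc_accuracy <- if (nrow(aa)) {
    ta <- gtruth$arcs$mult[match(aa$id, gtruth$arcs$id)]
    100 * mean(aa$map == ta)
  } else NA_real_

  clamp <- function(m) pmin(m, m_max + 1)
  lv <- 0:(m_max + 1)
  lab <- c(as.character(0:m_max), paste0(">", m_max))
  confusion <- table(estimated = factor(clamp(an$map[pure]), levels = lv, labels = lab),
                     true = factor(clamp(tn$mult[pure]), levels = lv, labels = lab))

  # trusted/untrusted over k-mers: positive class = erroneous (truth 0)
  tp <- tn_ <- fp <- fn <- 0
  for (i in seq_len(nrow(an))) {
    kmult <- kt[[i]]
    pred0 <- an$map[i] == 0
    err <- kmult == 0
    tp <- tp + sum(err & pred0)
    fn <- fn + sum(err & !pred0)
    fp <- fp + sum(!err & pred0)
    tn_ <- tn_ + sum(!err & !pred0)
  }
  classification <- list(TP = tp, TN = tn_, FP = fp, FN = fn,
                         sensitivity = if (tp + fn) tp / (tp + fn) else NA,
                         specificity = if (tn_ + fp) tn_ / (tn_ + fp) else NA,
                         f1 = if (2 * tp + fp + fn) 2 * tp / (2 * tp + fp + fn) else NA)
  list(node_accuracy = node_accuracy, kmer_accuracy = kmer_accuracy,
       arc_accuracy = arc_accuracy, n_nodes_evaluated = sum(pure),
       n_mixed_excluded = sum(!pure), confusion = confusion,
       classification = classification)
}
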