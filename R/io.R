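# Sequence and graph file I/O.  FASTA/FASTQ reading goes through Biostrings
# (gzip-transparent); GFA1 is the BCALM 2-style unitig-graph dialect with
# S-lines, L-lines carrying a (k-1)M overlap CIGAR, and KC/km count tags.

#' Read a FASTQ file
#' @param path FASTQ file, optionally gzipped.
#' @return list with character vectors `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns while
  # assembling the quality-scaled set; the reader is otherwise clean
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(list(seq = unname(as.character(x)),
                        qual = unname(as.character(Biostrings::quality(x)))))
}

#' Write reads to a FASTQ file
#' @param reads list with `seq` and `qual` character vectors.
#' @param path output path (plain text).
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads$seq)
  stopifnot(length(reads$qual) == n)
  lines <- character(4 * n)
  lines[seq(1, by = 4, length.out = n)] <- sprintf("@read%d", seq_len(n))
  lines[seq(2, by = 4, length.out = n)] <- reads$seq
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file, optionally gzipped.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Write a de Bruijn graph to GFA1
#'
#' Segments carry the BCALM-style tags `KC:i` (rounded total k-mer count) and
#' `km:f` (average coverage, written with 9 significant digits so that a
#' write/load round trip preserves coverage); links carry `kc:f` with the
#' arc's k+1-mer coverage.  Link orientations encode sides: exiting through
#' the right side is `+`, through the left side `-`; entering through the
#' left side is `+`, through the right side `-`.
#'
#' @param graph a `dbg_graph`.
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "dbg_graph"))
  u <- graph$unitigs
  a <- graph$arcs
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%d\t%s\tKC:i:%d\tkm:f:%.9g",
                     u$id, u$seq, as.integer(round(u$cov_sum)), u$avg_cov))
  if (nrow(a)) {
    lines <- c(lines, sprintf("L\t%d\t%s\t%d\t%s\t%dM\tkc:f:%.9g",
                              a$from, ifelse(a$from_side == "right", "+", "-"),
                              a$to, ifelse(a$to_side == "left", "+", "-"),
                              graph$k - 1L, a$cov))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a de Bruijn graph from GFA1
#'
#' Accepts the graphs written by [write_gfa()] as well as BCALM 2 output.
#' Segment coverage is taken from a `kc:f` tag when present, else from
#' `km:f` (average, full precision) or `KC:i` (rounded total count).  Links
#' must carry an overlap
#' CIGAR of exactly `(k-1)M`; mirrored duplicate links (the same bidirected
#' arc written from both directions) are collapsed.
#'
#' @param path GFA1 file.
#' @param k k-mer size; if `NULL`, inferred from the first link overlap.
#' @return A `dbg_graph`.  Unitig ids are re-assigned in canonical-sequence
#'   sort order.
#' @export
read_gfa <- function(path, k = NULL) {
  lines <- readLines(path)
  stype <- substr(lines, 1, 1)
  sfields <- strsplit(lines[stype == "S"], "\t", fixed = TRUE)
  lfields <- strsplit(lines[stype == "L"], "\t", fixed = TRUE)
  if (!length(sfields)) stop("GFA format error: no segments")

  if (is.null(k)) {
    if (!length(lfields)) stop("cannot infer k from a GFA without links; pass k")
    ov <- lfields[[1]][6]
    if (!grepl("^\\d+M$", ov)) stop("GFA format error: unsupported overlap CIGAR")
    k <- as.integer(sub("M$", "", ov)) + 1L
  }

  get_tag <- function(fields, from, tag) {
    if (length(fields) < from) return(NA_character_)
    tags <- fields[seq(from, length(fields))]
    hit <- tags[startsWith(tags, tag)]
    if (!length(hit)) NA_character_ else sub(paste0("^", tag), "", hit[1])
  }

  names_in <- vapply(sfields, `[`, "", 2)
  seqs <- toupper(vapply(sfields, `[`, "", 3))
  cov_sum <- vapply(seq_along(sfields), function(i) {
    nk <- nchar(seqs[i]) - k + 1
    kc <- get_tag(sfields[[i]], 4, "kc:f:")
    if (!is.na(kc)) return(as.numeric(kc))
    km <- get_tag(sfields[[i]], 4, "km:f:")
    if (!is.na(km)) return(as.numeric(km) * nk)
    KC <- get_tag(sfields[[i]], 4, "KC:i:")
    if (!is.na(KC)) return(as.numeric(KC))
    0
  }, 0)

  ord <- order(seqs)
  seqs <- seqs[ord]
  cov_sum <- cov_sum[ord]
  id_of <- stats::setNames(seq_along(ord), names_in[ord])

  arcs <- NULL
  if (length(lfields)) {
    lmat <- do.call(rbind, lapply(lfields, function(f) {
      if (length(f) < 6) stop("GFA format error: malformed L-line")
      if (f[6] != sprintf("%dM", k - 1))
        stop(sprintf("GFA format error: link overlap '%s', expected %dM", f[6], k - 1))
      if (!f[2] %in% names(id_of) || !f[4] %in% names(id_of))
        stop(sprintf("GFA format error: dangling link %s -> %s", f[2], f[4]))
      c(f[2], f[3], f[4], f[5], get_tag(f, 7, "kc:f:"))
    }))
    from <- unname(id_of[lmat[, 1]])
    from_side <- ifelse(lmat[, 2] == "+", "right", "left")
    to <- unname(id_of[lmat[, 3]])
    to_side <- ifelse(lmat[, 4] == "+", "left", "right")
    cov <- suppressWarnings(as.numeric(lmat[, 5]))
    cov[is.na(cov)] <- 0
    k1mer <- .arc_k1mer(seqs, from, from_side, to, to_side, k)
    canon <- pmin(k1mer, revcomp(k1mer))
    keep <- !duplicated(canon)
    arcs <- data.frame(from = from, from_side = from_side, to = to,
                       to_side = to_side, k1mer = k1mer, cov = cov)[keep, ]
    # store arcs in canonical k+1-mer orientation
    flip <- arcs$k1mer != canon[keep]
    if (any(flip)) {
      tmp <- arcs[flip, ]
      arcs[flip, c("from", "from_side", "to", "to_side")] <-
        data.frame(tmp$to, ifelse(tmp$to_side == "left", "right", "left"),
                   tmp$from, ifelse(tmp$from_side == "right", "left", "right"))
      arcs$k1mer[flip] <- canon[keep][flip]
    }
  }
  dbg_graph(k, data.frame(seq = seqs, cov_sum = cov_sum), arcs)
}

# the k+1-mer implied by an arc: last k bases of the exit-oriented `from`
# unitig followed by the k-th base of the entry-oriented `to` unitig
.arc_k1mer <- function(seqs, from, from_side, to, to_side, k) {
  sf <- ifelse(from_side == "right", seqs[from], revcomp(seqs[from]))
  st <- ifelse(to_side == "left", seqs[to], revcomp(seqs[to]))
  left <- substr(sf, nchar(sf) - k + 1, nchar(sf))
  right <- substr(st, k, k)
  if (any(substr(st, 1, k - 1) != substr(left, 2, k)))
    stop("GFA format error: link endpoints do not overlap by k-1 bases")
  paste0(left, right)
}

#' Reverse complement of DNA strings
#' @param x character vector over A,C,G,T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
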