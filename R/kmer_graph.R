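# Colored de Bruijn graph substrate: canonical k-mer counting per sample
# ("color"), color merging, and k-mer-frequency-spectrum cleaning.

new_kmer_graph <- function(k, kmers, counts, sample_ids) {
  counts <- as.matrix(counts)
  colnames(counts) <- sample_ids
  structure(list(k = as.integer(k), kmers = kmers, counts = counts,
                 sample_ids = sample_ids),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: k=%d, %d canonical k-mers, %d color(s): %s\n",
              x$k, length(x$kmers), length(x$sample_ids),
              paste(x$sample_ids, collapse = ", ")))
  invisible(x)
}

#' Count canonical k-mers of a read set (one graph color)
#'
#' Each k-mer is stored as the lexicographic minimum of itself and its
#' reverse complement; k-mers containing `N` are skipped. `k` must be odd so
#' no k-mer is its own reverse complement.
#'
#' @param reads a `read_set`, or a character vector of sequences.
#' @param k odd k-mer size, `11 <= k <= 63` (small odd k is permitted for
#'   toy examples).
#' @param sample_id color label; defaults to the read set's sample id.
#' @return a single-color `kmer_graph`.
#' @export
count_kmers <- function(reads, k, sample_id = NULL) {
  if (inherits(reads, "read_set")) {
    if (is.null(sample_id)) sample_id <- reads$sample_id
    reads <- all_reads(reads)
  }
  if (is.null(sample_id)) sample_id <- "S1"
  k <- as.integer(k)
  if (k %% 2 == 0)
    stop("k must be odd (even k makes palindromic k-mers ambiguous)")
  if (k < 1 || k > 63) stop("k must be in [1, 63]")
  res <- cpp_count_kmers(as.character(reads), k)
  new_kmer_graph(k, res$kmer, matrix(res$count, ncol = 1), sample_id)
}

#' Merge single-color graphs into a colored graph
#'
#' Union of k-mers; per-sample count vectors aligned in input order, with 0
#' for k-mers absent from a color.
#'
#' @param graphs list of `kmer_graph` objects with identical `k`.
#' @return a multi-color `kmer_graph`.
#' @export
merge_colors <- function(graphs) {
  stopifnot(length(graphs) >= 1,
            all(vapply(graphs, inherits, TRUE, "kmer_graph")))
  ks <- vapply(graphs, `[[`, 1L, "k")
  if (length(unique(ks)) != 1) stop("cannot merge graphs with different k")
  ids <- unlist(lapply(graphs, `[[`, "sample_ids"))
  all_k <- sort(unique(unlist(lapply(graphs, `[[`, "kmers"))))
  counts <- matrix(0L, nrow = length(all_k), ncol = length(ids))
  col <- 1L
  for (g in graphs) {
    idx <- match(g$kmers, all_k)
    nc <- ncol(g$counts)
    counts[idx, col:(col + nc - 1L)] <- g$counts
    col <- col + nc
  }
  new_kmer_graph(ks[1], all_k, counts, ids)
}

#' Cleaning policy for the k-mer frequency spectrum
#'
#' Error correction by k-mer frequency spectrum: k-mers below a count
#' threshold are removed before assembly and bubble calling.
#'
#' @param min_total_count minimum count (>= 1); 1 keeps everything.
#' @param per_color if `TRUE` the threshold applies to every color
#'   separately (a k-mer is kept if any color reaches it); otherwise to the
#'   summed counts.
#' @return a `cleaning_policy`.
#' @export
cleaning_policy <- function(min_total_count = 2, per_color = FALSE) {
  stopifnot(min_total_count >= 1)
  structure(list(min_total_count = as.integer(min_total_count),
                 per_color = per_color),
            class = "cleaning_policy")
}

#' Estimate the k-mer coverage of a graph
#'
#' Count-weighted median of the summed per-k-mer counts: the median coverage
#' of a k-mer *instance*. Unlike the plain median over distinct k-mers, this
#' is robust to the flood of singleton error k-mers that sequencing errors
#' add to the frequency spectrum.
#'
#' @param graph a `kmer_graph`.
#' @return estimated coverage (numeric).
#' @export
estimate_kmer_coverage <- function(graph) {
  totals <- sort(rowSums(graph$counts))
  if (length(totals) == 0) return(0)
  cw <- cumsum(as.numeric(totals))
  totals[which(cw >= cw[length(cw)] / 2)[1]]
}

#' Default cleaning threshold for a given mean coverage
#'
#' `max(2, round(mean_depth / 10))` — a tenth of the expected coverage,
#' floored at 2 so singleton error k-mers are always removed.
#'
#' @param mean_depth expected per-sample fold coverage.
#' @return integer threshold.
#' @export
default_clean_threshold <- function(mean_depth) {
  max(2L, as.integer(round(mean_depth / 10)))
}

#' Remove low-frequency k-mers from a graph
#'
#' @param graph a `kmer_graph`.
#' @param policy a [cleaning_policy()], or a bare integer threshold on summed
#'   counts.
#' @return the cleaned `kmer_graph` (a subset of the input; counts are never
#'   increased).
#' @export
clean_graph <- function(graph, policy = cleaning_policy()) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (is.numeric(policy)) policy <- cleaning_policy(policy)
  if (policy$per_color) {
    keep <- apply(graph$counts >= policy$min_total_count, 1, any)
  } else {
    keep <- rowSums(graph$counts) >= policy$min_total_count
  }
  new_kmer_graph(graph$k, graph$kmers[keep],
                 graph$counts[keep, , drop = FALSE], graph$sample_ids)
}

#' Canonicalise k-mer strings
#'
#' @param x character vector of k-mers (equal, odd length).
#' @return lexicographic minimum of each k-mer and its reverse complement.
#' @export
canonical_kmers <- function(x) {
  pmin(x, revcomp(x))
}

#' Dump a graph as TSV (kmer + one count column per color)
#'
#' @param graph a `kmer_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(kmer = graph$kmers, graph$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
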