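# Assembly layer: unitig extraction from the k-mer graph, read-pair
# scaffolding with the ">3 linking pairs" rule, length filters, and
# N20/N50/N80 summary statistics.

#' Extract unitigs (contigs) from a k-mer graph
#'
#' Maximal non-branching paths of the (cleaned) graph, each emitted once in
#' canonical orientation. Branching k-mers that extend in neither direction
#' appear as k-bp singletons.
#'
#' @param graph a cleaned `kmer_graph`.
#' @return data frame with `id`, `sequence`, `length`,
#'   `mean_kmer_coverage` (mean summed-color count along the path), ordered
#'   by decreasing length.
#' @export
unitigs <- function(graph) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (length(graph$kmers) == 0)
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), mean_kmer_coverage = numeric()))
  res <- cpp_unitigs(graph$kmers, rowSums(graph$counts), graph$k)
  data.frame(id = sprintf("contig_%d", seq_along(res$sequence)),
             sequence = res$sequence,
             length = nchar(res$sequence),
             mean_kmer_coverage = res$mean_coverage)
}

# Infer (contig end, overhang) implied by one mapped mate.
# For mate 1 the fragment runs in the read direction; for mate 2 against it.
mate_edge <- function(strand, pos, read_len, contig_len, is_mate1) {
  frag_strand <- if (is_mate1) strand else -strand
  if (frag_strand > 0) {
    # fragment extends rightwards
    if (is_mate1) list(edge = "R", over = contig_len - pos)
    else list(edge = "L", over = pos + read_len)
  } else {
    if (is_mate1) list(edge = "L", over = pos + read_len)
    else list(edge = "R", over = contig_len - pos)
  }
}

#' Join contigs into scaffolds using read-pair links
#'
#' Both mates are placed on the contigs by exact-seed anchoring with banded
#' extension; a pair whose mates land on two different contigs is a link.
#' Contig pairs connected by more than 3 read pairs (i.e. `>= min_links = 4`)
#' with a consistent implied junction are joined; a contig end implicated in
#' two or more qualifying junctions is conflicted and left unscaffolded on
#' that side. Gaps are estimated as `insert_mean` minus the observed
#' overhangs, floored at 1 so every join is visible in the sequence.
#'
#' @param contigs data frame from [unitigs()] or a character vector.
#' @param readset a `read_set` used for linking.
#' @param min_links minimum number of linking pairs (>= 1); the default 4
#'   encodes the "more than 3 read pairs" rule.
#' @param insert_mean fragment length used for gap estimates; defaults to the
#'   read set's.
#' @param k_anchor,band mapping parameters (see [map_reads()]).
#' @return data frame with `id`, `contigs` (comma list of `id:orientation`),
#'   `n_contigs`, `links` (comma list of supporting pair counts), `sequence`
#'   (gap-filled with `N`), `length`.
#' @export
scaffold_contigs <- function(contigs, readset, min_links = 4,
                             insert_mean = NULL, k_anchor = 31, band = 15) {
  if (min_links < 1) stop("min_links must be >= 1")
  if (is.character(contigs))
    contigs <- data.frame(id = sprintf("contig_%d", seq_along(contigs)),
                          sequence = as.character(contigs))
  n <- nrow(contigs)
  singleton <- function() {
    data.frame(id = sprintf("scaffold_%d", seq_len(n)),
               contigs = paste0(contigs$id, ":+"),
               n_contigs = 1L, links = "",
               sequence = contigs$sequence,
               length = nchar(contigs$sequence))
  }
  if (n < 2 || is.infinite(min_links)) return(singleton())
  if (is.null(insert_mean)) insert_mean <- readset$insert_mean
  npairs <- length(readset$r1)
  if (npairs == 0) return(singleton())
  rl <- readset$read_length
  m1 <- cpp_map_reads(readset$r1, contigs$sequence, k_anchor, band, FALSE)
  m2 <- cpp_map_reads(readset$r2, contigs$sequence, k_anchor, band, FALSE)
  link <- which(!is.na(m1$ref) & !is.na(m2$ref) & m1$ref != m2$ref)
  if (length(link) == 0) return(singleton())
  clen <- nchar(contigs$sequence)
  keys <- character(length(link)); gaps <- numeric(length(link))
  for (ii in seq_along(link)) {
    i <- link[ii]
    a <- m1$ref[i]; b <- m2$ref[i]
    ea <- mate_edge(m1$strand[i], m1$pos0[i], rl, clen[a], TRUE)
    eb <- mate_edge(m2$strand[i], m2$pos0[i], rl, clen[b], FALSE)
    gap <- insert_mean - ea$over - eb$over
    if (a < b) keys[ii] <- paste(a, ea$edge, b, eb$edge, sep = "|")
    else keys[ii] <- paste(b, eb$edge, a, ea$edge, sep = "|")
    gaps[ii] <- gap
  }
  tab <- tapply(gaps, keys, function(g) c(n = length(g), gap = mean(g)))
  junc <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  jdf <- data.frame(a = as.integer(junc[, 1]), ea = junc[, 2],
                    b = as.integer(junc[, 3]), eb = junc[, 4],
                    n = vapply(tab, `[[`, 0, "n"),
                    gap = vapply(tab, `[[`, 0, "gap"))
  jdf <- jdf[jdf$n >= min_links, , drop = FALSE]
  if (nrow(jdf) > 0) {
    # break ambiguous multi-way joins: an end in >= 2 qualifying junctions
    ends <- c(paste(jdf$a, jdf$ea), paste(jdf$b, jdf$eb))
    bad_ends <- names(which(table(ends) > 1))
    ok <- !(paste(jdf$a, jdf$ea) %in% bad_ends) &
      !(paste(jdf$b, jdf$eb) %in% bad_ends)
    jdf <- jdf[ok, , drop = FALSE]
  }
  # chain walk: each contig end participates in at most one junction now
  partner <- list() # "contig end" -> c(other contig, other end, gap, n)
  for (r in seq_len(nrow(jdf))) {
    partner[[paste(jdf$a[r], jdf$ea[r])]] <-
      list(ctg = jdf$b[r], end = jdf$eb[r], gap = jdf$gap[r], n = jdf$n[r])
    partner[[paste(jdf$b[r], jdf$eb[r])]] <-
      list(ctg = jdf$a[r], end = jdf$ea[r], gap = jdf$gap[r], n = jdf$n[r])
  }
  used <- rep(FALSE, n)
  out <- list()
  other_end <- function(e) if (e == "L") "R" else "L"
  for (start in seq_len(n)) {
    if (used[start]) next
    # find a free end to start from (handle cycles by starting anywhere)
    ori <- "+"; cur <- start
    ent <- "L" # entering end for '+' orientation
    if (!is.null(partner[[paste(start, "L")]]) &&
        is.null(partner[[paste(start, "R")]])) {
      ori <- "-"; ent <- "R"
    }
    chain <- list(list(ctg = cur, ori = ori))
    used[cur] <- TRUE
    gaps_chain <- numeric(0); links_chain <- numeric(0)
    repeat {
      exit_end <- other_end(ent)
      nx <- partner[[paste(cur, exit_end)]]
      if (is.null(nx) || used[nx$ctg]) break
      gaps_chain <- c(gaps_chain, nx$gap)
      links_chain <- c(links_chain, nx$n)
      cur <- nx$ctg
      ent <- nx$end
      used[cur] <- TRUE
      chain[[length(chain) + 1]] <-
        list(ctg = cur, ori = if (ent == "L") "+" else "-")
    }
    out[[length(out) + 1]] <-
      list(chain = chain, gaps = gaps_chain, links = links_chain)
  }
  rows <- lapply(seq_along(out), function(si) {
    ch <- out[[si]]$chain
    gaps_chain <- pmax(1, round(out[[si]]$gaps))
    seqs <- vapply(ch, function(e) {
      s <- contigs$sequence[e$ctg]
      if (e$ori == "-") revcomp(s) else s
    }, "")
    parts <- character(0)
    for (i in seq_along(seqs)) {
      parts <- c(parts, seqs[i])
      if (i < length(seqs)) parts <- c(parts, strrep("N", gaps_chain[i]))
    }
    seqstr <- paste(parts, collapse = "")
    data.frame(id = sprintf("scaffold_%d", si),
               contigs = paste(vapply(ch, function(e)
                 paste0(contigs$id[e$ctg], ":", e$ori), ""), collapse = ","),
               n_contigs = length(ch),
               links = paste(out[[si]]$links, collapse = ","),
               sequence = seqstr, length = nchar(seqstr))
  })
  do.call(rbind, rows)
}

#' Filter sequences by length
#'
#' The final-assembly rules: scaffolds are kept only if longer than 100 bp
#' (strictly greater), and joint-assembly contigs shorter than 200 bp are
#' excluded (keep `>= 200`, i.e. `strict = FALSE`).
#'
#' @param x character vector of sequences, or a data frame with a `sequence`
#'   column.
#' @param min_bp length threshold (>= 0).
#' @param strict if `TRUE` keep `length > min_bp`, else `length >= min_bp`.
#' @return the filtered object, input order preserved.
#' @export
filter_by_length <- function(x, min_bp, strict = TRUE) {
  stopifnot(min_bp >= 0)
  len <- if (is.data.frame(x)) nchar(x$sequence) else nchar(x)
  keep <- if (strict) len > min_bp else len >= min_bp
  if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
}

nxx_length <- function(lengths, frac) {
  ls <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(ls))
  ls[which(cs >= frac * cs[length(cs)])[1]]
}

#' Assembly summary statistics
#'
#' `NXX` is the length L such that sequences of length >= L together contain
#' at least XX% of the total assembly length (L is one of the sequence
#' lengths, taken in descending order).
#'
#' @param x character vector of sequences, a data frame with a `sequence`
#'   column, or a numeric vector of lengths.
#' @return an `assembly_stats` list: `n20`, `n50`, `n80`, `avg_length`,
#'   `max_length`, `total_number`, `total_length`.
#' @export
assembly_stats <- function(x) {
  lengths <- if (is.data.frame(x)) nchar(x$sequence)
  else if (is.character(x)) nchar(x) else as.numeric(x)
  if (length(lengths) == 0) stop("assembly_stats needs a non-empty input")
  structure(list(n20 = nxx_length(lengths, 0.2),
                 n50 = nxx_length(lengths, 0.5),
                 n80 = nxx_length(lengths, 0.8),
                 avg_length = mean(lengths),
                 max_length = max(lengths),
                 total_number = length(lengths),
                 total_length = sum(as.numeric(lengths))),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("N20 %d | N50 %d | N80 %d | avg %.1f | max %d | ",
                     "n %d | total %.0f bp\n"),
              x$n20, x$n50, x$n80, x$avg_length, x$max_length,
              x$total_number, x$total_length))
  invisible(x)
}

#' Write assembly statistics blocks as TSV
#'
#' One column per named block (e.g. contigs and scaffolds of each sample),
#' with the conventional row labels.
#'
#' @param blocks named list of `assembly_stats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats_tsv <- function(blocks, path) {
  rows <- c("N20 (bp)", "N50 (bp)", "N80 (bp)", "Av. length (bp)",
            "Max. length (bp)", "Total number", "Total (bp)")
  m <- vapply(blocks, function(s)
    c(s$n20, s$n50, s$n80, round(s$avg_length, 1), s$max_length,
      s$total_number, s$total_length), numeric(7))
  df <- data.frame(statistic = rows, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample assembly: graph, clean, unitigs, scaffold, length filter
#'
#' The per-sample workflow: count k-mers, clean by frequency spectrum,
#' extract contigs, scaffold with read pairs, and keep scaffolds longer than
#' `min_scaffold_bp`.
#'
#' @param readset a `read_set`.
#' @param k odd k-mer size.
#' @param min_count cleaning threshold; default
#'   [default_clean_threshold()] of the estimated coverage.
#' @param min_links scaffolding link threshold.
#' @param min_scaffold_bp strict scaffold length filter.
#' @return list with `contigs`, `scaffolds`, `stats` (list of two
#'   `assembly_stats`).
#' @export
assemble_sample <- function(readset, k = 31, min_count = NULL,
                            min_links = 4, min_scaffold_bp = 100) {
  g <- count_kmers(readset, k)
  if (is.null(min_count))
    min_count <- default_clean_threshold(estimate_kmer_coverage(g))
  g <- clean_graph(g, cleaning_policy(min_count))
  ctg <- unitigs(g)
  scf <- scaffold_contigs(ctg, readset, min_links = min_links)
  scf <- filter_by_length(scf, min_scaffold_bp, strict = TRUE)
  list(contigs = ctg, scaffolds = scf,
       stats = list(contigs = assembly_stats(ctg),
                    scaffolds = assembly_stats(scf)))
}

#' Joint assembly of several samples
#'
#' Counts k-mers per sample, merges colors, cleans the merged spectrum and
#' extracts contigs; contigs shorter than `min_contig_bp` are excluded.
#'
#' @param readsets named list of `read_set`.
#' @param k odd k-mer size.
#' @param min_count cleaning threshold on summed counts; default derived from
#'   the median k-mer count.
#' @param min_contig_bp exclusion threshold (keep `>= min_contig_bp`).
#' @return data frame of contigs as in [unitigs()].
#' @export
joint_assembly <- function(readsets, k = 31, min_count = NULL,
                           min_contig_bp = 200) {
  graphs <- lapply(names(readsets), function(id)
    count_kmers(readsets[[id]], k, sample_id = id))
  g <- merge_colors(graphs)
  if (is.null(min_count))
    min_count <- default_clean_threshold(estimate_kmer_coverage(g))
  g <- clean_graph(g, cleaning_policy(min_count))
  ctg <- unitigs(g)
  filter_by_length(ctg, min_contig_bp, strict = FALSE)
}
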