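# Reference-free variant discovery: bubble motifs in the colored de Bruijn
# graph, SNP/indel/complex classification, per-sample genotyping, and the
# two-k joint calling workflow.

#' Find bubbles in a colored k-mer graph
#'
#' A bubble is a fork k-mer whose two simple-path branches reconverge at the
#' same join k-mer: the graph signature of a variant between samples (or
#' between repeat copies). Branch strings are the bases contributed by the
#' interior path nodes, so an isolated SNP yields two branches of length
#' exactly `k` and a d-bp indel yields branches differing in length by d.
#' Branches longer than `max_branch_bp` are dropped.
#'
#' @param graph a cleaned, merged `kmer_graph`.
#' @param max_branch_bp branch length cap; default `2 * k + 50`.
#' @return a `bubble_set`: list with `bubbles` (data frame `flank5`,
#'   `flank3`, `branch_a`, `branch_b`; `branch_a` is the lexicographically
#'   smaller branch), `cov_a`/`cov_b` (per-sample mean branch k-mer coverage
#'   matrices), `k`, `sample_ids`. Deterministically ordered by `flank5`.
#' @export
find_bubbles <- function(graph, max_branch_bp = NULL) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (is.null(max_branch_bp)) max_branch_bp <- 2 * graph$k + 50
  res <- cpp_find_bubbles(graph$kmers, graph$counts, graph$k,
                          as.integer(max_branch_bp))
  bubbles <- data.frame(flank5 = res$flank5, flank3 = res$flank3,
                        branch_a = res$branch_a, branch_b = res$branch_b)
  cov_a <- res$cov_a; cov_b <- res$cov_b
  colnames(cov_a) <- colnames(cov_b) <- graph$sample_ids
  structure(list(bubbles = bubbles, cov_a = cov_a, cov_b = cov_b,
                 k = graph$k, sample_ids = graph$sample_ids),
            class = "bubble_set")
}

#' @export
print.bubble_set <- function(x, ...) {
  cat(sprintf("bubble_set: %d bubbles at k=%d over %d sample(s)\n",
              nrow(x$bubbles), x$k, length(x$sample_ids)))
  invisible(x)
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ca <- substring(a, 1:n, 1:n); cb <- substring(b, 1:n, 1:n)
  d <- which(ca != cb)
  if (length(d) == 0) n else d[1] - 1L
}

#' Classify a bubble's branch pair into variant calls
#'
#' Equal-length branches with a single mismatch are a SNP; a branch pair
#' whose difference is one clean gap is an insertion or deletion of that
#' length; anything else is a composite variant, decomposed by unit-cost
#' global alignment into `SNP_FROM_COMPLEX` and `INDEL_FROM_COMPLEX`
#' components (clusters of nearby SNPs, SNPs plus indels, etc.).
#'
#' @param branch_ref,branch_alt branch sequences; `branch_ref` is the
#'   reference-side branch (coordinates and `INS`/`DEL` polarity are relative
#'   to it).
#' @param anchor base immediately 5' of the branches (the last base of the
#'   5' flank), used as the indel anchor when a gap starts at branch
#'   position 0.
#' @return data frame with `offset0` (0-based position on `branch_ref`; -1
#'   when the indel anchor is the flank base), `type`, `ref`, `alt`.
#' @export
classify_bubble <- function(branch_ref, branch_alt, anchor = "N") {
  if (identical(branch_ref, branch_alt))
    stop("bubble branches are identical (invariant violation)")
  la <- nchar(branch_ref); lb <- nchar(branch_alt)
  if (la == lb) {
    ca <- substring(branch_ref, 1:la, 1:la)
    cb <- substring(branch_alt, 1:lb, 1:lb)
    d <- which(ca != cb)
    if (length(d) == 1)
      return(data.frame(offset0 = d - 1L, type = "SNP",
                        ref = ca[d], alt = cb[d]))
  } else {
    p <- longest_common_prefix(branch_ref, branch_alt)
    rr <- paste(rev(seq_chars(branch_ref)), collapse = "")
    ra <- paste(rev(seq_chars(branch_alt)), collapse = "")
    s <- longest_common_prefix(rr, ra)
    s <- min(s, min(la, lb) - p)
    if (p + s == min(la, lb)) {
      d <- abs(la - lb)
      anchor_base <- if (p > 0) substring(branch_ref, p, p) else anchor
      if (la > lb) { # alt branch lacks d bases: deletion
        deleted <- substring(branch_ref, p + 1, p + d)
        return(data.frame(offset0 = p - 1L, type = "DEL",
                          ref = paste0(anchor_base, deleted),
                          alt = anchor_base))
      } else {
        inserted <- substring(branch_alt, p + 1, p + d)
        return(data.frame(offset0 = p - 1L, type = "INS",
                          ref = anchor_base,
                          alt = paste0(anchor_base, inserted)))
      }
    }
  }
  # composite: decompose an optimal unit-cost alignment
  al <- cpp_global_align(branch_ref, branch_alt)
  A <- seq_chars(al[1]); B <- seq_chars(al[2])
  rows <- list()
  refpos <- 0L # ref bases consumed
  i <- 1L
  while (i <= length(A)) {
    if (A[i] != "-" && B[i] != "-") {
      if (A[i] != B[i])
        rows[[length(rows) + 1]] <-
          data.frame(offset0 = refpos, type = "SNP_FROM_COMPLEX",
                     ref = A[i], alt = B[i])
      refpos <- refpos + 1L
      i <- i + 1L
    } else if (B[i] == "-") { # deletion run
      j <- i
      while (j <= length(A) && B[j] == "-") j <- j + 1L
      deleted <- paste(A[i:(j - 1)], collapse = "")
      anchor_base <- if (refpos > 0) substring(branch_ref, refpos, refpos)
        else anchor
      rows[[length(rows) + 1]] <-
        data.frame(offset0 = refpos - 1L, type = "INDEL_FROM_COMPLEX",
                   ref = paste0(anchor_base, deleted), alt = anchor_base)
      refpos <- refpos + (j - i)
      i <- j
    } else { # insertion run
      j <- i
      while (j <= length(A) && A[j] == "-") j <- j + 1L
      inserted <- paste(B[i:(j - 1)], collapse = "")
      anchor_base <- if (refpos > 0) substring(branch_ref, refpos, refpos)
        else anchor
      rows[[length(rows) + 1]] <-
        data.frame(offset0 = refpos - 1L, type = "INDEL_FROM_COMPLEX",
                   ref = anchor_base, alt = paste0(anchor_base, inserted))
      i <- j
    }
  }
  do.call(rbind, rows)
}

#' Genotype bubbles per sample from branch coverage
#'
#' A sample supports a branch when its mean branch k-mer coverage reaches
#' `min_support`. Supporting only one branch gives `"a"`/`"b"`; both gives
#' `"both"` (expected for mycelium pools and within-nucleus repeat
#' variants); neither gives `"missing"` (amplification dropout).
#'
#' @param bset a `bubble_set`.
#' @param min_support minimum mean branch k-mer coverage.
#' @return character matrix (bubbles x samples).
#' @export
genotype_bubbles <- function(bset, min_support = 2) {
  sa <- bset$cov_a >= min_support
  sb <- bset$cov_b >= min_support
  gt <- matrix("missing", nrow = nrow(bset$bubbles),
               ncol = length(bset$sample_ids),
               dimnames = list(NULL, bset$sample_ids))
  gt[sa & !sb] <- "a"
  gt[!sa & sb] <- "b"
  gt[sa & sb] <- "both"
  gt
}

# The reverse-orientation representation of a bubble. The flipped branch is
# the reverse complement of full[1..m] (0-based) where full = flank5 +
# branch + last base of flank3; the flipped flanks swap and complement.
flip_bubble <- function(flank5, flank3, branch_a, branch_b) {
  k <- nchar(flank5)
  y <- substring(flank3, k, k)
  fa <- paste0(flank5, branch_a, y)
  fb <- paste0(flank5, branch_b, y)
  list(f5 = revcomp(flank3), f3 = revcomp(flank5),
       ba = revcomp(substring(fa, 2, 1 + nchar(branch_a))),
       bb = revcomp(substring(fb, 2, 1 + nchar(branch_b))))
}

# Locate a bubble on a reference: returns NULL (unliftable) or a list with
# ref_name, flank_start1 (1-based start of the 5' flank occurrence),
# ref_branch ("a"/"b"), strand.
lift_bubble <- function(flank5, flank3, branch_a, branch_b, reference, k) {
  hits <- list()
  fl <- flip_bubble(flank5, flank3, branch_a, branch_b)
  orients <- list(
    list(f5 = flank5, ba = branch_a, bb = branch_b, strand = 1L),
    list(f5 = fl$f5, ba = fl$ba, bb = fl$bb, strand = -1L))
  for (o in orients) {
    for (which_branch in c("a", "b")) {
      pat <- paste0(o$f5, if (which_branch == "a") o$ba else o$bb)
      for (rn in names(reference)) {
        m <- gregexpr(pat, reference[[rn]], fixed = TRUE)[[1]]
        if (m[1] == -1) next
        for (pos in as.integer(m))
          hits[[length(hits) + 1]] <-
            list(ref_name = rn, flank_start1 = pos, strand = o$strand,
                 ref_branch = which_branch,
                 f5 = o$f5, ba = o$ba, bb = o$bb)
      }
    }
  }
  if (length(hits) != 1) return(NULL)
  hits[[1]]
}

#' Joint reference-free variant calling at two k values
#'
#' Runs the full bubble-calling workflow per k (count, merge, clean, find
#' bubbles, classify, genotype), then takes the union of calls over the k
#' passes, deduplicated by position and alleles. With a reference the calls
#' are lifted by exact flank matching and reported in reference coordinates;
#' without one, coordinates are on a per-bubble pseudo-reference (5' flank +
#' branch a + 3' flank) and genotypes are relative to branch a.
#'
#' @param readsets named list of `read_set` (>= 2 samples; run the
#'   single-nucleus group and the mycelium group separately to compare them
#'   without a reference).
#' @param ks k values for the passes (default the low-k/high-k pair 31, 61).
#' @param reference optional named character vector of reference sequences.
#' @param min_support genotype support threshold (mean branch k-mer
#'   coverage).
#' @param min_count cleaning threshold per pass; default derived from the
#'   median summed k-mer count.
#' @param max_branch_bp branch cap per pass; default `2 * k + 50`.
#' @return data frame of calls: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `type`, `btype` (bubble classification), `k_discovered`, `lifted`, and
#'   one `gt_<sample>` column per sample with values
#'   `"ref"/"alt"/"both"/"missing"` (lifted calls) or
#'   `"a"/"b"/"both"/"missing"` (pseudo-reference calls). The
#'   pseudo-reference sequences are attached as `attr(, "pseudo_ref")`.
#' @export
joint_call <- function(readsets, ks = c(31, 61), reference = NULL,
                       min_support = 2, min_count = NULL,
                       max_branch_bp = NULL) {
  if (length(readsets) < 2)
    stop("joint calling needs at least two samples")
  sample_ids <- names(readsets)
  if (is.null(sample_ids))
    sample_ids <- vapply(readsets, `[[`, "", "sample_id")
  all_calls <- list()
  pseudo <- character(0)
  for (k in ks) {
    graphs <- lapply(seq_along(readsets), function(i)
      count_kmers(readsets[[i]], k, sample_id = sample_ids[i]))
    g <- merge_colors(graphs)
    mc <- min_count
    if (is.null(mc))
      mc <- default_clean_threshold(estimate_kmer_coverage(g))
    g <- clean_graph(g, cleaning_policy(mc))
    bset <- find_bubbles(g, max_branch_bp)
    nb <- nrow(bset$bubbles)
    if (nb == 0) next
    gt <- genotype_bubbles(bset, min_support)
    for (i in seq_len(nb)) {
      b <- bset$bubbles[i, ]
      lift <- if (!is.null(reference))
        lift_bubble(b$flank5, b$flank3, b$branch_a, b$branch_b,
                    reference, k) else NULL
      if (!is.null(lift)) {
        bref <- if (lift$ref_branch == "a") lift$ba else lift$bb
        balt <- if (lift$ref_branch == "a") lift$bb else lift$ba
        anchor <- substring(lift$f5, k, k)
        cls <- classify_bubble(bref, balt, anchor)
        gmap <- c(a = "ref", b = "alt", both = "both", missing = "missing")
        if (lift$ref_branch == "b")
          gmap <- c(a = "alt", b = "ref", both = "both", missing = "missing")
        gts <- gmap[gt[i, ]]
        chrom <- lift$ref_name
        pos <- lift$flank_start1 + k + cls$offset0
        lifted <- TRUE
      } else {
        cls <- classify_bubble(b$branch_a, b$branch_b,
                               substring(b$flank5, k, k))
        gts <- gt[i, ]
        chrom <- sprintf("bubble_k%d_%d", k, i)
        # the branch's trailing bases overlap the 3' flank by k-1, so the
        # contig appends only the join k-mer's final base
        pseudo[chrom] <- paste0(b$flank5, b$branch_a,
                                substring(b$flank3, k, k))
        pos <- k + 1L + cls$offset0
        lifted <- FALSE
      }
      btype <- if (nrow(cls) == 1 && cls$type[1] %in% c("SNP", "INS", "DEL"))
        cls$type[1] else "COMPLEX"
      gtdf <- as.data.frame(as.list(unname(gts)))
      names(gtdf) <- paste0("gt_", sample_ids)
      rows <- cbind(data.frame(chrom = chrom, pos = pos, ref = cls$ref,
                               alt = cls$alt, type = cls$type,
                               btype = btype, k_discovered = as.character(k),
                               lifted = lifted),
                    gtdf[rep(1, nrow(cls)), , drop = FALSE])
      all_calls[[length(all_calls) + 1]] <- rows
    }
  }
  if (length(all_calls) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character(), btype = character(),
                      k_discovered = character(), lifted = logical())
    for (s in sample_ids) out[[paste0("gt_", s)]] <- character()
    attr(out, "pseudo_ref") <- pseudo
    return(out)
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  key <- ifelse(calls$lifted,
                paste("L", calls$chrom, calls$pos, calls$ref, calls$alt),
                paste("U", calls$chrom, calls$pos, calls$ref, calls$alt))
  dup_of <- match(key, key)
  first <- dup_of == seq_along(key)
  for (i in which(!first)) {
    j <- dup_of[i]
    if (calls$k_discovered[j] != calls$k_discovered[i])
      calls$k_discovered[j] <- "both"
  }
  calls <- calls[first, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "pseudo_ref") <- pseudo
  calls
}

#' Write variant calls as VCF 4.2
#'
#' One record per call; `KDISC` and `BTYPE` INFO fields carry the k pass(es)
#' that discovered the call and the bubble classification; per-sample `GT`
#' columns encode ref/alt/both/missing as `0`, `1`, `0/1`, `.`.
#'
#' @param calls data frame from [joint_call()].
#' @param path output VCF path.
#' @param contigs optional named lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, contigs = NULL) {
  gtcols <- grep("^gt_", names(calls), value = TRUE)
  samples <- sub("^gt_", "", gtcols)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=coenokaryo",
           "##INFO=<ID=KDISC,Number=1,Type=String,Description=\"k pass(es) that discovered the call\">",
           "##INFO=<ID=BTYPE,Number=1,Type=String,Description=\"Bubble classification\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  enc <- c(ref = "0", a = "0", alt = "1", b = "1", both = "0/1",
           missing = ".")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    gts <- enc[unlist(calls[i, gtcols])]
    paste(c(calls$chrom[i], calls$pos[i], ".", calls$ref[i], calls$alt[i],
            ".", "PASS",
            sprintf("KDISC=%s;BTYPE=%s", calls$k_discovered[i],
                    calls$btype[i]),
            "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
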