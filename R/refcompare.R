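# Reference-based comparison: seed-and-extend read mapping, per-sample
# SNP/indel counting from pileups, the aligned-identity statistic, per-window
# variant density tracks, and the self-alignment redundancy check.

#' Map reads to a reference by seed-and-extend
#'
#' Exact k-mer seeds propose candidate placements; each candidate is scored
#' by banded unit-cost edit distance (semi-global: the read must align end to
#' end). A read gets at most one placement — the best score; equally good
#' distinct placements (exact repeats) leave the read unmapped, trading
#' sensitivity in repeats for determinism.
#'
#' @param readset a `read_set` or character vector of reads.
#' @param reference named character vector of reference sequences.
#' @param k_anchor seed length.
#' @param band edit-distance band; alignments with more than `band` edits are
#'   rejected.
#' @return data frame with `read`, `ref` (name or `NA`), `pos0`, `strand`
#'   (+1/-1), `edits`, `mapped`.
#' @export
map_reads <- function(readset, reference, k_anchor = 31, band = 15) {
  if (length(reference) == 0 || all(!nzchar(reference)))
    stop("empty reference")
  reads <- if (inherits(readset, "read_set")) all_reads(readset)
    else as.character(readset)
  res <- cpp_map_reads(reads, unname(reference), k_anchor, band, FALSE)
  data.frame(read = seq_along(reads),
             ref = names(reference)[res$ref],
             pos0 = res$pos0, strand = res$strand, edits = res$edits,
             mapped = !is.na(res$ref))
}

#' Pileup of a read set on a reference
#'
#' Maps all reads (both mates) and accumulates per-position base counts,
#' deletion marks and insertion openings/lengths.
#'
#' @inheritParams map_reads
#' @return a `sample_pileup`: list with `sample_id`, `pileups` (named list,
#'   one `L x 8` integer matrix per reference sequence; columns `A`, `C`,
#'   `G`, `T`, `N`, `del`, `ins_n`, `ins_bp`), `aligned_bases`, `avg_depth`
#'   (aligned bases / total reference length), `n_reads`, `n_mapped`.
#' @export
pileup_reads <- function(readset, reference, k_anchor = 31, band = 15) {
  if (length(reference) == 0 || all(!nzchar(reference)))
    stop("empty reference")
  reads <- if (inherits(readset, "read_set")) all_reads(readset)
    else as.character(readset)
  sid <- if (inherits(readset, "read_set")) readset$sample_id else "S1"
  res <- cpp_map_reads(reads, unname(reference), k_anchor, band, TRUE)
  piles <- res$pileup
  names(piles) <- names(reference)
  for (i in seq_along(piles))
    colnames(piles[[i]]) <- c("A", "C", "G", "T", "N", "del", "ins_n",
                              "ins_bp")
  structure(list(sample_id = sid, pileups = piles,
                 aligned_bases = res$aligned_bases,
                 avg_depth = res$aligned_bases / sum(nchar(reference)),
                 n_reads = length(reads),
                 n_mapped = sum(!is.na(res$ref))),
            class = "sample_pileup")
}

# Call sites for one sample on one reference sequence.
call_sites_one <- function(P, refseq, min_depth, min_alt_fraction) {
  L <- nrow(P)
  depth <- rowSums(P[, 1:6, drop = FALSE])
  callable <- depth >= min_depth
  refch <- seq_chars(refseq)
  ref_idx <- match(refch, c("A", "C", "G", "T"))
  base <- P[, 1:4, drop = FALSE]
  ok <- !is.na(ref_idx)
  ref_count <- rep(0L, L)
  ref_count[ok] <- base[cbind(which(ok), ref_idx[ok])]
  masked <- base
  masked[cbind(which(ok), ref_idx[ok])] <- -1L
  alt_count <- apply(masked, 1, max)
  alt_idx <- apply(masked, 1, which.max)
  snp <- callable & alt_count > 0 & (alt_count / depth) >= min_alt_fraction
  sites <- list()
  if (any(snp)) {
    w <- which(snp)
    sites$snp <- data.frame(pos0 = w - 1L, type = "SNP",
                            ref = refch[w],
                            alt = c("A", "C", "G", "T")[alt_idx[w]],
                            len = 1L)
  }
  delfrac <- ifelse(depth > 0, P[, "del"] / depth, 0)
  delcall <- callable & delfrac >= min_alt_fraction & P[, "del"] > 0
  if (any(delcall)) {
    r <- rle(delcall)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    sites$del <- data.frame(pos0 = starts[w] - 2L, type = "DEL",
                            ref = substring(refseq, starts[w] - 1L, ends[w]),
                            alt = substring(refseq, starts[w] - 1L,
                                            starts[w] - 1L),
                            len = r$lengths[w])
  }
  insfrac <- ifelse(depth > 0, P[, "ins_n"] / depth, 0)
  inscall <- callable & insfrac >= min_alt_fraction & P[, "ins_n"] > 0
  if (any(inscall)) {
    w <- which(inscall)
    ilen <- as.integer(round(P[w, "ins_bp"] / P[w, "ins_n"]))
    sites$ins <- data.frame(pos0 = w - 2L, type = "INS",
                            ref = substring(refseq, w - 1L, w - 1L),
                            alt = NA_character_, len = ilen)
  }
  list(sites = if (length(sites)) do.call(rbind, sites)
       else data.frame(pos0 = integer(), type = character(),
                       ref = character(), alt = character(),
                       len = integer()),
       callable = callable)
}

#' Count SNPs and indels per sample against a reference
#'
#' A site is called a SNP for a sample when its depth reaches `min_depth` and
#' the top non-reference base reaches `min_alt_fraction` of the depth.
#' Deletion runs and insertion openings are counted once per event; event
#' lengths are summed into `indel_bp`. Positions below `min_depth` are
#' no-calls, not reference matches.
#'
#' @param pileups named list of `sample_pileup` objects on the same
#'   reference.
#' @param reference named character vector of reference sequences.
#' @param min_depth minimum depth for a callable position.
#' @param min_alt_fraction minimum alternate-allele fraction (use ~0.8 for
#'   haploid single-nucleus samples, ~0.2 for pooled mycelium samples).
#' @return a `variant_counts`: list with `counts` (data frame `sample`,
#'   `snps`, `indels`, `indel_bp`), `sites` (per-sample site table with
#'   `sample`, `ref_id`, `pos0`, `type`, `ref`, `alt`, `len`), `callable`
#'   (per reference: logical positions x samples matrix), `reference`
#'   lengths.
#' @export
count_variants <- function(pileups, reference, min_depth = 5,
                           min_alt_fraction = 0.8) {
  samples <- names(pileups)
  if (length(min_alt_fraction) == 1)
    min_alt_fraction <- setNames(rep(min_alt_fraction, length(samples)),
                                 samples)
  sites <- list()
  callable <- lapply(reference, function(r)
    matrix(FALSE, nrow = nchar(r), ncol = length(samples),
           dimnames = list(NULL, samples)))
  counts <- data.frame(sample = samples, snps = 0L, indels = 0L,
                       indel_bp = 0L)
  for (s in samples) {
    for (rn in names(reference)) {
      res <- call_sites_one(pileups[[s]]$pileups[[rn]], reference[[rn]],
                            min_depth, min_alt_fraction[[s]])
      callable[[rn]][, s] <- res$callable
      if (nrow(res$sites)) {
        res$sites$sample <- s
        res$sites$ref_id <- rn
        sites[[length(sites) + 1]] <- res$sites
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites)
    else data.frame(pos0 = integer(), type = character(), ref = character(),
                    alt = character(), len = integer(), sample = character(),
                    ref_id = character())
  rownames(sites) <- NULL
  for (i in seq_along(samples)) {
    ss <- sites[sites$sample == samples[i], , drop = FALSE]
    counts$snps[i] <- sum(ss$type == "SNP")
    counts$indels[i] <- sum(ss$type != "SNP")
    counts$indel_bp[i] <- sum(ss$len[ss$type != "SNP"])
  }
  structure(list(counts = counts, sites = sites, callable = callable,
                 reference_lengths = nchar(reference)),
            class = "variant_counts")
}

site_key <- function(sites) {
  ifelse(sites$type == "SNP",
         paste(sites$ref_id, sites$pos0, "SNP", sites$alt),
         paste(sites$ref_id, sites$pos0, sites$type, sites$len))
}

#' Aligned-identity statistic between samples
#'
#' `identity = 1 - (snp_sites + indel_bp) / aligned_bp`, where `aligned_bp`
#' counts reference positions callable in all compared samples, computed for
#' every sample pair and jointly across the whole set. Because whether the
#' headline fraction counts indel events or affected bases is a modelling
#' choice, both variants are reported (`identity` uses bases,
#' `identity_events` uses events).
#'
#' @param vc a `variant_counts` from [count_variants()].
#' @param samples samples to compare (default: all).
#' @return an `identity_stat`: list with `pairwise` (data frame per pair) and
#'   `joint` (aligned bp, union variant sites, identities).
#' @export
identity_statistic <- function(vc, samples = NULL) {
  stopifnot(inherits(vc, "variant_counts"))
  if (is.null(samples)) samples <- vc$counts$sample
  if (length(samples) < 2) stop("need at least two samples")
  # restrict helper: sites of sample s at positions callable in all `grp`
  callable_all <- function(grp) {
    lapply(vc$callable, function(m)
      rowSums(m[, grp, drop = FALSE]) == length(grp))
  }
  sites_in <- function(s, mask) {
    ss <- vc$sites[vc$sites$sample == s, , drop = FALSE]
    if (nrow(ss) == 0) return(ss)
    keep <- vapply(seq_len(nrow(ss)), function(i) {
      m <- mask[[ss$ref_id[i]]]
      p <- ss$pos0[i] + 1L
      p >= 1 && p <= length(m) && m[p]
    }, TRUE)
    ss[keep, , drop = FALSE]
  }
  pairs <- utils::combn(samples, 2)
  prow <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]; j <- pairs[2, ci]
    mask <- callable_all(c(i, j))
    aligned <- sum(vapply(mask, sum, 0))
    if (aligned == 0) stop("no positions callable in both samples")
    si <- sites_in(i, mask); sj <- sites_in(j, mask)
    ki <- site_key(si); kj <- site_key(sj)
    diff_i <- si[!(ki %in% kj), , drop = FALSE]
    diff_j <- sj[!(kj %in% ki), , drop = FALSE]
    d <- rbind(diff_i, diff_j)
    snp_sites <- length(unique(paste(d$ref_id, d$pos0)[d$type == "SNP"]))
    ind <- d[d$type != "SNP", , drop = FALSE]
    indel_events <- nrow(unique(ind[, c("ref_id", "pos0", "type", "len")]))
    indel_bp <- sum(unique(ind[, c("ref_id", "pos0", "type",
                                   "len")])$len)
    data.frame(sample_i = i, sample_j = j, aligned_bp = aligned,
               snp_sites = snp_sites, indel_events = indel_events,
               indel_bp = indel_bp,
               identity = 1 - (snp_sites + indel_bp) / aligned,
               identity_events = 1 - (snp_sites + indel_events) / aligned)
  })
  mask <- callable_all(samples)
  aligned <- sum(vapply(mask, sum, 0))
  if (aligned == 0) stop("no positions callable in all samples")
  allsites <- do.call(rbind, lapply(samples, sites_in, mask = mask))
  snp_sites <- length(unique(paste(allsites$ref_id,
                                   allsites$pos0)[allsites$type == "SNP"]))
  ind <- allsites[allsites$type != "SNP", , drop = FALSE]
  uind <- unique(ind[, c("ref_id", "pos0", "type", "len")])
  structure(list(pairwise = do.call(rbind, prow),
                 joint = list(aligned_bp = aligned, snp_sites = snp_sites,
                              indel_events = nrow(uind),
                              indel_bp = sum(uind$len),
                              identity = 1 - (snp_sites + sum(uind$len)) /
                                aligned,
                              identity_events = 1 - (snp_sites +
                                                       nrow(uind)) /
                                aligned)),
            class = "identity_stat")
}

#' Per-window SNP and indel density track
#'
#' Tiles each reference sequence with half-open windows and counts called
#' sites per window per sample — the per-contig variant track.
#'
#' @param sites site table from [count_variants()] (`$sites`).
#' @param ref_lengths named reference lengths.
#' @param window_bp window size (>= 1).
#' @return data frame with `ref_id`, `start0`, `end0`, `sample`, `snp`,
#'   `indel`.
#' @export
variant_density_track <- function(sites, ref_lengths, window_bp = 10000) {
  stopifnot(window_bp >= 1)
  samples <- unique(sites$sample)
  if (length(samples) == 0) samples <- character(0)
  rows <- list()
  for (rn in names(ref_lengths)) {
    L <- ref_lengths[[rn]]
    starts <- seq.int(0L, max(0L, L - 1L), by = window_bp)
    ends <- pmin(starts + window_bp, L)
    for (s in samples) {
      ss <- sites[sites$sample == s & sites$ref_id == rn, , drop = FALSE]
      w <- findInterval(ss$pos0, starts)
      snp <- tabulate(w[ss$type == "SNP"], length(starts))
      ind <- tabulate(w[ss$type != "SNP"], length(starts))
      rows[[length(rows) + 1]] <-
        data.frame(ref_id = rn, start0 = starts, end0 = ends, sample = s,
                   snp = snp, indel = ind)
    }
  }
  if (length(rows) == 0)
    return(data.frame(ref_id = character(), start0 = integer(),
                      end0 = integer(), sample = character(),
                      snp = integer(), indel = integer()))
  do.call(rbind, rows)
}

#' Write a density track as BED (0-based half-open)
#'
#' @param track data frame from [variant_density_track()].
#' @param path output path; name column is `sample|snp|indel`.
#' @return `path`, invisibly.
#' @export
write_density_bed <- function(track, path) {
  bed <- data.frame(track$ref_id, track$start0, track$end0,
                    sprintf("%s|SNP=%d|INDEL=%d", track$sample, track$snp,
                            track$indel))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Mask of reference positions matching a repeat unit
#'
#' Marks every reference position covered by an exact k-mer shared with the
#' repeat unit (either strand). Used to exclude the collapsed repeat locus
#' from genome-wide variant counting and the identity statistic: variation
#' among repeat copies is within-nucleus variation and is quantified
#' separately on the unit.
#'
#' @param reference named character vector of reference sequences.
#' @param unit repeat-unit sequence.
#' @param k seed length.
#' @return named list of logical vectors (one per reference sequence).
#' @export
unit_region_mask <- function(reference, unit, k = 21) {
  unit <- unname(unit)
  lapply(reference, function(s) {
    m <- rep(FALSE, nchar(s))
    sm <- cpp_seed_matches(s, unit, k)
    if (length(sm$pos_a)) {
      pos <- unique(sm$pos_a)
      idx <- unique(unlist(Map(seq.int, pos + 1L, pmin(pos + k, nchar(s)))))
      m[idx] <- TRUE
    }
    m
  })
}

#' Remove masked reference positions from a variant-count object
#'
#' Drops called sites inside the mask, marks masked positions uncallable,
#' and recomputes the per-sample totals.
#'
#' @param vc a `variant_counts`.
#' @param mask named list of logical vectors as from [unit_region_mask()].
#' @return the filtered `variant_counts`.
#' @export
apply_reference_mask <- function(vc, mask) {
  stopifnot(inherits(vc, "variant_counts"))
  s <- vc$sites
  if (nrow(s)) {
    drop <- vapply(seq_len(nrow(s)), function(i) {
      m <- mask[[s$ref_id[i]]]
      p <- s$pos0[i] + 1L
      !is.null(m) && p >= 1 && p <= length(m) && m[p]
    }, TRUE)
    vc$sites <- s[!drop, , drop = FALSE]
  }
  for (rn in names(vc$callable))
    if (!is.null(mask[[rn]])) vc$callable[[rn]][mask[[rn]], ] <- FALSE
  for (i in seq_len(nrow(vc$counts))) {
    ss <- vc$sites[vc$sites$sample == vc$counts$sample[i], , drop = FALSE]
    vc$counts$snps[i] <- sum(ss$type == "SNP")
    vc$counts$indels[i] <- sum(ss$type != "SNP")
    vc$counts$indel_bp[i] <- sum(ss$len[ss$type != "SNP"])
  }
  vc
}

# Merge possibly-overlapping [start, end) intervals; returns total covered bp.
covered_bp <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs)
}

#' Flag potentially redundant scaffolds by self-alignment
#'
#' For each scaffold, exact-seed matches against every other scaffold are
#' chained by diagonal, each chained region is scored by banded edit
#' distance, and regions reaching `min_identity` are accumulated. A scaffold
#' is flagged as a potential artificial duplication when more than
#' `min_alignable` of its length is alignable elsewhere at that identity.
#'
#' @param scaffolds named character vector of sequences (>= 2), or a data
#'   frame with `id` and `sequence`.
#' @param seed_k exact seed length (small enough to seed 95%-identity
#'   alignments).
#' @param min_identity identity floor for a chained region to count.
#' @param min_alignable alignable-fraction threshold (strictly greater
#'   than).
#' @param chain_gap maximum diagonal scatter within one chain.
#' @return data frame with `scaffold_id`, `length`, `alignable_fraction`,
#'   `max_identity`, `flagged`; summary totals as attributes `flagged_bp`
#'   and `flagged_fraction`.
#' @export
self_alignment_redundancy <- function(scaffolds, seed_k = 17,
                                      min_identity = 0.95,
                                      min_alignable = 0.70,
                                      chain_gap = 30) {
  if (is.data.frame(scaffolds))
    scaffolds <- setNames(scaffolds$sequence, scaffolds$id)
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  n <- length(scaffolds)
  if (n < 2) stop("self-alignment needs at least two scaffolds")
  lens <- nchar(scaffolds)
  out <- data.frame(scaffold_id = names(scaffolds), length = lens,
                    alignable_fraction = 0, max_identity = NA_real_,
                    flagged = FALSE, row.names = NULL)
  for (i in seq_len(n)) {
    ivs <- NULL
    maxid <- NA_real_
    for (j in seq_len(n)) {
      if (i == j) next
      sm <- cpp_seed_matches(scaffolds[[i]], scaffolds[[j]], seed_k)
      if (length(sm$pos_a) == 0) next
      diag <- ifelse(sm$strand > 0, sm$pos_a - sm$pos_b,
                     sm$pos_a + sm$pos_b)
      grp <- paste(sm$strand, round(diag / chain_gap))
      for (g in unique(grp)) {
        idx <- grp == g
        a0 <- min(sm$pos_a[idx]); a1 <- max(sm$pos_a[idx]) + seed_k
        b0 <- min(sm$pos_b[idx]); b1 <- max(sm$pos_b[idx]) + seed_k
        sub_a <- substring(scaffolds[[i]], a0 + 1, a1)
        sub_b <- substring(scaffolds[[j]], b0 + 1, b1)
        if (sm$strand[idx][1] < 0) sub_b <- revcomp(sub_b)
        alen <- max(nchar(sub_a), nchar(sub_b))
        band <- max(16L, as.integer(ceiling(0.25 * alen)))
        d <- cpp_banded_edit(sub_a, sub_b, band)
        if (d < 0) next
        idf <- 1 - d / alen
        maxid <- max(maxid, idf, na.rm = TRUE)
        if (idf >= min_identity)
          ivs <- rbind(ivs, c(a0, a1))
      }
    }
    if (!is.null(ivs))
      out$alignable_fraction[i] <- covered_bp(ivs[, 1], ivs[, 2]) / lens[i]
    out$max_identity[i] <- maxid
    out$flagged[i] <- out$alignable_fraction[i] > min_alignable
  }
  attr(out, "flagged_bp") <- sum(out$length[out$flagged])
  attr(out, "flagged_fraction") <- sum(out$length[out$flagged]) /
    sum(out$length)
  out
}
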