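# Within-sample polymorphism across a multi-copy repeat unit: all copies of
# the tandem array collapse onto one unit reference, and per-site
# reference-genotype (G1) vs polymorphic-genotype (G2) read support is
# tallied per sample against the sample's average depth over the unit.

#' Pileup of a sample's reads on a repeat-unit reference
#'
#' Reads are recruited by exact seed match to the unit (reads from outside
#' the repeat locus carry no unit seed and are not recruited); all repeat
#' copies collapse onto unit coordinates. Average depth is total aligned
#' bases divided by unit length — the dashed per-sample depth line of the
#' per-site support histograms.
#'
#' @param readset a `read_set`.
#' @param unit_reference single-sequence named character vector (or plain
#'   string) of the repeat unit.
#' @param k_anchor seed length (shorter than the mapping default so reads
#'   spanning several variant copies still seed).
#' @param band edit band.
#' @param clip_den read-end soft-clip cost denominator (one edit per
#'   `clip_den` clipped bases). Locus-boundary reads trail into the flank;
#'   clipping lets their array-derived part contribute to the pileup while
#'   the flank tail is discarded, so the first and last copies of the array
#'   are not undersampled.
#' @return a `sample_pileup` restricted to the unit; warns when no read is
#'   recruited.
#' @export
pileup_on_unit <- function(readset, unit_reference, k_anchor = 21,
                           band = 15, clip_den = 4) {
  if (length(unit_reference) != 1)
    stop("unit_reference must be a single sequence")
  nm <- names(unit_reference)
  if (is.null(nm)) nm <- "unit"
  unit <- unname(unit_reference)
  L <- nchar(unit)
  reads <- all_reads(readset)
  # the array is tandem, so the unit is treated as circular: reads are
  # placed on a doubled unit and placements folded modulo the unit length
  res <- cpp_map_reads(reads, strrep(unit, 2L), k_anchor, band, TRUE, L,
                       clip_den)
  P <- res$pileup[[1]]
  colnames(P) <- c("A", "C", "G", "T", "N", "del", "ins_n", "ins_bp")
  piles <- setNames(list(P), nm)
  pu <- structure(list(sample_id = readset$sample_id, pileups = piles,
                       aligned_bases = res$aligned_bases,
                       avg_depth = res$aligned_bases / L,
                       n_reads = length(reads),
                       n_mapped = sum(!is.na(res$ref))),
                  class = "sample_pileup")
  if (pu$n_mapped == 0)
    warning("no reads recruited to the repeat unit for sample ",
            pu$sample_id)
  pu
}

#' Per-site G1/G2 read-support table over the repeat unit
#'
#' For every unit position, G1 is the reference base and G2 the most
#' frequent non-reference base pooled over all samples. A site is
#' intra-sample polymorphic for a sample when both genotypes are supported
#' by at least `min_minor_reads` reads and the minor genotype reaches
#' `min_minor_fraction` of the G1+G2 support. Sites polymorphic in at least
#' one sample are reported, ordered by position (1-based, matching the
#' convention of positions on a repeat-unit reference).
#'
#' @param pileups named list of `sample_pileup` objects from
#'   [pileup_on_unit()].
#' @param unit_sequence the unit reference string.
#' @param min_minor_reads minimum reads supporting the minor genotype.
#' @param min_minor_fraction minimum minor-genotype fraction of G1+G2.
#' @return data frame with `position` (1-based), `g1`, `g2`, and per sample
#'   `g1_<s>`, `g2_<s>`, `other_<s>`, `depth_<s>`, `polymorphic_<s>`;
#'   per-sample average unit depth attached as `attr(, "avg_depth")`.
#' @export
repeat_site_table <- function(pileups, unit_sequence, min_minor_reads = 3,
                              min_minor_fraction = 0.05) {
  if (length(unit_sequence) == 1 && !is.null(names(unit_sequence)))
    unit_sequence <- unname(unit_sequence)
  samples <- names(pileups)
  L <- nchar(unit_sequence)
  refch <- seq_chars(unit_sequence)
  ref_idx <- match(refch, c("A", "C", "G", "T"))
  mats <- lapply(pileups, function(p) p$pileups[[1]][, 1:4, drop = FALSE])
  pooled <- Reduce(`+`, mats)
  masked <- pooled
  ok <- !is.na(ref_idx)
  masked[cbind(which(ok), ref_idx[ok])] <- -1L
  g2_idx <- apply(masked, 1, which.max)
  g2_count <- apply(masked, 1, max)
  g2 <- c("A", "C", "G", "T")[g2_idx]
  rows <- data.frame(position = seq_len(L), g1 = refch, g2 = g2)
  poly_any <- rep(FALSE, L)
  for (s in samples) {
    m <- mats[[s]]
    g1c <- ifelse(ok, m[cbind(seq_len(L), ref_idx)], 0L)
    g2c <- m[cbind(seq_len(L), g2_idx)]
    tot <- rowSums(m)
    other <- tot - g1c - g2c
    minor <- pmin(g1c, g2c)
    frac_den <- g1c + g2c
    poly <- minor >= min_minor_reads &
      ifelse(frac_den > 0, minor / frac_den, 0) >= min_minor_fraction
    rows[[paste0("g1_", s)]] <- g1c
    rows[[paste0("g2_", s)]] <- g2c
    rows[[paste0("other_", s)]] <- other
    rows[[paste0("depth_", s)]] <- tot
    rows[[paste0("polymorphic_", s)]] <- poly
    poly_any <- poly_any | poly
  }
  out <- rows[poly_any & g2_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "avg_depth") <-
    vapply(pileups, `[[`, 0, "avg_depth")
  attr(out, "samples") <- samples
  out
}

#' Summarise repeat-unit heterogeneity per sample and between samples
#'
#' Per sample: number of intra-sample polymorphic sites and the mean minor
#' (G2 or G1, whichever is rarer) fraction over those sites. Between
#' samples: mean absolute difference of per-site G2 fractions over sites
#' with depth at least `min_depth` in both samples — different samples can
#' show quantitative variation in the same polymorphic repeat variants.
#'
#' @param site_tab table from [repeat_site_table()].
#' @param min_depth per-sample depth required for a site to enter the
#'   pairwise dissimilarity.
#' @return list with `per_sample` (data frame `sample`,
#'   `polymorphic_sites`, `mean_minor_fraction`, `avg_depth`) and `pairwise`
#'   (data frame `sample_i`, `sample_j`, `dissimilarity`, `n_sites`).
#' @export
heterogeneity_summary <- function(site_tab, min_depth = 10) {
  samples <- attr(site_tab, "samples")
  avg_depth <- attr(site_tab, "avg_depth")
  if (is.null(samples))
    samples <- sub("^g2_", "", grep("^g2_", names(site_tab), value = TRUE))
  n <- nrow(site_tab)
  per_sample <- data.frame(sample = samples, polymorphic_sites = 0L,
                           mean_minor_fraction = 0,
                           avg_depth = if (is.null(avg_depth)) NA_real_
                           else unname(avg_depth[samples]))
  g2frac <- matrix(NA_real_, nrow = n, ncol = length(samples),
                   dimnames = list(NULL, samples))
  depth_ok <- matrix(FALSE, nrow = n, ncol = length(samples),
                     dimnames = list(NULL, samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    if (n > 0) {
      g1c <- site_tab[[paste0("g1_", s)]]
      g2c <- site_tab[[paste0("g2_", s)]]
      den <- g1c + g2c
      poly <- site_tab[[paste0("polymorphic_", s)]]
      per_sample$polymorphic_sites[si] <- sum(poly)
      minor_frac <- ifelse(den > 0, pmin(g1c, g2c) / den, 0)
      per_sample$mean_minor_fraction[si] <-
        if (any(poly)) mean(minor_frac[poly]) else 0
      g2frac[, si] <- ifelse(den > 0, g2c / den, NA_real_)
      depth_ok[, si] <- site_tab[[paste0("depth_", s)]] >= min_depth
    }
  }
  pairs <- if (length(samples) >= 2) utils::combn(samples, 2) else
    matrix(character(0), nrow = 2)
  prow <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]; j <- pairs[2, ci]
    use <- depth_ok[, i] & depth_ok[, j] &
      !is.na(g2frac[, i]) & !is.na(g2frac[, j])
    data.frame(sample_i = i, sample_j = j,
               dissimilarity = if (any(use))
                 mean(abs(g2frac[use, i] - g2frac[use, j])) else 0,
               n_sites = sum(use))
  })
  list(per_sample = per_sample,
       pairwise = if (length(prow)) do.call(rbind, prow)
       else data.frame(sample_i = character(), sample_j = character(),
                       dissimilarity = numeric(), n_sites = integer()))
}

#' Write the repeat-unit polymorphism table as TSV
#'
#' Layout: position, G1, G2, then per-sample G1/G2/depth columns, with the
#' per-sample average depths in a header comment line.
#'
#' @param site_tab table from [repeat_site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_sites_tsv <- function(site_tab, path) {
  avg <- attr(site_tab, "avg_depth")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(avg))
    writeLines(paste0("# avg_depth: ",
                      paste(sprintf("%s=%.1f", names(avg), avg),
                            collapse = " ")), con)
  write.table(site_tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
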