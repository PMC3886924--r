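# Synthetic coenocyte generator: founder genome with a tandem repeat array,
# derived haploid nuclei at low divergence, MDA-style amplification bias, and
# paired-end read simulation with retained ground truth.

#' Describe a tandem repeat array
#'
#' Models a multi-copy repeat unit (a 45S rDNA-like locus) whose copies may
#' carry alternative bases at given unit positions in a fraction of copies.
#'
#' @param unit_sequence DNA string of the repeat unit.
#' @param copy_number number of tandem copies (>= 1).
#' @param variant_sites data frame with columns `unit_pos0` (0-based position
#'   on the unit), `alt` (alternative base) and `copy_fraction` (fraction of
#'   copies carrying `alt`, in (0, 1]); may be `NULL` for a variant-free array.
#' @return a `repeat_array` object.
#' @export
repeat_array <- function(unit_sequence, copy_number,
                         variant_sites = NULL) {
  stopifnot(is.character(unit_sequence), length(unit_sequence) == 1,
            copy_number >= 1)
  unit_len <- nchar(unit_sequence)
  if (is.null(variant_sites)) {
    variant_sites <- data.frame(unit_pos0 = integer(), alt = character(),
                                copy_fraction = numeric())
  }
  stopifnot(all(c("unit_pos0", "alt", "copy_fraction") %in%
                  names(variant_sites)))
  if (nrow(variant_sites)) {
    stopifnot(all(variant_sites$unit_pos0 >= 0),
              all(variant_sites$unit_pos0 < unit_len),
              all(variant_sites$copy_fraction > 0),
              all(variant_sites$copy_fraction <= 1))
    refb <- substring(unit_sequence, variant_sites$unit_pos0 + 1,
                      variant_sites$unit_pos0 + 1)
    if (any(refb == variant_sites$alt))
      stop("variant_sites alt base equals the unit reference base")
    if (any(round(variant_sites$copy_fraction * copy_number) < 1))
      stop("copy_fraction too small: no copy would carry the variant")
  }
  structure(list(unit_sequence = unit_sequence,
                 copy_number = as.integer(copy_number),
                 variant_sites = variant_sites),
            class = "repeat_array")
}

#' Generate a random repeat array
#'
#' Convenience constructor: a random unit plus variant sites at seeded random
#' unit positions, one per requested copy fraction.
#'
#' @param unit_bp unit length in bp.
#' @param copy_number number of tandem copies.
#' @param copy_fractions numeric vector; one variant site is created per
#'   entry, carried by `round(copy_fraction * copy_number)` copies.
#' @param gc GC fraction of the unit.
#' @param seed integer seed.
#' @return a `repeat_array` object.
#' @export
random_repeat_array <- function(unit_bp = 200, copy_number = 10,
                                copy_fractions = c(0.2, 0.4, 0.6),
                                gc = 0.5, seed = 1) {
  with_seed(seed, {
    unit <- random_dna(unit_bp, gc)
    ns <- length(copy_fractions)
    sites <- data.frame(unit_pos0 = integer(), alt = character(),
                        copy_fraction = numeric())
    if (ns > 0) {
      # sites >= 5 bp apart so per-site tallies are independent columns, and
      # clear of the copy junction where locus-boundary alignment noise sits
      lo <- min(10L, unit_bp %/% 8)
      cand <- sort(sample(seq.int(lo, max(lo, unit_bp - 1L - lo)),
                          min(ns * 10, unit_bp %/% 2)))
      cand <- cand[c(TRUE, diff(cand) >= 5)]
      pos <- sort(sample(cand, ns))
      refb <- substring(unit, pos + 1, pos + 1)
      alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                             1), "")
      sites <- data.frame(unit_pos0 = pos, alt = unname(alt),
                          copy_fraction = copy_fractions)
    }
    repeat_array(unit, copy_number, sites)
  })
}

#' Generate a founder genome containing a tandem repeat locus
#'
#' The founder stands in for the haploid genome all nuclei of the coenocyte
#' descend from. The repeat locus (reference alleles only) is placed centrally
#' and flanked by i.i.d. random sequence at the requested GC.
#'
#' @param length total genome length in bp.
#' @param gc_fraction GC fraction of the flanks.
#' @param repeat_array a [repeat_array()] or `NULL` for no repeat locus.
#' @param seed integer seed (determinism: identical calls give byte-identical
#'   sequences).
#' @param read_length read length the genome must accommodate (sizing check).
#' @return a `founder_genome` object with fields `sequence`, `length`,
#'   `gc_fraction`, `repeat_span` (0-based half-open) and `repeat_array`.
#' @export
generate_founder <- function(length, gc_fraction = 0.35, repeat_array = NULL,
                             seed = 1, read_length = 90) {
  stopifnot(length >= 1)
  span_len <- 0L
  if (!is.null(repeat_array)) {
    stopifnot(inherits(repeat_array, "repeat_array"))
    span_len <- nchar(repeat_array$unit_sequence) * repeat_array$copy_number
    if (length < span_len + 2 * read_length)
      stop("founder length too small for the repeat array plus flanks")
  }
  with_seed(seed, {
    left_len <- (length - span_len) %/% 2
    right_len <- length - span_len - left_len
    left <- random_dna(left_len, gc_fraction)
    right <- random_dna(right_len, gc_fraction)
    locus <- if (span_len > 0)
      strrep(repeat_array$unit_sequence, repeat_array$copy_number) else ""
    structure(list(sequence = paste0(left, locus, right),
                   length = as.integer(length),
                   gc_fraction = gc_fraction,
                   repeat_span = c(left_len, left_len + span_len),
                   repeat_array = repeat_array,
                   seed = seed),
              class = "founder_genome")
  })
}

#' Apply planted variants to a genome sequence
#'
#' Variants use anchor conventions: SNP replaces one base at `pos0`; DEL keeps
#' the anchor base at `pos0` and removes the following `nchar(ref) - 1` bases;
#' INS keeps the anchor and inserts `substring(alt, 2)` after it.
#'
#' @param sequence genome string.
#' @param variants data frame with columns `pos0`, `type`, `ref`, `alt`,
#'   sorted or unsorted (sorted internally); footprints must not overlap.
#' @return the edited sequence string.
#' @export
apply_variants <- function(sequence, variants) {
  if (is.null(variants) || nrow(variants) == 0) return(sequence)
  v <- variants[order(variants$pos0), , drop = FALSE]
  L <- nchar(sequence)
  pieces <- character(0)
  cursor <- 0L # 0-based, next founder position to copy
  for (i in seq_len(nrow(v))) {
    p <- v$pos0[i]
    if (p < cursor) stop("overlapping variant footprints")
    pieces <- c(pieces, substring(sequence, cursor + 1, p))
    if (v$type[i] == "SNP") {
      pieces <- c(pieces, v$alt[i])
      cursor <- p + 1L
    } else if (v$type[i] == "DEL") {
      pieces <- c(pieces, v$alt[i]) # anchor base
      cursor <- p + nchar(v$ref[i])
    } else if (v$type[i] == "INS") {
      pieces <- c(pieces, v$alt[i]) # anchor + inserted bases
      cursor <- p + 1L
    } else stop("unknown variant type: ", v$type[i])
  }
  pieces <- c(pieces, substring(sequence, cursor + 1, L))
  paste(pieces, collapse = "")
}

#' Derive a haploid nucleus genome from the founder
#'
#' Plants SNPs and short indels (1-10 bp) at the requested per-bp rates in the
#' non-repeat portion of the founder, and realises the repeat array by
#' assigning each array variant to `round(copy_fraction * copy_number)` seeded
#' randomly chosen copies. Slightly divergent nuclei coexisting in one
#' mycelium are the scientific object being modelled, so rates are expected
#' to be small.
#'
#' @param founder a `founder_genome`.
#' @param snp_rate per-bp SNP probability in `[0, 0.05]`.
#' @param indel_rate per-bp indel probability in `[0, 0.05]`.
#' @param array_variant_sites variant sites to realise in the repeat array;
#'   defaults to the founder array's own sites.
#' @param nucleus_id label.
#' @param seed integer seed.
#' @return a `nucleus_genome` with fields `sequence`, `planted_variants`
#'   (columns `pos0`, `type`, `ref`, `alt`, `in_array`) and
#'   `array_realization` (logical copies x sites matrix).
#' @export
derive_nucleus <- function(founder, snp_rate = 0, indel_rate = 0,
                           array_variant_sites = NULL, nucleus_id = "N1",
                           seed = 1) {
  stopifnot(inherits(founder, "founder_genome"),
            snp_rate >= 0, snp_rate <= 0.05,
            indel_rate >= 0, indel_rate <= 0.05)
  L <- founder$length
  span <- founder$repeat_span
  if (is.null(array_variant_sites) && !is.null(founder$repeat_array))
    array_variant_sites <- founder$repeat_array$variant_sites
  with_seed(seed, {
    # keep variants clear of the coverage taper at the sequence ends (about
    # one insert length) and of the repeat locus boundary (about one k)
    edge <- 400L
    locus_margin <- 70L
    eligible <- seq_len(L) - 1L
    if (span[2] > span[1])
      eligible <- eligible[eligible < span[1] - locus_margin |
                             eligible >= span[2] + locus_margin]
    eligible <- eligible[eligible >= edge & eligible < L - edge]
    n_elig <- length(eligible)
    n_snp <- rbinom(1, n_elig, snp_rate)
    n_ind <- rbinom(1, n_elig, indel_rate)
    vars <- data.frame(pos0 = integer(), type = character(),
                       ref = character(), alt = character(),
                       in_array = logical())
    if (n_snp + n_ind > 0) {
      pos <- sample(eligible, min(n_snp + n_ind, n_elig))
      is_snp <- rep(c(TRUE, FALSE), c(n_snp, max(0, n_ind)))[
        seq_along(pos)]
      ilen <- ifelse(is_snp, 0L, sample.int(10, length(pos), replace = TRUE))
      idel <- !is_snp & (runif(length(pos)) < 0.5)
      # drop overlapping footprints: need pos + footprint < next pos
      o <- order(pos)
      pos <- pos[o]; is_snp <- is_snp[o]; ilen <- ilen[o]; idel <- idel[o]
      foot <- ifelse(is_snp, 1L, ifelse(idel, ilen + 1L, 2L))
      keep <- rep(TRUE, length(pos))
      last_end <- -1L
      for (i in seq_along(pos)) {
        if (pos[i] <= last_end + 1L) { keep[i] <- FALSE; next }
        # deletions must not run into the repeat locus or off the end
        if (!is_snp[i] && idel[i] &&
            (pos[i] + ilen[i] >= L - edge ||
             (span[2] > span[1] && pos[i] < span[1] &&
              pos[i] + ilen[i] >= span[1] - locus_margin))) {
          keep[i] <- FALSE; next
        }
        last_end <- pos[i] + foot[i] - 1L
      }
      pos <- pos[keep]; is_snp <- is_snp[keep]
      ilen <- ilen[keep]; idel <- idel[keep]
      rows <- lapply(seq_along(pos), function(i) {
        p <- pos[i]
        if (is_snp[i]) {
          rb <- substring(founder$sequence, p + 1, p + 1)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          data.frame(pos0 = p, type = "SNP", ref = rb, alt = ab,
                     in_array = FALSE)
        } else if (idel[i]) {
          anchor <- substring(founder$sequence, p + 1, p + 1)
          delseq <- substring(founder$sequence, p + 1, p + 1 + ilen[i])
          data.frame(pos0 = p, type = "DEL", ref = delseq, alt = anchor,
                     in_array = FALSE)
        } else {
          anchor <- substring(founder$sequence, p + 1, p + 1)
          insseq <- random_dna(ilen[i], 0.5)
          data.frame(pos0 = p, type = "INS", ref = anchor,
                     alt = paste0(anchor, insseq), in_array = FALSE)
        }
      })
      vars <- do.call(rbind, rows)
    }
    # realise the repeat array
    arr <- founder$repeat_array
    realization <- NULL
    if (!is.null(arr) && !is.null(array_variant_sites) &&
        nrow(array_variant_sites) > 0) {
      unit_len <- nchar(arr$unit_sequence)
      realization <- matrix(FALSE, nrow = arr$copy_number,
                            ncol = nrow(array_variant_sites))
      arows <- list()
      for (s in seq_len(nrow(array_variant_sites))) {
        st <- array_variant_sites[s, ]
        n_alt <- round(st$copy_fraction * arr$copy_number)
        carriers <- sample.int(arr$copy_number, n_alt)
        realization[carriers, s] <- TRUE
        gpos <- span[1] + (carriers - 1L) * unit_len + st$unit_pos0
        rb <- substring(founder$sequence, gpos + 1, gpos + 1)
        arows[[s]] <- data.frame(pos0 = gpos, type = "SNP", ref = rb,
                                 alt = st$alt, in_array = TRUE)
      }
      vars <- rbind(vars, do.call(rbind, arows))
    }
    vars <- vars[order(vars$pos0), , drop = FALSE]
    rownames(vars) <- NULL
    structure(list(nucleus_id = nucleus_id,
                   sequence = apply_variants(founder$sequence, vars),
                   planted_variants = vars,
                   array_realization = realization,
                   founder_length = L,
                   seed = seed),
              class = "nucleus_genome")
  })
}

#' MDA amplification-bias profile
#'
#' Whole-genome amplification of a single nucleus produces uneven coverage
#' and locus dropout. This profile models per-window log-normal amplification
#' multipliers (mean 1 in expectation) plus Bernoulli window dropout.
#'
#' @param window_bp window granularity in bp (>= read length, so that dropout
#'   produces contiguous uncovered loci).
#' @param bias_sigma standard deviation of the log-normal multiplier (0 =
#'   uniform amplification).
#' @param dropout_fraction per-window zero-coverage probability in `[0, 1]`.
#' @param seed integer seed.
#' @return an `mda_profile` object.
#' @export
mda_profile <- function(window_bp = 1000, bias_sigma = 0.7,
                        dropout_fraction = 0.05, seed = 1) {
  stopifnot(window_bp >= 90, bias_sigma >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1)
  structure(list(window_bp = as.integer(window_bp), bias_sigma = bias_sigma,
                 dropout_fraction = dropout_fraction, seed = seed),
            class = "mda_profile")
}

#' Simulate per-window MDA coverage targets
#'
#' @param genome a `nucleus_genome`, `founder_genome`, or an integer genome
#'   length.
#' @param mean_depth target mean fold-coverage (> 0).
#' @param profile an [mda_profile()].
#' @return numeric vector of per-window target depths, with attributes
#'   `window_bp` and `dropout` (logical mask of dropped windows).
#' @export
simulate_mda_coverage <- function(genome, mean_depth, profile) {
  stopifnot(mean_depth > 0, inherits(profile, "mda_profile"))
  L <- if (is.numeric(genome)) as.integer(genome) else nchar(genome$sequence)
  n_win <- as.integer(ceiling(L / profile$window_bp))
  with_seed(profile$seed, {
    mult <- rlnorm(n_win, meanlog = -profile$bias_sigma^2 / 2,
                   sdlog = profile$bias_sigma)
    drop <- rbinom(n_win, 1, profile$dropout_fraction) == 1
    depth <- mean_depth * mult
    depth[drop] <- 0
    attr(depth, "window_bp") <- profile$window_bp
    attr(depth, "dropout") <- drop
    depth
  })
}

# i.i.d. substitution errors on a character vector of reads
apply_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[[1]])
  nerr <- rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    ch <- seq_chars(reads[i])
    pos <- sample.int(rl, nerr[i])
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

new_read_set <- function(sample_id, r1, r2, read_length, insert_mean,
                         insert_sd, error_rate, truth) {
  structure(list(sample_id = sample_id, r1 = r1, r2 = r2,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, truth = truth),
            class = "read_set")
}

#' Simulate paired-end reads from a genome under a coverage profile
#'
#' Fragments (~`insert_mean` bp) start in a window with expected count
#' proportional to the window's depth and may run into the next window;
#' fragments touching a zero-depth (dropout) window or running off the
#' genome end are rejected, so dropout windows contain no reads. Each pair
#' is a forward read from the fragment 5' end and the reverse complement of
#' the fragment 3' end (FR orientation).
#'
#' @param genome a `nucleus_genome`/`founder_genome` or plain sequence string.
#' @param depth_vector per-window depths from [simulate_mda_coverage()], or a
#'   single number for uniform coverage.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment-size distribution (normal, truncated
#'   at `[read_length, 2 * insert_mean]`).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param sample_id sample label.
#' @param window_bp window size when `depth_vector` is a scalar.
#' @param keep_truth record per-pair source coordinates.
#' @return a `read_set`; `truth` holds `start0` (fragment start) and `insert`.
#' @export
simulate_paired_reads <- function(genome, depth_vector, read_length = 90,
                                  insert_mean = 350, insert_sd = 35,
                                  error_rate = 0, seed = 1,
                                  sample_id = "S1", window_bp = 1000,
                                  keep_truth = TRUE) {
  seqstr <- if (is.character(genome)) genome else genome$sequence
  L <- nchar(seqstr)
  if (length(depth_vector) == 0) stop("empty depth vector")
  max_insert <- min(2 * insert_mean, window_bp)
  if (L <= max_insert) stop("genome shorter than the maximum insert size")
  if (length(depth_vector) == 1 && is.null(attr(depth_vector, "window_bp"))) {
    n_win <- as.integer(ceiling(L / window_bp))
    depth_vector <- rep(as.numeric(depth_vector), n_win)
    attr(depth_vector, "window_bp") <- window_bp
  }
  wbp <- attr(depth_vector, "window_bp")
  if (is.null(wbp)) wbp <- window_bp
  n_win <- length(depth_vector)
  with_seed(seed, {
    win_start <- (seq_len(n_win) - 1L) * wbp
    win_len <- pmin(wbp, L - win_start)
    dropped <- as.numeric(depth_vector) <= 0
    lambda <- as.numeric(depth_vector) * win_len / (2 * read_length)
    n_pairs <- rpois(n_win, lambda)
    win <- rep.int(seq_len(n_win), n_pairs)
    tot <- length(win)
    empty <- function()
      new_read_set(sample_id, character(0), character(0), read_length,
                   insert_mean, insert_sd, error_rate,
                   if (keep_truth) data.frame(start0 = integer(),
                                              insert = integer())
                   else NULL)
    if (tot == 0) return(empty())
    ins <- round(rnorm(tot, insert_mean, insert_sd))
    ins <- pmax(read_length, pmin(ins, max_insert))
    start0 <- win_start[win] + floor(runif(tot) * win_len[win])
    # reject fragments running off the genome or touching a dropout window
    end_win <- pmin((start0 + ins - 1L) %/% wbp + 1L, n_win)
    cd <- c(0, cumsum(dropped))
    keep <- start0 + ins <= L & (cd[end_win + 1L] - cd[win]) == 0
    start0 <- start0[keep]; ins <- ins[keep]
    if (length(start0) == 0) return(empty())
    r1 <- substring(seqstr, start0 + 1, start0 + read_length)
    r2 <- revcomp(substring(seqstr, start0 + ins - read_length + 1,
                            start0 + ins))
    r1 <- apply_read_errors(r1, error_rate)
    r2 <- apply_read_errors(r2, error_rate)
    new_read_set(sample_id, r1, r2, read_length, insert_mean, insert_sd,
                 error_rate,
                 if (keep_truth) data.frame(start0 = as.integer(start0),
                                            insert = as.integer(ins))
                 else NULL)
  })
}

#' Build the default multi-sample study design with ground truth
#'
#' Emulates the sequencing design of a single-nucleus study of a coenocytic
#' fungus: `n_nuclei` amplified single-nucleus samples (MDA bias and dropout)
#' plus `n_mycelium` bulk mycelium samples pooling reads from all nuclei
#' proportionally, without amplification dropout. All nuclei descend from one
#' founder at low divergence, and every nucleus carries the same multi-copy
#' repeat array variant sites (realised independently per nucleus).
#'
#' `divergence_snp`/`divergence_indel` are expected *pairwise* densities
#' between two nuclei; each nucleus is derived from the founder at half that
#' rate.
#'
#' @param n_nuclei number of single-nucleus samples (>= 1).
#' @param n_mycelium number of pooled mycelium samples.
#' @param founder_bp founder genome length.
#' @param gc flank GC fraction.
#' @param unit_bp,copy_number,copy_fractions repeat-array geometry; see
#'   [random_repeat_array()].
#' @param divergence_snp,divergence_indel expected pairwise SNP / indel
#'   densities between nuclei (per bp).
#' @param depth per-sample mean fold coverage.
#' @param window_bp,bias_sigma,dropout_fraction MDA profile parameters for the
#'   nucleus samples (see [mda_profile()]); mycelium samples are uniform.
#' @param read_length,insert_mean,insert_sd read geometry.
#' @param error_rate per-base substitution error rate.
#' @param mixing list (length `n_mycelium`) of per-nucleus proportions, each
#'   summing to 1; default equal mixing.
#' @param nucleus_ids,mycelium_ids sample labels.
#' @param seed integer master seed; all per-sample seeds derive from it.
#' @return a `study_design`: list with `readsets` (named list of `read_set`),
#'   `truth` (a `coenocyte_truth`) and `params`.
#' @export
make_study_design <- function(n_nuclei = 4, n_mycelium = 2,
                              founder_bp = 100000, gc = 0.35,
                              unit_bp = 200, copy_number = 10,
                              copy_fractions = c(0.2, 0.4, 0.6),
                              divergence_snp = 3e-4, divergence_indel = 3e-5,
                              depth = 30, window_bp = 1000, bias_sigma = 0.7,
                              dropout_fraction = 0.05, read_length = 90,
                              insert_mean = 350, insert_sd = 35,
                              error_rate = 0.001, mixing = NULL,
                              nucleus_ids = paste0("N", seq_len(n_nuclei)),
                              mycelium_ids = paste0("DNA",
                                                    seq_len(n_mycelium)),
                              seed = 1) {
  if (n_nuclei < 1) stop("need at least one nucleus")
  arr <- if (!is.null(unit_bp) && copy_number >= 1 && unit_bp > 0)
    random_repeat_array(unit_bp, copy_number, copy_fractions, gc = 0.5,
                        seed = seed) else NULL
  founder <- generate_founder(founder_bp, gc, arr, seed = seed,
                              read_length = read_length)
  nuclei <- lapply(seq_len(n_nuclei), function(i)
    derive_nucleus(founder, snp_rate = divergence_snp / 2,
                   indel_rate = divergence_indel / 2,
                   nucleus_id = nucleus_ids[i], seed = seed + i))
  readsets <- list()
  profiles <- list()
  for (i in seq_len(n_nuclei)) {
    prof <- mda_profile(window_bp, bias_sigma, dropout_fraction,
                        seed = seed + 100 + i)
    depth_vec <- simulate_mda_coverage(nuclei[[i]], depth, prof)
    readsets[[nucleus_ids[i]]] <-
      simulate_paired_reads(nuclei[[i]], depth_vec, read_length, insert_mean,
                            insert_sd, error_rate, seed = seed + 200 + i,
                            sample_id = nucleus_ids[i], window_bp = window_bp)
    profiles[[nucleus_ids[i]]] <- prof
  }
  if (n_mycelium > 0) {
    if (is.null(mixing))
      mixing <- rep(list(rep(1 / n_nuclei, n_nuclei)), n_mycelium)
    stopifnot(length(mixing) == n_mycelium)
    for (j in seq_len(n_mycelium)) {
      mix <- mixing[[j]]
      stopifnot(length(mix) == n_nuclei, abs(sum(mix) - 1) < 1e-8)
      parts <- lapply(seq_len(n_nuclei), function(i) {
        if (mix[i] <= 0) return(NULL)
        simulate_paired_reads(nuclei[[i]], depth * mix[i], read_length,
                              insert_mean, insert_sd, error_rate,
                              seed = seed + 300 + j * 10 + i,
                              sample_id = mycelium_ids[j],
                              window_bp = window_bp)
      })
      parts <- parts[!vapply(parts, is.null, TRUE)]
      pooled <- new_read_set(mycelium_ids[j],
                             unlist(lapply(parts, `[[`, "r1")),
                             unlist(lapply(parts, `[[`, "r2")),
                             read_length, insert_mean, insert_sd, error_rate,
                             do.call(rbind, lapply(parts, `[[`, "truth")))
      readsets[[mycelium_ids[j]]] <- pooled
    }
  } else mixing <- list()
  truth <- build_truth(founder, nuclei, nucleus_ids)
  structure(list(readsets = readsets, truth = truth,
                 params = list(n_nuclei = n_nuclei, n_mycelium = n_mycelium,
                               depth = depth, read_length = read_length,
                               insert_mean = insert_mean,
                               error_rate = error_rate, mixing = mixing,
                               nucleus_ids = nucleus_ids,
                               mycelium_ids = mycelium_ids, seed = seed,
                               profiles = profiles)),
            class = "study_design")
}

# Union table of planted variants with carrier sets.
build_truth <- function(founder, nuclei, nucleus_ids) {
  rows <- list()
  for (i in seq_along(nuclei)) {
    v <- nuclei[[i]]$planted_variants
    if (is.null(v) || nrow(v) == 0) next
    v$carrier <- nucleus_ids[i]
    rows[[i]] <- v
  }
  if (length(rows)) {
    all <- do.call(rbind, rows)
    key <- paste(all$pos0, all$type, all$ref, all$alt)
    agg <- lapply(split(all, key), function(g) {
      out <- g[1, c("pos0", "type", "ref", "alt", "in_array")]
      out$carriers <- paste(sort(unique(g$carrier)), collapse = ",")
      out
    })
    variants <- do.call(rbind, agg)
    variants <- variants[order(variants$pos0), , drop = FALSE]
    rownames(variants) <- NULL
  } else {
    variants <- data.frame(pos0 = integer(), type = character(),
                           ref = character(), alt = character(),
                           in_array = logical(), carriers = character())
  }
  structure(list(founder = founder, nuclei = nuclei, variants = variants,
                 nucleus_ids = nucleus_ids),
            class = "coenocyte_truth")
}

#' Planted variants at isolated, unique-sequence sites
#'
#' Returns the subset of the truth table lying outside the repeat locus with
#' no other planted variant (in any nucleus) within `min_sep` bp. These are
#' the sites where graph bubbles and reference pileups have clean signal.
#'
#' @param truth a `coenocyte_truth`.
#' @param min_sep minimum separation in bp (use the largest k of the calling
#'   passes).
#' @param types variant types to return.
#' @return the filtered truth variant table.
#' @export
truth_isolated_sites <- function(truth, min_sep = 61,
                                 types = c("SNP", "INS", "DEL")) {
  v <- truth$variants
  if (nrow(v) == 0) return(v)
  keep <- !v$in_array
  gap_prev <- c(Inf, diff(v$pos0))
  gap_next <- c(diff(v$pos0), Inf)
  keep <- keep & gap_prev > min_sep & gap_next > min_sep & v$type %in% types
  span <- truth$founder$repeat_span
  if (span[2] > span[1])
    keep <- keep & (v$pos0 < span[1] - min_sep |
                      v$pos0 >= span[2] + min_sep)
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write simulation truth tables as TSV
#'
#' @param truth a `coenocyte_truth`.
#' @param path output TSV path (columns: chrom, pos0, ref, alt, type,
#'   in_array, carriers).
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  v <- truth$variants
  out <- data.frame(chrom = "founder", pos0 = v$pos0, ref = v$ref,
                    alt = v$alt, type = v$type, in_array = v$in_array,
                    carriers = v$carriers)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
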