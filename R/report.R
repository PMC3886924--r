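# Karyotype verdict: integrate reference-based counts, reference-free calls
# and repeat-locus heterogeneity into a homokaryotic / heterokaryotic /
# inconclusive classification. The central disentangling rule: inter-nucleus
# variation (single-nucleus samples differing from one another) decides the
# verdict; intra-nucleus repeat heterogeneity never counts against
# homokaryosis, however divergent the repeat copies are.

#' Classify the karyotype of a coenocyte from the three evidence streams
#'
#' Homokaryotic requires (a) the minimum pairwise aligned identity among the
#' single-nucleus samples to reach `identity_threshold`, and (b) no nucleus
#' to carry private variants (sites where exactly one nucleus sample shows
#' the alternate allele with callable depth in all nucleus samples) at a
#' rate above `private_rate_threshold` per aligned bp. Failing either gives
#' heterokaryotic. The verdict is inconclusive when less than
#' `min_callable_fraction` of the reference is callable in all nucleus
#' samples (e.g. severe amplification dropout).
#'
#' @param vc a `variant_counts` from [count_variants()] covering at least
#'   the nucleus samples.
#' @param identity an `identity_stat` from [identity_statistic()] over the
#'   nucleus samples (computed from `vc` if `NULL`).
#' @param calls optional reference-free call table from [joint_call()] on
#'   the nucleus group (reported, and used for concordance).
#' @param repeat_summary optional output of [heterogeneity_summary()].
#' @param nucleus_samples ids of the single-nucleus samples (>= 1; >= 2 for
#'   a pairwise identity).
#' @param mycelium_samples ids of pooled samples; used only for a
#'   concordance check, never for the verdict.
#' @param identity_threshold minimum pairwise identity for homokaryosis.
#' @param private_rate_threshold maximum private-variant rate (per aligned
#'   bp) for homokaryosis.
#' @param min_callable_fraction callable fraction below which the verdict is
#'   inconclusive.
#' @return a `karyotype_report` list.
#' @export
classify_karyotype <- function(vc, identity = NULL, calls = NULL,
                               repeat_summary = NULL, nucleus_samples,
                               mycelium_samples = character(),
                               identity_threshold = 0.999,
                               private_rate_threshold = 1e-3,
                               min_callable_fraction = 0.1) {
  stopifnot(inherits(vc, "variant_counts"))
  if (length(nucleus_samples) == 0)
    stop("cannot assess karyotype without single-nucleus samples")
  if (is.null(identity))
    identity <- identity_statistic(vc, nucleus_samples)
  nuc_mask <- lapply(vc$callable, function(m)
    rowSums(m[, nucleus_samples, drop = FALSE]) == length(nucleus_samples))
  aligned <- sum(vapply(nuc_mask, sum, 0))
  callable_fraction <- aligned / sum(vc$reference_lengths)
  # private variants: exactly one nucleus sample carries the alternate,
  # position callable in every nucleus sample
  nsites <- vc$sites[vc$sites$sample %in% nucleus_samples, , drop = FALSE]
  private <- setNames(integer(length(nucleus_samples)), nucleus_samples)
  if (nrow(nsites)) {
    ok <- vapply(seq_len(nrow(nsites)), function(i) {
      m <- nuc_mask[[nsites$ref_id[i]]]
      p <- nsites$pos0[i] + 1L
      p >= 1 && p <= length(m) && m[p]
    }, TRUE)
    nsites <- nsites[ok, , drop = FALSE]
    if (nrow(nsites)) {
      keys <- site_key(nsites)
      carrier_n <- table(keys)
      priv <- nsites[carrier_n[keys] == 1, , drop = FALSE]
      tp <- table(priv$sample)
      private[names(tp)] <- as.integer(tp)
    }
  }
  private_rate <- private / aligned
  min_pair_identity <- min(identity$pairwise$identity)
  verdict <- if (callable_fraction < min_callable_fraction) "inconclusive"
  else if (min_pair_identity >= identity_threshold &&
           max(private_rate) <= private_rate_threshold) "homokaryotic"
  else "heterokaryotic"
  # mycelium concordance: nucleus-carried alternates should also be visible
  # in the pooled samples (informational only)
  concordance <- NA_real_
  if (length(mycelium_samples) &&
      any(vc$sites$sample %in% mycelium_samples) && nrow(nsites)) {
    mkeys <- site_key(vc$sites[vc$sites$sample %in% mycelium_samples, ,
                               drop = FALSE])
    concordance <- mean(site_key(nsites) %in% mkeys)
  }
  structure(list(
    verdict = verdict,
    per_sample_counts = vc$counts,
    identity = identity,
    min_pairwise_identity = min_pair_identity,
    joint_identity = identity$joint$identity,
    aligned_bp = aligned,
    callable_fraction = callable_fraction,
    private_variant_counts = private,
    private_variant_rate = private_rate,
    repeat_polymorphic_sites =
      if (!is.null(repeat_summary))
        setNames(repeat_summary$per_sample$polymorphic_sites,
                 repeat_summary$per_sample$sample) else NULL,
    n_reference_free_calls = if (!is.null(calls)) nrow(calls) else NA_integer_,
    mycelium_concordance = concordance,
    nucleus_samples = nucleus_samples,
    mycelium_samples = mycelium_samples,
    thresholds = list(identity_threshold = identity_threshold,
                      private_rate_threshold = private_rate_threshold,
                      min_callable_fraction = min_callable_fraction)),
    class = "karyotype_report")
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat(sprintf("karyotype verdict: %s\n", x$verdict))
  cat(sprintf("  min pairwise identity: %.6f (threshold %.4f)\n",
              x$min_pairwise_identity, x$thresholds$identity_threshold))
  cat(sprintf("  max private-variant rate: %.2e (threshold %.1e)\n",
              max(x$private_variant_rate),
              x$thresholds$private_rate_threshold))
  if (!is.null(x$repeat_polymorphic_sites))
    cat("  repeat-locus polymorphic sites (within-nucleus, not counted",
        "against homokaryosis):",
        paste(sprintf("%s=%d", names(x$repeat_polymorphic_sites),
                      x$repeat_polymorphic_sites), collapse = " "), "\n")
  invisible(x)
}

#' Write a karyotype report to disk
#'
#' Emits machine-readable JSON (versioned schema) and a plain-text summary;
#' round-tripping the JSON reproduces all numeric fields exactly.
#'
#' @param report a `karyotype_report`.
#' @param outdir output directory (created if needed).
#' @param tracks optional density-track data frame to write alongside (BED).
#' @param repeat_sites optional repeat-unit site table to write (TSV).
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, outdir, tracks = NULL,
                         repeat_sites = NULL) {
  stopifnot(inherits(report, "karyotype_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  paths <- c(json = file.path(outdir, "karyotype_report.json"),
             text = file.path(outdir, "karyotype_report.txt"))
  js <- list(schema_version = "1.0",
             verdict = report$verdict,
             min_pairwise_identity = report$min_pairwise_identity,
             joint_identity = report$joint_identity,
             aligned_bp = report$aligned_bp,
             callable_fraction = report$callable_fraction,
             per_sample_counts = report$per_sample_counts,
             private_variant_counts = as.list(report$private_variant_counts),
             private_variant_rate = as.list(report$private_variant_rate),
             repeat_polymorphic_sites =
               if (is.null(report$repeat_polymorphic_sites)) NULL
             else as.list(report$repeat_polymorphic_sites),
             n_reference_free_calls = report$n_reference_free_calls,
             mycelium_concordance = report$mycelium_concordance,
             nucleus_samples = report$nucleus_samples,
             mycelium_samples = report$mycelium_samples,
             thresholds = report$thresholds)
  jsonlite::write_json(js, paths[["json"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  txt <- c(sprintf("karyotype verdict: %s", report$verdict),
           sprintf("min pairwise identity: %.6f",
                   report$min_pairwise_identity),
           sprintf("joint identity: %.6f", report$joint_identity),
           sprintf("aligned bp (callable in all nuclei): %d",
                   report$aligned_bp),
           sprintf("private variants: %s",
                   paste(sprintf("%s=%d", names(report$private_variant_counts),
                                 report$private_variant_counts),
                         collapse = " ")),
           if (!is.null(report$repeat_polymorphic_sites))
             sprintf("repeat polymorphic sites (within-nucleus): %s",
                     paste(sprintf("%s=%d",
                                   names(report$repeat_polymorphic_sites),
                                   report$repeat_polymorphic_sites),
                           collapse = " ")))
  writeLines(txt, paths[["text"]])
  if (!is.null(tracks)) {
    paths[["bed"]] <- file.path(outdir, "variant_density.bed")
    write_density_bed(tracks, paths[["bed"]])
  }
  if (!is.null(repeat_sites)) {
    paths[["repeat_tsv"]] <- file.path(outdir, "repeat_sites.tsv")
    write_repeat_sites_tsv(repeat_sites, paths[["repeat_tsv"]])
  }
  invisible(paths)
}
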