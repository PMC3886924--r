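# End-to-end orchestration: simulate (or load) a study design, run the
# reference-based and reference-free comparisons and the repeat-locus
# analysis on the same samples, and produce the karyotype report.

#' Run the full karyotype analysis on a study design
#'
#' Chains the pipeline the way the sequencing study ran it: map every sample
#' to the reference and count SNPs/indels, compute pairwise aligned
#' identities among nuclei, joint-call variants reference-free at two k
#' values (single-nucleus group and mycelium group separately), quantify
#' repeat-unit polymorphism per sample, and classify the karyotype.
#'
#' @param design a `study_design` from [make_study_design()], or a list with
#'   `readsets` plus `reference` and `unit` supplied explicitly.
#' @param reference named character vector; defaults to the design's founder
#'   genome.
#' @param unit repeat-unit sequence; defaults to the design's repeat array
#'   unit.
#' @param ks k values for the reference-free passes.
#' @param min_depth callable-depth threshold for reference-based counting.
#' @param alt_frac_nucleus,alt_frac_mycelium alternate-allele fractions for
#'   haploid nucleus samples and pooled mycelium samples.
#' @param min_support genotype support for bubble calls.
#' @param identity_threshold,private_rate_threshold verdict thresholds (see
#'   [classify_karyotype()]).
#' @param window_bp density-track window.
#' @param assemble also compute per-sample and joint assembly statistics
#'   (slower; off by default).
#' @return list with `pileups`, `variant_counts`, `identity`,
#'   `calls_nuclei`, `calls_mycelium`, `repeat_sites`, `repeat_summary`,
#'   `tracks`, `report`, and optionally `assembly`.
#' @export
run_karyotype_analysis <- function(design, reference = NULL, unit = NULL,
                                   ks = c(31, 61), min_depth = 5,
                                   alt_frac_nucleus = 0.8,
                                   alt_frac_mycelium = 0.2,
                                   min_support = 2,
                                   identity_threshold = 0.999,
                                   private_rate_threshold = 1e-3,
                                   window_bp = 10000, assemble = FALSE) {
  readsets <- design$readsets
  nucleus_samples <- design$params$nucleus_ids
  mycelium_samples <- design$params$mycelium_ids
  if (is.null(nucleus_samples)) nucleus_samples <- names(readsets)
  if (is.null(mycelium_samples)) mycelium_samples <- character(0)
  if (is.null(reference)) {
    stopifnot(!is.null(design$truth))
    reference <- c(founder = design$truth$founder$sequence)
  }
  if (is.null(unit) && !is.null(design$truth) &&
      !is.null(design$truth$founder$repeat_array))
    unit <- design$truth$founder$repeat_array$unit_sequence

  pileups <- lapply(readsets, pileup_reads, reference = reference)
  alt_frac <- setNames(ifelse(names(readsets) %in% mycelium_samples,
                              alt_frac_mycelium, alt_frac_nucleus),
                       names(readsets))
  vc <- count_variants(pileups, reference, min_depth = min_depth,
                       min_alt_fraction = alt_frac)
  if (!is.null(unit))
    vc <- apply_reference_mask(vc, unit_region_mask(reference, unit))
  identity <- identity_statistic(vc, nucleus_samples)
  calls_nuclei <- joint_call(readsets[nucleus_samples], ks = ks,
                             reference = reference,
                             min_support = min_support)
  calls_mycelium <- if (length(mycelium_samples) >= 2)
    joint_call(readsets[mycelium_samples], ks = ks, reference = reference,
               min_support = min_support) else NULL
  repeat_sites <- NULL
  repeat_summary <- NULL
  if (!is.null(unit)) {
    upiles <- lapply(readsets, pileup_on_unit, unit_reference = unit)
    repeat_sites <- repeat_site_table(upiles, unit)
    repeat_summary <- heterogeneity_summary(repeat_sites)
  }
  tracks <- variant_density_track(vc$sites, nchar(reference), window_bp)
  report <- classify_karyotype(vc, identity, calls_nuclei, repeat_summary,
                               nucleus_samples, mycelium_samples,
                               identity_threshold = identity_threshold,
                               private_rate_threshold =
                                 private_rate_threshold)
  out <- list(pileups = pileups, variant_counts = vc, identity = identity,
              calls_nuclei = calls_nuclei, calls_mycelium = calls_mycelium,
              repeat_sites = repeat_sites, repeat_summary = repeat_summary,
              tracks = tracks, report = report)
  if (assemble) {
    out$assembly <- lapply(readsets, assemble_sample, k = ks[1])
    out$joint_contigs <- joint_assembly(readsets, k = ks[1])
  }
  out
}
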