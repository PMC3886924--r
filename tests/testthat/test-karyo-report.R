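# The verdict logic must separate the two biological readings of observed
# variation: differences among nuclei (counts against homokaryosis) and
# heterogeneity among repeat copies inside one nucleus (never counts).

small_design <- function(divergence, seed, copy_fractions = c(0.2, 0.4, 0.6),
                         n_mycelium = 0, error_rate = 0) {
  make_study_design(n_nuclei = 4, n_mycelium = n_mycelium,
                    founder_bp = 20000, depth = 20,
                    divergence_snp = divergence,
                    divergence_indel = divergence / 10,
                    copy_fractions = copy_fractions,
                    error_rate = error_rate, seed = seed)
}

test_that("identical nuclei with a highly polymorphic repeat array stay homokaryotic", {
  d <- small_design(0, seed = 1)
  res <- run_karyotype_analysis(d)
  expect_identical(res$report$verdict, "homokaryotic")
  # every nucleus is itself repeat-polymorphic: the within-nucleus
  # heterogeneity is real but does not flip the verdict
  expect_true(all(res$report$repeat_polymorphic_sites > 0))
  expect_equal(unname(res$report$private_variant_counts), rep(0L, 4))
  expect_equal(res$report$min_pairwise_identity, 1)
})

test_that("strongly divergent nucleus classes are called heterokaryotic", {
  # two nucleus classes at ~1% mutual divergence, two nuclei per class
  arr <- random_repeat_array(200, 10, c(0.4), seed = 2)
  f <- generate_founder(20000, 0.4, arr, seed = 3)
  clsA <- derive_nucleus(f, 5e-3, 5e-4, nucleus_id = "A", seed = 4)
  clsB <- derive_nucleus(f, 5e-3, 5e-4, nucleus_id = "B", seed = 5)
  rs <- list()
  for (i in 1:2) {
    src <- if (i == 1) clsA else clsB
    for (j in 1:2) {
      id <- paste0("N", (i - 1) * 2 + j)
      rs[[id]] <- uniform_reads(src$sequence, 20, seed = 10 * i + j,
                                sample_id = id)
    }
  }
  design <- list(readsets = rs,
                 truth = list(founder = f,
                              nuclei = list(clsA, clsA, clsB, clsB)),
                 params = list(nucleus_ids = names(rs),
                               mycelium_ids = character(0)))
  res <- run_karyotype_analysis(design,
                                reference = c(founder = f$sequence),
                                unit = arr$unit_sequence)
  expect_identical(res$report$verdict, "heterokaryotic")
  # pairwise identities partition the nuclei into the two planted classes
  p <- res$identity$pairwise
  within <- p$identity[(p$sample_i == "N1" & p$sample_j == "N2") |
                         (p$sample_i == "N3" & p$sample_j == "N4")]
  across <- p$identity[!((p$sample_i == "N1" & p$sample_j == "N2") |
                           (p$sample_i == "N3" & p$sample_j == "N4"))]
  expect_true(min(within) > max(across))
})

test_that("verdict requires single-nucleus samples and handles thresholds", {
  d <- small_design(0, seed = 6, copy_fractions = numeric(0))
  res <- run_karyotype_analysis(d)
  expect_error(classify_karyotype(res$variant_counts,
                                  nucleus_samples = character(0)),
               "cannot assess karyotype")
  # an absurd identity threshold forces heterokaryotic on the same data
  strict <- classify_karyotype(res$variant_counts, res$identity,
                               nucleus_samples = d$params$nucleus_ids,
                               identity_threshold = 1.0000001)
  expect_identical(strict$verdict, "heterokaryotic")
  # an impossible callable requirement gives inconclusive
  inc <- classify_karyotype(res$variant_counts, res$identity,
                            nucleus_samples = d$params$nucleus_ids,
                            min_callable_fraction = 1.1)
  expect_identical(inc$verdict, "inconclusive")
})

test_that("report files round-trip numerically and carry the verdict", {
  d <- small_design(0, seed = 7, n_mycelium = 2)
  res <- run_karyotype_analysis(d)
  outdir <- withr::local_tempdir()
  paths <- write_report(res$report, outdir, tracks = res$tracks,
                        repeat_sites = res$repeat_sites)
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_identical(js$verdict, res$report$verdict)
  expect_equal(js$min_pairwise_identity, res$report$min_pairwise_identity)
  expect_equal(js$aligned_bp, res$report$aligned_bp)
  expect_equal(unlist(js$private_variant_counts),
               unlist(as.list(res$report$private_variant_counts)))
  txt <- readLines(paths[["text"]])
  expect_true(any(grepl(res$report$verdict, txt, fixed = TRUE)))
  expect_true(file.exists(paths[["bed"]]))
  expect_true(file.exists(paths[["repeat_tsv"]]))
  # report on empty variant sets is still valid JSON with zero counts
  expect_equal(sum(unlist(js$private_variant_counts)), 0)
})
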