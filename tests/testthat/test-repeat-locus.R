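# All repeat copies collapse onto the unit reference, so a 10-copy array at
# 30x genome coverage gives ~300x pooled unit depth, and within-nucleus
# variant copies appear as intra-sample polymorphic sites.

make_array_design <- function(copy_fractions, n_nuclei = 2, depth = 30,
                              error_rate = 0, seed = 1,
                              same_realization = FALSE) {
  arr <- random_repeat_array(200, 10, copy_fractions, seed = seed)
  f <- generate_founder(20000, 0.4, arr, seed = seed + 1)
  nuclei <- lapply(seq_len(n_nuclei), function(i)
    derive_nucleus(f, 0, 0, nucleus_id = paste0("N", i),
                   seed = if (same_realization) 99 else seed + 10 + i))
  rs <- lapply(seq_len(n_nuclei), function(i)
    uniform_reads(nuclei[[i]]$sequence, depth, error_rate,
                  seed = seed + 20 + i, sample_id = paste0("N", i)))
  names(rs) <- paste0("N", seq_len(n_nuclei))
  list(founder = f, arr = arr, nuclei = nuclei, readsets = rs)
}

test_that("a variant-free array gives monomorphic columns and full pooled depth", {
  d <- make_array_design(numeric(0), n_nuclei = 1, seed = 3)
  pu <- pileup_on_unit(d$readsets$N1, d$arr$unit_sequence)
  # pooled depth ~ copies x genome depth (10 x 30), within sampling noise
  expect_lt(abs(pu$avg_depth - 300), 3 * sqrt(300) + 20)
  # average depth line is exactly total aligned bases / unit length
  expect_equal(pu$avg_depth, pu$aligned_bases / 200)
  st <- repeat_site_table(list(N1 = pu), d$arr$unit_sequence)
  expect_equal(nrow(st), 0)
  # non-reference base counts are negligible (error-free; the rare
  # locus-boundary read with a short flank tail inside the band may leave a
  # stray base or two)
  P <- pu$pileups[[1]]
  refc <- strsplit(d$arr$unit_sequence, "")[[1]]
  nonref <- sum(P[, 1:4]) - sum(P[cbind(1:200, match(refc, c("A", "C", "G", "T")))])
  expect_lt(nonref / sum(P[, 1:4]), 1e-3)
})

test_that("reads from outside the repeat locus are not recruited", {
  d <- make_array_design(c(0.4), n_nuclei = 1, seed = 4)
  span <- d$founder$repeat_span
  flank <- substring(d$founder$sequence, 1, span[1] - 400)
  rs <- uniform_reads(flank, 10, seed = 5, sample_id = "flank")
  expect_warning(pu <- pileup_on_unit(rs, d$arr$unit_sequence),
                 "no reads recruited")
  expect_equal(pu$n_mapped, 0)
})

test_that("planted copy fractions are recovered within binomial noise", {
  d <- make_array_design(c(0.2, 0.4, 0.6), n_nuclei = 2, seed = 6)
  pus <- lapply(d$readsets, pileup_on_unit,
                unit_reference = d$arr$unit_sequence)
  st <- repeat_site_table(pus, d$arr$unit_sequence)
  sites <- d$arr$variant_sites
  expect_setequal(st$position, sites$unit_pos0 + 1)
  for (s in names(pus)) {
    for (r in seq_len(nrow(st))) {
      cf <- sites$copy_fraction[match(st$position[r], sites$unit_pos0 + 1)]
      g1 <- st[[paste0("g1_", s)]][r]
      g2 <- st[[paste0("g2_", s)]][r]
      n <- g1 + g2
      expect_lt(abs(g2 / n - cf), 3 * sqrt(cf * (1 - cf) / n) + 0.01)
      expect_true(st[[paste0("polymorphic_", s)]][r])
    }
  }
  # G2 matches the planted alternative base
  expect_identical(st$g2,
                   sites$alt[match(st$position, sites$unit_pos0 + 1)])
})

test_that("sequencing errors alone do not create polymorphic sites", {
  d <- make_array_design(numeric(0), n_nuclei = 1, error_rate = 0.001,
                         seed = 7)
  pu <- pileup_on_unit(d$readsets$N1, d$arr$unit_sequence)
  st <- repeat_site_table(list(N1 = pu), d$arr$unit_sequence,
                          min_minor_reads = 3, min_minor_fraction = 0.05)
  expect_equal(nrow(st), 0)
})

test_that("heterogeneity summary: identical vs disjoint array realizations", {
  # identical realizations in both nuclei -> dissimilarity ~ 0
  d <- make_array_design(c(0.3, 0.5), n_nuclei = 2, seed = 8,
                         same_realization = TRUE)
  pus <- lapply(d$readsets, pileup_on_unit,
                unit_reference = d$arr$unit_sequence)
  st <- repeat_site_table(pus, d$arr$unit_sequence)
  hs <- heterogeneity_summary(st)
  expect_true(all(hs$pairwise$dissimilarity < 0.1))
  expect_true(all(hs$per_sample$polymorphic_sites > 0))
  # nuclei with different copy fractions at the same site differ
  arr <- random_repeat_array(200, 10, c(0.2), seed = 9)
  f <- generate_founder(20000, 0.4, arr, seed = 10)
  hi <- arr$variant_sites
  hi$copy_fraction <- 0.6
  n1 <- derive_nucleus(f, 0, 0, array_variant_sites = arr$variant_sites,
                       nucleus_id = "N1", seed = 11)
  n2 <- derive_nucleus(f, 0, 0, array_variant_sites = hi,
                       nucleus_id = "N2", seed = 12)
  rs <- list(N1 = uniform_reads(n1$sequence, 30, seed = 13, sample_id = "N1"),
             N2 = uniform_reads(n2$sequence, 30, seed = 14, sample_id = "N2"))
  pus2 <- lapply(rs, pileup_on_unit, unit_reference = arr$unit_sequence)
  st2 <- repeat_site_table(pus2, arr$unit_sequence)
  hs2 <- heterogeneity_summary(st2)
  expect_gt(hs2$pairwise$dissimilarity, 0.2)
  # zero polymorphic sites: zeros, no division by zero
  hs0 <- heterogeneity_summary(repeat_site_table(pus2[1], arr$unit_sequence)[0, ])
  expect_true(is.data.frame(hs0$per_sample))
})
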