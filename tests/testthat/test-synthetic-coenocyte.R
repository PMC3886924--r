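# The simulator is first-class code: everything downstream is validated
# against its ground truth, so its own bookkeeping must be exact.

test_that("founder generation is deterministic and respects the repeat geometry", {
  arr <- random_repeat_array(unit_bp = 200, copy_number = 10,
                             copy_fractions = c(0.4), seed = 2)
  f1 <- generate_founder(10000, 0.5, arr, seed = 1)
  f2 <- generate_founder(10000, 0.5, arr, seed = 1)
  expect_identical(f1$sequence, f2$sequence)
  expect_equal(diff(f1$repeat_span), 2000) # copy_number x unit length
  expect_identical(substring(f1$sequence, f1$repeat_span[1] + 1,
                             f1$repeat_span[2]),
                   strrep(arr$unit_sequence, 10))
  f3 <- generate_founder(10000, 0.5, arr, seed = 2)
  expect_false(identical(f1$sequence, f3$sequence))
  # degenerate GC: flanks contain only G/C
  f4 <- generate_founder(2000, 1.0, seed = 3)
  expect_false(grepl("[AT]", f4$sequence))
  # sizing error
  expect_error(generate_founder(2100, 0.5, arr, seed = 1), "too small")
})

test_that("derived nuclei reproduce exactly from founder plus planted variants", {
  arr <- random_repeat_array(200, 10, c(0.4), seed = 5)
  f <- generate_founder(30000, 0.4, arr, seed = 7)
  # zero rates, no array variants -> byte-identical to the founder
  n0 <- derive_nucleus(f, 0, 0, array_variant_sites = arr$variant_sites[0, ],
                       seed = 1)
  expect_identical(n0$sequence, f$sequence)
  expect_equal(nrow(n0$planted_variants), 0)
  for (seed in 1:3) {
    n <- derive_nucleus(f, snp_rate = 3e-4, indel_rate = 1e-4, seed = seed)
    v <- n$planted_variants
    # reconstruction is exact
    expect_identical(apply_variants(f$sequence, v), n$sequence)
    # the planted SNP records agree with an independent sequence diff
    diff <- oracle_seq_diff(f$sequence, n$sequence)
    expect_equal(diff$pos0[diff$type == "SNP"],
                 as.integer(v$pos0[v$type == "SNP"]))
    expect_identical(diff$alt[diff$type == "SNP"], v$alt[v$type == "SNP"])
    expect_equal(nrow(diff), nrow(v))
    # variant positions strictly increasing, none inside the repeat locus
    expect_true(all(diff(v$pos0) > 0))
    nonarr <- v[!v$in_array, ]
    expect_true(all(nonarr$pos0 < f$repeat_span[1] |
                      nonarr$pos0 >= f$repeat_span[2]))
  }
  # copy_fraction 0.4 on 10 copies -> exactly 4 copies carry the variant
  n <- derive_nucleus(f, 0, 0, seed = 9)
  expect_equal(colSums(n$array_realization), 4)
  site <- arr$variant_sites
  unit_len <- nchar(arr$unit_sequence)
  carried <- which(n$array_realization[, 1])
  gpos <- f$repeat_span[1] + (carried - 1) * unit_len + site$unit_pos0[1]
  expect_identical(unique(substring(n$sequence, gpos + 1, gpos + 1)),
                   site$alt[1])
})

test_that("MDA coverage: uniform limit, dropout fraction, empty dropout windows", {
  expect_equal(as.numeric(simulate_mda_coverage(
    10000, 25, mda_profile(1000, 0, 0, seed = 1))), rep(25, 10))
  expect_equal(as.numeric(simulate_mda_coverage(
    10000, 25, mda_profile(1000, 0.5, 1.0, seed = 1))), rep(0, 10))
  dv <- simulate_mda_coverage(1e6, 10, mda_profile(1000, 0.5, 0.1, seed = 4))
  nzero <- sum(attr(dv, "dropout"))
  expect_lt(abs(nzero - 100), 3 * sqrt(1000 * 0.1 * 0.9) + 1)
  # multipliers average to ~1 before dropout
  dv2 <- simulate_mda_coverage(1e6, 10, mda_profile(1000, 0.7, 0, seed = 5))
  expect_lt(abs(mean(dv2) / 10 - 1), 0.1)
  # fragments never touch a dropout window
  set.seed(1)
  g <- random_dna(20000, 0.5)
  prof <- mda_profile(1000, 0.3, 0.2, seed = 6)
  dvg <- simulate_mda_coverage(20000, 30, prof)
  rs <- simulate_paired_reads(g, dvg, seed = 7)
  dropped <- which(attr(dvg, "dropout"))
  frag_win <- lapply(seq_len(nrow(rs$truth)), function(i)
    (rs$truth$start0[i]:(rs$truth$start0[i] + rs$truth$insert[i] - 1)) %/%
      1000 + 1)
  expect_false(any(unlist(frag_win) %in% dropped))
})

test_that("paired reads: geometry, conservation, FASTQ round trip, determinism", {
  set.seed(2)
  g <- random_dna(50000, 0.35)
  rs <- simulate_paired_reads(g, 30, seed = 3, sample_id = "N1")
  expect_true(all(nchar(c(rs$r1, rs$r2)) == 90))
  total <- sum(nchar(rs$r1)) + sum(nchar(rs$r2))
  expect_lt(abs(total - 30 * 50000) / (30 * 50000), 0.05)
  # error-free reads are substrings of the genome or its reverse complement
  idx <- sample(length(rs$r1), 100)
  expect_true(all(vapply(idx, function(i)
    grepl(rs$r1[i], g, fixed = TRUE), TRUE)))
  expect_true(all(vapply(idx, function(i)
    grepl(revcomp(rs$r2[i]), g, fixed = TRUE), TRUE)))
  # errors appear at roughly the requested rate
  rs_err <- simulate_paired_reads(g, 5, error_rate = 0.01, seed = 3)
  nerr <- sum(!vapply(seq_along(rs_err$r1), function(i)
    grepl(rs_err$r1[i], g, fixed = TRUE), TRUE))
  expect_gt(nerr, 0)
  # FASTQ round trip and byte-identical determinism
  d1 <- withr::local_tempdir()
  write_fastq(rs, d1, "a")
  rs2 <- simulate_paired_reads(g, 30, seed = 3, sample_id = "N1")
  write_fastq(rs2, d1, "b")
  expect_identical(readLines(file.path(d1, "a_R1.fastq")),
                   readLines(file.path(d1, "b_R1.fastq")))
  back <- read_fastq_pair(file.path(d1, "a_R1.fastq"),
                          file.path(d1, "a_R2.fastq"), "N1")
  expect_identical(back$r1, rs$r1)
  expect_identical(back$r2, rs$r2)
  # exact duplicate pairs are removed by the optional dedup switch
  dup <- rs
  dup$r1 <- c(rs$r1, rs$r1[1]); dup$r2 <- c(rs$r2, rs$r2[1])
  dup$truth <- NULL
  expect_equal(length(dedup_pairs(dup)$r1),
               length(unique(paste(rs$r1, rs$r2))))
  expect_error(simulate_paired_reads(g, numeric(0)), "empty depth")
})

test_that("study design: labels, pooling, truth carriers", {
  d <- make_study_design(founder_bp = 20000, depth = 8, error_rate = 0,
                         divergence_snp = 1e-3, divergence_indel = 1e-4,
                         seed = 5)
  expect_identical(names(d$readsets),
                   c("N1", "N2", "N3", "N4", "DNA1", "DNA2"))
  v <- d$truth$variants
  expect_true(nrow(v) > 0)
  # every non-array variant's carriers are a subset of the nucleus ids and
  # most are private to one nucleus at this divergence
  carr <- strsplit(v$carriers[!v$in_array], ",")
  expect_true(all(unlist(carr) %in% d$params$nucleus_ids))
  expect_true(mean(lengths(carr) == 1) > 0.9)
  # mycelium pooled from a single nucleus reproduces that nucleus' origin
  d2 <- make_study_design(n_nuclei = 2, n_mycelium = 1, founder_bp = 12000,
                          depth = 5, error_rate = 0,
                          mixing = list(c(1, 0)), seed = 6)
  n1seq <- d2$truth$nuclei[[1]]$sequence
  dna1 <- d2$readsets$DNA1
  expect_true(all(vapply(dna1$r1, grepl, TRUE, x = n1seq, fixed = TRUE)))
  expect_error(make_study_design(n_nuclei = 0), "at least one nucleus")
})
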