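test_that("seed-and-extend mapping places reads uniquely and drops repeats", {
  set.seed(1)
  ref <- c(chr = random_dna(5000, 0.5))
  # error-free read from a known position maps there with 0 edits
  r <- substring(ref, 1001, 1090)
  m <- map_reads(r, ref)
  expect_true(m$mapped)
  expect_equal(m$pos0, 1000)
  expect_equal(m$edits, 0)
  expect_equal(m$strand, 1)
  # reverse-complement read maps to the same place on the minus strand
  m2 <- map_reads(revcomp(r), ref)
  expect_equal(m2$pos0, 1000)
  expect_equal(m2$strand, -1)
  # a read from a two-copy exact repeat is an ambiguous tie -> unmapped
  rep200 <- random_dna(200, 0.5)
  ref2 <- c(chr = paste0(random_dna(1000, 0.5), rep200, random_dna(1000, 0.5),
                         rep200, random_dna(1000, 0.5)))
  m3 <- map_reads(substring(rep200, 50, 139), ref2)
  expect_false(m3$mapped)
  # one substitution: mapped with edit distance 1
  r4 <- plant_snp(r, 45)
  m4 <- map_reads(r4, ref)
  expect_true(m4$mapped)
  expect_equal(m4$edits, 1)
  expect_equal(m4$pos0, 1000)
  expect_error(map_reads(r, character(0)), "empty reference")
})

test_that("variant counting recovers planted SNPs and indels exactly", {
  set.seed(2)
  g <- random_dna(20000, 0.4)
  # 10 SNPs and 2 deletions of 3 bp, all widely spaced
  snp_pos <- seq(2000, 11000, by = 1000)
  nuc <- g
  for (p in rev(snp_pos)) nuc <- plant_snp(nuc, p)
  del_pos <- c(14000, 16000)
  for (p in rev(del_pos)) nuc <- plant_del(nuc, p, 3)
  rs <- uniform_reads(nuc, 30, seed = 3, sample_id = "N1")
  ref <- c(chr = g)
  pu <- pileup_reads(rs, ref)
  vc <- count_variants(list(N1 = pu), ref, min_depth = 5,
                       min_alt_fraction = 0.8)
  expect_equal(vc$counts$snps, 10)
  expect_equal(vc$counts$indels, 2)
  expect_equal(vc$counts$indel_bp, 6)
  expect_setequal(vc$sites$pos0[vc$sites$type == "SNP"], snp_pos - 1)
  # a sample identical to the reference counts (0, 0)
  rs0 <- uniform_reads(g, 30, seed = 4, sample_id = "R")
  vc0 <- count_variants(list(R = pileup_reads(rs0, ref)), ref, 5, 0.8)
  expect_equal(vc0$counts$snps, 0)
  expect_equal(vc0$counts$indels, 0)
  # below min_depth the position is a no-call, not a reference match
  vc_hi <- count_variants(list(N1 = pu), ref, min_depth = 100,
                          min_alt_fraction = 0.8)
  expect_equal(vc_hi$counts$snps, 0)
  expect_false(any(vc_hi$callable$chr[, "N1"]))
})

test_that("truth-mode equivalence: error-free counts match planted variants", {
  set.seed(3)
  f <- generate_founder(20000, 0.4, seed = 5)
  ref <- c(founder = f$sequence)
  pus <- list()
  planted <- list()
  for (i in 1:2) {
    n <- derive_nucleus(f, 3e-4, 5e-5, nucleus_id = paste0("N", i),
                        seed = 10 + i)
    planted[[i]] <- n$planted_variants
    rs <- uniform_reads(n$sequence, 30, seed = 20 + i,
                        sample_id = paste0("N", i))
    pus[[paste0("N", i)]] <- pileup_reads(rs, ref)
  }
  vc <- count_variants(pus, ref, min_depth = 1, min_alt_fraction = 0.8)
  for (i in 1:2) {
    expect_equal(vc$counts$snps[i], sum(planted[[i]]$type == "SNP"))
    expect_equal(vc$counts$indels[i], sum(planted[[i]]$type != "SNP"))
  }
})

test_that("identity statistic follows its formula and decreases with density", {
  set.seed(4)
  f <- generate_founder(20000, 0.4, seed = 6)
  ref <- c(founder = f$sequence)
  mk <- function(rate, seed) {
    n <- derive_nucleus(f, rate, rate / 10, nucleus_id = paste0("S", seed),
                        seed = seed)
    pileup_reads(uniform_reads(n$sequence, 30, seed = seed + 50,
                               sample_id = paste0("S", seed)), ref)
  }
  pus <- list(S1 = mk(2e-4, 1), S2 = mk(2e-4, 2))
  vc <- count_variants(pus, ref, 5, 0.8)
  ident <- identity_statistic(vc)
  p <- ident$pairwise
  expect_equal(p$identity, 1 - (p$snp_sites + p$indel_bp) / p$aligned_bp)
  expect_equal(p$identity_events,
               1 - (p$snp_sites + p$indel_events) / p$aligned_bp)
  expect_equal(ident$joint$identity,
               1 - (ident$joint$snp_sites + ident$joint$indel_bp) /
                 ident$joint$aligned_bp)
  # monotone: denser planting gives lower identity
  pus_hi <- list(S1 = mk(2e-3, 3), S2 = mk(2e-3, 4))
  ident_hi <- identity_statistic(count_variants(pus_hi, ref, 5, 0.8))
  expect_lt(ident_hi$pairwise$identity, p$identity)
  # two identical samples: identity exactly 1
  pus_id <- list(A = pus$S1, B = pus$S1)
  names(pus_id) <- c("A", "B")
  vid <- count_variants(pus_id, ref, 5, 0.8)
  vid$counts$sample <- c("A", "B")
  expect_equal(identity_statistic(vid)$pairwise$identity, 1)
})

test_that("variant density tracks tile the reference and conserve counts", {
  sites <- data.frame(pos0 = c(10, 500, 900, 4500),
                      type = c("SNP", "SNP", "DEL", "SNP"),
                      ref = "A", alt = "C", len = c(1, 1, 3, 1),
                      sample = "N1", ref_id = "chr")
  tr <- variant_density_track(sites, c(chr = 10000), window_bp = 1000)
  expect_equal(nrow(tr), 10)
  expect_equal(sum(tr$snp), 3)
  expect_equal(sum(tr$indel), 1)
  expect_equal(tr$snp[tr$start0 == 0], 2)
  expect_equal(tr$indel[tr$start0 == 0], 1)
  expect_equal(tr$snp[tr$start0 == 4000], 1)
  # no variants -> all zeros
  tr0 <- variant_density_track(sites[0, ], c(chr = 10000), 1000)
  expect_true(nrow(tr0) == 0 || all(tr0$snp + tr0$indel == 0))
})

test_that("self-alignment redundancy flags duplications by the 70%/95% rule", {
  set.seed(5)
  x <- random_dna(1000, 0.5)
  dup <- c(a = x, b = x, c = random_dna(1000, 0.5))
  rf <- self_alignment_redundancy(dup)
  expect_true(all(rf$flagged[rf$scaffold_id %in% c("a", "b")]))
  expect_false(rf$flagged[rf$scaffold_id == "c"])
  expect_equal(rf$max_identity[1], 1)
  # all-unique random scaffolds share no seeds -> nothing flagged
  uniq <- setNames(vapply(1:5, function(i) random_dna(2000, 0.5), ""),
                   paste0("s", 1:5))
  expect_false(any(self_alignment_redundancy(uniq)$flagged))
  # 60% containment at full identity stays below the 70% rule
  part <- c(a = x, b = paste0(substring(x, 1, 600), random_dna(400, 0.5)))
  rp <- self_alignment_redundancy(part)
  expect_false(rp$flagged[rp$scaffold_id == "a"])
  expect_lt(abs(rp$alignable_fraction[1] - 0.6), 0.05)
  expect_error(self_alignment_redundancy(c(a = x)), "at least two")
})
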