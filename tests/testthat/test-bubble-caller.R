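test_that("a single isolated SNP yields exactly one bubble with branch length k", {
  set.seed(1)
  s1 <- random_dna(6000, 0.5)
  s2 <- plant_snp(s1, 3000)
  for (k in c(31, 61)) {
    g <- merge_colors(list(count_kmers(s1, k, "A"), count_kmers(s2, k, "B")))
    b <- find_bubbles(g)
    expect_equal(nrow(b$bubbles), 1)
    expect_equal(nchar(b$bubbles$branch_a), k)
    expect_equal(nchar(b$bubbles$branch_b), k)
  }
  # identical samples: no bubbles
  gid <- merge_colors(list(count_kmers(s1, 31, "A"),
                           count_kmers(s1, 31, "B")))
  expect_equal(nrow(find_bubbles(gid)$bubbles), 0)
  # a clean 2 bp deletion: branch lengths differ by exactly 2
  s3 <- plant_del(s1, 3000, 2)
  gd <- merge_colors(list(count_kmers(s1, 31, "A"), count_kmers(s3, 31, "B")))
  bd <- find_bubbles(gd)
  expect_equal(nrow(bd$bubbles), 1)
  expect_equal(abs(nchar(bd$bubbles$branch_a) - nchar(bd$bubbles$branch_b)),
               2)
})

test_that("bubble classification: SNP, clean indel, composite decomposition", {
  set.seed(2)
  k <- 31
  core <- random_dna(k, 0.5)
  mid <- ceiling(k / 2)
  alt <- plant_snp(core, mid)
  cls <- classify_bubble(core, alt)
  expect_identical(cls$type, "SNP")
  expect_equal(cls$offset0, mid - 1)
  expect_identical(cls$ref, substring(core, mid, mid))
  # clean 2 bp insertion
  ins <- paste0(substring(core, 1, 10), "GG", substring(core, 11))
  ci <- classify_bubble(core, ins)
  expect_identical(ci$type, "INS")
  expect_equal(nchar(ci$alt) - nchar(ci$ref), 2)
  # two SNPs 5 bp apart decompose into two SNP_FROM_COMPLEX calls
  two <- plant_snp(plant_snp(core, 10), 15)
  ct <- classify_bubble(core, two)
  expect_identical(ct$type, rep("SNP_FROM_COMPLEX", 2))
  expect_equal(ct$offset0, c(9, 14))
  # SNP next to an indel is a composite with an INDEL_FROM_COMPLEX part
  mix <- plant_snp(paste0(substring(core, 1, 20), substring(core, 24)), 5)
  cm <- classify_bubble(core, mix)
  expect_true("INDEL_FROM_COMPLEX" %in% cm$type)
  expect_true("SNP_FROM_COMPLEX" %in% cm$type)
  expect_error(classify_bubble(core, core), "identical")
})

test_that("classification agrees with a unit-cost edit-alignment oracle", {
  set.seed(3)
  edit_weight <- function(cls) {
    w <- 0
    for (i in seq_len(nrow(cls))) {
      w <- w + if (grepl("SNP", cls$type[i])) 1
      else abs(nchar(cls$ref[i]) - nchar(cls$alt[i]))
    }
    w
  }
  for (i in 1:50) {
    a <- random_dna(sample(20:60, 1), 0.5)
    b <- a
    for (j in seq_len(sample(1:3, 1))) {
      op <- sample(c("snp", "del", "ins"), 1)
      p <- sample(5:(nchar(b) - 5), 1)
      b <- switch(op, snp = plant_snp(b, p),
                  del = plant_del(b, p, sample(1:3, 1)),
                  ins = paste0(substring(b, 1, p), random_dna(2, 0.5),
                               substring(b, p + 1)))
    }
    if (identical(a, b)) next
    cls <- classify_bubble(a, b)
    expect_equal(edit_weight(cls), oracle_edit_distance(a, b))
  }
})

test_that("per-sample genotyping thresholds branch coverage", {
  bset <- structure(list(
    bubbles = data.frame(flank5 = "A", flank3 = "C", branch_a = "G",
                         branch_b = "T"),
    cov_a = matrix(c(30, 0.5, 10, 0), 1, 4,
                   dimnames = list(NULL, c("w", "x", "y", "z"))),
    cov_b = matrix(c(0.5, 25, 12, 1), 1, 4,
                   dimnames = list(NULL, c("w", "x", "y", "z"))),
    k = 31, sample_ids = c("w", "x", "y", "z")), class = "bubble_set")
  gt <- genotype_bubbles(bset, min_support = 2)
  expect_identical(as.vector(gt), c("a", "b", "both", "missing"))
})

test_that("joint calling at k=31 and k=61 unions, deduplicates and annotates", {
  set.seed(4)
  s1 <- random_dna(8000, 0.5)
  s2 <- plant_snp(s1, 4000)
  rs <- two_sample_reads(s1, s2, depth = 30, seed = 5)
  ref <- c(chr = s1)
  calls <- joint_call(rs, ks = c(31, 61), reference = ref)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$k_discovered, "both")
  expect_identical(calls$type, "SNP")
  expect_equal(calls$pos, 4000)
  expect_identical(calls$gt_A, "ref")
  expect_identical(calls$gt_B, "alt")
  # relabelling the samples permutes genotypes but not the call set
  calls_sw <- joint_call(rs[c(2, 1)], ks = c(31, 61), reference = ref)
  expect_equal(calls_sw[, c("chrom", "pos", "ref", "alt", "type")],
               calls[, c("chrom", "pos", "ref", "alt", "type")])
  expect_identical(calls_sw$gt_B, "alt")
  # identical samples: zero calls even with sequencing errors
  rs0 <- two_sample_reads(s1, s1, depth = 30, seed = 6, error_rate = 0.001)
  expect_equal(nrow(joint_call(rs0, ks = c(31, 61), reference = ref)), 0)
  expect_error(joint_call(rs[1]), "at least two")
})

test_that("a variant inside a 40 bp exact repeat needs the high-k pass", {
  set.seed(5)
  rep40 <- random_dna(40, 0.5)
  s1 <- paste0(random_dna(2500, 0.5), rep40, random_dna(2500, 0.5), rep40,
               random_dna(2500, 0.5))
  # SNP in the middle of the second repeat copy
  pos <- 2500 + 40 + 2500 + 20
  s2 <- plant_snp(s1, pos)
  rs <- two_sample_reads(s1, s2, depth = 30, seed = 6)
  ref <- c(chr = s1)
  lo <- joint_call(rs, ks = 31, reference = ref)
  hi <- joint_call(rs, ks = 61, reference = ref)
  both <- joint_call(rs, ks = c(31, 61), reference = ref)
  expect_equal(nrow(lo[lo$lifted & lo$pos == pos, ]), 0)
  expect_equal(nrow(hi[hi$lifted & hi$pos == pos, ]), 1)
  expect_identical(both$k_discovered[both$lifted & both$pos == pos], "61")
})

test_that("call set equals a direct alignment diff of the true sequences", {
  # the oracle-equivalence property on a small two-nucleus system
  set.seed(7)
  f <- generate_founder(20000, 0.4, seed = 8)
  n1 <- derive_nucleus(f, 2e-4, 5e-5, nucleus_id = "A", seed = 9)
  n2 <- derive_nucleus(f, 2e-4, 5e-5, nucleus_id = "B", seed = 10)
  rs <- list(A = uniform_reads(n1$sequence, 30, seed = 11, sample_id = "A"),
             B = uniform_reads(n2$sequence, 30, seed = 12, sample_id = "B"))
  calls <- joint_call(rs, ks = c(31, 61),
                      reference = c(founder = f$sequence))
  # oracle: diff each nucleus against the founder, take the union of
  # isolated variants
  d1 <- oracle_seq_diff(f$sequence, n1$sequence)
  d2 <- oracle_seq_diff(f$sequence, n2$sequence)
  truth <- unique(rbind(d1, d2))
  truth <- truth[order(truth$pos0), ]
  gap_prev <- c(Inf, diff(truth$pos0))
  gap_next <- c(diff(truth$pos0), Inf)
  iso <- truth[gap_prev > 61 & gap_next > 61, ]
  m <- match_calls_to_truth(calls, iso, f$sequence)
  expect_true(all(m$recovered))
  m_all <- match_calls_to_truth(calls[calls$lifted, ], truth, f$sequence)
  expect_equal(length(m_all$false_calls), 0)
})
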