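# Independent oracles used to check the implementation by other means:
# brute-force NXX from its definition, a plain DP edit distance, and a
# greedy synchronising diff of two sequences valid for isolated variants.

# NXX straight from the definition: the largest length L among the input
# lengths such that sequences of length >= L sum to at least frac * total.
oracle_nxx <- function(lengths, frac) {
  total <- sum(as.numeric(lengths))
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(as.numeric(lengths[lengths >= L])) >= frac * total) return(L)
  }
  NA
}

# Unit-cost edit distance by full DP (no banding, no traceback).
oracle_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- i
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1,
                        cur[j] + 1)
    }
    prev <- cur
  }
  prev[n + 1]
}

# Greedy synchronising diff of two sequences that differ only by isolated
# SNPs and short indels (each variant flanked by >= `sync` identical bases).
# Returns the variant table in the anchor convention used by the simulator:
# 0-based positions on `a`.
oracle_seq_diff <- function(a, b, max_indel = 12, sync = 20) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  out <- list()
  i <- 1L; j <- 1L
  same_ahead <- function(i2, j2) {
    w <- min(sync, length(A) - i2 + 1L, length(B) - j2 + 1L)
    w <= 0 || identical(A[i2:(i2 + w - 1L)], B[j2:(j2 + w - 1L)])
  }
  while (i <= length(A) && j <= length(B)) {
    if (A[i] == B[j]) { i <- i + 1L; j <- j + 1L; next }
    if (same_ahead(i + 1L, j + 1L)) {
      out[[length(out) + 1]] <- data.frame(pos0 = i - 1L, type = "SNP",
                                           ref = A[i], alt = B[j])
      i <- i + 1L; j <- j + 1L; next
    }
    hit <- FALSE
    for (d in seq_len(max_indel)) {
      if (same_ahead(i + d, j)) { # b lacks d bases of a: deletion
        out[[length(out) + 1]] <-
          data.frame(pos0 = i - 2L, type = "DEL",
                     ref = paste(A[(i - 1L):(i + d - 1L)], collapse = ""),
                     alt = A[i - 1L])
        i <- i + d; hit <- TRUE; break
      }
      if (same_ahead(i, j + d)) { # b has d extra bases: insertion
        out[[length(out) + 1]] <-
          data.frame(pos0 = i - 2L, type = "INS", ref = A[i - 1L],
                     alt = paste(c(A[i - 1L], B[j:(j + d - 1L)]),
                                 collapse = ""))
        j <- j + d; hit <- TRUE; break
      }
    }
    if (!hit) stop("oracle diff lost synchronisation (variants not isolated)")
  }
  if (length(out) == 0)
    return(data.frame(pos0 = integer(), type = character(),
                      ref = character(), alt = character()))
  do.call(rbind, out)
}

# Two variant representations are equivalent if applying them to the same
# backbone yields the same sequence (left/right-shifted indels in repetitive
# context are the same event).
variants_equivalent <- function(backbone, v1, v2) {
  identical(apply_variants(backbone, v1), apply_variants(backbone, v2))
}

# Match calls (1-based pos on the founder) against a truth table (0-based
# anchors). Returns list(recovered = logical per truth row, false_calls =
# call rows matching no truth variant even up to indel-shift equivalence).
match_calls_to_truth <- function(calls, truth_tab, founder_seq) {
  tkey <- paste(truth_tab$pos0 + 1L, truth_tab$ref, truth_tab$alt)
  ckey <- paste(calls$pos, calls$ref, calls$alt)
  recovered <- tkey %in% ckey
  unmatched_calls <- which(!(ckey %in% tkey))
  false_calls <- integer(0)
  for (ci in unmatched_calls) {
    vcall <- data.frame(pos0 = calls$pos[ci] - 1L,
                        type = if (nchar(calls$ref[ci]) >
                                   nchar(calls$alt[ci])) "DEL"
                        else if (nchar(calls$ref[ci]) <
                                 nchar(calls$alt[ci])) "INS" else "SNP",
                        ref = calls$ref[ci], alt = calls$alt[ci])
    hit <- FALSE
    for (ti in which(!recovered)) {
      vtrue <- truth_tab[ti, c("pos0", "type", "ref", "alt")]
      if (abs(vtrue$pos0 - vcall$pos0) <= 12 &&
          variants_equivalent(founder_seq, vtrue, vcall)) {
        recovered[ti] <- TRUE
        hit <- TRUE
        break
      }
    }
    if (!hit) false_calls <- c(false_calls, ci)
  }
  list(recovered = recovered, false_calls = false_calls)
}

# Enumerate the canonical k-mer set of a sequence directly in R.
oracle_genome_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1
  km <- substring(seq, 1:n, k:(n + k - 1))
  sort(unique(pmin(km, revcomp(km))))
}
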