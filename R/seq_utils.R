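# Small sequence helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T}` (case preserved, `N` and
#' other characters left unchanged).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Generate a random DNA string
#'
#' I.i.d. bases at a requested GC content, drawn from the current RNG state.
#'
#' @param n length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

#' Write a read set as a pair of FASTQ files
#'
#' Writes `<prefix>_R1.fastq` and `<prefix>_R2.fastq` with constant Phred-40
#' base qualities (`I`). Quality-aware processing is out of scope for this
#' pipeline, so qualities are a formality of the format.
#'
#' @param readset a `read_set` object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; defaults to the sample id.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(readset, dir, prefix = readset$sample_id) {
  stopifnot(inherits(readset, "read_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qual <- strrep("I", readset$read_length)
  ids <- sprintf("@%s_pair%d", readset$sample_id, seq_along(readset$r1))
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  writeLines(as.vector(rbind(paste0(ids, "/1"), readset$r1, "+", qual)), p1)
  writeLines(as.vector(rbind(paste0(ids, "/2"), readset$r2, "+", qual)), p2)
  invisible(c(p1, p2))
}

#' Read paired FASTQ files into a read set
#'
#' Standard 4-line FASTQ; plain or gzipped.
#'
#' @param r1_path,r2_path paths to the two mate files.
#' @param sample_id sample label for the resulting read set.
#' @return a `read_set` object (without simulation truth).
#' @export
read_fastq_pair <- function(r1_path, r2_path, sample_id = "sample") {
  rd <- function(p) {
    x <- readLines(p)
    x[seq(2, length(x), by = 4)]
  }
  r1 <- rd(r1_path)
  r2 <- rd(r2_path)
  stopifnot(length(r1) == length(r2))
  new_read_set(sample_id = sample_id, r1 = r1, r2 = r2,
               read_length = if (length(r1)) nchar(r1[[1]]) else 0L,
               insert_mean = NA_real_, insert_sd = NA_real_,
               error_rate = NA_real_, truth = NULL)
}

#' Remove exact duplicate read pairs
#'
#' Emulates duplicate-read removal as an optional exact-duplicate-pair filter:
#' pairs whose (mate 1, mate 2) sequences are byte-identical to an earlier
#' pair are dropped.
#'
#' @param readset a `read_set`.
#' @return the deduplicated `read_set`.
#' @export
dedup_pairs <- function(readset) {
  stopifnot(inherits(readset, "read_set"))
  key <- paste(readset$r1, readset$r2, sep = "\x01")
  keep <- !duplicated(key)
  readset$r1 <- readset$r1[keep]
  readset$r2 <- readset$r2[keep]
  if (!is.null(readset$truth)) readset$truth <- readset$truth[keep, , drop = FALSE]
  readset
}

# All reads (both mates) of a read set as one character vector.
all_reads <- function(readset) c(readset$r1, readset$r2)
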