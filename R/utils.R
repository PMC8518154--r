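# Internal helpers shared across modules.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  chars <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(COMP[chars], collapse = "")
}

check_nucleotides <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A,C,G,T,N}: ", x, call. = FALSE)
  invisible(x)
}

#' @importFrom Biostrings DNAStringSet
NULL

# Genome as a named character vector (fast substring access); accepts a
# DNAStringSet or an already-converted character vector.
as_genome_chars <- function(genome) {
  if (is.character(genome)) genome else as.character(genome)
}

# Extract genome[chrom][start, end) (0-based half-open), truncating at the
# chromosome bounds.  Returns an uppercase character string.
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  if (is.character(genome)) {
    len <- nchar(genome[[chrom]])
    s <- max(start, 0L); e <- min(end, len)
    if (e <= s) return("")
    substr(genome[[chrom]], s + 1L, e)
  } else {
    len <- Biostrings::width(genome[chrom])
    s <- max(start, 0L); e <- min(end, len)
    if (e <= s) return("")
    as.character(Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e))
  }
}

genome_seqlen <- function(genome, chrom) {
  if (is.character(genome)) nchar(genome[[chrom]])
  else Biostrings::width(genome[chrom])
}

# Longest run of a given letter in a string.
longest_run <- function(x, letter = "A") {
  if (!nzchar(x)) return(0L)
  r <- rle(strsplit(x, "", fixed = TRUE)[[1]])
  hit <- r$values == letter
  if (!any(hit)) return(0L)
  max(r$lengths[hit])
}

count_letter <- function(x, letter = "A") {
  if (!nzchar(x)) return(0L)
  sum(strsplit(x, "", fixed = TRUE)[[1]] == letter)
}

frac_letters <- function(x, letters) {
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  sum(strsplit(x, "", fixed = TRUE)[[1]] %in% letters) / n
}

# Derive a reproducible child seed from a master seed; kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
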