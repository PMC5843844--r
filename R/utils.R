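#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov TukeyHSD pf pchisq ks.test median rnorm runif
#'   setNames aggregate quantile sd rbinom
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Plain-character reverse complement for ACGTN (and U, read as T).
#' Used throughout the read-processing cascade where sequences are held
#' as character vectors rather than `DNAString` objects.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNacgtun", "TGCAANtgcaan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## all k-mers of a sequence (character scalar); returns character(0) if too short
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## vectorised per-position character matrix for equal-length sequences
seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

## deterministic integer sub-seed derived from a user seed and a stream label;
## kept below 2^31 - 1
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

## Phred integer vector <-> ASCII (offset 33)
phred_to_ascii <- function(q) intToUtf8(q + 33L)
ascii_to_phred <- function(s) utf8ToInt(s) - 33L
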