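#' IgH amplification primer scheme
#'
#' The barcoded multiplex primer set used for the IgH libraries: a 20-nt
#' universal handle, a 14-nt random barcode (UMI) with conserved T bases at
#' 1-based positions 5 and 10 (`NNNNTNNNNTNNNN`), an isotype-specific
#' constant-region tail per IgH class, six VH FR1 forward primers, and the
#' 3' universal reverse primer (its U bases are matched as T, since the
#' sequencer reports T at uracil positions).
#'
#' @return An object of class `primer_scheme`: a list with elements
#'   `handle`, `barcode_length`, `barcode_conserved` (1-based positions that
#'   must be T), `constant_tails` (named by isotype), `constant_primers`
#'   (handle + N-template + tail, as ordered), `vh_fr1` (named forward
#'   primers) and `universal_3p`.
#' @examples
#' sch <- igh_primer_scheme()
#' sch$constant_primers[["IGHM"]]
#' @export
igh_primer_scheme <- function() {
  handle <- "TGTCCAGCACGCTTCAGGCT"
  tails <- c(
    IGHA = "GAYGACCACGTTCCCATCT",
    IGHM = "TCGTATCCGACGGGGAATTC",
    IGHD = "GGGCTGTTATCCTTTGGGTG",
    IGHE = "AGAGTCACGGAGGTGGCATT",
    IGHG = "AGTAGTCCTTGACCAGGCAG"
  )
  template <- "NNNNTNNNNTNNNN"
  scheme <- list(
    handle = handle,
    barcode_length = 14L,
    barcode_conserved = c(5L, 10L),
    barcode_template = template,
    constant_tails = tails,
    constant_primers = setNames(paste0(handle, template, tails), names(tails)),
    vh_fr1 = c(
      `VH1-FR1` = "GGCCTCAGTGAAGGTCTCCTGCAAG",
      `VH2-FR1` = "GTCTGGTCCTACGCTGGTGAAACCC",
      `VH3-FR1` = "CTGGGGGGTCCCTGAGACTCTCCTG",
      `VH4-FR1` = "CTTCGGAGACCCTGTCCCTCACCTG",
      `VH5-FR1` = "CGGGGAGTCTCTGAACATCTCCTGT",
      `VH6-FR1` = "TCGCAGACCCTCTCACTCACCTGTG"
    ),
    universal_3p = "TGUCCAGCACGCTUCAGGC"
  )
  class(scheme) <- "primer_scheme"
  scheme
}

#' Validate a barcode against the scheme template
#'
#' A barcode is valid when it has the template length, contains only
#' unambiguous ACGT bases, and carries the conserved T at every conserved
#' template position (1-based positions 5 and 10 of the 14-mer).
#'
#' @param barcode character vector of candidate barcode sequences.
#' @param scheme a [igh_primer_scheme()] object.
#' @return logical vector.
#' @export
barcode_is_valid <- function(barcode, scheme = igh_primer_scheme()) {
  ok_len <- nchar(barcode) == scheme$barcode_length
  ok_acgt <- !grepl("[^ACGT]", barcode)
  ok_cons <- rep(TRUE, length(barcode))
  for (p in scheme$barcode_conserved) {
    ok_cons <- ok_cons & substr(barcode, p, p) == "T"
  }
  ok_len & ok_acgt & ok_cons
}

#' @export
print.primer_scheme <- function(x, ...) {
  cat("IgH primer scheme\n")
  cat("  handle:        ", x$handle, "\n")
  cat("  barcode:       ", x$barcode_template,
      sprintf("(%d nt, conserved T at %s)\n", x$barcode_length,
              paste(x$barcode_conserved, collapse = ", ")))
  cat("  constant tails:", paste(names(x$constant_tails), collapse = " "), "\n")
  cat("  VH FR1 primers:", length(x$vh_fr1), "\n")
  invisible(x)
}
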