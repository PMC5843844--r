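## Simplified junction annotator. IMGT numbering is deliberately not
## reimplemented: the downstream statistics need only the germline V/J
## call, the mismatch fraction over the aligned V span (SHM%), the frame
## status, and the anchor-delimited CDRH3 length, all of which are
## well-defined from a k-mer-seeded ungapped alignment plus the reference
## anchor positions (2nd-CYS codon in V, W/F motif in J).

## k-mer-seeded ungapped alignment of query vs one reference.
## Offsets are 0-based: query_pos = ref_pos + offset. Returns NULL when no
## seed k-mer is shared (the non-immunoglobulin case).
seed_align <- function(query, ref, k) {
  qk <- seq_kmers(query, k)
  rk <- seq_kmers(ref, k)
  hit <- match(qk, rk)
  found <- which(!is.na(hit))
  if (length(found) == 0L) return(NULL)
  offsets <- (found - 1L) - (hit[found] - 1L)
  off_tab <- table(offsets)
  d <- as.integer(names(off_tab))[which.max(off_tab)]
  nq <- nchar(query); nr <- nchar(ref)
  r0 <- max(0L, -d); r1 <- min(nr - 1L, nq - 1L - d)
  if (r1 < r0) return(NULL)
  ref_span <- substr(ref, r0 + 1L, r1 + 1L)
  q_span <- substr(query, r0 + d + 1L, r1 + d + 1L)
  eq <- strsplit(ref_span, "")[[1]] == strsplit(q_span, "")[[1]]
  list(offset = d, ref_start = r0, ref_end = r1,
       q_start = r0 + d, q_end = r1 + d,
       matches = sum(eq), aligned_len = r1 - r0 + 1L,
       identity = 100 * sum(eq) / (r1 - r0 + 1L),
       match_mask = eq)
}

#' Assign the germline V gene
#'
#' Screens the query against every V allele with a k-mer-seeded ungapped
#' alignment (the in-package similarity screen standing in for a BLAST
#' search) and keeps the best-matching allele, provided identity is at
#' least `min_identity` percent over at least `min_len` aligned nt;
#' anything below is rejected as non-immunoglobulin.
#'
#' @param seq query nucleotide sequence (e.g. a consensus insert).
#' @param refs a germline reference set.
#' @param min_identity,min_len retention thresholds (default 80 / 100).
#' @param k seed k-mer size (default 10).
#' @return list with `allele`, `identity`, `aligned_len`, `offset`,
#'   `ref_start`, `ref_end`, `status` (`"ok"` or `"reject"`), `aln`.
#' @export
assign_v_gene <- function(seq, refs, min_identity = 80, min_len = 100L,
                          k = 10L) {
  if (nchar(seq) < k) stop("query shorter than seed length")
  best <- NULL; best_id <- NA_character_
  for (i in seq_len(nrow(refs$v))) {
    a <- seed_align(seq, refs$v$seq[i], k)
    if (!is.null(a) && (is.null(best) || a$matches > best$matches)) {
      best <- a; best_id <- refs$v$id[i]
    }
  }
  if (is.null(best) || best$identity < min_identity ||
      best$aligned_len < min_len) {
    return(list(allele = NA_character_, identity = NA_real_,
                aligned_len = if (is.null(best)) 0L else best$aligned_len,
                offset = NA_integer_, ref_start = NA_integer_,
                ref_end = NA_integer_, status = "reject", aln = NULL))
  }
  list(allele = best_id, identity = best$identity,
       aligned_len = best$aligned_len, offset = best$offset,
       ref_start = best$ref_start, ref_end = best$ref_end,
       status = "ok", aln = best)
}

#' Assign the germline J gene
#'
#' As [assign_v_gene()], with thresholds suited to the short J segments:
#' identity at least 80 percent over at least 25 aligned nt, seed k = 8.
#'
#' @inheritParams assign_v_gene
#' @export
assign_j_gene <- function(seq, refs, min_identity = 80, min_len = 25L,
                          k = 8L) {
  if (nchar(seq) < k) stop("query shorter than seed length")
  best <- NULL; best_id <- NA_character_
  for (i in seq_len(nrow(refs$j))) {
    a <- seed_align(seq, refs$j$seq[i], k)
    if (!is.null(a) && (is.null(best) || a$matches > best$matches)) {
      best <- a; best_id <- refs$j$id[i]
    }
  }
  if (is.null(best) || best$identity < min_identity ||
      best$aligned_len < min_len) {
    return(list(allele = NA_character_, identity = NA_real_,
                aligned_len = if (is.null(best)) 0L else best$aligned_len,
                offset = NA_integer_, ref_start = NA_integer_,
                ref_end = NA_integer_, status = "reject", aln = NULL))
  }
  list(allele = best_id, identity = best$identity,
       aligned_len = best$aligned_len, offset = best$offset,
       ref_start = best$ref_start, ref_end = best$ref_end,
       status = "ok", aln = best)
}

codons_of <- function(seq, from0, to0) {
  ## 0-based [from0, to0]; truncates to whole codons
  n <- to0 - from0 + 1L
  n <- n - n %% 3L
  if (n < 3L) return(character(0))
  starts <- seq(from0 + 1L, from0 + n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Check the reading frame of an annotated sequence
#'
#' The frame is inherited from the germline V (codon phase 0 at the V
#' allele start). The sequence is in frame when (a) the translation from
#' the first V-frame codon through the end of the aligned J span contains
#' no stop codon, and (b) the V-J junction preserves phase: the J anchor
#' motif falls on a codon boundary of the V frame.
#'
#' @param seq query sequence.
#' @param v_assignment,j_assignment results of [assign_v_gene()] /
#'   [assign_j_gene()].
#' @param refs germline reference set (for the J motif position).
#' @return logical; `NA` if V or J was not assigned.
#' @export
check_reading_frame <- function(seq, v_assignment, j_assignment, refs) {
  if (v_assignment$status != "ok" || j_assignment$status != "ok")
    return(NA)
  d_v <- v_assignment$offset
  ## first query position on a V codon boundary: ref codons start at
  ## positions 0 mod 3, i.e. query positions congruent to d_v mod 3
  q0 <- d_v %% 3L
  j_row <- refs$j[refs$j$id == j_assignment$allele, ]
  q_m <- j_assignment$offset + j_row$motif_start
  phase_ok <- (q_m - d_v) %% 3L == 0L
  cods <- codons_of(seq, q0, j_assignment$aln$q_end)
  no_stop <- !any(cods %in% STOP_CODONS)
  phase_ok && no_stop
}

#' Somatic hypermutation percentage over the aligned V segment
#'
#' SHM is the percentage of mismatched positions over the aligned V span at
#' the nucleotide level, excluding reference positions covered by the FR1
#' amplification primer (primer bases are synthetic, not template) --
#' substitution events only; the ungapped alignment has no gap columns.
#'
#' @param seq query sequence.
#' @param v_assignment an [assign_v_gene()] result with `status == "ok"`.
#' @param refs germline reference set (for the primer-covered span).
#' @return numeric percentage in `[0, 100]`.
#' @export
compute_shm <- function(seq, v_assignment, refs) {
  if (v_assignment$status != "ok") stop("V not assigned")
  v_row <- refs$v[refs$v$id == v_assignment$allele, ]
  aln <- v_assignment$aln
  ref_pos <- aln$ref_start:aln$ref_end          # 0-based reference positions
  eligible <- ref_pos >= v_row$primer_len       # outside the FR1 primer span
  if (!any(eligible)) stop("aligned V span empty after primer exclusion")
  100 * sum(!aln$match_mask[eligible]) / sum(eligible)
}

#' CDRH3 length in nucleotides
#'
#' The CDRH3 is taken anchor-exclusive: the codons strictly between the V
#' segment's 2nd-CYS codon and the J segment's conserved W/F anchor codon
#' (TGG, TTT or TTC at the J motif position). Both anchors must be present
#' in the query at their mapped positions; otherwise the length is
#' undefined (`NA`). Comparisons against IMGT junction lengths should add
#' the 6 anchor nucleotides.
#'
#' @param seq query sequence.
#' @param v_assignment,j_assignment assignment results (`status == "ok"`).
#' @param refs germline reference set.
#' @return integer nt length (multiple of 3 for in-frame sequences) or `NA`.
#' @export
find_cdrh3 <- function(seq, v_assignment, j_assignment, refs) {
  if (v_assignment$status != "ok" || j_assignment$status != "ok")
    return(NA_integer_)
  v_row <- refs$v[refs$v$id == v_assignment$allele, ]
  j_row <- refs$j[refs$j$id == j_assignment$allele, ]
  q_c <- v_row$cys_start + v_assignment$offset    # 0-based cys codon start
  q_m <- j_row$motif_start + j_assignment$offset  # 0-based anchor codon start
  n <- nchar(seq)
  if (q_c < 0L || q_c + 2L >= n || q_m < 0L || q_m + 2L >= n)
    return(NA_integer_)
  cys <- substr(seq, q_c + 1L, q_c + 3L)
  anchor <- substr(seq, q_m + 1L, q_m + 3L)
  if (!cys %in% c("TGT", "TGC")) return(NA_integer_)
  if (!anchor %in% c("TGG", "TTT", "TTC")) return(NA_integer_)
  len <- q_m - (q_c + 3L)
  if (len < 0L) return(NA_integer_)
  as.integer(len)
}

#' Annotate consensus sequences
#'
#' Runs V and J assignment, the reading-frame check, SHM and CDRH3
#' computation over a set of sequences and returns an AIRR-style
#' rearrangement table. Sequences failing the V or J similarity screen are
#' reported with `v_call`/`j_call` `NA` and `filtered = TRUE` so callers
#' can drop non-immunoglobulin reads while keeping counts conserved.
#'
#' @param seqs named character vector (names become `sequence_id`) or a
#'   `process_reads()` consensus data.frame.
#' @param refs germline reference set.
#' @param c_calls optional isotype per sequence (taken from the consensus
#'   data.frame automatically).
#' @param ... passed to [assign_v_gene()] / [assign_j_gene()]
#'   (`min_identity` etc. are fixed per segment; use the individual
#'   functions for custom thresholds).
#' @return data.frame with `sequence_id`, `c_call`, `v_call`, `j_call`,
#'   `v_identity`, `j_identity`, `productive`, `shm_pct`,
#'   `junction_length_nt`, `filtered`.
#' @export
annotate_sequences <- function(seqs, refs, c_calls = NULL, ...) {
  if (is.data.frame(seqs)) {
    c_calls <- seqs$isotype
    seqs <- setNames(seqs$sequence, seqs$consensus_id)
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  if (is.null(c_calls)) c_calls <- rep(NA_character_, length(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    v <- assign_v_gene(s, refs)
    j <- if (v$status == "ok") assign_j_gene(s, refs) else
      list(status = "reject", allele = NA_character_, identity = NA_real_)
    filtered <- v$status != "ok" || j$status != "ok"
    inframe <- if (!filtered) check_reading_frame(s, v, j, refs) else NA
    shm <- if (v$status == "ok") compute_shm(s, v, refs) else NA_real_
    cdr <- if (!filtered) find_cdrh3(s, v, j, refs) else NA_integer_
    data.frame(sequence_id = names(seqs)[i], c_call = c_calls[i],
               v_call = v$allele, j_call = j$allele,
               v_identity = v$identity, j_identity = j$identity,
               productive = isTRUE(inframe), shm_pct = shm,
               junction_length_nt = cdr, filtered = filtered,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read AIRR-style rearrangement tables (TSV)
#'
#' @param rearr an [annotate_sequences()] data.frame.
#' @param path TSV path.
#' @return `path` invisibly; the reader returns a data.frame.
#' @export
write_rearrangements <- function(rearr, path) {
  write.table(rearr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rearrangements
#' @export
read_rearrangements <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
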