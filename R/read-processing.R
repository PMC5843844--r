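#' Pipeline filtering configuration
#'
#' Houses the numeric thresholds of the read-processing cascade: median
#' Phred strictly greater than 34, identical read-pair overlap strictly
#' greater than 50 nt, k = 10 k-mer matching against the first 50 bp of the
#' constant-region references, barcode-group sequence certainty strictly
#' greater than 0.80, a minimum k-mer score for an isotype call, and at most
#' 2 mismatches when locating the VH FR1 primer.
#'
#' @param median_phred_min strict lower bound on the median base quality.
#' @param min_overlap strict lower bound on the identical overlap length.
#' @param kmer_k k-mer size for isotype matching.
#' @param constant_prefix length of the constant-region reference prefix
#'   used for matching.
#' @param certainty_min strict lower bound on barcode-group certainty.
#' @param kmer_score_min minimum shared-k-mer count for an isotype call.
#' @param fr1_max_mismatch mismatch allowance for FR1 primer location.
#' @param length_slack members further than this many nt from the group
#'   modal length are dropped before consensus scoring.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(median_phred_min = 34, min_overlap = 50,
                            kmer_k = 10L, constant_prefix = 50L,
                            certainty_min = 0.80, kmer_score_min = 10L,
                            fr1_max_mismatch = 2L, length_slack = 2L) {
  stopifnot(median_phred_min > 0, min_overlap > 0, kmer_k > 0,
            kmer_k <= constant_prefix, certainty_min > 0, kmer_score_min > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Median base-quality filter
#'
#' A read passes when the median of its per-base Phred scores is strictly
#' greater than the threshold (median of an even-length vector is the mean
#' of the central pair, so a read whose median lands exactly on the
#' threshold fails).
#'
#' @param qual ASCII-33 quality string, or integer vector of Phred scores.
#' @param config a [pipeline_config()].
#' @return logical scalar.
#' @export
median_phred_filter <- function(qual, config = pipeline_config()) {
  q <- if (is.character(qual)) ascii_to_phred(qual) else as.integer(qual)
  if (length(q) == 0L) stop("empty read")
  median(q) > config$median_phred_min
}

#' Merge a read pair on an identical overlap
#'
#' The reverse read is reverse-complemented and the longest exact
#' suffix-of-forward = prefix-of-reverse-complement match strictly longer
#' than `min_overlap` defines the merge; a single mismatch anywhere in the
#' candidate overlap disqualifies it ("identical" is taken literally).
#' Overlap-region qualities take the per-position maximum of the two reads.
#' Pairs with no qualifying overlap are discarded (a result, not an error).
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual forward/reverse sequence and
#'   ASCII-33 quality strings (reverse read in its as-sequenced orientation).
#' @param config a [pipeline_config()].
#' @return list with `seq`, `qual`, `overlap`, or `NULL` when discarded.
#' @export
merge_pairs <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                        config = pipeline_config()) {
  rc <- revcomp(rev_seq)
  n1 <- nchar(fwd_seq); n2 <- nchar(rc)
  ## any qualifying overlap must contain the forward read's terminal k-mer,
  ## so its occurrences in the reverse complement index the candidates
  k <- min(25L, n1)
  anchor <- substr(fwd_seq, n1 - k + 1L, n1)
  hits <- gregexpr(anchor, rc, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  cand <- as.integer(hits) + k - 1L          # overlap length = match end
  cand <- sort(cand[cand > config$min_overlap & cand <= min(n1, n2)],
               decreasing = TRUE)
  for (ov in cand) {
    if (substr(fwd_seq, n1 - ov + 1L, n1) == substr(rc, 1L, ov)) {
      q_f <- ascii_to_phred(fwd_qual)
      q_r <- rev(ascii_to_phred(rev_qual))   # reverse-complement order
      q_ov <- pmax(q_f[(n1 - ov + 1L):n1], q_r[1:ov])
      qual <- c(q_f[seq_len(n1 - ov)], q_ov, q_r[seq(ov + 1L, length.out = n2 - ov)])
      return(list(seq = paste0(fwd_seq, substr(rc, ov + 1L, n2)),
                  qual = phred_to_ascii(qual), overlap = ov))
    }
  }
  NULL
}

#' Orient a merged read V-primer to constant-region primer
#'
#' Locates the universal handle: a read carrying the handle in sense
#' orientation is primer-sense (constant to V) and is flipped; a read
#' carrying its reverse complement already runs V to C and is returned
#' unchanged. Reads with the handle on both strands are flagged chimeric;
#' reads without it go to the unassigned bin.
#'
#' @param seq,qual merged sequence and ASCII-33 quality.
#' @param scheme a [igh_primer_scheme()].
#' @return list with `seq`, `qual`, `status` in
#'   `c("oriented", "unassigned", "chimeric")`.
#' @export
orient_read <- function(seq, qual, scheme = igh_primer_scheme()) {
  fwd_hit <- grepl(scheme$handle, seq, fixed = TRUE)
  rc_hit <- grepl(revcomp(scheme$handle), seq, fixed = TRUE)
  if (fwd_hit && rc_hit)
    return(list(seq = seq, qual = qual, status = "chimeric"))
  if (!fwd_hit && !rc_hit)
    return(list(seq = seq, qual = qual, status = "unassigned"))
  if (fwd_hit) {
    seq <- revcomp(seq)
    qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
  }
  list(seq = seq, qual = qual, status = "oriented")
}

#' Extract and validate the 14-nt barcode
#'
#' On a V-to-C oriented read the primer block sits reverse-complemented at
#' the 3' end, so the read is viewed primer-sense (reverse complement), the
#' handle located, and the 14 nt immediately following it taken as the
#' barcode. The barcode is rejected unless 1-based positions 5 and 10 are
#' the conserved T and all bases are unambiguous ACGT.
#'
#' @param seq V-to-C oriented sequence.
#' @param scheme a [igh_primer_scheme()].
#' @return list with `barcode` (or `NA`) and `status` in
#'   `c("ok", "reject", "truncated", "no-handle")`.
#' @export
extract_barcode <- function(seq, scheme = igh_primer_scheme()) {
  ps <- revcomp(seq)                       # primer-sense view
  pos <- regexpr(scheme$handle, ps, fixed = TRUE)
  if (pos == -1L) return(list(barcode = NA_character_, status = "no-handle"))
  start <- pos + nchar(scheme$handle)
  end <- start + scheme$barcode_length - 1L
  if (end > nchar(ps))
    return(list(barcode = NA_character_, status = "truncated"))
  bc <- substr(ps, start, end)
  if (!barcode_is_valid(bc, scheme))
    return(list(barcode = bc, status = "reject"))
  list(barcode = bc, status = "ok")
}

constant_kmer_index <- function(refs, config) {
  lapply(seq_len(nrow(refs$c)), function(i) {
    list(id = refs$c$id[i], isotype = refs$c$isotype[i],
         kmers = seq_kmers(substr(refs$c$seq50[i], 1L, config$constant_prefix),
                           config$kmer_k))
  })
}

#' Assign the isotype by constant-region k-mer matching
#'
#' Scores each constant-region allele by the number of its first-50-bp
#' k-mers (k = 10) found in the read; the best-scoring allele's isotype is
#' called. Calls below the score floor, or tied across different isotypes,
#' are ambiguous.
#'
#' @param seq V-to-C oriented sequence.
#' @param refs a [make_toy_references()]-style reference set.
#' @param config a [pipeline_config()].
#' @param index optional precomputed [constant_kmer_index] (internal reuse).
#' @return list with `isotype`, `allele`, `score`, `margin`, `status` in
#'   `c("ok", "ambiguous")`.
#' @export
assign_isotype <- function(seq, refs, config = pipeline_config(),
                           index = NULL) {
  if (nchar(seq) < config$kmer_k) stop("read shorter than k")
  if (is.null(index)) index <- constant_kmer_index(refs, config)
  read_k <- unique(seq_kmers(seq, config$kmer_k))
  scores <- vapply(index, function(a) sum(a$kmers %in% read_k), integer(1))
  best <- which.max(scores)
  iso_best <- index[[best]]$isotype
  other <- scores[vapply(index, `[[`, "", "isotype") != iso_best]
  margin <- scores[best] - if (length(other)) max(other) else 0L
  if (scores[best] < config$kmer_score_min || margin == 0L)
    return(list(isotype = NA_character_, allele = NA_character_,
                score = scores[best], margin = margin, status = "ambiguous"))
  list(isotype = iso_best, allele = index[[best]]$id,
       score = scores[best], margin = margin, status = "ok")
}

#' Trim primers and constant region from an oriented read
#'
#' Locates one of the VH FR1 forward primers at the 5' end (allowing
#' `fr1_max_mismatch` mismatches) and the start of the assigned
#' constant-region block (modal offset implied by shared k-mers with the
#' constant reference prefix), and returns the insert strictly between
#' them. The constant block, barcode and handle all lie 3' of the cut.
#'
#' @param seq,qual V-to-C oriented sequence and ASCII-33 quality.
#' @param refs reference set; `isotype_call` an [assign_isotype()] result.
#' @param config a [pipeline_config()].
#' @return list with `insert`, `qual`, `fr1_primer`, `c_start` (1-based),
#'   `status` in `c("ok", "no-primer", "no-constant", "empty-insert")`.
#' @export
trim_primers <- function(seq, qual, refs, isotype_call,
                         config = pipeline_config()) {
  scheme <- refs$scheme
  primers <- scheme$vh_fr1
  plen <- nchar(primers[[1]])
  head_seq <- substr(seq, 1L, plen)
  if (nchar(head_seq) < plen)
    return(list(insert = NA, qual = NA, fr1_primer = NA, c_start = NA,
                status = "no-primer"))
  mm <- vapply(primers, function(p) hamming(head_seq, p), integer(1))
  if (min(mm) > config$fr1_max_mismatch)
    return(list(insert = NA, qual = NA, fr1_primer = NA, c_start = NA,
                status = "no-primer"))
  fr1 <- names(primers)[which.min(mm)]

  c_row <- refs$c[refs$c$id == isotype_call$allele, ]
  ref_k <- seq_kmers(substr(c_row$seq50, 1L, config$constant_prefix),
                     config$kmer_k)
  read_k <- seq_kmers(seq, config$kmer_k)
  hit <- match(read_k, ref_k)             # read pos -> ref kmer index
  found <- which(!is.na(hit))
  if (length(found) == 0L)
    return(list(insert = NA, qual = NA, fr1_primer = fr1, c_start = NA,
                status = "no-constant"))
  starts <- found - (hit[found] - 1L)     # implied 1-based constant start
  c_start <- as.integer(names(sort(table(starts), decreasing = TRUE))[1])
  if (c_start <= plen + 1L)
    return(list(insert = NA, qual = NA, fr1_primer = fr1, c_start = c_start,
                status = "empty-insert"))
  list(insert = substr(seq, plen + 1L, c_start - 1L),
       qual = substr(qual, plen + 1L, c_start - 1L),
       fr1_primer = fr1, c_start = c_start, status = "ok")
}

#' Build the consensus of a barcode group
#'
#' Members further than `length_slack` nt from the group's modal length are
#' dropped; the consensus and its certainty are computed over members at
#' the modal length. Certainty is the mean, over positions, of the fraction
#' of members carrying the plurality base at that position (1.0 for a
#' singleton); the group is retained only if certainty is strictly greater
#' than 0.80. Plurality ties break toward the base with the highest summed
#' Phred score.
#'
#' @param seqs character vector of member insert sequences.
#' @param quals matching ASCII-33 quality strings.
#' @param config a [pipeline_config()].
#' @return list with `consensus`, `support` (members scored), `certainty`,
#'   `retained` (logical), `n_input`.
#' @export
barcode_consensus <- function(seqs, quals, config = pipeline_config()) {
  if (length(seqs) == 0L) stop("empty barcode group")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab))[which.max(tab)]
  keep <- abs(lens - modal) <= config$length_slack
  seqs <- seqs[keep]; quals <- quals[keep]; lens <- lens[keep]
  score <- lens == modal
  seqs <- seqs[score]; quals <- quals[score]
  n <- length(seqs)
  if (n == 1L)
    return(list(consensus = seqs, support = 1L, certainty = 1.0,
                retained = 1.0 > config$certainty_min, n_input = length(keep)))
  mat <- seq_matrix(seqs)
  qmat <- do.call(rbind, lapply(quals, ascii_to_phred))
  cons <- character(modal); plur <- numeric(modal)
  for (p in seq_len(modal)) {
    cnt <- table(mat[, p])
    topc <- max(cnt)
    cand <- names(cnt)[cnt == topc]
    if (length(cand) > 1L) {
      qsum <- vapply(cand, function(b) sum(qmat[mat[, p] == b, p]), numeric(1))
      cand <- cand[which.max(qsum)]
    }
    cons[p] <- cand
    plur[p] <- topc / n
  }
  certainty <- mean(plur)
  list(consensus = paste(cons, collapse = ""), support = n,
       certainty = certainty, retained = certainty > config$certainty_min,
       n_input = length(keep))
}

#' Run the full read-processing cascade
#'
#' Quality filter, pair merging, orientation, barcode extraction and
#' validation, isotype assignment, primer/constant trimming, barcode
#' grouping (keyed on barcode plus isotype, so barcode collisions across
#' isotypes never mix molecules) and consensus building -- in that order,
#' with a per-read ledger so counts are conserved at every stage.
#'
#' @param r1,r2 paired read data.frames (`id`, `seq`, `qual`).
#' @param refs reference set from [make_toy_references()] or
#'   [read_germline_reference()].
#' @param config a [pipeline_config()].
#' @return list of class `igh_processing`:
#'   `consensus` -- data.frame (`consensus_id`, `barcode`, `isotype`,
#'   `c_call`, `sequence`, `support`, `certainty`);
#'   `ledger` -- per-read data.frame (`read_id`, `stage_reached`,
#'   `reject_reason`, `barcode`, `isotype`);
#'   `stage_counts` -- named integer vector of reads surviving each stage
#'   plus consensus group tallies.
#' @export
process_reads <- function(r1, r2, refs, config = pipeline_config()) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$id == r2$id))
  n <- nrow(r1)
  scheme <- refs$scheme
  stage <- rep("input", n); reason <- rep(NA_character_, n)
  bc <- rep(NA_character_, n); iso <- rep(NA_character_, n)
  ins <- rep(NA_character_, n); insq <- rep(NA_character_, n)

  ## 1. median Phred on both mates
  pass_q <- vapply(seq_len(n), function(i) {
    median_phred_filter(r1$qual[i], config) &&
      median_phred_filter(r2$qual[i], config)
  }, logical(1))
  stage[!pass_q] <- "quality"; reason[!pass_q] <- "median_phred"

  ## 2. merge
  merged <- vector("list", n)
  for (i in which(pass_q)) {
    m <- merge_pairs(r1$seq[i], r1$qual[i], r2$seq[i], r2$qual[i], config)
    if (is.null(m)) { stage[i] <- "merge"; reason[i] <- "no_identical_overlap" }
    merged[i] <- list(m)
  }
  alive <- which(pass_q & !vapply(merged, is.null, logical(1)))

  ## 3. orient
  for (i in alive) {
    o <- orient_read(merged[[i]]$seq, merged[[i]]$qual, scheme)
    if (o$status != "oriented") {
      stage[i] <- "orient"; reason[i] <- o$status
      merged[i] <- list(NULL)
    } else merged[[i]] <- o
  }
  alive <- alive[!vapply(merged[alive], is.null, logical(1))]

  ## 4. barcode
  for (i in alive) {
    b <- extract_barcode(merged[[i]]$seq, scheme)
    if (b$status != "ok") {
      stage[i] <- "barcode"; reason[i] <- paste0("barcode_", b$status)
      merged[i] <- list(NULL)
    } else bc[i] <- b$barcode
  }
  alive <- alive[!vapply(merged[alive], is.null, logical(1))]

  ## 5. isotype
  idx <- constant_kmer_index(refs, config)
  for (i in alive) {
    a <- assign_isotype(merged[[i]]$seq, refs, config, index = idx)
    if (a$status != "ok") {
      stage[i] <- "isotype"; reason[i] <- "isotype_ambiguous"
      merged[i] <- list(NULL)
    } else { iso[i] <- a$isotype; attr(merged[[i]], "allele") <- a$allele }
  }
  alive <- alive[!vapply(merged[alive], is.null, logical(1))]

  ## 6. trim
  for (i in alive) {
    call <- list(allele = attr(merged[[i]], "allele"))
    t <- trim_primers(merged[[i]]$seq, merged[[i]]$qual, refs, call, config)
    if (t$status != "ok") {
      stage[i] <- "trim"; reason[i] <- paste0("trim_", t$status)
      merged[i] <- list(NULL)
    } else { ins[i] <- t$insert; insq[i] <- t$qual }
  }
  alive <- alive[!vapply(merged[alive], is.null, logical(1))]
  stage[alive] <- "grouped"
  allele_of <- vapply(alive, function(i) attr(merged[[i]], "allele"), "")

  ## 7. consensus per (barcode, isotype) group
  key <- paste(bc[alive], iso[alive], sep = "|")
  groups <- split(seq_along(alive), key)
  cons_rows <- vector("list", length(groups))
  g_id <- 0L
  for (k in names(groups)) {
    g_id <- g_id + 1L
    gi <- alive[groups[[k]]]
    cc <- barcode_consensus(ins[gi], insq[gi], config)
    if (!cc$retained) {
      stage[gi] <- "consensus"; reason[gi] <- "low_certainty"
      next
    }
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    cons_rows[[g_id]] <- data.frame(
      consensus_id = sprintf("cons%06d", g_id),
      barcode = parts[1], isotype = parts[2],
      c_call = allele_of[groups[[k]][1]],
      sequence = cc$consensus, support = cc$support,
      certainty = cc$certainty, stringsAsFactors = FALSE)
  }
  consensus <- if (any(!vapply(cons_rows, is.null, logical(1))))
    do.call(rbind, cons_rows) else
    data.frame(consensus_id = character(), barcode = character(),
               isotype = character(), c_call = character(),
               sequence = character(), support = integer(),
               certainty = numeric(), stringsAsFactors = FALSE)
  rownames(consensus) <- NULL

  ledger <- data.frame(read_id = r1$id, stage_reached = stage,
                       reject_reason = reason, barcode = bc, isotype = iso,
                       stringsAsFactors = FALSE)
  stage_counts <- c(
    input = n,
    pass_quality = sum(!stage %in% "quality"),
    pass_merge = sum(!stage %in% c("quality", "merge")),
    pass_orient = sum(!stage %in% c("quality", "merge", "orient")),
    pass_barcode = sum(!stage %in% c("quality", "merge", "orient", "barcode")),
    pass_isotype = sum(!stage %in% c("quality", "merge", "orient", "barcode",
                                     "isotype")),
    pass_trim = sum(stage %in% c("grouped", "consensus")),
    reads_in_retained_groups = sum(stage == "grouped"),
    groups_total = length(groups),
    consensus_retained = nrow(consensus)
  )
  structure(list(consensus = consensus, ledger = ledger,
                 stage_counts = stage_counts),
            class = "igh_processing")
}

#' @export
print.igh_processing <- function(x, ...) {
  cat("IgH read processing result\n")
  print(x$stage_counts)
  invisible(x)
}

#' Write processing outputs (consensus FASTA, ledger TSV, counts JSON)
#'
#' @param result a [process_reads()] result.
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_processing_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "consensus.fasta")
  if (nrow(result$consensus) > 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      setNames(result$consensus$sequence, result$consensus$consensus_id)), fa)
  } else writeLines(character(0), fa)
  led <- file.path(outdir, "read_ledger.tsv")
  write.table(result$ledger, led, sep = "\t", quote = FALSE, row.names = FALSE)
  cj <- file.path(outdir, "stage_counts.json")
  jsonlite::write_json(as.list(result$stage_counts), cj, auto_unbox = TRUE)
  ct <- file.path(outdir, "consensus.tsv")
  write.table(result$consensus, ct, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(consensus_fasta = fa, ledger = led, counts = cj, consensus_tsv = ct))
}
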