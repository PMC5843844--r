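## Synthetic data generators. Everything is deterministic per seed and
## carries a complete truth ledger, so pipeline recovery can be scored
## exactly without access-controlled donor data.

STOP_CODONS <- c("TAA", "TAG", "TGA")
coding_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  setdiff(paste0(g[, 1], g[, 2], g[, 3]), STOP_CODONS)
}

random_codons <- function(n) paste(sample(coding_codons(), n, replace = TRUE),
                                   collapse = "")
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Generate toy germline references and the matching primer scheme
#'
#' Builds a self-consistent reference set for simulation and testing: six V
#' alleles (each beginning with one of the six VH FR1 forward primers and
#' ending on its 2nd-CYS codon, mutually divergent), four J alleles carrying
#' the conserved W/F anchor motif at a fixed offset, and five constant-region
#' alleles (one per IgH class) whose 50-bp prefix ends with the
#' reverse complement of that class's primer tail, so the real primer
#' sequences anneal inside the reference prefix. IMGT germline sets are not
#' redistributed; these synthetic alleles make simulated truth unambiguous
#' by construction.
#'
#' @param seed integer seed; identical seeds give byte-identical references.
#' @param v_length V allele length in nt (multiple of 3; default 294).
#' @param j_length J allele length in nt (multiple of 3; default 48).
#' @return object of class `germline_reference`: list with data.frames `v`
#'   (`id`, `seq`, `cys_start` 0-based, `primer_id`, `primer_len`), `j`
#'   (`id`, `seq`, `motif_start` 0-based), `c` (`id`, `isotype`, `seq50`,
#'   `tail`), plus the `scheme`.
#' @export
make_toy_references <- function(seed = 1, v_length = 294L, j_length = 48L) {
  stopifnot(v_length %% 3 == 0, j_length %% 3 == 0)
  set.seed(derive_seed(seed, "toy-references"))
  scheme <- igh_primer_scheme()

  make_v <- function(primer_id) {
    primer <- scheme$vh_fr1[[primer_id]]
    body_nt <- v_length - nchar(primer) - 3L  # up to the final CYS codon
    ## keep the allele stop-free in frame 0: primer spans codons 0..8 plus
    ## one base; complete that codon then draw coding codons
    partial <- sample(DNA_BASES, (3L - nchar(primer) %% 3L) %% 3L, replace = TRUE)
    head_len <- nchar(primer) + length(partial)
    n_codons <- (v_length - head_len - 3L) / 3L
    ## stop-free only outside the primer span: annotation translates the
    ## primer-trimmed insert, so primer-internal phase is irrelevant
    first_free_codon <- 3L * (nchar(primer) %/% 3L) + 1L
    repeat {
      s <- paste0(primer, paste(partial, collapse = ""),
                  random_codons(n_codons), sample(c("TGT", "TGC"), 1L))
      cods <- substring(s, seq(first_free_codon, v_length - 2, 3),
                        seq(first_free_codon + 2, v_length, 3))
      if (!any(cods %in% STOP_CODONS)) return(s)
      partial <- sample(DNA_BASES, length(partial), replace = TRUE)
    }
  }
  v_ids <- paste0("IGHV", 1:6, "-toy*01")
  v <- data.frame(
    id = v_ids,
    seq = vapply(names(scheme$vh_fr1), make_v, character(1)),
    cys_start = v_length - 3L,
    primer_id = names(scheme$vh_fr1),
    primer_len = nchar(scheme$vh_fr1),
    stringsAsFactors = FALSE, row.names = NULL
  )

  motif_start <- 9L
  make_j <- function(anchor) {
    ## the pre-anchor bases sit inside CDRH3 and are translated: keep them
    ## stop-free codons (motif_start is a multiple of 3 here)
    n_codons <- (j_length - motif_start - 3L) / 3L
    paste0(random_codons(motif_start / 3L), anchor, random_codons(n_codons))
  }
  j_anchors <- c("TGG", "TTT", "TGG", "TTC")
  j <- data.frame(
    id = paste0("IGHJ", 1:4, "-toy*01"),
    seq = vapply(j_anchors, make_j, character(1)),
    motif_start = motif_start,
    stringsAsFactors = FALSE, row.names = NULL
  )

  resolve_iupac <- function(x) chartr("Y", "C", x)  # one fixed allele per tail
  isotypes <- names(scheme$constant_tails)
  tails <- vapply(scheme$constant_tails, resolve_iupac, character(1))
  c_tab <- data.frame(
    id = paste0(isotypes, "-toy*01"),
    isotype = isotypes,
    seq50 = vapply(isotypes, function(i) {
      rc_tail <- revcomp(tails[[i]])
      paste0(random_dna(50L - nchar(rc_tail)), rc_tail)
    }, character(1)),
    tail = unname(tails),
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(list(v = v, j = j, c = c_tab, scheme = scheme),
            class = "germline_reference")
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf("Germline reference set: %d V, %d J, %d constant alleles\n",
              nrow(x$v), nrow(x$j), nrow(x$c)))
  invisible(x)
}

#' Write / read germline references as FASTA plus an anchors sidecar TSV
#'
#' @param refs a [make_toy_references()] object.
#' @param fasta,anchors file paths (FASTA of all alleles; TSV with columns
#'   `allele_id`, `segment`, `isotype`, `anchor_start`, `primer_len`).
#' @return paths, invisibly (`read_germline_reference` returns the object).
#' @export
write_germline_reference <- function(refs, fasta, anchors) {
  seqs <- c(setNames(refs$v$seq, refs$v$id),
            setNames(refs$j$seq, refs$j$id),
            setNames(refs$c$seq50, refs$c$id))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  side <- rbind(
    data.frame(allele_id = refs$v$id, segment = "V", isotype = NA,
               anchor_start = refs$v$cys_start, primer_len = refs$v$primer_len),
    data.frame(allele_id = refs$j$id, segment = "J", isotype = NA,
               anchor_start = refs$j$motif_start, primer_len = 0L),
    data.frame(allele_id = refs$c$id, segment = "C", isotype = refs$c$isotype,
               anchor_start = 0L, primer_len = 0L)
  )
  write.table(side, anchors, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, anchors = anchors))
}

#' @rdname write_germline_reference
#' @export
read_germline_reference <- function(fasta, anchors) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  side <- read.delim(anchors, stringsAsFactors = FALSE)
  get <- function(seg) side[side$segment == seg, , drop = FALSE]
  scheme <- igh_primer_scheme()
  vv <- get("V"); jj <- get("J"); cc <- get("C")
  v <- data.frame(id = vv$allele_id,
                  seq = as.character(seqs[vv$allele_id]),
                  cys_start = vv$anchor_start,
                  primer_id = NA_character_, primer_len = vv$primer_len,
                  stringsAsFactors = FALSE)
  ## recover which FR1 primer heads each V allele, if any
  v$primer_id <- vapply(v$seq, function(s) {
    hit <- which(startsWith(s, scheme$vh_fr1))
    if (length(hit)) names(scheme$vh_fr1)[hit[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  j <- data.frame(id = jj$allele_id, seq = as.character(seqs[jj$allele_id]),
                  motif_start = jj$anchor_start, stringsAsFactors = FALSE)
  c_tab <- data.frame(id = cc$allele_id, isotype = cc$isotype,
                      seq50 = substr(as.character(seqs[cc$allele_id]), 1, 50),
                      tail = NA_character_, stringsAsFactors = FALSE)
  structure(list(v = v, j = j, c = c_tab, scheme = scheme),
            class = "germline_reference")
}

#' Per-subset isotype mixtures
#'
#' Default isotype compositions for the sorted memory B cell subsets:
#' IgM+IgD+ (unswitched, mostly IGHM with IGHD), IgM+IgD- (IgM-only),
#' IgM-IgD- (class-switched, IGHG/IGHA dominated) and IgM-IgD+ (rare,
#' IGHD dominated).
#'
#' @param subset one of `"IgM+IgD+"`, `"IgM+IgD-"`, `"IgM-IgD-"`,
#'   `"IgM-IgD+"`.
#' @return named probability vector over IGHM/IGHD/IGHG/IGHA/IGHE.
#' @export
subset_isotype_mix <- function(subset = c("IgM+IgD+", "IgM+IgD-",
                                          "IgM-IgD-", "IgM-IgD+")) {
  subset <- match.arg(subset)
  switch(subset,
    "IgM+IgD+" = c(IGHM = 0.80, IGHD = 0.15, IGHG = 0.03, IGHA = 0.02, IGHE = 0.00),
    "IgM+IgD-" = c(IGHM = 0.95, IGHD = 0.00, IGHG = 0.03, IGHA = 0.02, IGHE = 0.00),
    "IgM-IgD-" = c(IGHM = 0.02, IGHD = 0.00, IGHG = 0.60, IGHA = 0.35, IGHE = 0.03),
    "IgM-IgD+" = c(IGHM = 0.05, IGHD = 0.90, IGHG = 0.03, IGHA = 0.02, IGHE = 0.00))
}

#' Default CDRH3 nucleotide-length distribution
#'
#' A discretised bell over anchor-exclusive CDRH3 lengths 24-81 nt
#' (multiples of 3), centred on 45 nt (15 amino acids), approximating the
#' unimodal length profile of human IgH repertoires.
#'
#' @return named probability vector (names are nt lengths).
#' @export
default_cdrh3_probs <- function() {
  lens <- seq(24L, 81L, by = 3L)      # nt, anchor-exclusive, multiples of 3
  w <- exp(-((lens - 45) / 15)^2)     # bell around 45 nt (15 aa)
  setNames(w / sum(w), lens)
}

#' Parameters for the IgH repertoire / read simulator
#'
#' @param n_clones number of distinct clones.
#' @param molecules_per_clone mRNA molecules per clone (each gets its own
#'   barcode).
#' @param isotype_mix named probabilities over IGHM/IGHD/IGHG/IGHA/IGHE
#'   (per-clone isotype); defaults to the IgM-IgD- switched-subset mixture.
#' @param shm_rate per-site substitution probability over non-primer V
#'   positions, applied per molecule.
#' @param cdrh3_len_probs named probability vector over anchor-exclusive
#'   CDRH3 nucleotide lengths (multiples of 3, >= the J anchor offset).
#' @param reads_per_molecule sequenced read pairs per molecule.
#' @param error_rate per-base sequencing substitution probability.
#' @param read_length read length in nt (paired 300-bp chemistry default).
#' @param phred_correct,phred_error integer ranges the per-base qualities of
#'   correct and erroneous bases are drawn from.
#' @param subset sorted-cell subset label carried into the truth ledger.
#' @param seed mandatory integer seed.
#' @return list of class `repertoire_sim_params`.
#' @export
repertoire_sim_params <- function(n_clones = 100L, molecules_per_clone = 3L,
                                  isotype_mix = subset_isotype_mix("IgM-IgD-"),
                                  shm_rate = 0.02,
                                  cdrh3_len_probs = default_cdrh3_probs(),
                                  reads_per_molecule = 10L, error_rate = 0,
                                  read_length = 300L,
                                  phred_correct = 36:40, phred_error = 18:28,
                                  subset = "IgM-IgD-", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(isotype_mix) - 1) < 1e-9, all(isotype_mix >= 0),
            abs(sum(cdrh3_len_probs) - 1) < 1e-9,
            shm_rate >= 0, shm_rate <= 1, error_rate >= 0, error_rate <= 1)
  structure(as.list(environment()), class = "repertoire_sim_params")
}

mutate_positions <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulate an IgH repertoire with full truth ledger
#'
#' Builds in-frame V-junction-J transcripts per clone, applies per-molecule
#' somatic hypermutation (substitutions, uniform over non-primer V
#' positions), assigns each molecule a unique template-conformant 14-nt
#' barcode, and attaches the amplification scaffolding (FR1 primer retained
#' at the 5' end of V, constant-region 50-bp prefix, reverse-complemented
#' barcode and universal handle at the 3' end) to give the full amplicon.
#'
#' @param params a [repertoire_sim_params()] object.
#' @param refs a [make_toy_references()] object.
#' @return data.frame of class `sim_truth`, one row per molecule:
#'   `molecule_id`, `clone_id`, `subset`, `isotype`, `c_call`, `v_call`,
#'   `j_call`, `cdrh3_nt`, `n_mut`, `mut_positions` (comma string, 1-based
#'   in the amplicon), `barcode`, `insert` (the true primer/constant-trimmed
#'   sequence), `amplicon`.
#' @export
simulate_repertoire <- function(params, refs) {
  stopifnot(inherits(params, "repertoire_sim_params"),
            inherits(refs, "germline_reference"))
  set.seed(derive_seed(params$seed, "repertoire"))
  scheme <- refs$scheme
  mix <- params$isotype_mix[params$isotype_mix > 0]
  if (!all(names(mix) %in% refs$c$isotype))
    stop("isotype mixture names not all present in constant references")

  n_clones <- params$n_clones
  lens <- as.integer(names(params$cdrh3_len_probs))
  motif_off <- refs$j$motif_start[1]
  if (any(lens < motif_off) || any(lens %% 3 != 0))
    stop("CDRH3 lengths must be multiples of 3 and >= the J anchor offset")

  clone_v <- sample.int(nrow(refs$v), n_clones, replace = TRUE)
  clone_j <- sample.int(nrow(refs$j), n_clones, replace = TRUE)
  clone_iso <- names(mix)[sample.int(length(mix), n_clones, replace = TRUE,
                                     prob = mix)]
  clone_len <- lens[sample.int(length(lens), n_clones, replace = TRUE,
                               prob = params$cdrh3_len_probs)]
  clone_ins <- vapply(clone_len, function(L) {
    ins <- L - motif_off
    if (ins == 0L) "" else random_codons(ins / 3L)
  }, character(1))

  n_mol <- n_clones * params$molecules_per_clone
  ## unique template-conformant barcodes: 12 free positions, T at 5 and 10
  free_idx <- sample.int(4^12, n_mol)  # without replacement
  enc <- function(ix) {
    ix <- ix - 1
    d <- vapply(1:12, function(k) {
      b <- ix %% 4; ix <<- ix %/% 4; DNA_BASES[b + 1]
    }, character(1))
    paste0(paste(d[1:4], collapse = ""), "T",
           paste(d[5:8], collapse = ""), "T",
           paste(d[9:12], collapse = ""))
  }
  barcodes <- vapply(free_idx, enc, character(1))

  rows <- vector("list", n_mol)
  m <- 0L
  for (cl in seq_len(n_clones)) {
    v <- refs$v[clone_v[cl], ]
    j <- refs$j[clone_j[cl], ]
    iso <- clone_iso[cl]
    c_row <- refs$c[refs$c$isotype == iso, ]
    ins <- clone_ins[cl]
    core_germ <- paste0(v$seq, ins, j$seq)   # in frame by construction
    eligible <- seq(v$primer_len + 1L, nchar(v$seq))  # non-primer V positions
    for (k in seq_len(params$molecules_per_clone)) {
      m <- m + 1L
      mut <- eligible[runif(length(eligible)) < params$shm_rate]
      core <- mutate_positions(core_germ, mut)
      bc <- barcodes[m]
      amplicon <- paste0(core, c_row$seq50, revcomp(bc), revcomp(scheme$handle))
      rows[[m]] <- data.frame(
        molecule_id = sprintf("mol%05d", m),
        clone_id = sprintf("clone%04d", cl),
        subset = params$subset, isotype = iso, c_call = c_row$id,
        v_call = v$id, j_call = j$id,
        cdrh3_nt = clone_len[cl], n_mut = length(mut),
        mut_positions = paste(mut, collapse = ","),
        barcode = bc,
        insert = substr(core, v$primer_len + 1L, nchar(core)),
        amplicon = amplicon, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  class(out) <- c("sim_truth", "data.frame")
  out
}

#' Simulate paired sequencing reads from molecules
#'
#' Emits R1/R2 read pairs covering each amplicon from its two ends
#' (overlapping in the middle, as with paired 300-bp reads on a ~460-nt
#' amplicon), with substitution errors at the configured rate and per-base
#' Phred values drawn from the correct/error quality ranges.
#'
#' @param truth a [simulate_repertoire()] ledger.
#' @param params the same [repertoire_sim_params()] object.
#' @return list with `r1`, `r2` (data.frames: `id`, `seq`, `qual` ASCII-33),
#'   and `links` (data.frame `read_id`, `molecule_id`).
#' @export
simulate_reads <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(derive_seed(params$seed, "reads"))
  L <- params$read_length
  amp_len <- nchar(truth$amplicon)
  ## overlap may be set at or below the merge threshold on purpose (boundary
  ## studies); only a non-positive overlap (reads not spanning the molecule)
  ## is a hard error
  if (any(2L * pmin(L, amp_len) - amp_len <= 0L))
    stop("reads do not span some molecules; increase read_length")

  sequence_one <- function(template) {
    n <- nchar(template)
    ch <- strsplit(template, "")[[1]]
    err <- which(runif(n) < params$error_rate)
    qual <- sample(params$phred_correct, n, replace = TRUE)
    if (length(err)) {
      for (p in err) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      qual[err] <- sample(params$phred_error, length(err), replace = TRUE)
    }
    list(seq = paste(ch, collapse = ""), qual = phred_to_ascii(qual))
  }

  n_reads <- nrow(truth) * params$reads_per_molecule
  r1 <- vector("list", n_reads); r2 <- vector("list", n_reads)
  ids <- character(n_reads); mols <- character(n_reads)
  i <- 0L
  for (mrow in seq_len(nrow(truth))) {
    amp <- truth$amplicon[mrow]
    n <- nchar(amp)
    fwd_t <- substr(amp, 1L, min(L, n))
    rev_t <- revcomp(substr(amp, max(1L, n - L + 1L), n))
    for (k in seq_len(params$reads_per_molecule)) {
      i <- i + 1L
      ids[i] <- sprintf("%s_r%02d", truth$molecule_id[mrow], k)
      mols[i] <- truth$molecule_id[mrow]
      r1[[i]] <- sequence_one(fwd_t)
      r2[[i]] <- sequence_one(rev_t)
    }
  }
  list(
    r1 = data.frame(id = ids, seq = vapply(r1, `[[`, "", "seq"),
                    qual = vapply(r1, `[[`, "", "qual"), stringsAsFactors = FALSE),
    r2 = data.frame(id = ids, seq = vapply(r2, `[[`, "", "seq"),
                    qual = vapply(r2, `[[`, "", "qual"), stringsAsFactors = FALSE),
    links = data.frame(read_id = ids, molecule_id = mols, stringsAsFactors = FALSE)
  )
}

#' Write / read paired reads as FASTQ
#'
#' @param reads a `r1`/`r2` data.frame from [simulate_reads()].
#' @param path FASTQ path.
#' @return `path` invisibly; `read_fastq` returns a data.frame
#'   (`id`, `seq`, `qual`).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  data.frame(id = names(x), seq = as.character(x), qual = as.character(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parameters for the factorial response simulator
#'
#' @param grand_mean baseline Ig readout.
#' @param main_effects named list: per factor, a numeric vector of additive
#'   effects per level (in level order).
#' @param interactions named list keyed `"A:B"`, each a matrix (levels of A
#'   by levels of B) of additive interaction effects.
#' @param donor_offsets numeric additive offset per donor (names become
#'   donor ids).
#' @param noise_sd Gaussian noise standard deviation.
#' @param replicates replicates per design point per donor.
#' @param isotypes isotype labels to emit tables for (same effects applied
#'   to each; default `"total"`).
#' @param seed mandatory integer seed.
#' @return list of class `doe_sim_params`.
#' @export
doe_sim_params <- function(grand_mean = 100,
                           main_effects = list(),
                           interactions = list(),
                           donor_offsets = c(d1 = -5, d2 = 0, d3 = 5),
                           noise_sd = 5, replicates = 3L,
                           isotypes = "total", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0, replicates >= 1L)
  structure(as.list(environment()), class = "doe_sim_params")
}

#' The study-condition effect scenario for recovery testing
#'
#' Main effects increasing with dose for IL-21, R848 and CD40 stimulation,
#' a null CpG, and an IL-21 x CD40 interaction; noise SD defaults to 25% of
#' the largest effect. Mirrors the qualitative outcome of the optimisation
#' screen (high IL-21 / high R848 / high CD40, CpG dropped).
#'
#' @param seed integer seed.
#' @param noise_sd noise SD; default `0.25 * 20`.
#' @return a [doe_sim_params()] object (attribute `nonnull_terms` lists the
#'   truly non-null ANOVA terms, attribute `best_levels` the injected
#'   optimum).
#' @export
doe_effects_scenario <- function(seed, noise_sd = 0.25 * 20) {
  inter <- matrix(0, 3, 3)
  inter[2, 2] <- 4; inter[3, 3] <- 8; inter[3, 2] <- 4; inter[2, 3] <- 4
  p <- doe_sim_params(
    grand_mean = 100,
    main_effects = list(IL21 = c(0, 10, 20), CpG = c(0, 0, 0),
                        R848 = c(0, 8, 16), CD40 = c(0, 9, 18)),
    interactions = list("IL21:CD40" = inter),
    donor_offsets = c(d1 = -5, d2 = 0, d3 = 5),
    noise_sd = noise_sd, replicates = 3L, seed = seed)
  attr(p, "nonnull_terms") <- c("IL21", "R848", "CD40", "IL21:CD40")
  attr(p, "best_levels") <- c(IL21 = "100", CpG = "0", R848 = "0.5", CD40 = "1:1")
  p
}

#' Simulate a balanced factorial response table
#'
#' Response = grand mean + per-factor main effects + pairwise interactions
#' + donor offset + Gaussian noise, replicated per design point per donor.
#'
#' @param design an [enumerate_design()] result.
#' @param params a [doe_sim_params()] object.
#' @return response table data.frame (`condition_id`, factor columns,
#'   `donor`, `replicate`, `isotype`, `response`) with the effect truth in
#'   `attr(, "params")`.
#' @export
simulate_doe_response <- function(design, params) {
  stopifnot(inherits(design, "factorial_design"),
            inherits(params, "doe_sim_params"))
  set.seed(derive_seed(params$seed, "doe-response"))
  factors <- attr(design, "factors")
  fnames <- vapply(factors, `[[`, character(1), "name")
  lv <- setNames(lapply(factors, `[[`, "levels"), fnames)

  for (f in names(params$main_effects))
    if (!f %in% fnames) stop("main effect for unknown factor: ", f)
  for (key in names(params$interactions)) {
    pr <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (!all(pr %in% fnames)) stop("interaction for unknown factors: ", key)
    if (!all(dim(params$interactions[[key]]) ==
             c(length(lv[[pr[1]]]), length(lv[[pr[2]]]))))
      stop("interaction matrix ", key, " has wrong dimensions")
  }

  donors <- names(params$donor_offsets)
  if (is.null(donors)) donors <- paste0("d", seq_along(params$donor_offsets))
  grid <- design[rep(seq_len(nrow(design)),
                     each = length(donors) * params$replicates), , drop = FALSE]
  grid$donor <- rep(rep(donors, each = params$replicates), nrow(design))
  grid$replicate <- rep(seq_len(params$replicates),
                        length(donors) * nrow(design))

  mu <- rep(params$grand_mean, nrow(grid))
  for (f in names(params$main_effects)) {
    eff <- params$main_effects[[f]]
    mu <- mu + eff[match(grid[[f]], lv[[f]])]
  }
  for (key in names(params$interactions)) {
    pr <- strsplit(key, ":", fixed = TRUE)[[1]]
    mm <- params$interactions[[key]]
    mu <- mu + mm[cbind(match(grid[[pr[1]]], lv[[pr[1]]]),
                        match(grid[[pr[2]]], lv[[pr[2]]]))]
  }
  mu <- mu + params$donor_offsets[match(grid$donor, donors)]

  out <- do.call(rbind, lapply(params$isotypes, function(iso) {
    g <- grid
    g$isotype <- iso
    g$response <- mu + rnorm(nrow(g), 0, params$noise_sd)
    g
  }))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  attr(out, "params") <- params
  attr(out, "factors") <- factors
  out
}
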