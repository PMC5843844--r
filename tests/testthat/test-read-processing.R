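test_that("median Phred filter applies the strict >34 rule", {
  cfg <- pipeline_config()
  expect_true(median_phred_filter(rep(40L, 100), cfg))
  expect_false(median_phred_filter(rep(34L, 99), cfg))          # exactly 34
  expect_false(median_phred_filter(c(30L, 33L, 35L, 40L), cfg)) # median 34.0
  expect_true(median_phred_filter(c(30L, 35L, 35L, 40L), cfg))  # median 35
  expect_true(median_phred_filter(qual_string(40, 10), cfg))    # ASCII form
  expect_error(median_phred_filter(integer(0), cfg), "empty")
})

test_that("pairs merge only on an identical overlap strictly longer than 50", {
  set.seed(14)
  mol <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
               collapse = "")
  fwd <- substr(mol, 1, 150)
  rev60 <- revcomp(substr(mol, 91, 240))    # 60 nt overlap
  q150 <- qual_string(38, 150)
  m <- merge_pairs(fwd, q150, rev60, q150)
  expect_equal(m$overlap, 60L)
  expect_equal(nchar(m$seq), 240L)
  expect_equal(m$seq, mol)

  ## exactly 50 identical: discarded by the strict rule
  rev50 <- revcomp(substr(mol, 101, 240))
  q140 <- qual_string(38, 140)
  expect_null(merge_pairs(fwd, q150, rev50, q140))

  ## one mismatch inside a 60 nt overlap: discarded ("identical" is literal)
  mm <- substr(mol, 91, 240)
  mid <- 30
  bad <- paste0(substr(mm, 1, mid - 1),
                setdiff(c("A", "C", "G", "T"), substr(mm, mid, mid))[1],
                substr(mm, mid + 1, 150))
  expect_null(merge_pairs(fwd, q150, revcomp(bad), q150))

  ## exhaustive-scan oracle agrees on the chosen overlap length
  rc <- substr(mol, 91, 240)
  oracle <- 0L
  for (ov in seq(min(150, 150), 51)) {
    if (substr(fwd, 150 - ov + 1, 150) == substr(rc, 1, ov)) {
      oracle <- ov; break
    }
  }
  expect_equal(m$overlap, oracle)

  ## overlap qualities take the per-position maximum
  qf <- paste0(qual_string(30, 90), qual_string(20, 60))
  qr <- paste0(qual_string(35, 60), qual_string(25, 90))  # rc order reverses
  m2 <- merge_pairs(fwd, qf, rev60, revcomp_qual <- paste(
    rev(strsplit(qr, "")[[1]]), collapse = ""))
  q <- utf8ToInt(m2$qual) - 33L
  expect_equal(q[91:150], rep(35L, 60))  # max(20, 35)
})

test_that("orientation is an involution and unlocatable handles are binned", {
  run <- small_run()
  amp <- run$truth$amplicon[1]
  q <- qual_string(38, nchar(amp))
  o1 <- orient_read(amp, q)
  expect_equal(o1$status, "oriented")
  expect_equal(o1$seq, amp)           # already V -> C: unchanged
  o2 <- orient_read(revcomp(amp), q)
  expect_equal(o2$seq, o1$seq)        # involution

  set.seed(3)
  rando <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  expect_equal(orient_read(rando, qual_string(38, 200))$status, "unassigned")

  sch <- igh_primer_scheme()
  chim <- paste0(sch$handle, rando, revcomp(sch$handle))
  expect_equal(orient_read(chim, qual_string(38, nchar(chim)))$status,
               "chimeric")
})

test_that("barcode extraction enforces the conserved-T template", {
  sch <- igh_primer_scheme()
  mk <- function(bc) revcomp(paste0(sch$handle, bc, "GACGACCACGTTCC"))
  ok <- extract_barcode(mk("ACGTTGGGGTAAAA"), sch)
  expect_equal(ok$status, "ok")
  expect_equal(ok$barcode, "ACGTTGGGGTAAAA")

  bad5 <- extract_barcode(mk("ACGTAGGGGTAAAA"), sch)   # position 5 = A
  expect_equal(bad5$status, "reject")
  bad10 <- extract_barcode(mk("ACGTTGGGGCAAAA"), sch)  # position 10 = C
  expect_equal(bad10$status, "reject")
  ambig <- extract_barcode(mk("ACGTTGGGGTAANA"), sch)
  expect_equal(ambig$status, "reject")

  short <- extract_barcode(revcomp(paste0(sch$handle, "ACGTTGGGGTAAA")), sch)
  expect_equal(short$status, "truncated")
})

test_that("isotype k-mer matching scores shared 10-mers against 50-bp prefixes", {
  refs <- toy_refs()
  cfg <- pipeline_config()
  ## read embedding an exact copy of the IGHM prefix: 41 shared 10-mers
  ighm <- refs$c$seq50[refs$c$isotype == "IGHM"]
  set.seed(21)
  pad <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  call <- assign_isotype(paste0(pad, ighm), refs, cfg)
  expect_equal(call$status, "ok")
  expect_equal(call$isotype, "IGHM")
  expect_equal(call$score, 41L)       # 50 - 10 + 1

  ## brute-force 10-mer set intersection oracle
  kmers <- function(x, k = 10) substring(x, 1:(nchar(x) - k + 1),
                                         k:nchar(x))
  oracle <- length(intersect(unique(kmers(paste0(pad, ighm))),
                             unique(kmers(ighm))))
  expect_equal(call$score, oracle)

  expect_equal(assign_isotype(pad, refs, cfg)$status, "ambiguous")
  expect_error(assign_isotype("ACGT", refs, cfg), "shorter than k")
})

test_that("primer and constant trimming recovers the simulated insert", {
  run <- small_run()
  refs <- run$refs
  cfg <- pipeline_config()
  for (i in c(1, 7, 20)) {
    amp <- run$truth$amplicon[i]
    q <- qual_string(38, nchar(amp))
    call <- assign_isotype(amp, refs, cfg)
    tr <- trim_primers(amp, q, refs, call, cfg)
    expect_equal(tr$status, "ok")
    expect_equal(tr$insert, run$truth$insert[i])
  }

  ## 3 mismatches in the FR1 primer exceed the allowance of 2
  amp <- run$truth$amplicon[1]
  mangled <- paste0("AAAAAAAAAA", substr(amp, 11, nchar(amp)))
  call <- assign_isotype(mangled, refs, cfg)
  expect_equal(trim_primers(mangled, qual_string(38, nchar(mangled)),
                            refs, call, cfg)$status, "no-primer")
})

test_that("barcode-group consensus applies the certainty rule", {
  cfg <- pipeline_config()
  s <- "ACGTACGTACGTACGTACGT"
  q <- qual_string(38, 20)
  same3 <- barcode_consensus(rep(s, 3), rep(q, 3), cfg)
  expect_equal(same3$certainty, 1.0)
  expect_equal(same3$consensus, s)
  expect_true(same3$retained)

  single <- barcode_consensus(s, q, cfg)
  expect_equal(single$support, 1L)
  expect_equal(single$certainty, 1.0)
  expect_true(single$retained)

  ## 4 members, one diverging at 30% of positions: brute-force oracle
  div <- s
  pos <- c(2, 5, 8, 11, 14, 17)                 # 6/20 = 30%
  for (p in pos) substr(div, p, p) <- "A"
  div <- gsub("AA", "AA", div)  # no-op; keep literal
  members <- c(rep(s, 3), div)
  res <- barcode_consensus(members, rep(q, 4), cfg)
  mat <- do.call(rbind, strsplit(members, ""))
  plur <- apply(mat, 2, function(col) max(table(col)) / length(col))
  expect_equal(res$certainty, mean(plur))
  expect_equal(res$consensus, s)                # plurality = majority here
  expect_equal(res$retained, mean(plur) > 0.80)

  ## 2 members disagreeing at one position: tie broken by summed Phred
  alt <- s; substr(alt, 3, 3) <- "T"
  qlow <- paste0(qual_string(38, 2), intToUtf8(20 + 33),
                 qual_string(38, 17))
  tie <- barcode_consensus(c(s, alt), c(q, qlow), cfg)
  expect_equal(substr(tie$consensus, 3, 3), substr(s, 3, 3))

  ## members far from the modal length are dropped before scoring
  longer <- paste0(s, "AAAAAAA")
  res2 <- barcode_consensus(c(s, s, longer), rep(q, 3), cfg)
  expect_equal(res2$support, 2L)

  expect_error(barcode_consensus(character(0), character(0), cfg), "empty")
})

test_that("the cascade conserves read counts and is orientation-invariant", {
  run <- small_run(seed = 23, n_clones = 8)
  res <- process_reads(run$reads$r1, run$reads$r2, run$refs)
  led <- res$ledger
  expect_equal(nrow(led), nrow(run$reads$r1))
  ## every read is exactly one of: rejected at a stage, or grouped
  expect_equal(sum(led$stage_reached %in%
                   c("quality", "merge", "orient", "barcode", "isotype",
                     "trim", "consensus", "grouped")), nrow(led))
  expect_equal(res$stage_counts[["input"]],
               sum(led$stage_reached != "input"))

  ## swapping R1/R2 (so each merged read comes out reverse-complemented
  ## before orientation) yields identical consensus records
  res_swapped <- process_reads(run$reads$r2, run$reads$r1, run$refs)
  a <- res$consensus[order(res$consensus$barcode), c("barcode", "isotype",
                                                     "sequence", "support")]
  b <- res_swapped$consensus[order(res_swapped$consensus$barcode),
                             c("barcode", "isotype", "sequence", "support")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
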