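## a hand-built minimal reference set for anchor/frame edge cases
tiny_refs <- function() {
  v <- data.frame(
    id = "Vtoy",
    seq = paste0("ATGGCCTCAGTGAAGGTCTCC",          # 21 nt, 7 codons
                 "GCTAGCGATCGATTTGCAACC",          # 7 distinct codons
                 "TGT"),                           # 2nd-CYS, last codon
    cys_start = 42L, primer_id = NA, primer_len = 0L,
    stringsAsFactors = FALSE)
  j <- data.frame(id = "Jtoy",
                  seq = paste0("GCAACGGTA", "TGG", "GGCCAAGGCACC"),
                  motif_start = 9L, stringsAsFactors = FALSE)
  j0 <- data.frame(id = "Jzero", seq = paste0("TGG", "GGCCAAGGCACCACT"),
                   motif_start = 0L, stringsAsFactors = FALSE)
  list(v = v, j = rbind(j, j0),
       c = data.frame(id = character(), isotype = character(),
                      seq50 = character(), tail = character()),
       scheme = igh_primer_scheme())
}

test_that("V assignment recovers the source allele and screens junk", {
  refs <- toy_refs()
  ## exact germline segment: self-match at 100%
  for (i in c(1, 4, 6)) {
    a <- assign_v_gene(refs$v$seq[i], refs)
    expect_equal(a$allele, refs$v$id[i])
    expect_equal(a$identity, 100)
  }

  ## 2% substitutions: same allele still wins on the divergent toy set
  set.seed(61)
  for (i in 1:6) {
    s <- refs$v$seq[i]
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(0.02 * length(ch)))
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    a <- assign_v_gene(paste(ch, collapse = ""), refs)
    expect_equal(a$allele, refs$v$id[i])
    expect_lt(a$identity, 100)
  }

  ## random sequence: rejected below the 80% / 100 nt rule
  set.seed(62)
  rando <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  expect_equal(assign_v_gene(rando, refs)$status, "reject")
  expect_error(assign_v_gene("ACGTA", refs), "shorter than seed")
})

test_that("identity agrees with the pairwise-alignment oracle", {
  refs <- toy_refs()
  set.seed(63)
  for (i in c(2, 5)) {
    s <- refs$v$seq[i]
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), 6)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    q <- paste(ch, collapse = "")
    a <- assign_v_gene(q, refs)
    pa <- Biostrings::pairwiseAlignment(q, refs$v$seq[i], type = "global")
    expect_equal(a$identity, Biostrings::pid(pa), tolerance = 1e-9)
  }
})

test_that("J assignment handles short segments and single substitutions", {
  refs <- toy_refs()
  j1 <- refs$j$seq[1]
  a <- assign_j_gene(j1, refs)
  expect_equal(a$allele, refs$j$id[1])
  expect_equal(a$identity, 100)

  ## one substitution in a 45-nt J context: identity 44/45
  j45 <- substr(j1, 1, 45)
  mut <- j45
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(j45, 30, 30))[1]
  am <- assign_j_gene(mut, refs)
  expect_equal(am$allele, refs$j$id[1])
  expect_equal(am$identity, 100 * 44 / 45, tolerance = 1e-9)

  set.seed(64)
  nojay <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  expect_equal(assign_j_gene(nojay, refs)$status, "reject")
})

test_that("reading-frame check catches stops and frame shifts", {
  refs <- tiny_refs()
  vseq <- refs$v$seq[1]; jseq <- refs$j$seq[1]
  good <- paste0(vseq, "GCTGCTGCT", jseq)      # in-frame 9-nt junction
  v <- assign_v_gene(good, refs, min_len = 40L)
  j <- assign_j_gene(good, refs, min_len = 20L)
  expect_true(check_reading_frame(good, v, j, refs))

  ## 1-nt deletion in the junction shifts the J phase
  shifted <- paste0(vseq, "GCTGCTGC", jseq)
  v2 <- assign_v_gene(shifted, refs, min_len = 40L)
  j2 <- assign_j_gene(shifted, refs, min_len = 20L)
  expect_false(check_reading_frame(shifted, v2, j2, refs))

  ## premature stop inside V (translate-and-scan oracle built the case)
  stopped <- good
  substr(stopped, 22, 24) <- "TAA"
  v3 <- assign_v_gene(stopped, refs, min_len = 40L)
  j3 <- assign_j_gene(stopped, refs, min_len = 20L)
  expect_false(check_reading_frame(stopped, v3, j3, refs))
})

test_that("SHM is the mismatch fraction outside the primer span", {
  refs <- toy_refs()
  vfull <- refs$v$seq[3]
  a <- assign_v_gene(vfull, refs)
  expect_equal(compute_shm(vfull, a, refs), 0)

  ## 6 substitutions over the 269 eligible positions
  set.seed(65)
  eligible <- (refs$v$primer_len[3] + 1):nchar(vfull)
  pos <- sample(eligible, 6)
  ch <- strsplit(vfull, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  mut <- paste(ch, collapse = "")
  am <- assign_v_gene(mut, refs)
  expect_equal(compute_shm(mut, am, refs), 100 * 6 / 269, tolerance = 1e-9)

  ## mutations inside the primer span are excluded
  ch2 <- strsplit(vfull, "")[[1]]
  ch2[3] <- setdiff(c("A", "C", "G", "T"), ch2[3])[1]
  prim <- paste(ch2, collapse = "")
  ap <- assign_v_gene(prim, refs)
  expect_equal(compute_shm(prim, ap, refs), 0)
})

test_that("CDRH3 length is anchor-exclusive and undefined without anchors", {
  refs <- tiny_refs()
  vseq <- refs$v$seq[1]
  ## 45-nt junction insert + the 9 pre-anchor J nt = 54 nt CDRH3
  ins <- paste(rep("GCT", 15), collapse = "")
  s <- paste0(vseq, ins, refs$j$seq[1])
  v <- assign_v_gene(s, refs, min_len = 40L)
  j <- assign_j_gene(s, refs, min_len = 20L)
  expect_equal(find_cdrh3(s, v, j, refs), 45L + 9L)

  ## brute-force anchor-scan oracle
  q_cys <- refs$v$cys_start[1] + v$offset
  q_mot <- refs$j$motif_start[refs$j$id == j$allele] + j$offset
  expect_equal(find_cdrh3(s, v, j, refs), q_mot - (q_cys + 3L))

  ## anchors directly adjacent: zero-length CDRH3
  s0 <- paste0(vseq, refs$j$seq[refs$j$id == "Jzero"])
  v0 <- assign_v_gene(s0, refs, min_len = 40L)
  j0 <- assign_j_gene(s0, refs, min_len = 15L)
  expect_equal(find_cdrh3(s0, v0, j0, refs), 0L)

  ## J motif mutated away: undefined
  sm <- s
  substr(sm, nchar(vseq) + 45 + 10, nchar(vseq) + 45 + 12) <- "AAA"
  vm <- assign_v_gene(sm, refs, min_len = 40L)
  jm <- assign_j_gene(sm, refs, min_len = 20L)
  expect_true(is.na(find_cdrh3(sm, vm, jm, refs)))
})

test_that("annotation is deterministic and recovers simulated truth", {
  run <- small_run(seed = 33, n_clones = 12)
  refs <- run$refs
  seqs <- setNames(run$truth$insert, run$truth$molecule_id)
  r1 <- annotate_sequences(seqs, refs)
  r2 <- annotate_sequences(seqs, refs)
  expect_identical(r1, r2)

  expect_equal(r1$v_call, run$truth$v_call)
  expect_equal(r1$j_call, run$truth$j_call)
  defined <- !is.na(r1$junction_length_nt)
  expect_equal(r1$junction_length_nt[defined], run$truth$cdrh3_nt[defined])
  expect_equal(r1$shm_pct, 100 * run$truth$n_mut / 269, tolerance = 1e-9)
})

test_that("mean SHM increases strictly with the injected mutation rate", {
  refs <- toy_refs()
  means <- vapply(c(0, 0.01, 0.03), function(rate) {
    p <- repertoire_sim_params(n_clones = 60, molecules_per_clone = 1L,
                               shm_rate = rate, error_rate = 0,
                               reads_per_molecule = 1L, seed = 71)
    tr <- simulate_repertoire(p, refs)
    ann <- annotate_sequences(setNames(tr$insert, tr$molecule_id), refs)
    mean(ann$shm_pct)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(means[1], 0)
})
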