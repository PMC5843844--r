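## Shared fixtures, built in code. The toy reference set is deterministic
## per seed and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

toy_refs <- function(seed = 42) {
  key <- paste0("refs", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_toy_references(seed = seed)
  .fixture_cache[[key]]
}

## a small balanced 3^4 response table with random effects, for oracles
random_response_table <- function(seed, replicates = 2L, donors = 2L) {
  des <- enumerate_design(mbc_expansion_factors())
  set.seed(seed)
  p <- doe_sim_params(
    grand_mean = 50,
    main_effects = list(IL21 = rnorm(3, 0, 5), CpG = rnorm(3, 0, 5),
                        R848 = rnorm(3, 0, 5), CD40 = rnorm(3, 0, 5)),
    interactions = list("IL21:CD40" = matrix(rnorm(9, 0, 2), 3, 3),
                        "CpG:R848" = matrix(rnorm(9, 0, 2), 3, 3)),
    donor_offsets = setNames(rnorm(donors, 0, 3), paste0("d", seq_len(donors))),
    noise_sd = 4, replicates = replicates, seed = seed)
  simulate_doe_response(des, p)
}

## independent sum-of-squares oracle via stats::aov (balanced data:
## sequential SS are order-independent and equal the mean-based SS)
aov_ss_oracle <- function(table, with_donor = TRUE) {
  df <- data.frame(y = table$response,
                   IL21 = factor(table$IL21), CpG = factor(table$CpG),
                   R848 = factor(table$R848), CD40 = factor(table$CD40))
  form <- y ~ IL21 + CpG + R848 + CD40 +
    IL21:CpG + IL21:R848 + IL21:CD40 + CpG:R848 + CpG:CD40 + R848:CD40
  if (with_donor) {
    df$donor <- factor(table$donor)
    form <- stats::update(form, . ~ . + donor)
  }
  fit <- stats::aov(form, data = df)
  s <- summary(fit)[[1]]
  ss <- s[["Sum Sq"]]
  names(ss) <- trimws(rownames(s))
  p <- s[["Pr(>F)"]]
  names(p) <- trimws(rownames(s))
  list(ss = ss, p = p)
}

## a tiny error-free sequencing run, shared by several files
small_run <- function(seed = 11, n_clones = 15, reads = 3) {
  params <- repertoire_sim_params(
    n_clones = n_clones, molecules_per_clone = 2L,
    reads_per_molecule = reads, error_rate = 0, shm_rate = 0.02,
    seed = seed)
  refs <- toy_refs()
  truth <- simulate_repertoire(params, refs)
  reads <- simulate_reads(truth, params)
  list(params = params, refs = refs, truth = truth, reads = reads)
}

## ASCII quality string for a constant Phred value
qual_string <- function(q, n) paste(rep(intToUtf8(q + 33L), n), collapse = "")
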