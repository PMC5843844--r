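## End-to-end orchestration with run manifests. Stage order is fixed to the
## library-processing cascade: quality filter -> merge -> orient -> barcode
## -> isotype -> trim -> consensus -> frame / V-J similarity screen.

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the repertoire pipeline end to end
#'
#' Reads paired FASTQ (or takes in-memory read tables), runs the full
#' processing cascade, annotates the retained consensus sequences, applies
#' the frame / V-J similarity screen, and writes consensus FASTA, per-read
#' ledger, rearrangement TSV and a run manifest into `outdir`. Re-running
#' with identical inputs and configuration reproduces identical outputs.
#'
#' @param r1,r2 FASTQ paths or read data.frames (`id`, `seq`, `qual`).
#' @param refs germline reference set.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return list with `processing` ([process_reads()] result),
#'   `rearrangements` (annotation table), `manifest`, `paths`.
#' @export
run_repertoire_pipeline <- function(r1, r2, refs, outdir,
                                    config = pipeline_config()) {
  inputs <- character(0)
  if (is.character(r1)) {
    if (!file.exists(r1) || !file.exists(r2)) stop("missing input FASTQ")
    inputs <- c(r1, r2)
    r1 <- read_fastq(r1); r2 <- read_fastq(inputs[2])
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  proc <- process_reads(r1, r2, refs, config)
  paths <- write_processing_result(proc, outdir)

  rearr <- if (nrow(proc$consensus) > 0)
    annotate_sequences(proc$consensus, refs)
  else
    data.frame(sequence_id = character(), c_call = character(),
               v_call = character(), j_call = character(),
               v_identity = numeric(), j_identity = numeric(),
               productive = logical(), shm_pct = numeric(),
               junction_length_nt = integer(), filtered = logical())
  rpath <- file.path(outdir, "rearrangements.tsv")
  write_rearrangements(rearr, rpath)

  manifest <- list(
    tool = "ighdoe", version = as.character(utils::packageVersion("ighdoe")),
    config_hash = config_hash(config),
    input_checksums = file_checksums(inputs),
    stage_counts = as.list(proc$stage_counts),
    annotation = list(
      consensus_in = nrow(proc$consensus),
      v_j_retained = sum(!rearr$filtered),
      productive = sum(rearr$productive)
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  mpath <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  list(processing = proc, rearrangements = rearr, manifest = manifest,
       paths = c(paths, rearrangements = rpath, manifest = mpath))
}

#' Run the factorial analysis end to end
#'
#' Reads a response table CSV (or takes a data.frame), runs the variance
#' decomposition per isotype, computes sensitivity indices, marginal means
#' and the optimal condition, and writes a TSV report, an optimal-condition
#' JSON and a run manifest into `outdir`.
#'
#' @param responses CSV path or response data.frame.
#' @param factors list of [doe_factor()] objects (defaults to the four
#'   expansion stimulants, [mbc_expansion_factors()]).
#' @param outdir output directory.
#' @param max_order interaction order (default 2).
#' @param alpha significance level for optimal-condition selection.
#' @param block_donor model donor as an additive block (default `TRUE`).
#' @return list with per-isotype `reports` (sensitivity data.frames),
#'   `optimal` (per isotype), `manifest`, `paths`.
#' @export
run_doe_analysis <- function(responses, factors = mbc_expansion_factors(),
                             outdir, max_order = 2, alpha = 0.05,
                             block_donor = TRUE) {
  inputs <- character(0)
  if (is.character(responses)) {
    if (!file.exists(responses)) stop("missing response table")
    inputs <- responses
    responses <- read_response_table(responses)
  }
  if (nrow(responses) == 0L) stop("empty response table")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (!all(fnames %in% names(responses)))
    stop("response table lacks factor column(s): ",
         paste(setdiff(fnames, names(responses)), collapse = ", "))
  isotypes <- if ("isotype" %in% names(responses))
    unique(responses$isotype) else "total"

  reports <- list(); optimal <- list(); paths <- character(0)
  for (iso in isotypes) {
    tab <- if ("isotype" %in% names(responses))
      responses[responses$isotype == iso, , drop = FALSE] else responses
    dec <- anova_decompose(tab, max_order = max_order,
                           include_donor_block = block_donor)
    rep_i <- sensitivity_indices(dec)
    marg <- setNames(lapply(fnames, function(f) marginal_means(tab, f)), fnames)
    opt <- select_optimal(rep_i, marg, factors, alpha = alpha)
    tsv <- file.path(outdir, paste0("sensitivity_", iso, ".tsv"))
    write_sensitivity_report(rep_i, tsv, optimal = opt)
    reports[[iso]] <- rep_i; optimal[[iso]] <- opt
    paths <- c(paths, tsv)
  }
  manifest <- list(
    tool = "ighdoe", version = as.character(utils::packageVersion("ighdoe")),
    config_hash = config_hash(list(max_order = max_order, alpha = alpha,
                                   block_donor = block_donor,
                                   factors = fnames)),
    input_checksums = file_checksums(inputs),
    rows = nrow(responses), isotypes = isotypes,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  mpath <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  list(reports = reports, optimal = optimal, manifest = manifest,
       paths = c(paths, manifest = mpath))
}
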