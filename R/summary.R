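#' Isotype composition of a sample
#'
#' Fraction of records assigned to each IgH class: the per-sample
#' percentage-of-reads view of repertoire isotype structure.
#'
#' @param records data.frame with a `c_call` column of isotype labels
#'   (e.g. an [annotate_sequences()] rearrangement table).
#' @param isotypes optional label set to report over (absent classes get
#'   fraction 0); defaults to the classes observed.
#' @param collapse_by optional column name (e.g. `"clone_id"`): records are
#'   deduplicated on it before counting, giving a clonality-aware
#'   composition instead of the default percentage-of-reads view.
#' @return data.frame with `isotype`, `count`, `fraction` (fractions sum
#'   to 1).
#' @export
isotype_composition <- function(records, isotypes = NULL, collapse_by = NULL) {
  if (!is.null(collapse_by))
    records <- records[!duplicated(records[[collapse_by]]), , drop = FALSE]
  if (nrow(records) == 0L) stop("empty sample")
  calls <- records$c_call
  if (is.null(isotypes)) isotypes <- sort(unique(calls))
  cnt <- vapply(isotypes, function(i) sum(calls == i), integer(1))
  data.frame(isotype = isotypes, count = cnt, fraction = cnt / sum(cnt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' SHM trajectory across culture timepoints
#'
#' Per-day mean and dispersion of the V-segment SHM percentage, plus the
#' final-minus-baseline difference in means with a seeded bootstrap
#' confidence interval. A CI covering zero is the computational face of
#' "SHM did not increase during culture".
#'
#' @param records data.frame with `day` (numeric) and `shm_pct` columns.
#' @param nboot bootstrap resamples for the difference CI (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return list with `per_day` (data.frame `day`, `n`, `mean`, `sd`),
#'   `diff` (last-day mean minus first-day mean), `ci` (length-2 vector).
#' @export
shm_trajectory <- function(records, nboot = 10000L, conf = 0.95, seed = 1L) {
  stopifnot(all(c("day", "shm_pct") %in% names(records)))
  records <- records[!is.na(records$shm_pct), , drop = FALSE]
  days <- sort(unique(records$day))
  if (length(days) < 2L) stop("need records from at least two timepoints")
  per_day <- do.call(rbind, lapply(days, function(d) {
    x <- records$shm_pct[records$day == d]
    if (length(x) == 0L) stop("no records for day ", d)
    data.frame(day = d, n = length(x), mean = mean(x), sd = sd(x))
  }))
  x0 <- records$shm_pct[records$day == days[1]]
  x1 <- records$shm_pct[records$day == days[length(days)]]
  dobs <- mean(x1) - mean(x0)
  set.seed(derive_seed(seed, "shm-bootstrap"))
  boot <- vapply(seq_len(nboot), function(b) {
    mean(sample(x1, length(x1), replace = TRUE)) -
      mean(sample(x0, length(x0), replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(per_day = per_day, diff = dobs,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))))
}

#' CDRH3 length density
#'
#' Normalised histogram of CDRH3 nucleotide lengths in 3-nt (codon) bins;
#' the fraction of records with undefined CDRH3 (missing anchors) is
#' reported separately and excluded from the histogram mass.
#'
#' @param records data.frame with a `junction_length_nt` column.
#' @param binwidth bin width in nt (default 3).
#' @return list with `density` (data.frame `length_nt` bin start, `count`,
#'   `density` summing to 1) and `undefined_fraction`.
#' @export
cdrh3_density <- function(records, binwidth = 3L) {
  lens <- records$junction_length_nt
  undef <- mean(is.na(lens))
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0L) stop("no defined CDRH3 lengths")
  bins <- (lens %/% binwidth) * binwidth
  tab <- table(bins)
  data <- data.frame(length_nt = as.integer(names(tab)),
                     count = as.integer(tab),
                     density = as.integer(tab) / length(lens))
  list(density = data, undefined_fraction = undef)
}

#' Isotype composition stability between two timepoints
#'
#' Total-variation distance between the two isotype fraction vectors plus a
#' chi-square homogeneity test on the underlying counts: a formal version
#' of "the subsets remained within their relative proportions over
#' culture".
#'
#' @param comp0,comp1 [isotype_composition()] data.frames for the two
#'   timepoints (any isotype absent from one side is treated as count 0).
#' @return list with `tvd`, `statistic`, `df`, `p_value`.
#' @export
composition_stability <- function(comp0, comp1) {
  isotypes <- union(comp0$isotype, comp1$isotype)
  c0 <- setNames(rep(0L, length(isotypes)), isotypes)
  c1 <- c0
  c0[comp0$isotype] <- comp0$count
  c1[comp1$isotype] <- comp1$count
  if (sum(c0) == 0L || sum(c1) == 0L) stop("empty composition")
  p0 <- c0 / sum(c0); p1 <- c1 / sum(c1)
  tvd <- sum(abs(p0 - p1)) / 2
  keep <- (c0 + c1) > 0
  m <- rbind(c0[keep], c1[keep])
  if (sum(keep) < 2L) {
    return(list(tvd = tvd, statistic = 0, df = 0L, p_value = 1))
  }
  ## Pearson chi-square homogeneity test, no continuity correction
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expd)^2 / expd)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(tvd = tvd, statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-sample repertoire summary
#'
#' Aggregates rearrangement records by sample key (any of `subset`, `day`,
#' `donor` present in the records or supplied via a manifest join) into
#' isotype fractions, SHM summaries and CDRH3 histograms.
#'
#' @param records rearrangement data.frame; rows with `filtered == TRUE`
#'   are dropped first when that column is present.
#' @param by character vector of grouping columns present in `records`
#'   (default: whichever of `subset`, `day`, `donor` exist).
#' @return data.frame with one row per group x isotype for fractions and
#'   attached attributes `shm` (per-group mean/sd) and `cdrh3`
#'   (per-group histograms).
#' @export
summarize_repertoire <- function(records, by = NULL) {
  if (!is.null(records$filtered)) records <- records[!records$filtered, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records to summarize")
  if (is.null(by)) by <- intersect(c("subset", "day", "donor"), names(records))
  key <- if (length(by)) do.call(paste, c(records[by], sep = "|")) else
    rep("all", nrow(records))
  groups <- split(seq_len(nrow(records)), key)
  frac <- do.call(rbind, lapply(names(groups), function(g) {
    comp <- isotype_composition(records[groups[[g]], , drop = FALSE])
    cbind(group = g, comp, stringsAsFactors = FALSE)
  }))
  shm <- do.call(rbind, lapply(names(groups), function(g) {
    x <- records$shm_pct[groups[[g]]]
    x <- x[!is.na(x)]
    data.frame(group = g, n = length(x),
               mean_shm = if (length(x)) mean(x) else NA_real_,
               sd_shm = if (length(x) > 1) sd(x) else NA_real_)
  }))
  cdr <- lapply(groups, function(ix) {
    r <- records[ix, , drop = FALSE]
    if (all(is.na(r$junction_length_nt))) NULL else cdrh3_density(r)
  })
  structure(frac, shm = shm, cdrh3 = cdr, row.names = NULL)
}
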