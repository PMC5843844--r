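## Balanced N-way decomposition of a factorial response table.
##
## All sums of squares are computed directly from marginal and cell means,
## which on a balanced full factorial is an orthogonal decomposition:
##   SS_f  = sum_l n_l (mean_l - grand)^2                   (first order)
##   SS_fg = sum_cells n_c (mean_c - grand)^2 - SS_f - SS_g (second order)
## Interactions of order > 2 (and any donor x factor structure) are pooled
## into the residual.

factor_columns <- function(table) {
  reserved <- c("condition_id", "donor", "replicate", "isotype", "response")
  setdiff(names(table), reserved)
}

check_response_table <- function(table, factors = NULL) {
  stopifnot(is.data.frame(table))
  if (!"response" %in% names(table)) stop("table needs a 'response' column")
  if (nrow(table) == 0L) stop("empty response table")
  if (any(!is.finite(table$response))) stop("responses must be finite")
  fcols <- if (is.null(factors)) factor_columns(table) else factors
  if (length(fcols) == 0L) stop("no factor columns found")
  if (!all(fcols %in% names(table))) {
    stop("factor column(s) absent: ",
         paste(setdiff(fcols, names(table)), collapse = ", "))
  }
  fcols
}

single_isotype <- function(table, isotype) {
  if (!"isotype" %in% names(table)) return(table)
  if (!is.null(isotype)) {
    table <- table[table$isotype == isotype, , drop = FALSE]
    if (nrow(table) == 0L) stop("no rows for isotype ", isotype)
  } else if (length(unique(table$isotype)) > 1L) {
    stop("table contains multiple isotypes; pass `isotype =` to pick one")
  }
  table
}

#' Marginal mean response per factor level
#'
#' For each level of the named stimulant, the mean response over all rows at
#' that level while every other stimulant varies over its full grid -- the
#' quantity the factorial screen reads as "the mean Ig detected while factor
#' x remains constant". On a balanced table the mean of the marginals equals
#' the grand mean.
#'
#' @param table a response table (see [read_response_table()]): factor
#'   columns plus `donor`, `replicate`, optional `isotype`, and `response`.
#' @param factor name of the factor column to marginalise on.
#' @return data.frame with columns `level`, `isotype`, `mean`, `n`; levels
#'   appear in their order of first appearance in the table.
#' @export
marginal_means <- function(table, factor) {
  check_response_table(table, factors = factor)
  iso <- if ("isotype" %in% names(table)) table$isotype else "total"
  lev <- table[[factor]]
  key <- paste(iso, lev, sep = "\r")
  m <- tapply(table$response, key, mean)
  n <- tapply(table$response, key, length)
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  out <- data.frame(level = parts[, 2], isotype = parts[, 1],
                    mean = as.numeric(m), n = as.integer(n),
                    stringsAsFactors = FALSE)
  ## preserve encounter order of levels and isotypes
  out <- out[order(match(out$isotype, unique(iso)),
                   match(out$level, unique(lev))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose response variance over a balanced factorial design
#'
#' Computes first-order (per-stimulant) and second-order (stimulant-pair)
#' sums of squares from level and cell means of a balanced full factorial
#' response table, with an optional additive donor block. Higher-order
#' interactions are pooled into the residual, whose mean square is the
#' denominator of every F statistic.
#'
#' @param table response table restricted to one isotype (or pass
#'   `isotype`); must be balanced (equal replication in every full
#'   factor-by-donor cell).
#' @param max_order 1 or 2; order of interaction terms to extract.
#' @param include_donor_block include `donor` as an additive block term
#'   (default `TRUE` when a donor column is present).
#' @param isotype optional isotype to select from a multi-isotype table.
#' @param log_transform analyse `log(response)` instead of the raw readout
#'   (default `FALSE`: the raw Ig scale).
#' @return object of class `anova_decomposition`: a data.frame of terms
#'   (`term`, `order`, `ss`, `df`, `f`, `p`) with attributes `ss_total`,
#'   `df_total`, `degenerate`.
#' @examples
#' tab <- simulate_doe_response(enumerate_design(mbc_expansion_factors()),
#'                              doe_sim_params(seed = 1))
#' anova_decompose(tab, isotype = "total")
#' @export
anova_decompose <- function(table, max_order = 2, include_donor_block = TRUE,
                            isotype = NULL, log_transform = FALSE) {
  table <- single_isotype(table, isotype)
  if (log_transform) {
    if (any(table$response <= 0))
      stop("log transform requires strictly positive responses")
    table$response <- log(table$response)
  }
  fcols <- check_response_table(table)
  if (!max_order %in% 1:2) stop("max_order must be 1 or 2")
  has_donor <- "donor" %in% names(table) && include_donor_block &&
    length(unique(table$donor)) > 1L

  ## balance check: every full factorial (x donor) cell equally replicated
  cell_key <- do.call(paste, c(table[fcols],
                               if (has_donor) list(table$donor), sep = "\r"))
  n_levels <- vapply(fcols, function(f) length(unique(table[[f]])), integer(1))
  n_cells_expected <- prod(n_levels) * (if (has_donor) length(unique(table$donor)) else 1L)
  counts <- table(cell_key)
  if (length(counts) != n_cells_expected || length(unique(as.integer(counts))) != 1L)
    stop("unbalanced table: unequal replication across design cells")

  y <- table$response
  n <- length(y)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  df_total <- n - 1L

  ss_group <- function(key) {
    m <- tapply(y, key, mean)
    cnt <- tapply(y, key, length)
    sum(cnt * (m - grand)^2)
  }

  terms <- list()
  add_term <- function(term, order, ss, df) {
    terms[[length(terms) + 1L]] <<- data.frame(
      term = term, order = order, ss = ss, df = df, stringsAsFactors = FALSE)
  }

  for (f in fcols)
    add_term(f, 1L, ss_group(table[[f]]), length(unique(table[[f]])) - 1L)
  main_ss <- setNames(vapply(terms, function(t) t$ss, numeric(1)),
                      vapply(terms, function(t) t$term, character(1)))

  if (max_order >= 2 && length(fcols) >= 2) {
    for (i in seq_len(length(fcols) - 1L)) {
      for (j in seq(i + 1L, length(fcols))) {
        f <- fcols[i]; g <- fcols[j]
        ss_cells <- ss_group(paste(table[[f]], table[[g]], sep = "\r"))
        ss_int <- max(ss_cells - main_ss[[f]] - main_ss[[g]], 0)
        add_term(paste0(f, ":", g), 2L, ss_int,
                 (length(unique(table[[f]])) - 1L) *
                   (length(unique(table[[g]])) - 1L))
      }
    }
  }

  if (has_donor)
    add_term("donor", 1L, ss_group(table$donor),
             length(unique(table$donor)) - 1L)

  tab <- do.call(rbind, terms)
  ss_res <- max(ss_total - sum(tab$ss), 0)
  df_res <- df_total - sum(tab$df)
  if (df_res < 0L) stop("model degrees of freedom exceed total")
  tab <- rbind(tab, data.frame(term = "residual", order = NA_integer_,
                               ss = ss_res, df = df_res))

  degenerate <- ss_total <= 0
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  tab$f <- ifelse(tab$term == "residual", NA_real_,
                  if (!is.na(ms_res) && ms_res > 0) (tab$ss / tab$df) / ms_res
                  else NA_real_)
  tab$p <- ifelse(is.na(tab$f), NA_real_,
                  pf(tab$f, tab$df, df_res, lower.tail = FALSE))
  if (degenerate) { tab$f <- NA_real_; tab$p <- NA_real_ }

  rownames(tab) <- NULL
  structure(tab, ss_total = ss_total, df_total = df_total,
            degenerate = degenerate,
            class = c("anova_decomposition", "data.frame"))
}

#' Sensitivity indices from a variance decomposition
#'
#' The sensitivity index of a term is its share of total response variance,
#' `SS_term / SS_total` (an eta-squared): first-order indices for single
#' stimulants, second-order indices for stimulant pairs. Indices plus the
#' residual fraction sum to one. On a degenerate table (zero total variance)
#' all indices are 0 by convention and the report is flagged.
#'
#' @param decomp an [anova_decompose()] result.
#' @return object of class `sensitivity_report`: data.frame of terms with
#'   `index`, full-precision `p`, and a 4-decimal `p_display` column;
#'   attribute `degenerate`.
#' @export
sensitivity_indices <- function(decomp) {
  stopifnot(inherits(decomp, "anova_decomposition"))
  ss_total <- attr(decomp, "ss_total")
  degenerate <- attr(decomp, "degenerate")
  idx <- if (degenerate) rep(0, nrow(decomp)) else decomp$ss / ss_total
  out <- data.frame(term = decomp$term, order = decomp$order,
                    ss = decomp$ss, df = decomp$df, f = decomp$f,
                    p = decomp$p, index = idx,
                    p_display = round(decomp$p, 4),
                    stringsAsFactors = FALSE)
  structure(out, degenerate = degenerate, ss_total = ss_total,
            class = c("sensitivity_report", "data.frame"))
}

#' Select the optimal stimulation condition
#'
#' For each stimulant whose first-order effect is significant at `alpha`,
#' pick the dose level maximising its marginal mean response; stimulants
#' without a significant first-order effect are set to their lowest dose
#' (the rule under which CpG, with no detectable effect on Ig secretion,
#' drops to zero). Ties in the marginal means break toward the lower dose.
#'
#' @param report a [sensitivity_indices()] report (first-order p-values are
#'   read from it).
#' @param marginals named list: for each factor, its [marginal_means()]
#'   data.frame. Multi-isotype marginals are averaged across isotypes.
#' @param factors list of [doe_factor()] objects giving dose order.
#' @param alpha significance level for the first-order test (default 0.05).
#' @return object of class `optimal_condition`: data.frame with `factor`,
#'   `level`, `rationale` (`"significant-max"` or `"default-lowest"`), `p`.
#' @export
select_optimal <- function(report, marginals, factors, alpha = 0.05) {
  stopifnot(inherits(report, "sensitivity_report"))
  if (inherits(factors, "doe_factor")) factors <- list(factors)
  rows <- lapply(factors, function(f) {
    p <- report$p[report$term == f$name & report$order %in% 1L]
    if (length(p) != 1L) stop("no first-order term for factor ", f$name)
    significant <- !is.na(p) && p < alpha
    if (significant) {
      mm <- marginals[[f$name]]
      if (is.null(mm)) stop("missing marginal means for significant factor ",
                            f$name)
      agg <- tapply(mm$mean, mm$level, mean)  # average across isotypes
      agg <- agg[f$levels]                    # dose order, low to high
      if (anyNA(agg)) stop("marginals for ", f$name, " lack some levels")
      best <- f$levels[which.max(agg)]        # which.max takes first = lower dose on ties
      data.frame(factor = f$name, level = best, rationale = "significant-max",
                 p = p, stringsAsFactors = FALSE)
    } else {
      data.frame(factor = f$name, level = f$levels[1L],
                 rationale = "default-lowest", p = p, stringsAsFactors = FALSE)
    }
  })
  structure(do.call(rbind, rows),
            alpha = alpha, class = c("optimal_condition", "data.frame"))
}

#' Two-way ANOVA with Tukey's post-hoc test
#'
#' Convenience wrapper fitting a two-way (crossed) ANOVA and running Tukey's
#' honestly-significant-difference comparisons on each factor, the
#' comparison used for final condition-versus-condition readouts.
#'
#' @param data data.frame with a numeric response and two grouping columns.
#' @param response,factor1,factor2 column names.
#' @param interaction include the interaction term when replication allows
#'   (default `TRUE`).
#' @return list with `anova` (the ANOVA table) and `tukey` (a named list of
#'   data.frames of pairwise comparisons: `diff`, `lwr`, `upr`, `p_adj`).
#' @export
two_way_anova_tukey <- function(data, response = "response",
                                factor1, factor2, interaction = TRUE) {
  stopifnot(all(c(response, factor1, factor2) %in% names(data)))
  g1 <- factor(data[[factor1]]); g2 <- factor(data[[factor2]])
  if (nlevels(g1) < 2L || nlevels(g2) < 2L) stop("each factor needs >= 2 groups")
  cnt <- table(g1, g2)
  if (any(cnt == 0L)) stop("empty factor combination")
  if (min(table(g1)) < 2L || min(table(g2)) < 2L)
    stop("each group needs >= 2 observations")
  df <- data.frame(y = data[[response]], f1 = g1, f2 = g2)
  form <- if (interaction && all(cnt >= 2L)) y ~ f1 * f2 else y ~ f1 + f2
  fit <- aov(form, data = df)
  tk <- TukeyHSD(fit, which = c("f1", "f2"))
  tidy_tk <- lapply(tk, function(m) {
    out <- as.data.frame(m)
    names(out) <- c("diff", "lwr", "upr", "p_adj")
    out$comparison <- rownames(m); rownames(out) <- NULL
    out[, c("comparison", "diff", "lwr", "upr", "p_adj")]
  })
  names(tidy_tk) <- c(factor1, factor2)
  list(anova = summary(fit)[[1]], tukey = tidy_tk)
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf("Balanced factorial decomposition (SS_total = %.4g%s)\n",
              attr(x, "ss_total"),
              if (attr(x, "degenerate")) ", degenerate" else ""))
  NextMethod()
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity indices (SS_term / SS_total)",
      if (attr(x, "degenerate")) "[degenerate: zero total variance]" else "",
      "\n")
  df <- as.data.frame(x)
  df$p <- NULL  # show the 4-decimal display column only
  print(df, ...)
  invisible(x)
}

#' @export
print.optimal_condition <- function(x, ...) {
  cat(sprintf("Optimal condition (alpha = %g)\n", attr(x, "alpha")))
  NextMethod()
}

#' Read / write factorial response tables
#'
#' CSV interchange format: `condition_id`, one column per factor, `donor`,
#' `replicate`, `isotype`, `response`.
#'
#' @param path file path.
#' @param table a response table data.frame.
#' @return `read_response_table` returns a data.frame;
#'   `write_response_table` returns `path` invisibly.
#' @export
read_response_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!"response" %in% names(tab)) stop("no 'response' column in ", path)
  tab$response <- as.numeric(tab$response)
  tab
}

#' @rdname read_response_table
#' @export
write_response_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sensitivity report as TSV (plus optional JSON optimal condition)
#'
#' @param report a [sensitivity_indices()] result.
#' @param path output TSV path.
#' @param optimal optional [select_optimal()] result; written as JSON next
#'   to `path` (extension `.optimal.json`).
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path, optimal = NULL) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(optimal)) {
    jpath <- paste0(sub("\\.tsv$", "", path), ".optimal.json")
    jsonlite::write_json(
      list(alpha = attr(optimal, "alpha"),
           condition = setNames(as.list(optimal$level), optimal$factor),
           rationale = setNames(as.list(optimal$rationale), optimal$factor)),
      jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
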