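#' Define a design factor
#'
#' A factor is a named stimulant with an ordered set of dose levels. Level
#' order is meaningful: the first level is the lowest dose, which is the
#' fallback level for non-significant factors in [select_optimal()].
#'
#' @param name factor name, e.g. `"IL21"`.
#' @param levels character vector of unique level labels, lowest dose first.
#' @param doses optional numeric doses matching `levels`.
#' @param units optional dose units, e.g. `"ng/ml"`.
#' @return an object of class `doe_factor`.
#' @export
doe_factor <- function(name, levels, doses = NULL, units = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("factor '", name, "' must have at least 2 levels")
  if (anyDuplicated(levels))
    stop("factor '", name, "' has duplicated level labels")
  if (!is.null(doses) && length(doses) != length(levels))
    stop("doses must match levels in length")
  structure(list(name = name, levels = levels, doses = doses, units = units),
            class = "doe_factor")
}

#' The memory B cell expansion factors at their factorial doses
#'
#' The four stimulation factors varied in the expansion optimisation, each
#' at three dose levels (low, intermediate, high): IL-21 at 10/50/100 ng/ml,
#' CpG ODN2006 at 0/0.25/1 ug/ml, R848 at 0/0.25/0.5 ug/ml, and CD40
#' stimulation delivered as CD40L-expressing feeder (HV13280) cells at
#' 1:5 / 1:2 / 1:1 feeder-to-memory-B-cell ratios.
#'
#' @return list of four [doe_factor()] objects.
#' @export
mbc_expansion_factors <- function() {
  list(
    doe_factor("IL21", c("10", "50", "100"), doses = c(10, 50, 100), units = "ng/ml"),
    doe_factor("CpG",  c("0", "0.25", "1"),  doses = c(0, 0.25, 1),  units = "ug/ml"),
    doe_factor("R848", c("0", "0.25", "0.5"), doses = c(0, 0.25, 0.5), units = "ug/ml"),
    doe_factor("CD40", c("1:5", "1:2", "1:1"), doses = c(0.2, 0.5, 1), units = "feeder:MBC ratio")
  )
}

#' Enumerate a full factorial design
#'
#' Builds the complete Cartesian grid over the factor levels. With four
#' factors at three levels this yields the 3^4 = 81 culture conditions of
#' the expansion screen. Ordering is deterministic: lexicographic by factor
#' order, the last listed factor varying fastest.
#'
#' @param factors list of [doe_factor()] objects (or a single one).
#' @return an object of class `factorial_design`: a data.frame with one
#'   column per factor plus a `condition_id` column, and the factor
#'   definitions in `attr(, "factors")`.
#' @examples
#' des <- enumerate_design(mbc_expansion_factors())
#' nrow(des)  # 81
#' @export
enumerate_design <- function(factors) {
  if (inherits(factors, "doe_factor")) factors <- list(factors)
  if (length(factors) == 0L) stop("empty factor list")
  ok <- vapply(factors, inherits, logical(1), "doe_factor")
  if (!all(ok)) stop("all elements must be doe_factor objects")
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("factor names must be unique")
  lv <- lapply(factors, `[[`, "levels")
  names(lv) <- nms
  ## last factor varies fastest: build grid in reverse then reorder columns
  grid <- rev(expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  grid <- grid[, nms, drop = FALSE]
  grid <- cbind(condition_id = sprintf("c%03d", seq_len(nrow(grid))), grid,
                stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  structure(grid, factors = factors, class = c("factorial_design", "data.frame"))
}

#' Count design points with two factors fixed
#'
#' In a full factorial design, fixing a pair of factors at given levels
#' leaves the sub-grid over all remaining factors: for the 3^4 design this
#' is the 9 combinations in which the two stimulants stay at the same
#' concentration while the other stimulants vary, the slice that underlies
#' second-order interaction assessment.
#'
#' @param design a [enumerate_design()] result.
#' @param factorA,factorB named character vectors or 2-element lists
#'   `c(name =, level =)` identifying the fixed factor/level pairs. Pass
#'   `factorB = NULL` to fix only one factor.
#' @return integer count of matching design points.
#' @examples
#' des <- enumerate_design(mbc_expansion_factors())
#' count_fixed_pair_slice(des, c(name = "IL21", level = "100"),
#'                        c(name = "CpG", level = "0"))  # 9
#' @export
count_fixed_pair_slice <- function(design, factorA, factorB = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  fix_one <- function(fx) {
    fx <- as.list(fx)
    if (is.null(fx$name) || is.null(fx$level))
      stop("fixed factors need 'name' and 'level'")
    if (!fx$name %in% names(design))
      stop("unknown factor: ", fx$name)
    if (!fx$level %in% design[[fx$name]])
      stop("unknown level '", fx$level, "' for factor ", fx$name)
    design[[fx$name]] == fx$level
  }
  keep <- fix_one(factorA)
  if (!is.null(factorB)) keep <- keep & fix_one(factorB)
  sum(keep)
}

#' @export
print.factorial_design <- function(x, ...) {
  fx <- attr(x, "factors")
  cat(sprintf("Full factorial design: %d factors, %d points\n",
              length(fx), nrow(x)))
  for (f in fx)
    cat(sprintf("  %-6s %s%s\n", f$name, paste(f$levels, collapse = "/"),
                if (!is.null(f$units)) paste0(" [", f$units, "]") else ""))
  NextMethod()
}
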