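# Agreement of SGE functional calls with a clinical classification, and the
# Bhapkar chi-square test of marginal homogeneity between two paired sets of
# agreement categories.

#' Agreement categories, worst to best
#' @return `c("major_error", "minor_error", "concordant")`.
#' @export
agreement_levels <- function() c("major_error", "minor_error", "concordant")

# collapse a clinical classification to its three-way side. Accepts the
# five-tier labels and IARC classes (1-2 benign-side, 3 uncertain, 4-5
# pathogenic-side).
.clinical_side <- function(clinical) {
  key <- toupper(trimws(as.character(clinical)))
  side <- c(PV = "pathogenic", LPV = "pathogenic", VUS = "uncertain",
            LBV = "benign", BV = "benign",
            "5" = "pathogenic", "4" = "pathogenic", "3" = "uncertain",
            "2" = "benign", "1" = "benign")[key]
  if (anyNA(side)) {
    stop("unrecognized clinical classification: ",
         paste(sQuote(unique(clinical[is.na(side)])), collapse = ", "),
         call. = FALSE)
  }
  unname(side)
}

#' Agreement category of a functional call versus a clinical classification
#'
#' A major error is a pathogenic functional result for a benign-side
#' classification or a benign functional result for a pathogenic-side one.
#' A minor error is an uncertain functional result for a definitive (non-VUS)
#' classification, or a definitive functional result for a VUS. Everything
#' else is concordant.
#'
#' @param clinical Five-tier labels (`PV`/`LPV`/`VUS`/`LBV`/`BV`) or IARC
#'   classes (1-5; 1-2 benign-side, 3 uncertain, 4-5 pathogenic-side).
#' @param call Functional calls from [functional_call()] (`"pathogenic"`,
#'   `"benign"`, `"uncertain"`), or SGE categories in any form accepted by
#'   [sge_category()].
#' @return Character vector over [agreement_levels()].
#' @examples
#' agreement_category("LBV", "pathogenic") # major_error
#' agreement_category("PV", "uncertain")   # minor_error
#' @export
agreement_category <- function(clinical, call) {
  side <- .clinical_side(clinical)
  call <- as.character(call)
  if (!all(call %in% c("pathogenic", "benign", "uncertain"))) {
    call <- functional_call(call)
  }
  stopifnot(length(side) == length(call))
  major <- (side == "benign" & call == "pathogenic") |
    (side == "pathogenic" & call == "benign")
  minor <- (side != "uncertain" & call == "uncertain") |
    (side == "uncertain" & call != "uncertain")
  ifelse(major, "major_error", ifelse(minor, "minor_error", "concordant"))
}

# round half away from zero at `digits` decimals (percentages are reported
# to one decimal; base round() would round half to even)
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Major / minor / concordance rate summary
#'
#' @param categories Character vector of agreement categories for one
#'   dataset (values from [agreement_levels()]).
#' @return A list with `n`, integer `counts` per category, and `major_pct`,
#'   `minor_pct`, `concordant_pct` as percentages rounded to one decimal
#'   (half away from zero).
#' @export
rate_summary <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) == 0L) {
    stop("rate_summary needs at least one record", call. = FALSE)
  }
  stopifnot(all(categories %in% agreement_levels()))
  counts <- table(factor(categories, levels = agreement_levels()))
  n <- length(categories)
  pct <- round_half_away(100 * as.numeric(counts) / n, 1)
  list(n = n, counts = as.integer(counts),
       major_pct = pct[1], minor_pct = pct[2], concordant_pct = pct[3])
}

#' Cross-tabulate paired agreement categories
#'
#' @param cat1,cat2 Agreement categories of the two datasets over the same
#'   variants.
#' @param levels Ordered category set shared by both axes.
#' @return A k x k integer matrix of counts; row marginals are dataset-1
#'   category counts, column marginals dataset-2 counts.
#' @export
crosstab_agreement <- function(cat1, cat2, levels = agreement_levels()) {
  stopifnot(length(cat1) == length(cat2))
  tab <- table(factor(cat1, levels = levels), factor(cat2, levels = levels))
  matrix(as.integer(tab), length(levels), length(levels),
         dimnames = list(levels, levels))
}

#' Bhapkar test of marginal homogeneity
#'
#' Chi-square test that two paired k-category margins are homogeneous (the
#' k > 2 generalization of McNemar's test). With cell proportions
#' p_ij = n_ij / n and marginal differences d_i = p_i. - p_.i for
#' i = 1..k-1, the covariance estimate V has diagonal
#' v_ii = p_i. + p_.i - 2 p_ii - d_i^2 and off-diagonal
#' v_ij = -(p_ij + p_ji) - d_i d_j; the statistic is n d' V^-1 d, referred
#' to a chi-square distribution with k - 1 degrees of freedom. When V is
#' singular (small tables with empty categories) the Moore-Penrose
#' generalized inverse is used and the degrees of freedom drop to rank(V).
#' A fully degenerate table (d = 0, V = 0) yields statistic 0 and p-value 1
#' by convention.
#'
#' @param pair_table k x k matrix of paired counts (k >= 2), e.g. from
#'   [crosstab_agreement()].
#' @return A list of class `"bhapkar"` with `statistic`, `df`, `p_value`,
#'   `pair_table` and `n`.
#' @export
bhapkar_test <- function(pair_table) {
  tab <- as.matrix(pair_table)
  k <- nrow(tab)
  if (k < 2L || ncol(tab) != k) {
    stop("pair_table must be a square matrix with k >= 2", call. = FALSE)
  }
  if (anyNA(tab) || any(tab < 0)) {
    stop("pair_table must hold non-negative counts", call. = FALSE)
  }
  n <- sum(tab)
  if (n < 1) stop("pair_table must contain at least one observation", call. = FALSE)
  p <- tab / n
  idx <- seq_len(k - 1L)
  d <- (rowSums(p) - colSums(p))[idx]
  V <- matrix(0, k - 1L, k - 1L)
  for (a in idx) {
    for (b in idx) {
      V[a, b] <- if (a == b) {
        sum(p[a, ]) + sum(p[, a]) - 2 * p[a, a] - d[a]^2
      } else {
        -(p[a, b] + p[b, a]) - d[a] * d[b]
      }
    }
  }
  if (all(d == 0) && all(V == 0)) {
    res <- list(statistic = 0, df = k - 1L, p_value = 1,
                pair_table = tab, n = n)
    class(res) <- "bhapkar"
    return(res)
  }
  r <- qr(V)$rank
  Vinv <- if (r < k - 1L) MASS::ginv(V) else solve(V)
  stat <- max(0, drop(n * t(d) %*% Vinv %*% d))
  df <- r
  res <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              pair_table = tab, n = n)
  class(res) <- "bhapkar"
  res
}

#' @export
print.bhapkar <- function(x, ...) {
  cat(sprintf("Bhapkar marginal-homogeneity test: chi2 = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}
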