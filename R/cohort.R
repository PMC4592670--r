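## Cohort-level association statistics: exact Fisher tests on 2x2 clone/tumor
## contingency tables, Welch's t, and the 10,000-permutation mean-difference
## test.

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric exact test. The two-sided p-value follows the
#' minimum-likelihood convention: the sum of probabilities of all tables with
#' fixed margins whose probability does not exceed the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector filled by row.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (sidedness refers
#'   to the odds ratio of the first cell).
#' @return `list(p_value, table, alternative)`.
#' @examples
#' fisher_exact(matrix(c(9, 49, 0, 40), 2, byrow = TRUE))$p_value  # ~0.0098
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != floor(table)))
    stop("table cells must be non-negative integers")
  if (all(rowSums(table) == 0) || all(colSums(table) == 0))
    return(list(p_value = 1, table = table, alternative = alternative))
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  p <- stats::fisher.test(table, alternative = alt)$p.value
  list(p_value = p, table = table, alternative = alternative)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, two-sided.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return `list(t, df, p_value)`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs n >= 2")
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0)
    stop("degenerate variance in both samples")
  ht <- stats::t.test(sample_a, sample_b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Permutation test of a mean difference
#'
#' Group labels are shuffled `n_perm` times and the absolute mean difference
#' recomputed; the p-value is `(1 + #{|diff*| >= |diff|}) / (n_perm + 1)` (the
#' add-one correction avoids zero p-values; `add_one = FALSE` gives the plain
#' fraction).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed or `NULL`.
#' @param add_one Use the add-one correction (default `TRUE`).
#' @return `list(observed, p_value)`.
#' @export
permutation_mean_diff <- function(sample_a, sample_b, n_perm = 10000,
                                  seed = NULL, add_one = TRUE) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  obs <- abs(mean(sample_a) - mean(sample_b))
  pool <- c(sample_a, sample_b)
  na <- length(sample_a)
  with_seed(seed, {
    count <- 0L
    for (r in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) count <- count + 1L
    }
    p <- if (add_one) (1 + count) / (n_perm + 1) else count / n_perm
    list(observed = obs, p_value = p)
  })
}

#' Summarize a cohort of clone reports
#'
#' Builds ploidy-by-event contingency tables (clustered copy-number
#' alterations; chromothripsis) from per-clone flags and runs Fisher's exact
#' test on each.
#'
#' @param cohort `data.frame` with columns `clone`, `ploidy` (values
#'   `"diploid"`/`"hyperploid"`), and logical `clustered` and
#'   `chromothripsis`.
#' @param alternative Sidedness passed to [fisher_exact()] (default
#'   two-sided).
#' @return `list(tables, tests)` of class `cast_cohort`.
#' @export
summarize_cohort <- function(cohort, alternative = "two_sided") {
  if (nrow(cohort) < 2L) stop("cohort must contain at least 2 clones")
  req <- c("clone", "ploidy", "clustered", "chromothripsis")
  if (!all(req %in% names(cohort)))
    stop("cohort needs columns: ", paste(req, collapse = ", "))
  mk_table <- function(flag) {
    hp <- cohort$ploidy == "hyperploid"
    m <- matrix(c(sum(hp & flag), sum(hp & !flag),
                  sum(!hp & flag), sum(!hp & !flag)), 2, 2, byrow = TRUE,
                dimnames = list(c("hyperploid", "diploid"),
                                c("event", "no_event")))
    m
  }
  tables <- list(clustered = mk_table(cohort$clustered),
                 chromothripsis = mk_table(cohort$chromothripsis))
  tests <- lapply(tables, fisher_exact, alternative = alternative)
  structure(list(tables = tables, tests = tests, n = nrow(cohort)),
            class = "cast_cohort")
}

#' @export
print.cast_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d clones\n", x$n))
  for (nm in names(x$tables)) {
    cat(sprintf("\n%s x ploidy:\n", nm))
    print(x$tables[[nm]])
    cat(sprintf("Fisher's exact (%s): p = %.4g\n",
                x$tests[[nm]]$alternative, x$tests[[nm]]$p_value))
  }
  invisible(x)
}
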