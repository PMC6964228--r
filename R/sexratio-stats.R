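#' Exact two-sided binomial test (point-probability method)
#'
#' Tests whether \code{k} successes in \code{n} trials deviate from a null
#' proportion \code{p0}. The two-sided p-value follows the point-probability
#' convention: it sums P(X = i) over every outcome i whose point probability
#' does not exceed that of the observed outcome (with a relative tolerance
#' of 1e-7 on the comparison), where X ~ Binomial(n, p0). Point
#' probabilities are compared in log space, so the test is stable for n in
#' the tens of thousands. The p-value is capped at 1. A 95\%
#' Clopper-Pearson confidence interval for the proportion is included as an
#' extra beyond the bare test.
#'
#' @param k Number of successes (integer, 0 <= k <= n).
#' @param n Number of trials (integer >= 1).
#' @param p0 Null proportion in (0, 1); default 0.5 (balanced sex ratio).
#' @return A list of class \code{binom_sexratio}: \code{k}, \code{n},
#'   \code{p0}, \code{proportion}, \code{p_value}, \code{conf_int}
#'   (95\% Clopper-Pearson).
#' @examples
#' binom_test_two_sided(11, 13)   # p = 0.0225
#' binom_test_two_sided(34, 69)   # p = 1
#' @export
binom_test_two_sided <- function(k, n, p0 = 0.5) {
  k <- assert_count(k, "k"); n <- assert_count(n, "n", min = 1L)
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop("`p0` must be in (0, 1)", call. = FALSE)
  }
  ld <- stats::dbinom(0:n, n, p0, log = TRUE)
  keep <- ld <= ld[k + 1L] + log1p(1e-7)
  p <- min(1, sum(exp(ld[keep])))
  ci <- c(
    lower = if (k == 0L) 0 else stats::qbeta(0.025, k, n - k + 1L),
    upper = if (k == n) 1 else stats::qbeta(0.975, k + 1L, n - k))
  structure(list(k = k, n = n, p0 = p0, proportion = k / n,
                 p_value = p, conf_int = ci),
            class = "binom_sexratio")
}

#' @export
print.binom_sexratio <- function(x, ...) {
  cat(sprintf(
    "exact binomial test: %d/%d = %.3f vs p0 = %g, two-sided p = %.4g\n",
    x$k, x$n, x$proportion, x$p0, x$p_value))
  cat(sprintf("  95%% CI [%.3f, %.3f]\n",
              x$conf_int["lower"], x$conf_int["upper"]))
  invisible(x)
}

#' Observed proportion of females
#'
#' @param x Either a data.frame of records with a \code{sex} column
#'   (F counted as success), or the female count \code{k}.
#' @param n Total count when \code{x} is a number.
#' @return The proportion, with a \code{"formatted"} attribute rounded to
#'   3 decimals.
#' @examples
#' proportion_female(623, 1441)  # 0.432
#' @export
proportion_female <- function(x, n = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("empty group", call. = FALSE)
    k <- sum(x$sex == "F"); n <- nrow(x)
  } else {
    k <- assert_count(x, "k"); n <- assert_count(n, "n", min = 1L)
    if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  }
  structure(k / n, formatted = sprintf("%.3f", k / n))
}

#' Sex-ratio report over a grouping
#'
#' One exact two-sided binomial test per group of records: female and male
#' counts, total, observed proportion of females and the p-value against a
#' balanced (or other null) ratio. Row order is the sorted group labels, so
#' output is deterministic.
#'
#' @param records data.frame with a \code{sex} column (\code{"M"}/\code{"F"})
#'   and the grouping column.
#' @param by Name of the grouping column.
#' @param p0 Null proportion of females.
#' @return data.frame with columns \code{group}, \code{females},
#'   \code{males}, \code{total}, \code{prop_female}, \code{p_value}
#'   (full precision).
#' @export
group_sexratio_report <- function(records, by, p0 = 0.5) {
  stopifnot(is.data.frame(records), "sex" %in% names(records))
  if (!by %in% names(records)) {
    stop(sprintf("grouping column '%s' not found", by), call. = FALSE)
  }
  if (anyNA(records[[by]])) {
    stop("grouping key missing on some records", call. = FALSE)
  }
  groups <- sort(unique(as.character(records[[by]])))
  rows <- lapply(groups, function(g) {
    sub <- records[records[[by]] == g, ]
    nf <- sum(sub$sex == "F"); nm <- sum(sub$sex == "M")
    bt <- binom_test_two_sided(nf, nf + nm, p0)
    data.frame(group = g, females = nf, males = nm, total = nf + nm,
               prop_female = bt$proportion, p_value = bt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median split of records on a numeric covariate
#'
#' Labels each record \code{"low"} (value <= overall median) or
#' \code{"high"} (value > median); ties at the median go to the low group,
#' matching the usual "<= median / > median" partition of covariates such
#' as pollen dispersal distance or parent kinship.
#'
#' @param records data.frame.
#' @param field Name of the numeric column to split on; must be non-missing
#'   on all included records.
#' @return The records with an added \code{split} column
#'   (factor low/high) and attribute \code{"median"}. Errors if all values
#'   are identical (no split exists).
#' @export
median_split <- function(records, field) {
  stopifnot(is.data.frame(records))
  if (!field %in% names(records)) {
    stop(sprintf("field '%s' not found", field), call. = FALSE)
  }
  x <- records[[field]]
  if (anyNA(x)) stop("field has missing values; filter first",
                     call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("all values identical: median split is undefined", call. = FALSE)
  }
  med <- stats::median(x)
  records$split <- factor(ifelse(x <= med, "low", "high"),
                          levels = c("low", "high"))
  attr(records, "median") <- med
  records
}

#' Pearson correlation test
#'
#' Computes r and the two-sided p-value from the t transform
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on n - 2 degrees of freedom.
#' \code{p_from_r()} gives the same p-value from a published r and sample
#' size, for summary-level checks.
#'
#' @param x,y Numeric vectors of equal length n >= 3 with non-zero
#'   variance.
#' @return \code{pearson_test()}: list of class \code{pearson_cor} with
#'   \code{r}, \code{df} (n - 2), \code{t}, \code{p_value}.
#'   \code{p_from_r()}: the two-sided p-value.
#' @examples
#' p_from_r(0.252, 58)   # ~0.056
#' p_from_r(-0.177, 58)  # ~0.18
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  structure(list(r = r, df = n - 2L,
                 t = r * sqrt(n - 2) / sqrt(1 - r^2),
                 p_value = p_from_r(r, n)),
            class = "pearson_cor")
}

#' @rdname pearson_test
#' @param r Correlation coefficient in (-1, 1).
#' @param n Sample size (>= 3); degrees of freedom are n - 2.
#' @export
p_from_r <- function(r, n) {
  n <- assert_count(n, "n", min = 3L)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r(%d) = %.3f, two-sided p = %.4g\n",
              x$df, x$r, x$p_value))
  invisible(x)
}

#' Seed-trait dimorphism summary
#'
#' Per-sex mean and standard error of a seed trait (mass, length), plus a
#' point-biserial correlation test of the trait against sex (sex coded
#' 0 = male, 1 = female), asking whether the trait predicts the seedling's
#' sex.
#'
#' @param records data.frame with \code{sex} and the trait column; rows
#'   with missing trait are dropped. Needs >= 2 records of each sex.
#' @param trait Name of the numeric trait column.
#' @return A list of class \code{dimorphism_summary}: \code{trait},
#'   \code{by_sex} (data.frame: sex, n, mean, se) and \code{test}
#'   (a \code{pearson_cor}).
#' @export
seed_dimorphism_summary <- function(records, trait = "seed_mass_kg") {
  stopifnot(is.data.frame(records), "sex" %in% names(records))
  if (!trait %in% names(records)) {
    stop(sprintf("trait '%s' not found", trait), call. = FALSE)
  }
  sub <- records[!is.na(records[[trait]]), ]
  tab <- table(sub$sex)
  if (!all(c("F", "M") %in% names(tab)) || any(tab[c("F", "M")] < 2)) {
    stop("need at least 2 records of each sex", call. = FALSE)
  }
  by_sex <- do.call(rbind, lapply(c("F", "M"), function(s) {
    v <- sub[[trait]][sub$sex == s]
    data.frame(sex = s, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  test <- if (stats::sd(sub[[trait]]) > 0) {
    pearson_test(sub[[trait]], as.numeric(sub$sex == "F"))
  }  # NULL when the trait is constant: no correlation is defined
  structure(list(trait = trait, by_sex = by_sex, test = test),
            class = "dimorphism_summary")
}

#' @export
print.dimorphism_summary <- function(x, ...) {
  cat(sprintf("%s by sex:\n", x$trait))
  df <- x$by_sex
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: %.1f +/- %.1f (N = %d)\n",
                df$sex[i], df$mean[i], df$se[i], df$n[i]))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  point-biserial r = %.3f, p = %.3g\n",
                x$test$r, x$test$p_value))
  }
  invisible(x)
}
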