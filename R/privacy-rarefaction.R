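#' Build a presence/absence matrix from a read-count table
#'
#' Presence of a contig in an individual is defined as a mapped read count of
#' at least \code{min_reads} (default 1, i.e. any mapped read counts as
#' presence). This is the input to the privacy rarefaction scan.
#'
#' @param counts Integer matrix (contigs x individuals) of non-negative read
#'   counts, with unique row and column names, or a \code{rad_cohort}.
#' @param min_reads Minimum read count for presence (integer >= 1).
#' @return A logical matrix of class \code{presence_matrix} with attribute
#'   \code{min_reads}.
#' @examples
#' m <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("i1", "i2")))
#' build_presence_matrix(m)
#' @export
build_presence_matrix <- function(counts, min_reads = 1) {
  if (inherits(counts, "rad_cohort")) counts <- counts$counts
  min_reads <- assert_count(min_reads, "min_reads", min = 1L)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("read counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry contig rownames and individual colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate contig ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate individual ids", call. = FALSE)
  }
  structure(counts >= min_reads, min_reads = min_reads,
            class = c("presence_matrix", "matrix", "array"))
}

#' Privacy rarefaction scan for sex-specific contigs
#'
#' At each stringency level \eqn{s = 1 \ldots S}, repeatedly draws \eqn{s}
#' males and \eqn{s} females uniformly without replacement and records, per
#' draw, which contigs are \emph{male-private} (present in all \eqn{s} drawn
#' males and absent in all \eqn{s} drawn females) or \emph{female-private}
#' (the mirror image). Genuinely sex-hemizygous loci stay private as
#' stringency grows, while missing-data artefacts are eliminated, so the two
#' candidate-count curves diverge in species with sex chromosomes.
#'
#' A contig's bootstrap support at level \eqn{s} is the fraction of the
#' \code{n_boot} draws at that level in which it was private to the given
#' sex. The per-level candidate-count summary is the mean over draws (median
#' and quantiles are also kept).
#'
#' With \code{method = "exhaustive"} every possible (male-subset,
#' female-subset) pair is enumerated instead of sampled; this is feasible
#' only for small cohorts and gives exact supports.
#'
#' @param presence A \code{presence_matrix} from [build_presence_matrix()].
#' @param sexes Sex registry data.frame (\code{individual_id}, \code{sex});
#'   every column of \code{presence} must appear in it with sex M or F.
#' @param n_boot Number of random draws per stringency level.
#' @param max_stringency Highest stringency level; defaults to
#'   \code{min(#males, #females)} and may not exceed it.
#' @param seed Integer seed for the subsampling.
#' @param method \code{"bootstrap"} (default) or \code{"exhaustive"}.
#' @return An object of class \code{privacy_rarefaction} with elements
#'   \describe{
#'     \item{levels}{evaluated stringency levels}
#'     \item{support_male, support_female}{contig x level support matrices
#'       in [0, 1]}
#'     \item{counts_male, counts_female}{per-level lists of per-draw private
#'       candidate counts}
#'     \item{summary}{data.frame of per-level mean/median/q05/q95 counts for
#'       both sexes}
#'     \item{n_boot, seed, method, n_males, n_females}{scan metadata}
#'   }
#' @export
privacy_rarefaction <- function(presence, sexes, n_boot = 200,
                                max_stringency = NULL, seed = 1,
                                method = c("bootstrap", "exhaustive")) {
  method <- match.arg(method)
  if (!inherits(presence, "presence_matrix")) {
    presence <- build_presence_matrix(presence)
  }
  stopifnot(is.data.frame(sexes),
            all(c("individual_id", "sex") %in% names(sexes)))
  n_boot <- assert_count(n_boot, "n_boot", min = 1L)

  ind <- colnames(presence)
  sx <- sexes$sex[match(ind, sexes$individual_id)]
  if (anyNA(sx)) {
    stop("individuals missing from the sex registry: ",
         paste(ind[is.na(sx)], collapse = ", "), call. = FALSE)
  }
  males <- which(sx == "M")
  females <- which(sx == "F")
  if (length(males) < 1L || length(females) < 1L) {
    stop("need at least one male and one female", call. = FALSE)
  }
  s_max_possible <- min(length(males), length(females))
  if (is.null(max_stringency)) max_stringency <- s_max_possible
  max_stringency <- assert_count(max_stringency, "max_stringency", min = 1L)
  if (max_stringency > s_max_possible) {
    stop(sprintf("max_stringency (%d) exceeds min(#males, #females) = %d",
                 max_stringency, s_max_possible), call. = FALSE)
  }

  P <- presence
  storage.mode(P) <- "double"
  levels <- seq_len(max_stringency)
  n_contig <- nrow(P)
  sup_m <- sup_f <- matrix(
    0, n_contig, max_stringency,
    dimnames = list(rownames(P), paste0("s", levels)))
  cnt_m <- cnt_f <- vector("list", max_stringency)

  # Subsampling streams are keyed to each group's (sorted) individual ids,
  # not to the M/F label, so that swapping all sex labels swaps the
  # male-/female-private outputs exactly, and permuting column order leaves
  # all outputs unchanged.
  group_seed <- function(ids) {
    ch <- utf8ToInt(paste(sort(ids), collapse = "\r"))
    h <- sum(ch * ((seq_along(ch) - 1L) %% 97L + 1L)) %% 1000003L
    (abs(as.integer(seed)) %% 1000000L) * 1009L + as.integer(h)
  }
  draw_patterns <- function(ids) {
    ids <- sort(ids)
    with_local_seed(group_seed(ids), {
      lapply(levels, function(s) {
        lapply(seq_len(n_boot), function(b) sample(ids, s))
      })
    })
  }

  ids_m <- sort(ind[males])
  ids_f <- sort(ind[females])
  if (method == "bootstrap") {
    pat_m <- draw_patterns(ids_m)
    pat_f <- draw_patterns(ids_f)
  }

  sel_matrix <- function(patterns) {
    sel <- matrix(0, ncol(P), length(patterns))
    for (b in seq_along(patterns)) {
      sel[match(patterns[[b]], ind), b] <- 1
    }
    sel
  }

  for (s in levels) {
    if (method == "bootstrap") {
      sel_m <- sel_matrix(pat_m[[s]])
      sel_f <- sel_matrix(pat_f[[s]])
    } else {
      cm <- utils::combn(ids_m, s)
      cf <- utils::combn(ids_f, s)
      pairs_m <- rep(seq_len(ncol(cm)), each = ncol(cf))
      pairs_f <- rep(seq_len(ncol(cf)), times = ncol(cm))
      sel_m <- sel_matrix(lapply(pairs_m, function(i) cm[, i]))
      sel_f <- sel_matrix(lapply(pairs_f, function(j) cf[, j]))
    }
    in_m <- P %*% sel_m   # contig x draw: number of selected males present
    in_f <- P %*% sel_f
    mp <- (in_m == s) & (in_f == 0)
    fp <- (in_f == s) & (in_m == 0)
    sup_m[, s] <- rowMeans(mp)
    sup_f[, s] <- rowMeans(fp)
    cnt_m[[s]] <- colSums(mp)
    cnt_f[[s]] <- colSums(fp)
  }

  summarise <- function(cnts) {
    data.frame(
      mean = vapply(cnts, mean, numeric(1)),
      median = vapply(cnts, stats::median, numeric(1)),
      q05 = vapply(cnts, stats::quantile, numeric(1), probs = 0.05,
                   names = FALSE),
      q95 = vapply(cnts, stats::quantile, numeric(1), probs = 0.95,
                   names = FALSE))
  }
  sm <- summarise(cnt_m); sf <- summarise(cnt_f)
  summary <- data.frame(stringency = levels,
                        mean_male = sm$mean, median_male = sm$median,
                        q05_male = sm$q05, q95_male = sm$q95,
                        mean_female = sf$mean, median_female = sf$median,
                        q05_female = sf$q05, q95_female = sf$q95)

  structure(list(levels = levels,
                 support_male = sup_m, support_female = sup_f,
                 counts_male = cnt_m, counts_female = cnt_f,
                 summary = summary,
                 n_boot = n_boot, seed = seed, method = method,
                 n_males = length(males), n_females = length(females)),
            class = "privacy_rarefaction")
}

#' @export
print.privacy_rarefaction <- function(x, ...) {
  cat(sprintf(
    "privacy_rarefaction scan: %d contigs, %dM + %dF, %s (%d draws/level)\n",
    nrow(x$support_male), x$n_males, x$n_females, x$method, x$n_boot))
  print(x$summary[, c("stringency", "mean_male", "mean_female")],
        row.names = FALSE)
  invisible(x)
}

#' Retained sex-specific candidate contigs
#'
#' Applies the retention rule: keep contigs with bootstrap support of at
#' least \code{min_support} for privacy to one sex at any stringency level
#' of at least \code{min_stringency} (default: >= 50\% support at level
#' >= 3). Each retained contig is annotated with the full set of levels it
#' passed.
#'
#' @param result A \code{privacy_rarefaction} object.
#' @param min_support Minimum bootstrap support in [0, 1].
#' @param min_stringency Lowest stringency level that counts.
#' @return data.frame with columns \code{contig_id}, \code{sex}
#'   (\code{"M"}/\code{"F"}), \code{passed_levels} (list column of integer
#'   vectors, all levels >= \code{min_stringency} with support >=
#'   \code{min_support}), \code{max_support}.
#' @export
candidate_contigs <- function(result, min_support = 0.5,
                              min_stringency = 3) {
  stopifnot(inherits(result, "privacy_rarefaction"))
  assert_prob(min_support, "min_support", allow_one = TRUE)
  min_stringency <- assert_count(min_stringency, "min_stringency", min = 1L)
  lv <- result$levels[result$levels >= min_stringency]
  if (length(lv) == 0L) {
    stop("scan has no levels at or above min_stringency", call. = FALSE)
  }

  pick <- function(sup, sex) {
    sub <- sup[, lv, drop = FALSE]
    hit <- which(apply(sub, 1L, max) >= min_support)
    if (length(hit) == 0L) return(NULL)
    data.frame(
      contig_id = rownames(sup)[hit],
      sex = sex,
      passed_levels = I(lapply(hit, function(i) lv[sub[i, ] >= min_support])),
      max_support = apply(sub[hit, , drop = FALSE], 1L, max),
      stringsAsFactors = FALSE)
  }
  out <- rbind(pick(result$support_male, "M"),
               pick(result$support_female, "F"))
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), sex = character(0),
                      passed_levels = I(list()),
                      max_support = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$sex, out$contig_id), ]
  rownames(out) <- NULL
  out
}

#' Classify the heterogametic system from a privacy rarefaction scan
#'
#' In an XY (male-heterogametic) system, male-private candidates persist to
#' the highest stringency while apparent female-private candidates are
#' eliminated as false positives; a ZW system shows the mirror image; with
#' no sex chromosomes both curves collapse to zero. Classification looks at
#' the mean candidate counts at the maximal evaluated stringency: a sex's
#' signal is "present" if its mean count is > 0 and the other sex's mean
#' count rounds to 0 (i.e. is < 0.5).
#'
#' @param result A \code{privacy_rarefaction} object covering at least 3
#'   stringency levels.
#' @return A list of class \code{heterogamety_call}:
#'   \code{label} (\code{"XY-like"}, \code{"ZW-like"} or \code{"none"}),
#'   \code{mean_male}/\code{mean_female} at maximal stringency, and the full
#'   per-level \code{curves}.
#' @export
classify_heterogamety <- function(result) {
  stopifnot(inherits(result, "privacy_rarefaction"))
  if (length(result$levels) < 3L) {
    stop("scan must cover at least 3 stringency levels", call. = FALSE)
  }
  smax <- max(result$levels)
  m <- mean(result$counts_male[[smax]])
  f <- mean(result$counts_female[[smax]])
  xy <- m > 0 && f < 0.5
  zw <- f > 0 && m < 0.5
  label <- if (xy && !zw) "XY-like" else if (zw && !xy) "ZW-like" else "none"
  structure(list(label = label, mean_male = m, mean_female = f,
                 stringency = smax, curves = result$summary),
            class = "heterogamety_call")
}

#' @export
print.heterogamety_call <- function(x, ...) {
  cat(sprintf(
    "heterogamety: %s (at stringency %d: mean male-private %.3g, female-private %.3g)\n",
    x$label, x$stringency, x$mean_male, x$mean_female))
  invisible(x)
}

#' Incidence of sex-specific markers in an assembly
#'
#' Expresses the mean number of sex-private candidates at a given stringency
#' as a percentage of the assembly's total contig count, e.g. a mean of 5.29
#' male-private candidates among 94,968 contigs is an incidence of 0.0056\%.
#'
#' @param result A \code{privacy_rarefaction} object, or directly the mean
#'   candidate count (numeric).
#' @param total Total number of contigs in the assembly (> 0).
#' @param stringency Stringency level at which to take the mean male-private
#'   count (defaults to the scan's maximum); ignored when \code{result} is
#'   numeric.
#' @param sex Which sex's candidates to report (default male).
#' @return Numeric percentage, with a \code{"formatted"} attribute printed
#'   at 2 significant figures.
#' @examples
#' incidence_report(5.29, 94968)  # 0.0056%
#' @export
incidence_report <- function(result, total, stringency = NULL, sex = "M") {
  if (!is.numeric(total) || length(total) != 1L || total <= 0) {
    stop("`total` must be a positive number", call. = FALSE)
  }
  mean_count <- if (inherits(result, "privacy_rarefaction")) {
    cnts <- if (sex == "M") result$counts_male else result$counts_female
    s <- if (is.null(stringency)) max(result$levels) else stringency
    if (!s %in% result$levels) stop("stringency not in scan", call. = FALSE)
    mean(cnts[[s]])
  } else {
    as.numeric(result)
  }
  pct <- 100 * mean_count / total
  structure(pct, formatted = paste0(signif(pct, 2), "%"))
}
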