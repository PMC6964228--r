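#' Reference allele frequencies from a genotype table
#'
#' Per-locus allele frequencies over a reference sample of diploid
#' individuals (e.g. the whole adult dataset), together with the number of
#' gene copies observed. An individual is treated as missing at a locus if
#' either allele is NA, and missingness is handled per locus
#' (pairwise-complete). Loci with no observations in the reference are
#' dropped with a warning.
#'
#' @param genotypes Long-format data.frame with columns
#'   \code{individual_id}, \code{locus}, \code{allele1}, \code{allele2}.
#' @param reference_ids Individual ids forming the reference sample;
#'   default all individuals present.
#' @return A list of class \code{allele_freqs}, one element per locus:
#'   \code{freqs} (named, sums to 1), \code{n_copies} (2 x non-missing
#'   individuals), \code{n_ind}.
#' @export
allele_freqs <- function(genotypes, reference_ids = NULL) {
  stopifnot(is.data.frame(genotypes),
            all(c("individual_id", "locus", "allele1", "allele2") %in%
                  names(genotypes)))
  g <- genotypes
  if (!is.null(reference_ids)) {
    g <- g[g$individual_id %in% reference_ids, ]
    if (nrow(g) == 0L) stop("no reference individuals found", call. = FALSE)
  }
  out <- list()
  dropped <- character(0)
  for (l in unique(g$locus)) {
    sub <- g[g$locus == l, ]
    ok <- !is.na(sub$allele1) & !is.na(sub$allele2)
    if (!any(ok)) { dropped <- c(dropped, l); next }
    al <- c(sub$allele1[ok], sub$allele2[ok])
    tab <- table(al)
    fr <- sort(stats::setNames(as.numeric(tab) / length(al), names(tab)),
               decreasing = TRUE)
    out[[l]] <- list(freqs = fr, n_copies = length(al), n_ind = sum(ok))
  }
  if (length(dropped)) {
    warning("dropped loci with no observations: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(out) == 0L) {
    stop("no locus has any observations in the reference", call. = FALSE)
  }
  structure(out, class = "allele_freqs")
}

# Allele dosage/2 for one individual at one locus: named vector over the
# union of reference and carried alleles; NULL if missing.
.dosage <- function(a1, a2, allele_names) {
  if (is.na(a1) || is.na(a2)) return(NULL)
  alleles <- union(allele_names, c(a1, a2))
  p <- stats::setNames(numeric(length(alleles)), alleles)
  p[a1] <- p[a1] + 0.5
  p[a2] <- p[a2] + 0.5
  p
}

#' Loiselle pairwise kinship coefficient
#'
#' Estimates the kinship coefficient F between two diploid individuals from
#' multi-allelic codominant genotypes, relative to the allele frequencies of
#' a reference sample. Per locus l with reference frequencies
#' \eqn{\bar p_{la}} over \eqn{n_l} gene copies, writing
#' \eqn{p_{ia} \in \{0, 0.5, 1\}} for individual i's allele-a dosage / 2:
#' \deqn{num_l = \sum_a (p_{ia} - \bar p_{la})(p_{ja} - \bar p_{la})
#'       + \sum_a \bar p_{la}(1 - \bar p_{la})/(n_l - 1), \quad
#'       den_l = \sum_a \bar p_{la}(1 - \bar p_{la})}
#' and the multilocus estimate is the ratio of sums
#' \eqn{F = \sum_l num_l / \sum_l den_l} over loci where both individuals
#' are genotyped, which downweights uninformative loci naturally. The
#' sample-size term corrects the downward bias of finite reference panels.
#' Expected values are ~0.25 for parent-offspring or full sibs, ~0.125 for
#' half sibs and ~0 for individuals unrelated relative to the reference.
#'
#' @param i,j Individual ids.
#' @param genotypes Long-format genotype data.frame (see [allele_freqs()]).
#' @param freqs An \code{allele_freqs} object; computed from the whole of
#'   \code{genotypes} if NULL (whole-sample reference convention).
#' @return A list of class \code{kinship_estimate}: \code{pair}, \code{F},
#'   \code{per_locus} (data.frame: locus, num, den, n_copies),
#'   \code{n_loci}.
#' @export
loiselle_kinship <- function(i, j, genotypes, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_freqs(genotypes)
  stopifnot(inherits(freqs, "allele_freqs"))
  gi <- genotypes[genotypes$individual_id == i, ]
  gj <- genotypes[genotypes$individual_id == j, ]
  if (nrow(gi) == 0L || nrow(gj) == 0L) {
    stop("both individuals must be genotyped", call. = FALSE)
  }
  rows <- list()
  for (l in names(freqs)) {
    fl <- freqs[[l]]
    if (fl$n_copies < 2L) {
      stop(sprintf("locus %s has fewer than 2 gene copies", l),
           call. = FALSE)
    }
    ri <- gi[gi$locus == l, ]; rj <- gj[gj$locus == l, ]
    if (nrow(ri) != 1L || nrow(rj) != 1L) next
    pi <- .dosage(ri$allele1, ri$allele2, names(fl$freqs))
    pj <- .dosage(rj$allele1, rj$allele2, names(fl$freqs))
    if (is.null(pi) || is.null(pj)) next
    alleles <- union(names(pi), names(pj))
    pbar <- stats::setNames(numeric(length(alleles)), alleles)
    pbar[names(fl$freqs)] <- fl$freqs
    di <- stats::setNames(numeric(length(alleles)), alleles); di[names(pi)] <- pi
    dj <- stats::setNames(numeric(length(alleles)), alleles); dj[names(pj)] <- pj
    num <- sum((di - pbar) * (dj - pbar)) +
      sum(pbar * (1 - pbar)) / (fl$n_copies - 1)
    den <- sum(pbar * (1 - pbar))
    rows[[l]] <- data.frame(locus = l, num = num, den = den,
                            n_copies = fl$n_copies,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no shared genotyped locus between the pair", call. = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL
  structure(list(pair = c(i, j),
                 F = sum(per_locus$num) / sum(per_locus$den),
                 per_locus = per_locus, n_loci = nrow(per_locus)),
            class = "kinship_estimate")
}

#' @export
print.kinship_estimate <- function(x, ...) {
  cat(sprintf("Loiselle kinship F(%s, %s) = %.4f over %d loci\n",
              x$pair[1], x$pair[2], x$F, x$n_loci))
  invisible(x)
}

#' All-pairs Loiselle kinship matrix
#'
#' Matrix version of [loiselle_kinship()] for many individuals at once,
#' using per-locus centred dosage cross-products. Missing genotypes are
#' handled pairwise-complete: each pair's ratio of sums runs over the loci
#' where both members are genotyped.
#'
#' @param genotypes Long-format genotype data.frame.
#' @param ids Individuals to include (default: all in \code{genotypes}).
#' @param freqs An \code{allele_freqs} object; computed from the whole of
#'   \code{genotypes} if NULL.
#' @return A symmetric numeric matrix of F values (diagonal = self-kinship,
#'   usually ~0.5 for non-inbred individuals).
#' @export
loiselle_matrix <- function(genotypes, ids = NULL, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_freqs(genotypes)
  if (is.null(ids)) ids <- unique(genotypes$individual_id)
  n <- length(ids)
  num_sum <- matrix(0, n, n, dimnames = list(ids, ids))
  den_sum <- matrix(0, n, n, dimnames = list(ids, ids))
  for (l in names(freqs)) {
    fl <- freqs[[l]]
    if (fl$n_copies < 2L) next
    sub <- genotypes[genotypes$locus == l &
                       genotypes$individual_id %in% ids, ]
    sub <- sub[!is.na(sub$allele1) & !is.na(sub$allele2), ]
    if (nrow(sub) == 0L) next
    alleles <- union(names(fl$freqs), c(sub$allele1, sub$allele2))
    pbar <- stats::setNames(numeric(length(alleles)), alleles)
    pbar[names(fl$freqs)] <- fl$freqs
    D <- matrix(0, nrow(sub), length(alleles),
                dimnames = list(sub$individual_id, alleles))
    ridx <- seq_len(nrow(sub))
    D[cbind(ridx, match(sub$allele1, alleles))] <-
      D[cbind(ridx, match(sub$allele1, alleles))] + 0.5
    D[cbind(ridx, match(sub$allele2, alleles))] <-
      D[cbind(ridx, match(sub$allele2, alleles))] + 0.5
    C <- sweep(D, 2L, pbar)
    corr <- sum(pbar * (1 - pbar)) / (fl$n_copies - 1)
    den <- sum(pbar * (1 - pbar))
    present <- match(sub$individual_id, ids)
    num_sum[present, present] <- num_sum[present, present] +
      tcrossprod(C) + corr
    den_sum[present, present] <- den_sum[present, present] + den
  }
  out <- num_sum / den_sum
  out[den_sum == 0] <- NA_real_
  out
}

#' Annotate offspring with parent-pair kinship
#'
#' Computes the Loiselle kinship F between the assigned mother and father of
#' each offspring, relative to a reference sample (by default all
#' individuals in the genotype table, i.e. the whole-adult-sample
#' convention), producing the \code{parent_kinship} column used for
#' median-split sex-ratio analyses. Offspring whose parents lack genotypes
#' are flagged (\code{excluded = TRUE}, F = NA) rather than silently
#' dropped.
#'
#' @param offspring data.frame with \code{mother_id} and \code{father_id}.
#' @param genotypes Long-format genotype data.frame covering the parents.
#' @param freqs Optional precomputed \code{allele_freqs}.
#' @return The offspring data.frame with columns \code{parent_kinship} and
#'   \code{excluded} added (replacing any existing \code{parent_kinship}).
#' @export
parent_pair_table <- function(offspring, genotypes, freqs = NULL) {
  stopifnot(is.data.frame(offspring),
            all(c("mother_id", "father_id") %in% names(offspring)))
  if (is.null(freqs)) freqs <- allele_freqs(genotypes)
  typed <- unique(genotypes$individual_id)
  pairs <- unique(offspring[, c("mother_id", "father_id")])
  key <- function(m, f) paste(m, f, sep = "\r")
  fmap <- stats::setNames(rep(NA_real_, nrow(pairs)),
                          key(pairs$mother_id, pairs$father_id))
  for (p in seq_len(nrow(pairs))) {
    mo <- pairs$mother_id[p]; fa <- pairs$father_id[p]
    if (is.na(mo) || is.na(fa) || !mo %in% typed || !fa %in% typed) next
    fmap[key(mo, fa)] <- loiselle_kinship(mo, fa, genotypes, freqs)$F
  }
  offspring$parent_kinship <-
    unname(fmap[key(offspring$mother_id, offspring$father_id)])
  offspring$excluded <- is.na(offspring$parent_kinship)
  if (any(offspring$excluded)) {
    warning(sprintf("%d offspring excluded (missing parent genotypes)",
                    sum(offspring$excluded)), call. = FALSE)
  }
  offspring
}
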