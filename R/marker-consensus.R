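#' Collapse candidate contigs that are identical across assemblies
#'
#' Groups candidate marker contigs from one or more assemblies at 100%
#' sequence identity: two candidates fall in the same group if one's
#' sequence, or its reverse complement, is identical to or an exact
#' substring of the other's. Grouping is the transitive closure of this
#' relation; each group's representative is its longest member (ties broken
#' by contig id). No mismatches or alignment heuristics are allowed — the
#' collapse is purely exact-match, so it is reproducible.
#'
#' @param candidates data.frame with columns \code{contig_id},
#'   \code{assembly_id}, \code{sequence} (A/C/G/T only) and, for downstream
#'   ranking, \code{passed_levels} (list column of integer stringency levels
#'   passed in that assembly).
#' @return A list of class \code{marker_groups}: \code{members} (the input
#'   with an integer \code{group} column) and \code{groups} (one row per
#'   group: \code{group}, \code{representative_id},
#'   \code{representative_seq}, \code{n_members}).
#' @export
collapse_identical <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("contig_id", "assembly_id", "sequence") %in%
                  names(candidates)))
  seqs <- candidates$sequence
  if (length(seqs) == 0L) {
    return(structure(list(
      members = cbind(candidates, group = integer(0)),
      groups = data.frame(group = integer(0),
                          representative_id = character(0),
                          representative_seq = character(0),
                          n_members = integer(0))),
      class = "marker_groups"))
  }
  if (any(nchar(seqs) == 0L) || !is_dna(seqs)) {
    stop("sequences must be non-empty and contain only A/C/G/T",
         call. = FALSE)
  }

  n <- length(seqs)
  rc <- revcomp(seqs)
  # union-find over exact identity / containment on either strand
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  matches <- function(i, j) {
    # is the shorter of (i, j) contained in the longer, on either strand?
    if (nchar(seqs[i]) > nchar(seqs[j])) { tmp <- i; i <- j; j <- tmp }
    grepl(seqs[i], seqs[j], fixed = TRUE) ||
      grepl(rc[i], seqs[j], fixed = TRUE)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (matches(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))

  # representative = longest member, ties by contig id; groups numbered by
  # representative id for a stable order
  reps <- vapply(split(seq_len(n), root), function(ix) {
    ix[order(-nchar(seqs[ix]), candidates$contig_id[ix])][1L]
  }, integer(1))
  reps <- reps[order(candidates$contig_id[reps])]
  group_of_root <- stats::setNames(seq_along(reps), names(reps))
  group <- unname(group_of_root[as.character(root)])

  members <- cbind(candidates, group = group)
  groups <- data.frame(
    group = seq_along(reps),
    representative_id = candidates$contig_id[reps],
    representative_seq = seqs[reps],
    n_members = as.integer(table(factor(group, levels = seq_along(reps)))),
    stringsAsFactors = FALSE)
  structure(list(members = members, groups = groups),
            class = "marker_groups")
}

#' Rank marker groups by cumulative stringency support
#'
#' Each group's score is the sum, over all its member candidates (i.e. over
#' all assemblies in which the locus was recovered), of the stringency
#' levels those members passed. A locus found at high stringency in many
#' alternative assemblies thus outranks one supported by a single assembly.
#' Ties are broken by the highest single-member support, then by
#' representative contig id, giving a stable total order.
#'
#' @param groups A \code{marker_groups} object from [collapse_identical()];
#'   members must carry a \code{passed_levels} list column.
#' @return data.frame of class \code{ranked_markers}, one row per group in
#'   rank order: \code{rank}, \code{representative_id}, \code{sequence},
#'   \code{score}, \code{n_assemblies}, \code{assemblies}.
#' @export
cumulative_support_rank <- function(groups) {
  stopifnot(inherits(groups, "marker_groups"))
  mem <- groups$members
  if (!"passed_levels" %in% names(mem)) {
    stop("members must carry a passed_levels column", call. = FALSE)
  }
  per_member <- vapply(mem$passed_levels, function(lv) sum(as.numeric(lv)),
                       numeric(1))
  g <- groups$groups
  score <- vapply(g$group, function(k) sum(per_member[mem$group == k]),
                  numeric(1))
  best_single <- vapply(g$group, function(k) {
    v <- per_member[mem$group == k]
    if (length(v)) max(v) else 0
  }, numeric(1))
  n_asm <- vapply(g$group, function(k) {
    length(unique(mem$assembly_id[mem$group == k]))
  }, integer(1))
  asm <- vapply(g$group, function(k) {
    paste(sort(unique(mem$assembly_id[mem$group == k])), collapse = ",")
  }, character(1))

  ord <- order(-score, -best_single, g$representative_id)
  out <- data.frame(
    rank = seq_along(ord),
    representative_id = g$representative_id[ord],
    sequence = g$representative_seq[ord],
    score = score[ord],
    n_assemblies = n_asm[ord],
    assemblies = asm[ord],
    stringsAsFactors = FALSE)
  class(out) <- c("ranked_markers", "data.frame")
  out
}

#' Extend a contig with exactly matching reads
#'
#' Greedily extends both ends of a contig using reads whose prefix (or
#' suffix, on either strand) matches the contig end exactly over at least
#' \code{min_overlap} bases — the in-silico analogue of recruiting 100%
#' identical, fully aligned reads to lengthen a candidate marker. Extension
#' proceeds base by base and stops at the first position where two
#' supporting reads disagree; the input sequence is always a substring of
#' the output.
#'
#' @param sequence Contig sequence (A/C/G/T).
#' @param reads Character vector of read sequences (searched on both
#'   strands).
#' @param min_overlap Minimum exact overlap in bases (>= 1).
#' @return The extended sequence (unchanged if no read matches).
#' @examples
#' extend_contig("AAAACCCC", "CCCCGGGG", min_overlap = 4)  # "AAAACCCCGGGG"
#' @export
extend_contig <- function(sequence, reads, min_overlap = 20) {
  min_overlap <- assert_count(min_overlap, "min_overlap", min = 1L)
  stopifnot(length(sequence) == 1L)
  if (!is_dna(sequence)) stop("invalid characters in sequence",
                              call. = FALSE)
  if (length(reads) == 0L) return(sequence)
  if (!is_dna(reads)) stop("invalid characters in reads", call. = FALSE)
  pool <- unique(c(reads, revcomp(reads)))
  budget <- sum(nchar(pool))  # hard cap against degenerate repeat walks

  extend_right <- function(seq) {
    grown <- 0L
    repeat {
      ns <- nchar(seq)
      exts <- character(0)
      for (r in pool) {
        nr <- nchar(r)
        for (L in seq.int(min(nr - 1L, ns), min_overlap)) {
          if (L < min_overlap) break
          if (substr(seq, ns - L + 1L, ns) == substr(r, 1L, L)) {
            exts <- c(exts, substr(r, L + 1L, nr))
            break  # longest overlap per read
          }
        }
      }
      exts <- exts[nchar(exts) > 0L]
      if (length(exts) == 0L) return(seq)
      # agree base-by-base until the first conflict among supporting reads
      agreed <- character(0)
      for (pos in seq_len(max(nchar(exts)))) {
        bases <- unique(substr(exts[nchar(exts) >= pos], pos, pos))
        if (length(bases) != 1L) break
        agreed <- c(agreed, bases)
      }
      if (length(agreed) == 0L) return(seq)
      seq <- paste0(seq, paste(agreed, collapse = ""))
      grown <- grown + length(agreed)
      if (grown > budget) return(seq)
    }
  }

  out <- extend_right(sequence)
  out <- revcomp(extend_right(revcomp(out)))
  out
}

#' Export the top-ranked candidate markers as FASTA
#'
#' @param ranked A \code{ranked_markers} data.frame from
#'   [cumulative_support_rank()].
#' @param k Number of top markers to keep (default 11, a typical shortlist
#'   for primer design); the whole list if fewer exist.
#' @param path Optional FASTA output path; headers carry rank, assembly
#'   provenance and cumulative score, so reruns are byte-identical.
#' @return A \code{Biostrings::DNAStringSet} of the selected markers,
#'   invisibly if \code{path} is given.
#' @export
select_top <- function(ranked, k = 11, path = NULL) {
  stopifnot(inherits(ranked, "ranked_markers"))
  k <- assert_count(k, "k", min = 1L)
  top <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(top$sequence)
  names(seqs) <- sprintf("rank%02d|%s|assemblies=%s|score=%g",
                         top$rank, top$representative_id,
                         top$assemblies, top$score)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(seqs, path)
    return(invisible(seqs))
  }
  seqs
}
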