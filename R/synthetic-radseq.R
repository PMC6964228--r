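#' Simulate a ddRAD presence/absence cohort with planted sex-linked loci
#'
#' Generates a per-contig x per-individual read-count table for a dioecious
#' cohort in which a known set of Y-hemizygous (male-only) and optionally
#' W-hemizygous (female-only) loci has been planted. Before dropout, planted
#' Y loci are present (positive read count) in every male and absent in every
#' female; autosomal loci are present in everyone. Read counts for present
#' cells are drawn from a zero-truncated Poisson so that downstream presence
#' thresholds are exercised; dropout then independently zeroes each
#' (contig, individual) cell with probability \code{dropout_prob}, emulating
#' the stochastic locus dropout of reduced-representation libraries.
#'
#' Defaults emulate a study design of 20 males and 20 females with a
#' scaled-down contig catalogue (2000 contigs) carrying 10 Y-hemizygous loci
#' at moderate (10\%) per-cell dropout.
#'
#' @param n_males,n_females Number of individuals of each sex (>= 1).
#' @param n_contigs Total number of contigs in the catalogue.
#' @param n_y_loci Number of planted Y-hemizygous (male-only) loci.
#' @param n_w_loci Number of planted W-hemizygous (female-only) loci.
#' @param dropout_prob Per-cell dropout probability in [0, 1).
#' @param mean_depth Poisson mean for read counts of present cells.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A list of class \code{rad_cohort} with elements
#'   \describe{
#'     \item{counts}{integer matrix, rows = contigs, columns = individuals}
#'     \item{sexes}{data.frame with \code{individual_id} and
#'       \code{sex} (\code{"M"}/\code{"F"}) — the sample-sex registry}
#'     \item{truth}{list with \code{y_loci}, \code{w_loci} (planted contig
#'       ids) and the simulation parameters}
#'   }
#' @examples
#' coh <- simulate_cohort(n_males = 3, n_females = 3, n_contigs = 50,
#'                        n_y_loci = 2, dropout_prob = 0, seed = 1)
#' rowSums(coh$counts[coh$truth$y_loci, ] > 0)  # present in exactly 3 males
#' @export
simulate_cohort <- function(n_males = 20, n_females = 20, n_contigs = 2000,
                            n_y_loci = 10, n_w_loci = 0,
                            dropout_prob = 0.1, mean_depth = 20, seed = 1) {
  n_males <- assert_count(n_males, "n_males", min = 1L)
  n_females <- assert_count(n_females, "n_females", min = 1L)
  n_contigs <- assert_count(n_contigs, "n_contigs", min = 1L)
  n_y_loci <- assert_count(n_y_loci, "n_y_loci")
  n_w_loci <- assert_count(n_w_loci, "n_w_loci")
  assert_prob(dropout_prob, "dropout_prob")
  if (n_y_loci + n_w_loci > n_contigs) {
    stop("planted loci cannot outnumber contigs", call. = FALSE)
  }
  if (mean_depth <= 0) stop("`mean_depth` must be positive", call. = FALSE)

  ids <- sprintf("contig%05d", seq_len(n_contigs))
  ind <- c(sprintf("M%02d", seq_len(n_males)),
           sprintf("F%02d", seq_len(n_females)))
  sex <- rep(c("M", "F"), c(n_males, n_females))

  with_local_seed(seed, {
    planted <- sample(ids, n_y_loci + n_w_loci)
    y_loci <- planted[seq_len(n_y_loci)]
    w_loci <- setdiff(planted, y_loci)

    present <- matrix(TRUE, n_contigs, n_males + n_females,
                      dimnames = list(ids, ind))
    present[y_loci, sex == "F"] <- FALSE
    present[w_loci, sex == "M"] <- FALSE

    if (dropout_prob > 0) {
      keep <- matrix(stats::runif(length(present)) >= dropout_prob,
                     nrow = n_contigs)
      present <- present & keep
    }

    counts <- matrix(0L, n_contigs, n_males + n_females,
                     dimnames = list(ids, ind))
    npos <- sum(present)
    # zero-truncated Poisson by inverse-cdf restriction to counts >= 1
    counts[present] <- stats::qpois(
      stats::runif(npos, stats::ppois(0, mean_depth), 1), mean_depth)
    storage.mode(counts) <- "integer"

    structure(list(
      counts = counts,
      sexes = data.frame(individual_id = ind, sex = sex,
                         stringsAsFactors = FALSE),
      truth = list(
        y_loci = y_loci, w_loci = w_loci,
        params = list(n_males = n_males, n_females = n_females,
                      n_contigs = n_contigs, n_y_loci = n_y_loci,
                      n_w_loci = n_w_loci, dropout_prob = dropout_prob,
                      mean_depth = mean_depth, seed = seed))
    ), class = "rad_cohort")
  })
}

#' @export
print.rad_cohort <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "rad_cohort: %d contigs x %d individuals (%dM + %dF)\n",
    p$n_contigs, p$n_males + p$n_females, p$n_males, p$n_females))
  cat(sprintf("  planted Y loci: %d, W loci: %d, dropout: %.3g\n",
              p$n_y_loci, p$n_w_loci, p$dropout_prob))
  invisible(x)
}

#' Simulate alternative de novo pseudo-assemblies of the same loci
#'
#' Emulates running several alternative de novo assemblies over the same
#' underlying loci, as done to guard marker discovery against artefacts of
#' any single assembly choice. Each true locus receives a fixed master
#' sequence; in each assembly the locus appears either as one contig carrying
#' that exact sequence, or (with probability \code{split_prob}) as two
#' overlapping fragment contigs that share the underlying locus id.
#'
#' @param cohort A \code{rad_cohort} from [simulate_cohort()]; its contig ids
#'   are the true locus ids.
#' @param n_assemblies Number of alternative assemblies (>= 1).
#' @param split_prob Probability that a locus is split into two contigs in a
#'   given assembly.
#' @param locus_length Length (bases) of each master locus sequence.
#' @param seed Integer seed.
#' @return A list of data.frames, one per assembly, each with columns
#'   \code{contig_id}, \code{locus_id}, \code{sequence}. Names are
#'   \code{asm1 ... asmN}.
#' @export
simulate_assemblies <- function(cohort, n_assemblies = 6, split_prob = 0.05,
                                locus_length = 131, seed = 1) {
  stopifnot(inherits(cohort, "rad_cohort"))
  n_assemblies <- assert_count(n_assemblies, "n_assemblies", min = 1L)
  assert_prob(split_prob, "split_prob", allow_one = TRUE)
  locus_length <- assert_count(locus_length, "locus_length", min = 20L)

  loci <- rownames(cohort$counts)
  with_local_seed(seed, {
    master <- vapply(loci, function(id) {
      paste(sample(c("A", "C", "G", "T"), locus_length, replace = TRUE),
            collapse = "")
    }, character(1))

    half <- ceiling(locus_length / 2) + 10L  # fragments overlap in the middle
    out <- lapply(seq_len(n_assemblies), function(a) {
      split <- stats::runif(length(loci)) < split_prob
      rows <- lapply(seq_along(loci), function(i) {
        id <- loci[i]
        if (!split[i]) {
          data.frame(contig_id = sprintf("asm%d_%s", a, id),
                     locus_id = id, sequence = master[[i]],
                     stringsAsFactors = FALSE)
        } else {
          s <- master[[i]]
          data.frame(
            contig_id = sprintf("asm%d_%s_frag%d", a, id, 1:2),
            locus_id = id,
            sequence = c(substr(s, 1L, half),
                         substr(s, nchar(s) - half + 1L, nchar(s))),
            stringsAsFactors = FALSE)
        }
      })
      do.call(rbind, rows)
    })
    names(out) <- sprintf("asm%d", seq_len(n_assemblies))
    out
  })
}

#' Write an assembly contig set to FASTA
#'
#' @param assembly One element of the list returned by
#'   [simulate_assemblies()] (data.frame with \code{contig_id},
#'   \code{sequence}).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path) {
  seqs <- Biostrings::DNAStringSet(assembly$sequence)
  names(seqs) <- assembly$contig_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Simulate a PCR sexing-assay call table
#'
#' Emulates screening every individual with male-linked markers plus a
#' positive control. Females never amplify male markers. A male fails to
#' amplify with probability \code{marker_failure_prob}; failure is a
#' per-individual DNA-quality event that hits all male markers jointly
#' (mirroring how a single degraded sample fails every marker, not one).
#' The positive control fails independently per individual.
#'
#' @param cohort A \code{rad_cohort}, or a sex-registry data.frame with
#'   columns \code{individual_id} and \code{sex}.
#' @param markers Character vector of male-linked marker ids.
#' @param marker_failure_prob Per-male probability of joint marker failure.
#' @param control_failure_prob Per-individual probability of positive-control
#'   failure.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{individual_id}, \code{marker_id},
#'   \code{amplified} (0/1) and \code{control} (\code{"pass"}/\code{"fail"});
#'   one row per individual x marker.
#' @export
simulate_assay_calls <- function(cohort,
                                 markers = c("Lm123977", "Lm435135"),
                                 marker_failure_prob = 0.01,
                                 control_failure_prob = 0,
                                 seed = 1) {
  reg <- if (inherits(cohort, "rad_cohort")) cohort$sexes else cohort
  stopifnot(is.data.frame(reg),
            all(c("individual_id", "sex") %in% names(reg)))
  assert_prob(marker_failure_prob, "marker_failure_prob", allow_one = TRUE)
  assert_prob(control_failure_prob, "control_failure_prob", allow_one = TRUE)
  if (length(markers) < 1L) stop("need at least one marker", call. = FALSE)

  with_local_seed(seed, {
    n <- nrow(reg)
    joint_fail <- stats::runif(n) < marker_failure_prob
    ctrl_fail <- stats::runif(n) < control_failure_prob
    amplifies <- reg$sex == "M" & !joint_fail

    out <- expand.grid(individual_id = reg$individual_id,
                       marker_id = markers,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- out[order(match(out$individual_id, reg$individual_id)), ]
    idx <- match(out$individual_id, reg$individual_id)
    out$amplified <- as.integer(amplifies[idx])
    out$control <- ifelse(ctrl_fail[idx], "fail", "pass")
    rownames(out) <- NULL
    out
  })
}

#' Simulate an offspring table with sex, parentage and covariates
#'
#' Generates the per-offspring records consumed by the sex-ratio module:
#' sex, mother/father assignment, realised pollen dispersal distance,
#' parent-pair kinship, cohort, sub-population, and seed mass/length for the
#' youngest cohort. Sexes are independent Bernoulli draws at
#' \code{prop_female} unless exact per-cohort counts are forced. Pollen
#' distances are log-normal (default median 21.9 m, matching the study
#' system's short insect-mediated pollination distances); parent kinship is
#' normal around a slightly positive mean, as expected in dense stands of
#' related adults.
#'
#' Default cohort sizes (49 young seedlings, 54 seedlings, 460 juveniles,
#' 26 adolescents; 589 total) and sub-population sizes mirror the study's
#' sampling design.
#'
#' @param n Number of offspring; derived from \code{cohort_sizes} when those
#'   are given.
#' @param prop_female Probability that an offspring is female.
#' @param cohort_sizes Named integer vector of offspring per age cohort.
#' @param subpop_sizes Named integer vector of offspring per sub-population
#'   (padded/truncated to \code{n}; remainder labelled \code{"other"}).
#' @param female_counts Optional named integer vector (same names as
#'   \code{cohort_sizes}) forcing the exact number of females per cohort.
#' @param n_mothers,n_fathers Sizes of the parental pools.
#' @param pollen_meanlog,pollen_sdlog Log-normal parameters for pollen
#'   distance in metres.
#' @param kinship_mean,kinship_sd Normal parameters for parent-pair kinship.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{offspring_id}, \code{sex},
#'   \code{mother_id}, \code{father_id}, \code{pollen_distance_m},
#'   \code{parent_kinship}, \code{cohort}, \code{subpopulation},
#'   \code{seed_mass_kg}, \code{seed_length_cm} (the last two are NA outside
#'   the young-seedling cohort).
#' @export
simulate_offspring_table <- function(
    n = 589, prop_female = 0.5,
    cohort_sizes = c("young seedling" = 49, "seedling" = 54,
                     "juvenile" = 460, "adolescent" = 26),
    subpop_sizes = c("VdM" = 222, "FP" = 143, "FF" = 123, "CU" = 93),
    female_counts = NULL,
    n_mothers = 128, n_fathers = 659,
    pollen_meanlog = log(21.9), pollen_sdlog = 0.8,
    kinship_mean = 0.068, kinship_sd = 0.09,
    seed = 1) {
  assert_prob(prop_female, "prop_female", allow_one = TRUE)
  if (!is.null(cohort_sizes)) n <- sum(cohort_sizes)
  n <- assert_count(n, "n", min = 1L)

  with_local_seed(seed, {
    cohort <- if (is.null(cohort_sizes)) rep("all", n) else
      rep(names(cohort_sizes), cohort_sizes)

    if (!is.null(female_counts)) {
      if (is.null(cohort_sizes) ||
          !all(names(female_counts) %in% names(cohort_sizes))) {
        stop("`female_counts` names must match `cohort_sizes`", call. = FALSE)
      }
      sex <- unlist(lapply(names(cohort_sizes), function(co) {
        sz <- cohort_sizes[[co]]
        nf <- female_counts[[co]]
        if (nf > sz) stop("forced female count exceeds cohort size",
                          call. = FALSE)
        sample(rep(c("F", "M"), c(nf, sz - nf)))
      }), use.names = FALSE)
    } else {
      sex <- ifelse(stats::runif(n) < prop_female, "F", "M")
    }

    subpop <- rep("other", n)
    if (!is.null(subpop_sizes)) {
      lab <- rep(names(subpop_sizes), subpop_sizes)
      k <- min(length(lab), n)
      subpop[seq_len(k)] <- lab[seq_len(k)]
    }

    young <- !is.null(cohort_sizes) && "young seedling" %in% names(cohort_sizes)
    is_young <- cohort == "young seedling"
    mass <- len <- rep(NA_real_, n)
    if (any(is_young)) {
      f <- sex == "F" & is_young
      m <- sex == "M" & is_young
      mass[f] <- pmax(0.5, stats::rnorm(sum(f), 8.9, 1.9))
      mass[m] <- pmax(0.5, stats::rnorm(sum(m), 8.4, 2.5))
      len[f] <- pmax(5, stats::rnorm(sum(f), 30.8, 2.4))
      len[m] <- pmax(5, stats::rnorm(sum(m), 30.3, 3.6))
    }

    data.frame(
      offspring_id = sprintf("off%04d", seq_len(n)),
      sex = sex,
      mother_id = sprintf("mo%03d", sample.int(n_mothers, n, replace = TRUE)),
      father_id = sprintf("fa%03d", sample.int(n_fathers, n, replace = TRUE)),
      pollen_distance_m = stats::rlnorm(n, pollen_meanlog, pollen_sdlog),
      parent_kinship = stats::rnorm(n, kinship_mean, kinship_sd),
      cohort = cohort,
      subpopulation = subpop,
      seed_mass_kg = mass,
      seed_length_cm = len,
      stringsAsFactors = FALSE)
  })
}

#' Build offspring records from printed group counts
#'
#' Deterministic constructor turning a table of female/male counts per group
#' (e.g. the margins of a published sex-ratio table) into per-offspring
#' records suitable for [group_sexratio_report()].
#'
#' @param counts data.frame with columns \code{group}, \code{females},
#'   \code{males}.
#' @param group_col Name of the grouping column in the output.
#' @return data.frame with columns \code{offspring_id}, \code{sex} and the
#'   grouping column.
#' @examples
#' offspring_from_counts(
#'   data.frame(group = c("seedling", "juvenile"),
#'              females = c(28, 247), males = c(26, 213)))
#' @export
offspring_from_counts <- function(counts, group_col = "group") {
  stopifnot(all(c("group", "females", "males") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    nf <- counts$females[i]; nm <- counts$males[i]
    data.frame(sex = rep(c("F", "M"), c(nf, nm)),
               group = counts$group[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(offspring_id = sprintf("off%04d", seq_len(nrow(out))), out)
  names(out)[names(out) == "group"] <- group_col
  out
}

#' Simulate multi-allelic codominant genotypes down a pedigree
#'
#' Founders (individuals with no listed parents) are drawn from the given
#' per-locus allele frequencies under Hardy-Weinberg equilibrium; every other
#' individual receives one allele from each parent by fair Mendelian
#' sampling. Emulates a panel of polymorphic microsatellite loci.
#'
#' @param pedigree data.frame with columns \code{individual_id},
#'   \code{mother_id}, \code{father_id} (NA for founders). Cyclic pedigrees
#'   are rejected.
#' @param n_loci Number of loci (used when \code{allele_freqs} is NULL).
#' @param n_alleles Alleles per locus (>= 2; used when \code{allele_freqs}
#'   is NULL, in which case frequencies are equal).
#' @param allele_freqs Optional named list (one element per locus) of named
#'   numeric allele-frequency vectors; each must have >= 2 alleles and sum
#'   to 1.
#' @param seed Integer seed.
#' @return Long-format data.frame with columns \code{individual_id},
#'   \code{locus}, \code{allele1}, \code{allele2}.
#' @export
simulate_genotypes <- function(pedigree, n_loci = 12, n_alleles = 8,
                               allele_freqs = NULL, seed = 1) {
  stopifnot(is.data.frame(pedigree),
            all(c("individual_id", "mother_id", "father_id") %in%
                  names(pedigree)))
  if (anyDuplicated(pedigree$individual_id)) {
    stop("duplicate individual ids in pedigree", call. = FALSE)
  }
  if (is.null(allele_freqs)) {
    n_alleles <- assert_count(n_alleles, "n_alleles", min = 2L)
    n_loci <- assert_count(n_loci, "n_loci", min = 1L)
    allele_freqs <- stats::setNames(
      rep(list(stats::setNames(rep(1 / n_alleles, n_alleles),
                               sprintf("a%02d", seq_len(n_alleles)))),
          n_loci),
      sprintf("L%02d", seq_len(n_loci)))
  }
  for (l in names(allele_freqs)) {
    f <- allele_freqs[[l]]
    if (length(f) < 2L) {
      stop(sprintf("locus %s is monomorphic (< 2 alleles)", l),
           call. = FALSE)
    }
    if (abs(sum(f) - 1) > 1e-8) {
      stop(sprintf("allele frequencies at locus %s do not sum to 1", l),
           call. = FALSE)
    }
  }

  ids <- pedigree$individual_id
  # topological order; failure to make progress means a cycle
  order_ids <- character(0)
  placed <- character(0)
  remaining <- pedigree
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$mother_id) | remaining$mother_id %in% placed) &
      (is.na(remaining$father_id) | remaining$father_id %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    placed <- c(placed, remaining$individual_id[ready])
    order_ids <- placed
    remaining <- remaining[!ready, , drop = FALSE]
  }

  with_local_seed(seed, {
    loci <- names(allele_freqs)
    ped <- pedigree[match(order_ids, pedigree$individual_id), ]
    n_ind <- nrow(ped)
    # a1[ind, locus], a2[ind, locus]; maternal allele in a1
    a1 <- a2 <- matrix(NA_character_, n_ind, length(loci),
                       dimnames = list(ped$individual_id, loci))
    founder <- is.na(ped$mother_id) & is.na(ped$father_id)
    for (l in loci) {
      f <- allele_freqs[[l]]
      nf <- sum(founder)
      if (nf > 0) {
        a1[founder, l] <- sample(names(f), nf, replace = TRUE, prob = f)
        a2[founder, l] <- sample(names(f), nf, replace = TRUE, prob = f)
      }
    }
    for (i in which(!founder)) {
      mo <- ped$mother_id[i]; fa <- ped$father_id[i]
      for (l in loci) {
        f <- allele_freqs[[l]]
        a1[i, l] <- if (is.na(mo)) sample(names(f), 1, prob = f) else
          sample(c(a1[mo, l], a2[mo, l]), 1)
        a2[i, l] <- if (is.na(fa)) sample(names(f), 1, prob = f) else
          sample(c(a1[fa, l], a2[fa, l]), 1)
      }
    }

    out <- data.frame(
      individual_id = rep(ids, each = length(loci)),
      locus = rep(loci, times = length(ids)),
      allele1 = as.vector(t(a1[ids, , drop = FALSE])),
      allele2 = as.vector(t(a2[ids, , drop = FALSE])),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Read/write pipeline input tables
#'
#' \code{write_count_table()}/\code{read_count_table()} handle the
#' contig x individual read-count TSV (first column \code{contig_id});
#' \code{write_sex_registry()}/\code{read_sex_registry()} handle the
#' sample-sex CSV (\code{individual_id}, \code{sex} in M/F/U).
#'
#' @param counts Integer matrix with contig rownames and individual colnames.
#' @param registry data.frame with \code{individual_id} and \code{sex}.
#' @param path File path.
#' @return Readers return the parsed object; writers return \code{path}
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(contig_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname pipeline_io
#' @export
write_sex_registry <- function(registry, path) {
  utils::write.csv(registry[, c("individual_id", "sex")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sex_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "sex") %in% names(reg))) {
    stop("sex registry must have individual_id and sex columns",
         call. = FALSE)
  }
  if (!all(reg$sex %in% c("M", "F", "U"))) {
    stop("sex must be one of M, F, U", call. = FALSE)
  }
  reg
}
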