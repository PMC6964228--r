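# Independent oracles used to cross-check package computations. These are
# deliberately written as naive enumerations, structurally unlike the
# implementations they verify.

# Two-sided binomial p-value by direct enumeration of all n + 1 outcomes.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  probs <- vapply(0:n, function(i) {
    choose(n, i) * p0^i * (1 - p0)^(n - i)
  }, numeric(1))
  obs <- probs[k + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Privacy-rarefaction support by looping over every (male-subset,
# female-subset) pair with explicit presence checks.
oracle_privacy_support <- function(presence, male_ids, female_ids, s) {
  ms <- utils::combn(male_ids, s, simplify = FALSE)
  fs <- utils::combn(female_ids, s, simplify = FALSE)
  sup_m <- sup_f <- stats::setNames(numeric(nrow(presence)),
                                    rownames(presence))
  total <- 0L
  for (m in ms) for (f in fs) {
    total <- total + 1L
    for (cg in rownames(presence)) {
      in_m <- presence[cg, m]
      in_f <- presence[cg, f]
      if (all(in_m) && !any(in_f)) sup_m[cg] <- sup_m[cg] + 1
      if (all(in_f) && !any(in_m)) sup_f[cg] <- sup_f[cg] + 1
    }
  }
  list(male = sup_m / total, female = sup_f / total)
}

# Loiselle per-locus formula transcribed symbol by symbol for two
# individuals at a single locus (dosages as plain numbers).
oracle_loiselle_single_locus <- function(geno_i, geno_j, freqs, n_copies) {
  alleles <- names(freqs)
  dose <- function(g) {
    vapply(alleles, function(a) sum(g == a) / 2, numeric(1))
  }
  pi <- dose(geno_i); pj <- dose(geno_j)
  num <- sum((pi - freqs) * (pj - freqs)) +
    sum(freqs * (1 - freqs)) / (n_copies - 1)
  den <- sum(freqs * (1 - freqs))
  num / den
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

make_toy_registry <- function(n_m, n_f) {
  data.frame(
    individual_id = c(sprintf("M%02d", seq_len(n_m)),
                      sprintf("F%02d", seq_len(n_f))),
    sex = rep(c("M", "F"), c(n_m, n_f)),
    stringsAsFactors = FALSE)
}
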