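# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive permutation logrank p-value: enumerate all assignments of the
# observed group sizes and rank the package's chi-square statistic among
# them (the statistic itself is recomputed per assignment via survdiff so
# the oracle does not share the package's logrank code)
perm_logrank_p <- function(time, event, group) {
  n <- length(time)
  n1 <- sum(group)
  combos <- utils::combn(n, n1)
  stat <- function(g) {
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }
  obs <- stat(group)
  perm <- apply(combos, 2, function(idx) {
    g <- rep(FALSE, n); g[idx] <- TRUE
    stat(g)
  })
  mean(perm >= obs - 1e-12)
}

# hand step-up Benjamini-Hochberg
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small recovery-suite configuration: 1 training + 3 validation cohorts,
# 5 prognostic genes (HR 2.5-3, activation 25-35%), 120 null genes of which
# 20 are activated but non-prognostic
recovery_config <- function(seed) {
  sim_config(seed = seed, n_cohorts = 4,
             n_tumour = c(600, 250, 250, 250),
             n_nontumour = c(100, 60, 60, 60),
             cohort_roles = c("training", rep("validation", 3)))
}

# same cohort structure with no prognostic signal at all
null_config <- function(seed) {
  sim_config(seed = seed, n_genes = 120,
             n_predominant = c(testis = 7, placenta = 7, esc = 6),
             prognostic_genes = integer(0),
             n_cohorts = 4,
             n_tumour = c(600, 250, 250, 250),
             n_nontumour = c(100, 60, 60, 60),
             cohort_roles = c("training", rep("validation", 3)))
}
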