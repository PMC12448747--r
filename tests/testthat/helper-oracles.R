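# Independent oracles used across the suite. These re-derive expectations by
# brute force or closed form and never call the code paths they check.

# step-up BH from the definition: q_(i) = min over j >= i of p_(j) * m / j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# NB upper/lower tail by direct pmf summation; the upper tail is taken as
# the complement of a finite lower sum so there is no truncation error
nb_tail_brute_force <- function(obs, mu, size, upper = TRUE) {
  if (upper) {
    if (obs <= 0) return(1)
    1 - sum(dnbinom(0:(obs - 1), size = size, mu = mu))
  } else {
    sum(dnbinom(0:obs, size = size, mu = mu))
  }
}

# exact null P(rho <= x) for an m-guide gene (all guides selected) by grid
# enumeration over the m-dimensional uniform rank cube
rra_null_prob_grid <- function(x, m, grid = 400L) {
  u <- (seq_len(grid) - 0.5) / grid
  if (m == 1L) return(mean(pbeta(u, 1, 1) <= x))
  stopifnot(m == 2L)  # enumeration used for tiny instances only
  g <- expand.grid(u1 = u, u2 = u)
  r1 <- pmin(g$u1, g$u2); r2 <- pmax(g$u1, g$u2)
  rho <- pmin(pbeta(r1, 1, 2), pbeta(r2, 2, 1))
  mean(rho <= x)
}

# per-record re-statement of the peptide filter rules
peptide_keep_brute_force <- function(pep) {
  !pep$contaminant &
    (pep$intensity_light + pep$intensity_heavy) >= 1000 &
    pep$ratio >= 0.01 & pep$ratio <= 100
}

# per-record re-statement of the junction classification rules
junction_class_brute_force <- function(dpsi, presence,
                                       dpsi_cut = 0.10, lo = 0.05,
                                       hi = 0.10) {
  n <- length(dpsi)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (dpsi[i] > dpsi_cut && presence[i] < lo) "cryptic_gain"
      else if (dpsi[i] < -dpsi_cut && presence[i] > hi) "cryptic_loss"
      else if (abs(dpsi[i]) > dpsi_cut) "significant_noncryptic"
      else "none"
  }
  out
}

# per-record re-statement of the polyA rules
polya_class_brute_force <- function(cfc, fdr, cut = 0.25, fcut = 0.05) {
  out <- character(length(cfc))
  for (i in seq_along(cfc)) {
    out[i] <- if (fdr[i] < fcut && cfc[i] >= cut) "lengthening"
      else if (fdr[i] < fcut && cfc[i] <= -cut) "shortening"
      else "none"
  }
  out
}

# median-ratio size factors recomputed from the definition
median_ratio_brute_force <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[keep, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  apply(m[keep, , drop = FALSE], 2, function(col) median(col / geo))
}

`%0%` <- function(x, default) ifelse(is.na(x), default, x)

# small random guide-pair call fixture with known recombination labels
make_call_fixture <- function(n_genes = 5, n_calls = 60, recomb = 0.3,
                              seed = 1) {
  set.seed(seed)
  genes <- c(paste0("GENE", seq_len(n_genes)), "NT")
  lib <- data.frame(
    guide_id = c(paste0(genes, "_c1_A"), paste0(genes, "_c1_B")),
    gene = rep(genes, 2),
    guide_pair_id = rep(paste0(genes, "_c1"), 2),
    stringsAsFactors = FALSE)
  ia <- sample(length(genes), n_calls, replace = TRUE)
  ib <- ifelse(runif(n_calls) < recomb,
               sample(length(genes), n_calls, replace = TRUE), ia)
  data.frame(read_id = seq_len(n_calls),
             guide_a = paste0(genes[ia], "_c1_A"),
             guide_b = paste0(genes[ib], "_c1_B"),
             sample = sample(c("high", "low"), n_calls, replace = TRUE),
             stringsAsFactors = FALSE) -> calls
  list(calls = calls, library = lib,
       truth_same = genes[ia] == genes[ib])
}
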