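# Dual-guide FACS screen scoring: parser-style recombination filtering,
# count aggregation and normalization, negative-binomial guide tests, and
# gene-level robust rank aggregation (RRA) with a permutation null.

#' Filter recombined dual-guide read pairs
#'
#' A dual-guide cassette carries two guides against the same gene; lentiviral
#' template switching can pair guides from different cassettes. A call is
#' kept iff both guides target the same gene; NT-NT pairs are kept as
#' controls. Calls naming a guide absent from the library annotation are
#' routed to an error table, never silently dropped.
#'
#' @param calls data.frame with columns `read_id`, `guide_a`, `guide_b`
#'   (and optionally `sample`, preserved).
#' @param library data.frame with columns `guide_id`, `gene` (and optionally
#'   `guide_pair_id`).
#' @return A list: `kept` (subset of `calls`), `n_recombined` (count of
#'   removed cross-gene pairs), `errors` (calls with unknown guides, with an
#'   `error` reason column).
#' @export
filter_recombined_pairs <- function(calls, library) {
  stopifnot(all(c("guide_a", "guide_b") %in% names(calls)),
            all(c("guide_id", "gene") %in% names(library)))
  gene_of <- setNames(library$gene, library$guide_id)
  ga <- gene_of[calls$guide_a]
  gb <- gene_of[calls$guide_b]
  unknown <- is.na(ga) | is.na(gb)
  errors <- calls[unknown, , drop = FALSE]
  if (nrow(errors) > 0)
    errors$error <- ifelse(is.na(ga[unknown]) & is.na(gb[unknown]),
                           "both guides unknown",
                           ifelse(is.na(ga[unknown]), "guide_a unknown",
                                  "guide_b unknown"))
  same <- !unknown & ga == gb
  list(kept = calls[same, , drop = FALSE],
       n_recombined = sum(!unknown & ga != gb),
       errors = errors)
}

#' Aggregate kept guide-pair calls into per-cassette counts
#'
#' Tallies calls by cassette and sample; cassettes in the library with no
#' calls get explicit zero rows. A kept call is assigned to the cassette of
#' `guide_a` (for intact pairs both guides name the same cassette; same-gene
#' recombinants, which survive the gene-level filter, are attributed to the
#' cassette of guide A).
#'
#' @param kept data.frame of kept calls (`guide_a`, `sample`).
#' @param library guide annotation with `guide_id`, `gene`, `guide_pair_id`.
#' @param samples Sample names for the output columns; default the samples
#'   present in `kept`.
#' @return data.frame with `guide_pair_id`, `gene`, one count column per
#'   sample.
#' @export
aggregate_counts <- function(kept, library, samples = NULL) {
  stopifnot("guide_pair_id" %in% names(library))
  cass <- unique(library[, c("guide_pair_id", "gene")])
  samples <- samples %||% unique(kept$sample)
  if (length(samples) == 0L) samples <- "sample1"
  out <- data.frame(guide_pair_id = cass$guide_pair_id, gene = cass$gene,
                    stringsAsFactors = FALSE)
  pair_of <- setNames(library$guide_pair_id, library$guide_id)
  idx <- match(pair_of[kept$guide_a], cass$guide_pair_id)
  smp <- if ("sample" %in% names(kept)) kept$sample
         else rep(samples[1L], nrow(kept))
  for (s in samples)
    out[[s]] <- tabulate(idx[smp == s], nbins = nrow(cass))
  out
}

#' Remove low-count cassettes
#'
#' Retains cassettes whose mean count across the named samples is at least
#' `min_count`.
#'
#' @param counts Count table (`guide_pair_id`, `gene`, sample columns).
#' @param min_count Minimum mean count (default 10).
#' @param samples Sample columns to average over; default all non-annotation
#'   columns.
#' @return Filtered count table.
#' @export
filter_low_count_guides <- function(counts, min_count = 10, samples = NULL) {
  stopifnot_scalar_number(min_count, "min_count", lower = 0)
  samples <- samples %||% setdiff(names(counts), c("guide_pair_id", "gene"))
  keep <- rowMeans(as.matrix(counts[, samples, drop = FALSE])) >= min_count
  counts[keep, , drop = FALSE]
}

#' Median-ratio count normalization
#'
#' Size factor per sample = median over cassettes of count / geometric mean
#' of the cassette's row (cassettes containing any zero are excluded from
#' both). Falls back to total-count scaling when fewer than 100 all-nonzero
#' cassettes are available.
#'
#' @param counts Count table (`guide_pair_id`, `gene`, sample columns).
#' @param method `"median"` (median-ratio, default) or `"total"`.
#' @return A list: `normalized` (same shape, counts divided by size
#'   factors), `size_factors` (named numeric).
#' @export
normalize_counts <- function(counts, method = c("median", "total")) {
  method <- match.arg(method)
  samples <- setdiff(names(counts), c("guide_pair_id", "gene"))
  m <- as.matrix(counts[, samples, drop = FALSE])
  if (any(colSums(m) == 0)) stop("all-zero sample column", call. = FALSE)
  nonzero <- rowSums(m == 0) == 0L
  if (method == "median" && sum(nonzero) >= 100L) {
    loggeo <- rowMeans(log(m[nonzero, , drop = FALSE]))
    sf <- apply(exp(log(m[nonzero, , drop = FALSE]) - loggeo), 2L, median)
  } else {
    sf <- colSums(m) / 1e6
  }
  norm <- counts
  norm[, samples] <- sweep(m, 2L, sf, "/")
  list(normalized = norm, size_factors = setNames(sf, samples))
}

#' Negative-binomial guide test between sorted bins
#'
#' Fits a mean-variance trend `var(mu) = mu + k * mu^b` by regressing
#' `log(pmax(var - mean, eps))` on `log(mean)` across cassettes (all supplied
#' sample columns), then, per cassette, with reference mean `mu` taken from
#' the low bin, computes one-sided NB tail probabilities for the observed
#' high-bin count: `p_high = P(X >= high)` (enrichment in high),
#' `p_low = P(X <= high)` (depletion from high). Falls back to Poisson tails
#' when the trend fit degenerates. Log2 fold change uses a symmetric
#' pseudocount of 0.5.
#'
#' @param normalized Normalized count table (`guide_pair_id`, `gene`, sample
#'   columns).
#' @param high,low Character vectors of sample columns for the high and low
#'   bins (means taken across replicates).
#' @param pseudocount Pseudocount for the LFC (default 0.5).
#' @return data.frame with `guide_pair_id`, `gene`, `base_mean`, `lfc`,
#'   `p_low`, `p_high`.
#' @export
guide_nb_test <- function(normalized, high, low, pseudocount = 0.5) {
  stopifnot(all(c(high, low) %in% names(normalized)))
  hm <- rowMeans(as.matrix(normalized[, high, drop = FALSE]))
  lm_ <- rowMeans(as.matrix(normalized[, low, drop = FALSE]))
  all_cols <- as.matrix(normalized[, c(high, low), drop = FALSE])
  mu_all <- rowMeans(all_cols)
  var_all <- apply(all_cols, 1L, var)

  fit <- nb_trend_fit(mu_all, var_all)
  mu <- pmax(lm_, pseudocount)  # pseudocount floor when the low bin is empty
  obs <- round(hm)
  if (fit$poisson) {
    p_high <- ppois(obs - 1, mu, lower.tail = FALSE)
    p_low <- ppois(obs, mu)
  } else {
    size <- mu^(2 - fit$b) / fit$k
    p_high <- pnbinom(obs - 1, size = size, mu = mu, lower.tail = FALSE)
    p_low <- pnbinom(obs, size = size, mu = mu)
  }
  data.frame(guide_pair_id = normalized$guide_pair_id,
             gene = normalized$gene, base_mean = mu,
             lfc = log2((hm + pseudocount) / (lm_ + pseudocount)),
             p_low = pmin(pmax(p_low, .Machine$double.xmin), 1),
             p_high = pmin(pmax(p_high, .Machine$double.xmin), 1),
             stringsAsFactors = FALSE)
}

# regression of log((var - mean)+) on log(mean); returns k, b of
# var(mu) = mu + k*mu^b, or poisson = TRUE when the fit degenerates.
# Tukey's resistant line keeps the minority of true-hit cassettes (whose
# between-bin variance is biological, not technical) from inflating the trend
nb_trend_fit <- function(mu, v) {
  ok <- is.finite(mu) & is.finite(v) & mu > 0 & v > mu
  if (sum(ok) < 10L) return(list(poisson = TRUE))
  fit <- stats::line(log(mu[ok]), log(v[ok] - mu[ok]))
  b <- stats::coef(fit)[2L]
  k <- exp(stats::coef(fit)[1L])
  if (!is.finite(b) || !is.finite(k) || k <= 0)
    return(list(poisson = TRUE))
  list(poisson = FALSE, k = unname(k), b = unname(b))
}

#' Robust rank aggregation score for one gene's guide ranks
#'
#' With a gene's selected guides at ascending percentile ranks `r_(1..k)` out
#' of `m` guides total, the score is
#' `rho = min_j P(Beta(j, m - j + 1) <= r_(j))`, the smallest Beta
#' order-statistic tail probability. A gene with no selected guides scores 1.
#'
#' @param ranks Percentile ranks in (0, 1) of the gene's selected guides.
#' @param m Total number of guides the gene has (>= `length(ranks)`).
#' @return The RRA rho score in (0, 1].
#' @export
rra_rho <- function(ranks, m = length(ranks)) {
  k <- length(ranks)
  if (k == 0L) return(1)
  stopifnot(m >= k)
  r <- sort(ranks)
  j <- seq_len(k)
  min(pbeta(r, j, m - j + 1))
}

#' Gene-level robust rank aggregation with permutation null
#'
#' Ranks all cassettes by the directional NB p-value (percentile rank
#' `(rank - 0.5) / N`, ties broken by cassette id), selects each gene's
#' guides with p below `alpha`, scores genes by [rra_rho()], and assesses
#' significance against a permutation null built by drawing each gene's
#' guide ranks uniformly (selection in the null uses the empirical fraction
#' of cassettes passing the `alpha` cut, keeping observed and null selection
#' rules consistent). Non-targeting cassettes participate in the ranking but
#' are excluded from gene aggregation. Permutation p-values carry the +1
#' correction; FDR is Benjamini-Hochberg within the direction.
#'
#' @param guide_stats Output of [guide_nb_test()].
#' @param direction `"neg"` (rank by `p_low`: depletion from the high bin)
#'   or `"pos"` (rank by `p_high`).
#' @param alpha Guide selection threshold on the directional p (default
#'   0.25); guides failing it contribute nothing.
#' @param n_perm Number of null draws per gene size (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param nt_gene Gene sentinel for non-targeting cassettes.
#' @return data.frame with `gene`, `n_guides`, `rho`, `p`, `fdr`,
#'   `gene_lfc` (median guide LFC), sorted by `p` then `rho`.
#' @export
gene_rra <- function(guide_stats, direction = c("neg", "pos"), alpha = 0.25,
                     n_perm = 1000L, seed = 1L, nt_gene = NT_GENE) {
  direction <- match.arg(direction)
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                          allow_equal_lower = FALSE)
  stopifnot_scalar_number(n_perm, "n_perm", lower = 100)
  p <- if (direction == "neg") guide_stats$p_low else guide_stats$p_high
  n <- length(p)
  ord <- order(p, guide_stats$guide_pair_id)
  rank_ <- integer(n); rank_[ord] <- seq_len(n)
  r <- (rank_ - 0.5) / n
  selected <- p < alpha
  sel_frac <- mean(selected)

  targeting <- guide_stats$gene != nt_gene
  genes <- split(seq_len(n)[targeting], guide_stats$gene[targeting])
  rho <- vapply(genes, function(i) rra_rho(r[i][selected[i]], length(i)),
                numeric(1L))
  m_of <- lengths(genes)
  gene_lfc <- vapply(genes, function(i) median(guide_stats$lfc[i]),
                     numeric(1L))

  # null rho distribution, shared across genes with the same guide count
  perm_p <- with_seed(seed, {
    out <- numeric(length(genes))
    for (m in unique(m_of)) {
      u <- matrix(runif(n_perm * m), n_perm, m)
      null_rho <- apply(u, 1L, function(x) rra_rho(x[x < sel_frac], m))
      which_m <- which(m_of == m)
      ecdf_sorted <- sort(null_rho)
      cnt <- findInterval(rho[which_m], ecdf_sorted)
      out[which_m] <- (1 + cnt) / (n_perm + 1)
    }
    out
  })

  res <- data.frame(gene = names(genes), n_guides = as.integer(m_of),
                    rho = rho, p = perm_p,
                    fdr = p.adjust(perm_p, "BH"),
                    gene_lfc = gene_lfc, stringsAsFactors = FALSE,
                    row.names = NULL)
  res[order(res$p, res$rho), , drop = FALSE]
}

#' Combine directional RRA results into a screen summary
#'
#' Per gene, effect is the median guide LFC; p is the smaller of the two
#' directional permutation p-values, Bonferroni-doubled and capped at 1; the
#' winning direction is recorded.
#'
#' @param scores_neg,scores_pos [gene_rra()] outputs for the two directions.
#' @param screen_id Label stamped on every row.
#' @return data.frame with `screen_id`, `gene`, `effect`, `p`, `direction`,
#'   plus the directional p and FDR columns.
#' @export
screen_summary <- function(scores_neg, scores_pos, screen_id = "screen") {
  i <- match(scores_neg$gene, scores_pos$gene)
  stopifnot(!anyNA(i))
  pneg <- scores_neg$p
  ppos <- scores_pos$p[i]
  data.frame(screen_id = screen_id, gene = scores_neg$gene,
             effect = scores_neg$gene_lfc,
             p = pmin(2 * pmin(pneg, ppos), 1),
             direction = ifelse(pneg <= ppos, "neg", "pos"),
             p_neg = pneg, p_pos = ppos,
             fdr_neg = scores_neg$fdr, fdr_pos = scores_pos$fdr[i],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score a dual-guide FACS screen end to end
#'
#' Chains low-count filtering, median-ratio normalization, the NB guide test
#' and directional RRA into one call.
#'
#' @param counts Count table (`guide_pair_id`, `gene`, sample columns).
#' @param high,low Sample columns of the high and low bins.
#' @param min_count Low-count filter threshold (mean across `c(high, low)`).
#' @param alpha,n_perm,seed Passed to [gene_rra()].
#' @param screen_id Label for the summary.
#' @return A list: `guide_stats`, `gene_neg`, `gene_pos`, `summary`.
#' @export
score_screen <- function(counts, high, low, min_count = 10, alpha = 0.25,
                         n_perm = 1000L, seed = 1L, screen_id = "screen") {
  counts <- filter_low_count_guides(counts, min_count, c(high, low))
  norm <- normalize_counts(counts)$normalized
  gs <- guide_nb_test(norm, high, low)
  neg <- gene_rra(gs, "neg", alpha, n_perm, seed)
  pos <- gene_rra(gs, "pos", alpha, n_perm, seed + 1L)
  list(guide_stats = gs, gene_neg = neg, gene_pos = pos,
       summary = screen_summary(neg, pos, screen_id))
}
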