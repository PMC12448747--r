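# Cross-screen fixed-effects meta-analysis: harmonization of per-screen gene
# summaries to a common z/beta/SE scale, inverse-variance pooling with
# heterogeneity statistics, novelty classification, and permutation-FDR
# hypergeometric enrichment.

#' Harmonize a screen summary to standardized beta / SE scale
#'
#' Effects are aligned across screens by converting them to standardized
#' betas represented by z-scores: extreme p-values are stabilized by
#' truncation to `[p_floor, 1 - eps]` (making results conservative),
#' `z = sign(effect) * qnorm(1 - p/2)`, the effect is optionally z-scored
#' within the screen, and the standard error is derived by dividing the beta
#' estimate by the absolute value of the z-score. Rows with `z = 0` (effect
#' exactly 0) receive an infinite SE sentinel and zero pooling weight.
#'
#' @param summary data.frame with `gene`, `effect`, `p` (and optionally
#'   `screen_id`, preserved).
#' @param p_floor Lower truncation bound for p (default 1e-300).
#' @param standardize If `TRUE` (default), z-score effects within the screen
#'   before deriving SEs; screens report phenotype scores on different
#'   scales.
#' @param two_sided If `TRUE` (default) the reported p is two-sided.
#' @return data.frame with `gene`, `z`, `beta_std`, `se`, `p_trunc` (plus
#'   `screen_id` if present).
#' @export
harmonize <- function(summary, p_floor = 1e-300, standardize = TRUE,
                      two_sided = TRUE) {
  stopifnot(all(c("gene", "effect", "p") %in% names(summary)),
            all(summary$p > 0), all(summary$p <= 1))
  p_trunc <- pmin(pmax(summary$p, p_floor), 1 - 1e-16)
  # upper-tail parameterization keeps z finite down to the p floor, where
  # 1 - p/2 would round to 1 in double precision
  z <- sign(summary$effect) *
    if (two_sided) qnorm(p_trunc / 2, lower.tail = FALSE)
    else qnorm(p_trunc, lower.tail = FALSE)
  beta_std <- if (standardize) summary$effect / sd(summary$effect)
              else summary$effect
  se <- ifelse(z == 0, Inf, abs(beta_std / z))
  out <- data.frame(gene = summary$gene, z = z, beta_std = beta_std,
                    se = se, p_trunc = p_trunc, stringsAsFactors = FALSE)
  if ("screen_id" %in% names(summary)) out$screen_id <- summary$screen_id
  out
}

#' Inverse-variance fixed-effects pooling for one gene
#'
#' Weights `w_i = 1/se_i^2`; `pooled_beta = sum(w*b)/sum(w)`;
#' `pooled_se = sum(w)^(-1/2)`; two-sided normal p; Cochran's
#' `Q = sum(w * (b - pooled_beta)^2)` with `df = k - 1` and
#' `I2 = max(0, (Q - df)/Q)` (0 when Q = 0). Records with non-finite SE are
#' excluded and tallied.
#'
#' @param beta Per-screen standardized effects.
#' @param se Per-screen standard errors (same length).
#' @return A one-row data.frame with `pooled_beta`, `pooled_se`, `z_meta`,
#'   `p_meta`, `Q`, `df`, `I2`, `k` (screens used), `n_excluded`; or `NULL`
#'   when no usable record remains.
#' @export
fixed_effect_pool <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(ok)) return(NULL)
  b <- beta[ok]; w <- 1 / se[ok]^2
  pooled_beta <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_beta / pooled_se
  q <- sum(w * (b - pooled_beta)^2)
  k <- length(b)
  data.frame(pooled_beta = pooled_beta, pooled_se = pooled_se, z_meta = z,
             p_meta = 2 * pnorm(-abs(z)), Q = q, df = k - 1L,
             I2 = if (q > 0) max(0, (q - (k - 1L)) / q) else 0,
             k = k, n_excluded = sum(!ok))
}

#' Pool harmonized screens gene by gene
#'
#' Joins harmonized records by gene symbol; genes missing from some screens
#' are pooled over the screens that contain them, with coverage recorded.
#'
#' @param harmonized List of [harmonize()] outputs (one per screen).
#' @param screen_ids Optional names for the screens.
#' @return data.frame with one row per gene: pooled statistics from
#'   [fixed_effect_pool()], `q_meta` (BH over `p_meta`), `coverage`
#'   (comma-separated contributing screen ids), plus a `skipped` attribute
#'   listing genes with no usable record.
#' @export
pool_screens <- function(harmonized, screen_ids = NULL) {
  stopifnot(length(harmonized) >= 1L)
  screen_ids <- screen_ids %||% names(harmonized) %||%
    paste0("screen", seq_along(harmonized))
  genes <- sort(unique(unlist(lapply(harmonized, `[[`, "gene"))))
  bmat <- semat <- matrix(NA_real_, length(genes), length(harmonized))
  for (s in seq_along(harmonized)) {
    i <- match(harmonized[[s]]$gene, genes)
    bmat[i, s] <- harmonized[[s]]$beta_std
    semat[i, s] <- harmonized[[s]]$se
  }
  rows <- vector("list", length(genes))
  skipped <- character(0)
  for (g in seq_along(genes)) {
    pooled <- fixed_effect_pool(bmat[g, ], semat[g, ])
    if (is.null(pooled)) { skipped <- c(skipped, genes[g]); next }
    pooled$gene <- genes[g]
    has <- is.finite(semat[g, ]) & semat[g, ] > 0
    pooled$coverage <- paste(screen_ids[has], collapse = ",")
    rows[[g]] <- pooled
  }
  out <- do.call(rbind, rows)
  out <- out[, c("gene", "pooled_beta", "pooled_se", "z_meta", "p_meta",
                 "Q", "df", "I2", "k", "coverage")]
  out$q_meta <- bh_fdr(out$p_meta)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Fixed-effects meta-analysis over all screen combinations
#'
#' Runs [harmonize()] + [pool_screens()] for every subset of screens of size
#' at least 2.
#'
#' @param summaries List of screen summary data.frames (`gene`, `effect`,
#'   `p`), named by screen id.
#' @param ... Passed to [harmonize()].
#' @return Named list (subset ids joined by `+`) of [pool_screens()] tables.
#' @export
meta_all_combinations <- function(summaries, ...) {
  stopifnot(length(summaries) >= 2L)
  ids <- names(summaries) %||% paste0("screen", seq_along(summaries))
  names(summaries) <- ids
  harm <- lapply(summaries, harmonize, ...)
  out <- list()
  for (size in 2:length(ids)) {
    for (subset in asplit(combn(ids, size), 2L)) {
      key <- paste(subset, collapse = "+")
      tab <- pool_screens(harm[subset], subset)
      if (nrow(tab) == 0L)
        warning("empty gene intersection for subset ", key)
      out[[key]] <- tab
    }
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement; stable under permutation of the
#' input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Flag hits novel to the meta-analysis
#'
#' A gene is novel iff it is significant after FDR adjustment of the
#' meta-analysis (`q_meta < q_threshold`) but not significant after multiple
#' test correction in any constituent screen (`q_s >= q_threshold` for every
#' screen). For screens designated effect-filtered, the gene must
#' additionally pass `|effect - mean(effect)| >= lfc_threshold` in that
#' screen (the +/-1 LFC filter relative to the total population). Direction
#' of novelty follows the sign of the pooled beta.
#'
#' @param meta A [pool_screens()] table.
#' @param summaries Named list of constituent screen summaries (`gene`,
#'   `effect`, `p`); per-screen q-values are computed by [bh_fdr()] within
#'   each screen.
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold Effect filter for designated screens (default 1).
#' @param lfc_screens Character vector naming the screens subject to the
#'   effect filter (default none).
#' @return `meta` with added `novel` (logical), `novelty_direction`
#'   (`"up"`/`"down"`/`NA`), and `novelty_eligible` (FALSE when a constituent
#'   q is missing for the gene).
#' @export
classify_novelty <- function(meta, summaries, q_threshold = 0.05,
                             lfc_threshold = 1, lfc_screens = character(0)) {
  ids <- names(summaries) %||% paste0("screen", seq_along(summaries))
  names(summaries) <- ids
  used <- unique(unlist(strsplit(meta$coverage, ",", fixed = TRUE)))
  used <- intersect(ids, used)

  all_ns <- rep(TRUE, nrow(meta))      # not significant in every constituent
  eligible <- rep(TRUE, nrow(meta))
  lfc_ok <- rep(TRUE, nrow(meta))
  for (s in used) {
    sm <- summaries[[s]]
    qs <- bh_fdr(sm$p)[match(meta$gene, sm$gene)]
    miss <- is.na(qs)
    eligible <- eligible & !miss
    all_ns <- all_ns & (miss | qs >= q_threshold)
    if (s %in% lfc_screens) {
      eff <- sm$effect[match(meta$gene, sm$gene)]
      centered <- eff - mean(sm$effect)
      lfc_ok <- lfc_ok & !is.na(centered) & abs(centered) >= lfc_threshold
    }
  }
  novel <- eligible & meta$q_meta < q_threshold & all_ns & lfc_ok
  meta$novel <- novel
  meta$novelty_direction <- ifelse(novel,
                                   ifelse(meta$pooled_beta > 0, "up", "down"),
                                   NA_character_)
  meta$novelty_eligible <- eligible
  meta
}

#' Hypergeometric enrichment with permutation FDR
#'
#' Per term, `p_hyper` is the upper-tail hypergeometric probability of
#' observing at least `k` hits in the term given the hit-list and universe
#' sizes. The permutation FDR draws `n_perm` random hit sets of the same
#' size from the universe, recomputes all term p-values, and reports, per
#' term, the mean over permutations of (null terms with p <= p_obs) /
#' max(1, observed terms with p <= p_obs), clamped to [0, 1].
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param term_genes Named list mapping term id to its gene vector (each
#'   intersected with the universe).
#' @param universe Character vector of all testable genes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `p_hyper`,
#'   `perm_fdr`, sorted by `p_hyper`; empty for an empty hit set.
#' @export
hypergeom_enrichment <- function(hits, term_genes, universe,
                                 n_perm = 1000L, seed = 1L) {
  hits <- intersect(unique(hits), universe)
  if (length(hits) == 0L)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_hyper = numeric(0),
                      perm_fdr = numeric(0)))
  term_genes <- lapply(term_genes, intersect, universe)
  term_genes <- term_genes[lengths(term_genes) > 0L]
  nN <- length(universe); n <- length(hits)
  Ks <- lengths(term_genes)

  term_p <- function(hit_set) {
    ks <- vapply(term_genes, function(g) length(intersect(g, hit_set)),
                 integer(1L))
    # P(X >= k), X ~ Hypergeometric(K, N - K, n)
    pmin(phyper(ks - 1L, Ks, nN - Ks, n, lower.tail = FALSE) +
           .Machine$double.xmin, 1)
  }
  p_obs <- term_p(hits)

  fdr <- with_seed(seed, {
    acc <- numeric(length(p_obs))
    n_obs_le <- vapply(p_obs, function(x) sum(p_obs <= x), numeric(1L))
    for (b in seq_len(n_perm)) {
      p_null <- term_p(sample(universe, n))
      sorted_null <- sort(p_null)
      acc <- acc + findInterval(p_obs, sorted_null) / pmax(1, n_obs_le)
    }
    pmin(acc / n_perm, 1)
  })
  out <- data.frame(term = names(term_genes), k = vapply(
                      term_genes, function(g) length(intersect(g, hits)),
                      integer(1L)),
                    K = as.integer(Ks), n = n, N = nN,
                    p_hyper = p_obs, perm_fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_hyper), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, tab-separated genes).
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, character(1L), 1L))
}
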