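# RNA-seq normalization and noise-filter chain, plus the cryptic splice
# junction and polyadenylation event classification rules.

#' CPM, pedestal and log2 transform
#'
#' Within-sample counts-per-million normalization followed by pedestalling
#' with a constant (default 2) and log2 transformation:
#' `value = log2(count * 1e6 / colsum + pedestal)`.
#'
#' @param counts Nonnegative genes x samples matrix; column sums must be
#'   positive.
#' @param pedestal Pedestal constant (default 2).
#' @return Transformed matrix of the same shape.
#' @export
cpm_pedestal_log2 <- function(counts, pedestal = 2) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("zero-sum sample column", call. = FALSE)
  log2(sweep(counts, 2L, cs / 1e6, "/") + pedestal)
}

#' Cyclic loess normalization across samples
#'
#' For each sample pair, a smooth trend of M (difference) against A
#' (average) is fitted and half the fitted trend subtracted from each
#' member, cycling over all pairs for `iterations` passes (the pairwise
#' cyclic loess of Ballman et al. as implemented in
#' [limma::normalizeCyclicLoess()]). With fewer than two samples the input
#' is returned with a warning.
#'
#' @param logmat Log-scale genes x samples matrix.
#' @param iterations Number of full cycles (default 3).
#' @param span Loess span (default 0.7).
#' @return Normalized matrix.
#' @export
cyclic_loess_normalize <- function(logmat, iterations = 3L, span = 0.7) {
  logmat <- as.matrix(logmat)
  if (ncol(logmat) < 2L) {
    warning("fewer than 2 samples; returning input unchanged")
    return(logmat)
  }
  out <- limma::normalizeCyclicLoess(logmat, span = span,
                                     iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(logmat)
  out
}

#' CV~mean noise filter
#'
#' Per group, gene-wise mean and coefficient of variation are computed on
#' the linearized normalized scale (`2^value - pedestal`, floored at 0), a
#' smooth CV~mean trend is fitted (lowess on log10 mean), and the group's
#' noise threshold is the mean-expression value where the fitted trend
#' crosses a CV ceiling (default: median CV + 2 * MAD of CVs), found by
#' linear interpolation. A gene is noise-biased - and removed - iff its mean
#' lies below the threshold in every group.
#'
#' @param normalized Normalized log2 matrix (genes x samples).
#' @param groups Group label per column.
#' @param cv_ceiling CV ceiling; default `median(cv) + 2 * mad(cv)` per
#'   group.
#' @param pedestal Pedestal used in [cpm_pedestal_log2()] (default 2).
#' @param linear_scale Compute CV on the linearized scale (default TRUE);
#'   otherwise on the log values directly.
#' @return A list: `kept` (logical per gene), `thresholds` (named per
#'   group), `report` (per gene x group means/CVs and per-group fits).
#' @export
noise_filter <- function(normalized, groups, cv_ceiling = NULL,
                         pedestal = 2, linear_scale = TRUE) {
  normalized <- as.matrix(normalized)
  stopifnot(length(groups) == ncol(normalized))
  if (any(table(groups) < 2L))
    stop("need >= 2 samples per group", call. = FALSE)
  lin <- if (linear_scale) pmax(2^normalized - pedestal, 0) else normalized
  glev <- unique(groups)
  thresholds <- setNames(numeric(length(glev)), glev)
  below <- matrix(FALSE, nrow(normalized), length(glev),
                  dimnames = list(rownames(normalized), glev))
  fits <- list()
  for (g in glev) {
    sub <- lin[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    cv <- apply(sub, 1L, sd) / mu
    ok <- is.finite(cv) & mu > 0
    ceiling_g <- cv_ceiling %||% (median(cv[ok]) + 2 * mad(cv[ok]))
    fit <- lowess(log10(mu[ok]), cv[ok], f = 0.3)
    # walk the fitted trend (decreasing in mean) for the ceiling crossing
    cross <- which(fit$y <= ceiling_g)
    if (length(cross) == 0L || all(fit$y <= ceiling_g)) {
      # degenerate: trend never crosses (or is entirely below) the ceiling
      thr <- min(mu[ok])
      if (length(cross) == 0L)
        warning("CV trend never falls below the ceiling in group ", g,
                "; nothing filtered")
    } else {
      i <- cross[1L]
      thr <- if (i == 1L) 10^fit$x[1L] else {
        # linear interpolation between the bracketing fit points
        x0 <- fit$x[i - 1L]; x1 <- fit$x[i]
        y0 <- fit$y[i - 1L]; y1 <- fit$y[i]
        10^(x0 + (ceiling_g - y0) * (x1 - x0) / (y1 - y0))
      }
    }
    thresholds[g] <- thr
    below[, g] <- mu < thr
    fits[[g]] <- list(mean = mu, cv = cv, fit = fit, ceiling = ceiling_g)
  }
  list(kept = rowSums(below) < length(glev), thresholds = thresholds,
       report = fits)
}

#' Differential expression on normalized values
#'
#' Per gene, a test between the two groups on the normalized log2 values,
#' BH q-values, and up/down calls at the configured cuts. The default
#' `"moderated"` method is limma's empirical-Bayes moderated t
#' ([limma::lmFit()] + [limma::eBayes()]), the standard choice at the small
#' replicate numbers these designs have; `"welch"` gives a per-gene Welch
#' t-test. Zero-variance genes with equal means take the exact-equality fast
#' path (p = 1).
#'
#' @param normalized Normalized log2 matrix (genes x samples).
#' @param groups Group label per column (exactly two levels).
#' @param lfc_cut,p_cut Call thresholds on |lfc| and BH q (defaults 1,
#'   0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame with `gene`, `lfc` (second level over first), `p`,
#'   `q`, `call` in up/down/none.
#' @export
differential_expression <- function(normalized, groups, lfc_cut = 1,
                                    p_cut = 0.05,
                                    method = c("moderated", "welch")) {
  normalized <- as.matrix(normalized)
  method <- match.arg(method)
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  a <- normalized[, groups == lev[1L], drop = FALSE]
  b <- normalized[, groups == lev[2L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  if (method == "moderated") {
    design <- cbind(intercept = 1, grp = as.integer(groups == lev[2L]))
    fit <- limma::eBayes(limma::lmFit(normalized, design))
    p <- fit$p.value[, "grp"]
    lfc <- fit$coefficients[, "grp"]
  } else {
    w <- welch_rows(a, b)
    p <- w$p
    p[!is.finite(p)] <- 1  # zero-variance unequal-mean rows get t = +-Inf
    lfc <- w$mean_b - w$mean_a
  }
  q <- bh_fdr(pmax(p, .Machine$double.xmin))
  call <- ifelse(abs(lfc) >= lfc_cut & q < p_cut,
                 ifelse(lfc > 0, "up", "down"), "none")
  data.frame(gene = rownames(normalized) %||% seq_len(nrow(normalized)),
             lfc = lfc, p = p, q = q, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify splice junctions as cryptic
#'
#' Cryptic splicing is defined on the between-group PSI difference
#' `dpsi = mean(knockdown) - mean(control)` and the fraction of control
#' samples in which the junction is present (PSI above the detection
#' floor): `cryptic_gain` when `dpsi > dpsi_cut` and control presence is
#' below `presence_low`; `cryptic_loss` when `dpsi < -dpsi_cut` and control
#' presence exceeds `presence_high`; junctions passing the dpsi threshold
#' without the presence condition are `significant_noncryptic`; everything
#' else is `none`.
#'
#' @param psi data.frame with `junction_id` (and optionally `gene`) plus one
#'   PSI column per sample, or a junctions x samples matrix.
#' @param groups Group label per sample column: `"control"` or
#'   `"knockdown"`.
#' @param dpsi_cut PSI difference threshold (default 0.10).
#' @param presence_low,presence_high Control presence thresholds (defaults
#'   0.05 and 0.10).
#' @param detection_floor PSI above which a junction counts as present
#'   (default 0.01).
#' @return data.frame with `junction_id`, `dpsi`, `control_presence`,
#'   `class`.
#' @export
classify_junctions <- function(psi, groups, dpsi_cut = 0.10,
                               presence_low = 0.05, presence_high = 0.10,
                               detection_floor = 0.01) {
  if (is.data.frame(psi)) {
    meta_cols <- intersect(c("junction_id", "gene"), names(psi))
    ids <- psi$junction_id %||% seq_len(nrow(psi))
    m <- as.matrix(psi[, setdiff(names(psi), meta_cols), drop = FALSE])
  } else {
    m <- as.matrix(psi)
    ids <- rownames(m) %||% seq_len(nrow(m))
  }
  stopifnot(length(groups) == ncol(m))
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("PSI values outside [0, 1]", call. = FALSE)
  if (!all(c("control", "knockdown") %in% groups))
    stop("both groups must be represented", call. = FALSE)
  ctrl <- m[, groups == "control", drop = FALSE]
  kd <- m[, groups == "knockdown", drop = FALSE]
  dpsi <- rowMeans(kd) - rowMeans(ctrl)
  presence <- rowMeans(ctrl > detection_floor)
  class <- rep("none", nrow(m))
  class[abs(dpsi) > dpsi_cut] <- "significant_noncryptic"
  class[dpsi > dpsi_cut & presence < presence_low] <- "cryptic_gain"
  class[dpsi < -dpsi_cut & presence > presence_high] <- "cryptic_loss"
  data.frame(junction_id = ids, dpsi = dpsi, control_presence = presence,
             class = class, stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify polyadenylation events
#'
#' An event is a significant lengthening when its compositional fold change
#' satisfies `cFC >= cfc_cut` with `fdr < fdr_cut`, a shortening when
#' `cFC <= -cfc_cut` with `fdr < fdr_cut`, otherwise `none`. The cFC
#' boundary is inclusive; the FDR boundary is exclusive.
#'
#' @param events data.frame with `cfc` and `fdr` columns (gene/site columns
#'   preserved).
#' @param cfc_cut Absolute cFC threshold (default 0.25).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return `events` with an added `class` column in
#'   lengthening/shortening/none.
#' @export
filter_polya_events <- function(events, cfc_cut = 0.25, fdr_cut = 0.05) {
  stopifnot(all(c("cfc", "fdr") %in% names(events)),
            all(events$fdr > 0 & events$fdr <= 1))
  sig <- events$fdr < fdr_cut
  events$class <- ifelse(sig & events$cfc >= cfc_cut, "lengthening",
                         ifelse(sig & events$cfc <= -cfc_cut, "shortening",
                                "none"))
  events
}
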