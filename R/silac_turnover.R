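# Pulse-SILAC protein turnover: peptide filtering, single-time-point
# half-life estimation, harmonic-mean protein aggregation, and group
# contrasts of half-life and abundance.

#' Filter a SILAC peptide report
#'
#' Removes contaminant-flagged peptides, peptides with intensity below 1000,
#' and peptides with heavy/light ratios lower than 0.01 or higher than 100
#' (outlier half-life measurements). Boundary values (intensity exactly
#' 1000, ratio exactly 0.01 or 100) are kept: the cuts are strict
#' inequalities. Every rejection reason is tallied; a peptide failing
#' several rules is tallied under the first matching reason (contaminant,
#' then intensity, then ratio).
#'
#' @param peptides data.frame with `intensity_light`, `intensity_heavy`,
#'   `ratio`, `contaminant` (see [simulate_silac_peptides()]).
#' @param min_intensity Intensity floor (default 1000).
#' @param ratio_bounds Ratio window, default `c(0.01, 100)`.
#' @param intensity_mode `"total"` (light + heavy, default) or `"either"`
#'   (reject when either channel is below the floor).
#' @return A list: `kept`, `rejected` (with a `reason` column), and `tally`
#'   (named counts by reason).
#' @export
filter_peptides <- function(peptides, min_intensity = 1000,
                            ratio_bounds = c(0.01, 100),
                            intensity_mode = c("total", "either")) {
  intensity_mode <- match.arg(intensity_mode)
  low_int <- if (intensity_mode == "total")
    (peptides$intensity_light + peptides$intensity_heavy) < min_intensity
  else peptides$intensity_light < min_intensity |
    peptides$intensity_heavy < min_intensity
  bad_ratio <- peptides$ratio < ratio_bounds[1L] |
    peptides$ratio > ratio_bounds[2L]
  reason <- rep(NA_character_, nrow(peptides))
  reason[bad_ratio] <- "ratio_out_of_range"
  reason[low_int] <- "low_intensity"
  reason[peptides$contaminant] <- "contaminant"
  kept <- is.na(reason)
  rejected <- peptides[!kept, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!kept]
  list(kept = peptides[kept, , drop = FALSE], rejected = rejected,
       tally = c(contaminant = sum(reason == "contaminant", na.rm = TRUE),
                 low_intensity = sum(reason == "low_intensity", na.rm = TRUE),
                 ratio_out_of_range = sum(reason == "ratio_out_of_range",
                                          na.rm = TRUE)))
}

#' Single-time-point peptide half-life
#'
#' Assuming turnover steady state, a heavy/light ratio R after labeling time
#' t_s implies `t_half = t_s * ln(2) / ln(1 + R)`.
#'
#' @param R Heavy/light ratio(s), > 0.
#' @param t_s Labeling time in days, > 0.
#' @return Half-life in days (NA where R <= 0).
#' @export
peptide_half_life <- function(R, t_s) {
  stopifnot_scalar_number(t_s, "t_s", lower = 0, allow_equal_lower = FALSE)
  ifelse(R > 0, t_s * log(2) / log(1 + R), NA_real_)
}

#' Harmonic-mean protein half-life
#'
#' Peptide half-lives are computed with [peptide_half_life()], duplicate
#' peptide sequences within a protein x condition x replicate group are
#' collapsed to their median, and the protein half-life is the harmonic mean
#' `n / sum(1/t_i)` over the unique peptides.
#'
#' @param peptides Filtered peptide table with `protein_id`, `peptide_seq`,
#'   `ratio`, `label_time_days`, `condition`, `replicate`.
#' @return data.frame with `protein_id`, `condition`, `replicate`,
#'   `t_half_days`, `n_unique_peptides`. Peptides with non-positive ratio
#'   are skipped and counted in the `n_skipped` attribute.
#' @export
protein_half_life <- function(peptides) {
  need <- c("protein_id", "peptide_seq", "ratio", "label_time_days",
            "condition", "replicate")
  stopifnot(all(need %in% names(peptides)))
  usable <- peptides$ratio > 0
  n_skipped <- sum(!usable)
  pep <- peptides[usable, , drop = FALSE]
  pep$t_pep <- t_s_half(pep)

  # collapse duplicate sequences (charge states etc.) to one value,
  # then take the harmonic mean over unique peptides
  by_seq <- aggregate(t_pep ~ protein_id + condition + replicate +
                        peptide_seq, data = pep, FUN = median)
  out <- aggregate(t_pep ~ protein_id + condition + replicate,
                   data = by_seq, FUN = function(t) length(t) / sum(1 / t))
  names(out)[names(out) == "t_pep"] <- "t_half_days"
  npep <- aggregate(peptide_seq ~ protein_id + condition + replicate,
                    data = by_seq, FUN = length)
  out$n_unique_peptides <- npep$peptide_seq[
    match(paste(out$protein_id, out$condition, out$replicate),
          paste(npep$protein_id, npep$condition, npep$replicate))]
  out <- out[order(out$protein_id, out$condition, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

t_s_half <- function(pep) {
  pep$label_time_days * log(2) / log(1 + pep$ratio)
}

# vectorized Welch t-test on the rows of two matrices (NA-tolerant)
welch_rows <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1L, var, na.rm = TRUE); vb <- apply(b, 1L, var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  # exact-equality fast path for zero-variance rows
  zero <- is.finite(va) & is.finite(vb) & va == 0 & vb == 0
  p[zero & ma == mb] <- 1
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, n_a = na, n_b = nb)
}

contrast_table <- function(values, ids, condition, replicate,
                           group_a, group_b, lfc_cut, p_cut, log_input) {
  sel <- condition %in% c(group_a, group_b)
  values <- values[sel]; ids <- ids[sel]
  condition <- condition[sel]; replicate <- replicate[sel]
  proteins <- sort(unique(ids))
  reps_a <- sort(unique(replicate[condition == group_a]))
  reps_b <- sort(unique(replicate[condition == group_b]))
  fill <- function(group, reps) {
    m <- matrix(NA_real_, length(proteins), length(reps),
                dimnames = list(proteins, as.character(reps)))
    g <- condition == group
    m[cbind(match(ids[g], proteins),
            match(as.character(replicate[g]), as.character(reps)))] <-
      values[g]
    m
  }
  la <- fill(group_a, reps_a); lb <- fill(group_b, reps_b)
  if (!log_input) { la <- log2(la); lb <- log2(lb) }
  w <- welch_rows(la, lb)
  enough <- w$n_a >= 2 & w$n_b >= 2
  p <- ifelse(enough, w$p, NA_real_)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  lfc <- w$mean_b - w$mean_a   # log2 scale
  data.frame(protein_id = proteins, lfc = lfc, p = p, q = q,
             n_a = w$n_a, n_b = w$n_b,
             significant = !is.na(p) & abs(lfc) >= lfc_cut & p < p_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrast protein half-lives between conditions
#'
#' Per protein, log2 fold change of half-life (group B over group A) with a
#' Welch t-test on log2 half-lives across replicates, BH q-values, and a
#' significance call at `|lfc| >= lfc_cut` and `p < p_cut` (the volcano
#' thresholds: 0.5 and 0.05). Proteins lacking two replicates in either
#' group are emitted with missing p and excluded from the q computation.
#'
#' @param turnover A [protein_half_life()] table.
#' @param group_a,group_b Condition labels (LFC is B over A).
#' @param lfc_cut,p_cut Significance thresholds (defaults 0.5, 0.05).
#' @return data.frame with `protein_id`, `lfc`, `p`, `q`, `n_a`, `n_b`,
#'   `significant`.
#' @export
contrast_half_life <- function(turnover, group_a, group_b,
                               lfc_cut = 0.5, p_cut = 0.05) {
  contrast_table(turnover$t_half_days, turnover$protein_id,
                 turnover$condition, turnover$replicate,
                 group_a, group_b, lfc_cut, p_cut, log_input = FALSE)
}

#' Contrast protein abundances between conditions
#'
#' Same machinery as [contrast_half_life()] on log2 protein intensities,
#' with the abundance volcano thresholds (|lfc| >= 1, p < 0.05).
#'
#' @param abundance data.frame with `protein_id`, `intensity`, `condition`,
#'   `replicate`.
#' @param group_a,group_b Condition labels.
#' @param lfc_cut,p_cut Significance thresholds (defaults 1, 0.05).
#' @return As [contrast_half_life()].
#' @export
contrast_abundance <- function(abundance, group_a, group_b,
                               lfc_cut = 1, p_cut = 0.05) {
  contrast_table(abundance$intensity, abundance$protein_id,
                 abundance$condition, abundance$replicate,
                 group_a, group_b, lfc_cut, p_cut, log_input = FALSE)
}
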