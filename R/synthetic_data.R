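# Simulators for every input family the pipeline consumes. Each returns its
# ground truth so downstream recovery is checkable. All randomness flows from
# a single seeded stream per call; the caller's RNG state is restored.

#' Configuration for the sorting-screen simulator
#'
#' Describes a pooled dual-guide CRISPRi screen read out by FACS sorting of a
#' fluorescent reporter into low/high bins. Each gene is covered by
#' `guides_per_gene` dual-guide cassettes (two guides against the same gene on
#' one construct); non-targeting (NT) cassettes act as negative controls.
#' Reporter fluorescence per cell is modelled as Normal(effect, 1) in units of
#' the within-cell reporter standard deviation, so `effect_size_sd_units` is
#' the reporter shift a true hit causes.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Dual-guide cassettes per gene.
#' @param n_control_guides Number of non-targeting cassettes.
#' @param frac_true_hits Fraction of genes carrying a true effect.
#' @param effect_size_sd_units Reporter shift per true hit, in within-cell SD
#'   units (negative = knockdown lowers the reporter).
#' @param cells_per_guide Mean cells per cassette (lognormal across cassettes).
#' @param sort_fraction Fraction sorted into each tail bin, in (0, 0.5].
#'   Default 0.25 (high 25\% vs low 25\%).
#' @param reads_per_bin Sequencing reads emitted per bin. Default
#'   `500 * <number of cassettes>` (500x depth).
#' @param recombination_rate Fraction of emitted read pairs whose two guides
#'   come from independently drawn cassettes (lentiviral template switching).
#' @param seed Integer seed.
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 500L, guides_per_gene = 4L,
                              n_control_guides = 100L, frac_true_hits = 0.05,
                              effect_size_sd_units = -1,
                              cells_per_guide = 500, sort_fraction = 0.25,
                              reads_per_bin = NULL, recombination_rate = 0.1,
                              seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  stopifnot_scalar_number(guides_per_gene, "guides_per_gene", lower = 1)
  stopifnot_scalar_number(n_control_guides, "n_control_guides", lower = 0)
  stopifnot_scalar_number(frac_true_hits, "frac_true_hits", 0, 1)
  stopifnot_scalar_number(effect_size_sd_units, "effect_size_sd_units")
  stopifnot_scalar_number(cells_per_guide, "cells_per_guide", lower = 0,
                          allow_equal_lower = FALSE)
  stopifnot_scalar_number(sort_fraction, "sort_fraction", 0, 0.5,
                          allow_equal_lower = FALSE)
  n_cass <- n_genes * guides_per_gene + n_control_guides
  reads_per_bin <- reads_per_bin %||% (500L * n_cass)
  stopifnot_scalar_number(reads_per_bin, "reads_per_bin", lower = 1)
  stopifnot_scalar_number(recombination_rate, "recombination_rate", 0, 1,
                          allow_equal_upper = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), guides_per_gene = as.integer(guides_per_gene),
    n_control_guides = as.integer(n_control_guides),
    frac_true_hits = frac_true_hits,
    effect_size_sd_units = effect_size_sd_units,
    cells_per_guide = cells_per_guide, sort_fraction = sort_fraction,
    reads_per_bin = as.integer(reads_per_bin),
    recombination_rate = recombination_rate, seed = as.integer(seed)),
    class = "screen_sim_config")
}

#' Gene sentinel used for non-targeting control cassettes
#' @export
NT_GENE <- "NT"

#' Simulate a dual-guide FACS sorting screen
#'
#' Cells carrying each cassette are drawn lognormally around
#' `cells_per_guide`; each cell's reporter is Normal(gene effect, 1). Bin
#' membership is decided by quantiles of the pooled simulated population at
#' `sort_fraction` (matching FACS gating on the total population). Per bin,
#' `reads_per_bin` read pairs are emitted multinomially over cassettes
#' weighted by cells in the bin; a fraction `recombination_rate` of pairs
#' instead takes guide A and guide B from independently drawn cassettes.
#'
#' @param config A [screen_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{calls}{data.frame of read-level guide-pair calls
#'       (`read_id`, `guide_a`, `guide_b`, `sample`).}
#'     \item{counts}{data.frame of intact-cassette counts per bin
#'       (`guide_pair_id`, `gene`, `high`, `low`); recombined pairs appear
#'       only in `calls`.}
#'     \item{library}{guide annotation (`guide_id`, `gene`, `guide_pair_id`).}
#'     \item{truth}{data.frame (`gene`, `true_effect`), every simulated gene
#'       exactly once (NT sentinel included with effect 0).}
#'   }
#' @export
simulate_sorting_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    n_hits <- round(config$frac_true_hits * config$n_genes)
    effects <- setNames(numeric(config$n_genes), genes)
    if (n_hits > 0) effects[seq_len(n_hits)] <- config$effect_size_sd_units

    cass_gene <- c(rep(genes, each = config$guides_per_gene),
                   rep(NT_GENE, config$n_control_guides))
    n_cass <- length(cass_gene)
    cass_id <- paste0(cass_gene, "_c",
                      c(rep(seq_len(config$guides_per_gene), config$n_genes),
                        seq_len(config$n_control_guides)))
    cass_effect <- c(effects[cass_gene[seq_len(config$n_genes *
                                                 config$guides_per_gene)]],
                     rep(0, config$n_control_guides))

    # cell population and pooled-quantile gates
    sdlog <- 0.25
    n_cells <- pmax(1L, round(rlnorm(n_cass,
                                     log(config$cells_per_guide) - sdlog^2 / 2,
                                     sdlog)))
    cass_of_cell <- rep.int(seq_len(n_cass), n_cells)
    reporter <- rnorm(sum(n_cells)) + cass_effect[cass_of_cell]
    gates <- quantile(reporter, c(config$sort_fraction,
                                  1 - config$sort_fraction), names = FALSE)
    cells_low <- tabulate(cass_of_cell[reporter <= gates[1L]], n_cass)
    cells_high <- tabulate(cass_of_cell[reporter >= gates[2L]], n_cass)

    guide_a <- paste0(cass_id, "_A")
    guide_b <- paste0(cass_id, "_B")

    emit_bin <- function(bin_cells, sample_name) {
      n_rec <- rbinom(1L, config$reads_per_bin, config$recombination_rate)
      n_ok <- config$reads_per_bin - n_rec
      i_ok <- sample.int(n_cass, n_ok, replace = TRUE, prob = bin_cells)
      i_a <- sample.int(n_cass, n_rec, replace = TRUE, prob = bin_cells)
      i_b <- sample.int(n_cass, n_rec, replace = TRUE, prob = bin_cells)
      list(calls = data.frame(
             guide_a = guide_a[c(i_ok, i_a)],
             guide_b = guide_b[c(i_ok, i_b)],
             sample = sample_name,
             stringsAsFactors = FALSE),
           counts = tabulate(i_ok, n_cass))
    }
    high <- emit_bin(cells_high, "high")
    low <- emit_bin(cells_low, "low")
    calls <- rbind(high$calls, low$calls)
    # shuffle so read order carries no bin information, then id the reads
    calls <- calls[sample.int(nrow(calls)), , drop = FALSE]
    calls <- cbind(read_id = seq_len(nrow(calls)), calls)
    rownames(calls) <- NULL

    list(
      calls = calls,
      counts = data.frame(guide_pair_id = cass_id, gene = cass_gene,
                          high = high$counts, low = low$counts,
                          stringsAsFactors = FALSE),
      library = data.frame(
        guide_id = c(guide_a, guide_b),
        gene = c(cass_gene, cass_gene),
        guide_pair_id = c(cass_id, cass_id),
        stringsAsFactors = FALSE),
      truth = data.frame(gene = c(genes, NT_GENE),
                         true_effect = c(unname(effects), 0),
                         stringsAsFactors = FALSE))
  })
}

#' Expected high/low count ratio for a shifted-reporter cassette
#'
#' Closed-form oracle companion to [simulate_sorting_screen()]: with reporter
#' ~ Normal(effect, 1) and population gates at the `sort_fraction` quantiles
#' of the (approximately standard normal) pooled population, the expected
#' ratio of a cassette's read share in the high vs low bin is the ratio of
#' its Normal tail masses beyond the gates.
#'
#' @param effect Reporter shift in SD units.
#' @param sort_fraction Tail fraction per bin.
#' @return Expected high/low representation ratio.
#' @export
expected_bin_ratio <- function(effect, sort_fraction = 0.25) {
  hi <- pnorm(qnorm(1 - sort_fraction) - effect, lower.tail = FALSE)
  lo <- pnorm(qnorm(sort_fraction) - effect)
  hi / lo
}

#' Configuration for the multi-screen summary simulator
#'
#' Stress fixture for the meta-analysis stage: per gene g and screen s,
#' `beta = shared_g + specific_gs + Normal(0, se_s)`, with two-sided p from
#' `z = beta/se_s`. Shared hits carry `shared_effect` in every screen;
#' screen-specific hits carry `specific_effect` in exactly one screen.
#'
#' @param n_screens Number of screens (>= 1).
#' @param n_genes Genes per screen.
#' @param shared_hit_count Genes with an effect in every screen.
#' @param screen_specific_hit_count Genes with an effect in one screen only.
#' @param shared_effect Effect size of shared hits.
#' @param specific_effect Effect size of screen-specific hits (defaults to
#'   `shared_effect`).
#' @param screen_se Per-screen noise SE (scalar recycled or length
#'   `n_screens`).
#' @param seed Integer seed.
#' @return A validated list of class `meta_sim_config`.
#' @export
meta_sim_config <- function(n_screens = 3L, n_genes = 2000L,
                            shared_hit_count = 100L,
                            screen_specific_hit_count = 50L,
                            shared_effect = 3, specific_effect = shared_effect,
                            screen_se = 1, seed = 1L) {
  stopifnot_scalar_number(n_screens, "n_screens", lower = 1)
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  stopifnot_scalar_number(shared_hit_count, "shared_hit_count", lower = 0)
  stopifnot_scalar_number(screen_specific_hit_count,
                          "screen_specific_hit_count", lower = 0)
  if (shared_hit_count + screen_specific_hit_count > n_genes)
    stop("shared + specific hit counts exceed n_genes", call. = FALSE)
  if (!all(is.finite(screen_se)) || any(screen_se <= 0))
    stop("`screen_se` must be positive", call. = FALSE)
  structure(list(
    n_screens = as.integer(n_screens), n_genes = as.integer(n_genes),
    shared_hit_count = as.integer(shared_hit_count),
    screen_specific_hit_count = as.integer(screen_specific_hit_count),
    shared_effect = shared_effect, specific_effect = specific_effect,
    screen_se = rep_len(screen_se, n_screens), seed = as.integer(seed)),
    class = "meta_sim_config")
}

#' Simulate per-screen gene summary tables
#'
#' @param config A [meta_sim_config()].
#' @return A list with `summaries` (list of data.frames with `screen_id`,
#'   `gene`, `effect`, `p`) and `truth` (`gene`, `class` in
#'   shared/specific/null, `specific_screen`, `true_effect`).
#' @export
simulate_screen_summaries <- function(config) {
  stopifnot(inherits(config, "meta_sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    n_sh <- config$shared_hit_count
    n_sp <- config$screen_specific_hit_count
    class <- rep("null", config$n_genes)
    if (n_sh > 0) class[seq_len(n_sh)] <- "shared"
    if (n_sp > 0) class[n_sh + seq_len(n_sp)] <- "specific"
    specific_screen <- rep(NA_integer_, config$n_genes)
    if (n_sp > 0)
      specific_screen[n_sh + seq_len(n_sp)] <-
        rep_len(seq_len(config$n_screens), n_sp)

    summaries <- lapply(seq_len(config$n_screens), function(s) {
      se <- config$screen_se[s]
      mu <- ifelse(class == "shared", config$shared_effect, 0) +
        ifelse(!is.na(specific_screen) & specific_screen == s,
               config$specific_effect, 0)
      beta <- mu + rnorm(config$n_genes, 0, se)
      z <- beta / se
      data.frame(screen_id = paste0("screen", s), gene = genes,
                 effect = beta, p = 2 * pnorm(-abs(z)),
                 stringsAsFactors = FALSE)
    })
    list(summaries = summaries,
         truth = data.frame(
           gene = genes, class = class, specific_screen = specific_screen,
           true_effect = ifelse(class == "shared", config$shared_effect,
                                ifelse(class == "specific",
                                       config$specific_effect, 0)),
           stringsAsFactors = FALSE))
  })
}

#' Configuration for the pulse-SILAC peptide simulator
#'
#' Emulates a dynamic SILAC design: cultures switch to heavy lysine/arginine
#' media and are harvested after `label_time_days`. At turnover steady state
#' a protein with half-life T accumulates heavy/light ratio
#' `R = 2^(t_s/T) - 1`, which the simulator perturbs with lognormal noise of
#' the configured coefficient of variation.
#'
#' @param n_proteins Number of (non-contaminant) proteins.
#' @param peptides_per_protein Integer range `c(min, max)` of peptides per
#'   protein.
#' @param true_halflife_days Length-2 bounds of the log-uniform half-life
#'   distribution, in days.
#' @param label_time_days Labeling duration t_s in days (2 for a day-7
#'   harvest after a day-5 media switch; 10 for day 15).
#' @param ratio_noise_cv CV of multiplicative lognormal ratio noise.
#' @param contaminant_fraction Fraction of extra contaminant-flagged peptide
#'   rows injected.
#' @param extreme_ratio_fraction Fraction of peptides whose ratio is replaced
#'   by an out-of-range value (outside [0.01, 100]).
#' @param low_intensity_fraction Fraction of peptides whose total intensity
#'   is pushed below the 1000 filter floor.
#' @param condition,replicate Labels stamped on every emitted row, so
#'   multiple calls can be row-bound into a multi-condition experiment.
#' @param seed Integer seed.
#' @return A validated list of class `turnover_sim_config`.
#' @export
turnover_sim_config <- function(n_proteins = 500L,
                                peptides_per_protein = c(3L, 8L),
                                true_halflife_days = c(0.5, 20),
                                label_time_days = 2,
                                ratio_noise_cv = 0.2,
                                contaminant_fraction = 0.02,
                                extreme_ratio_fraction = 0.02,
                                low_intensity_fraction = 0.02,
                                condition = "NT", replicate = 1L,
                                seed = 1L) {
  stopifnot_scalar_number(n_proteins, "n_proteins", lower = 1)
  stopifnot(length(peptides_per_protein) == 2L,
            all(peptides_per_protein >= 1))
  if (length(true_halflife_days) != 2L || any(true_halflife_days <= 0))
    stop("`true_halflife_days` must be positive bounds", call. = FALSE)
  stopifnot_scalar_number(label_time_days, "label_time_days", lower = 0,
                          allow_equal_lower = FALSE)
  stopifnot_scalar_number(ratio_noise_cv, "ratio_noise_cv", lower = 0)
  stopifnot_scalar_number(contaminant_fraction, "contaminant_fraction", 0, 1)
  stopifnot_scalar_number(extreme_ratio_fraction, "extreme_ratio_fraction",
                          0, 1)
  stopifnot_scalar_number(low_intensity_fraction, "low_intensity_fraction",
                          0, 1)
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    true_halflife_days = sort(as.numeric(true_halflife_days)),
    label_time_days = label_time_days, ratio_noise_cv = ratio_noise_cv,
    contaminant_fraction = contaminant_fraction,
    extreme_ratio_fraction = extreme_ratio_fraction,
    low_intensity_fraction = low_intensity_fraction,
    condition = condition, replicate = replicate, seed = as.integer(seed)),
    class = "turnover_sim_config")
}

#' Simulate a pulse-SILAC peptide report
#'
#' @param config A [turnover_sim_config()].
#' @param true_halflife Optional vector of length `n_proteins` overriding the
#'   log-uniform half-life draw (used to share truth across conditions).
#' @return A list with `peptides` (one row per peptide: `protein_id`,
#'   `peptide_seq`, `intensity_light`, `intensity_heavy`, `ratio`,
#'   `condition`, `replicate`, `label_time_days`, `contaminant`) and `truth`
#'   (`protein_id`, `true_halflife_days`).
#' @export
simulate_silac_peptides <- function(config, true_halflife = NULL) {
  stopifnot(inherits(config, "turnover_sim_config"))
  with_seed(config$seed, {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    if (is.null(true_halflife)) {
      b <- log(config$true_halflife_days)
      true_halflife <- exp(runif(config$n_proteins, b[1L], b[2L]))
    }
    if (any(true_halflife <= 0))
      stop("true half-lives must be positive", call. = FALSE)
    # guard against sample()'s scalar expansion when min == max
    rng <- seq(config$peptides_per_protein[1L],
               config$peptides_per_protein[2L])
    npep <- if (length(rng) == 1L) rep.int(rng, config$n_proteins)
            else sample(rng, config$n_proteins, replace = TRUE)
    prot_of_pep <- rep.int(seq_len(config$n_proteins), npep)
    n_pep <- length(prot_of_pep)

    r_true <- 2^(config$label_time_days / true_halflife[prot_of_pep]) - 1
    sdlog <- sqrt(log(1 + config$ratio_noise_cv^2))
    ratio <- r_true * rlnorm(n_pep, -sdlog^2 / 2, sdlog)

    n_extreme <- round(config$extreme_ratio_fraction * n_pep)
    if (n_extreme > 0) {
      idx <- sample.int(n_pep, n_extreme)
      lo <- runif(n_extreme) < 0.5
      ratio[idx] <- ifelse(lo, runif(n_extreme, 1e-4, 0.009),
                           runif(n_extreme, 101, 1e4))
    }

    total <- rlnorm(n_pep, log(1e6), 1)
    n_low <- round(config$low_intensity_fraction * n_pep)
    if (n_low > 0) total[sample.int(n_pep, n_low)] <- runif(n_low, 10, 999)

    pep <- data.frame(
      protein_id = prot[prot_of_pep],
      peptide_seq = random_peptide_seqs(n_pep),
      intensity_light = total / (1 + ratio),
      intensity_heavy = total * ratio / (1 + ratio),
      ratio = ratio,
      condition = config$condition, replicate = config$replicate,
      label_time_days = config$label_time_days,
      contaminant = FALSE, stringsAsFactors = FALSE)

    n_con <- round(config$contaminant_fraction * n_pep)
    if (n_con > 0) {
      con <- data.frame(
        protein_id = sprintf("CON__%03d", sample.int(max(5L, n_con %/% 3 + 1L),
                                                     n_con, replace = TRUE)),
        peptide_seq = random_peptide_seqs(n_con),
        intensity_light = rlnorm(n_con, log(1e6), 1),
        intensity_heavy = rlnorm(n_con, log(1e6), 1),
        ratio = rlnorm(n_con, 0, 1),
        condition = config$condition, replicate = config$replicate,
        label_time_days = config$label_time_days,
        contaminant = TRUE, stringsAsFactors = FALSE)
      pep <- rbind(pep, con)
    }
    rownames(pep) <- NULL
    list(peptides = pep,
         truth = data.frame(protein_id = prot,
                            true_halflife_days = true_halflife,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a junction PSI table with planted cryptic junctions
#'
#' Canonical junctions draw percent-spliced-in (PSI) from a Beta with a
#' common mean across the control and knockdown groups. Cryptic junctions are
#' near-absent in controls (PSI above the detection floor in roughly
#' `control_presence_prob` of control samples) and gain `dpsi` PSI in the
#' knockdown group.
#'
#' @param n_junctions Total junctions.
#' @param n_samples_per_group Samples per group (control and knockdown),
#'   each >= 2.
#' @param cryptic_fraction Fraction of junctions planted as cryptic.
#' @param dpsi Planted knockdown PSI gain for cryptic junctions; a scalar or
#'   length-2 uniform bounds.
#' @param psi_sd Gaussian noise SD on cryptic knockdown PSI (0 = noiseless).
#' @param control_presence_prob Per-control-sample probability that a cryptic
#'   junction is weakly detected (PSI in (floor, 0.05]).
#' @param detection_floor PSI above which a junction counts as present.
#' @param seed Integer seed.
#' @return A list with `psi` (data.frame: `junction_id`, `gene`, one column
#'   per sample), `samples` (`sample`, `group`), and `truth` (`junction_id`,
#'   `planted`, `planted_dpsi`).
#' @export
simulate_junction_psi <- function(n_junctions = 1000L,
                                  n_samples_per_group = 10L,
                                  cryptic_fraction = 0.1,
                                  dpsi = 0.3, psi_sd = 0.02,
                                  control_presence_prob = 0.02,
                                  detection_floor = 0.01, seed = 1L) {
  stopifnot_scalar_number(n_junctions, "n_junctions", lower = 1)
  stopifnot_scalar_number(n_samples_per_group, "n_samples_per_group",
                          lower = 2)
  stopifnot_scalar_number(cryptic_fraction, "cryptic_fraction", 0, 1)
  stopifnot_scalar_number(psi_sd, "psi_sd", lower = 0)
  stopifnot_scalar_number(control_presence_prob, "control_presence_prob",
                          0, 1)
  with_seed(seed, {
    n_s <- as.integer(n_samples_per_group)
    samples <- data.frame(
      sample = c(paste0("ctrl", seq_len(n_s)), paste0("kd", seq_len(n_s))),
      group = rep(c("control", "knockdown"), each = n_s),
      stringsAsFactors = FALSE)
    n_cry <- round(cryptic_fraction * n_junctions)
    planted <- rep(c("cryptic", "canonical"),
                   c(n_cry, n_junctions - n_cry))
    jid <- sprintf("J%05d", seq_len(n_junctions))

    psi <- matrix(0, n_junctions, 2L * n_s,
                  dimnames = list(jid, samples$sample))
    is_can <- planted == "canonical"
    if (any(is_can)) {
      mu <- rbeta(sum(is_can), 2, 2)
      kappa <- 50
      psi[is_can, ] <- rbeta(sum(is_can) * 2L * n_s,
                             rep(mu * kappa, 2L * n_s),
                             rep((1 - mu) * kappa, 2L * n_s))
    }
    planted_dpsi <- rep(NA_real_, n_junctions)
    if (n_cry > 0) {
      d <- if (length(dpsi) == 2L) runif(n_cry, dpsi[1L], dpsi[2L])
           else rep(dpsi, n_cry)
      planted_dpsi[seq_len(n_cry)] <- d
      ctrl <- matrix(0, n_cry, n_s)
      weak <- matrix(runif(n_cry * n_s) < control_presence_prob, n_cry, n_s)
      ctrl[weak] <- runif(sum(weak), detection_floor + 1e-6, 0.05)
      kd <- matrix(rep(d, n_s), n_cry, n_s) +
        if (psi_sd > 0) matrix(rnorm(n_cry * n_s, 0, psi_sd), n_cry, n_s)
        else 0
      psi[seq_len(n_cry), seq_len(n_s)] <- ctrl
      psi[seq_len(n_cry), n_s + seq_len(n_s)] <- pmin(pmax(kd, 0), 1)
    }
    list(
      psi = data.frame(junction_id = jid,
                       gene = sprintf("G%04d", seq_len(n_junctions)),
                       psi, check.names = FALSE, stringsAsFactors = FALSE,
                       row.names = NULL),
      samples = samples,
      truth = data.frame(junction_id = jid, planted = planted,
                         planted_dpsi = planted_dpsi,
                         stringsAsFactors = FALSE))
  })
}

#' Simulate a gene count matrix with planted DE and noise-biased genes
#'
#' Negative binomial counts with gene means drawn log-uniformly and a
#' decreasing mean-dispersion trend (`phi = phi0 + a/mu`), emulating the
#' CV~mean structure the noise filter models. A `noise_gene_fraction` block
#' of genes is planted in the low-mean/high-dispersion regime; a
#' `de_fraction` subset of the remaining genes carries a log2 fold change of
#' `lfc` (alternating sign) in the second group.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of samples per group, e.g.
#'   `c(NT = 4, KD = 3)`; each entry >= 2.
#' @param de_fraction Fraction of non-noise genes that are differentially
#'   expressed.
#' @param lfc Planted absolute log2 fold change.
#' @param noise_gene_fraction Fraction of genes planted low-mean/high-CV.
#' @param dispersion `NULL` for the mean-dispersion trend, `0` for Poisson
#'   counts, or a constant dispersion.
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix), `samples`
#'   (`sample`, `group`), and `truth` (`gene`, `de`, `lfc`, `noise_biased`,
#'   `base_mean`).
#' @export
simulate_expression_counts <- function(n_genes = 2000L,
                                       groups = c(NT = 4L, KD = 3L),
                                       de_fraction = 0.1, lfc = 2,
                                       noise_gene_fraction = 0.1,
                                       dispersion = NULL, seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  if (length(groups) < 2L || any(groups < 2))
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  stopifnot_scalar_number(de_fraction, "de_fraction", 0, 1)
  stopifnot_scalar_number(noise_gene_fraction, "noise_gene_fraction", 0, 1)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    group_of <- rep(names(groups), groups)
    samples <- data.frame(
      sample = paste0(group_of, "_r",
                      unlist(lapply(groups, seq_len), use.names = FALSE)),
      group = group_of, stringsAsFactors = FALSE)

    n_noise <- round(noise_gene_fraction * n_genes)
    noise_biased <- c(rep(TRUE, n_noise), rep(FALSE, n_genes - n_noise))
    base_mean <- numeric(n_genes)
    base_mean[noise_biased] <- 10^runif(n_noise, log10(0.5), log10(5))
    base_mean[!noise_biased] <- 10^runif(n_genes - n_noise, log10(20),
                                         log10(5000))
    phi <- if (is.null(dispersion)) 0.01 + 2 / base_mean
           else rep(dispersion, n_genes)
    phi[noise_biased] <- phi[noise_biased] * 4

    de <- rep(FALSE, n_genes)
    eligible <- which(!noise_biased)
    n_de <- round(de_fraction * length(eligible))
    if (n_de > 0) de[sample(eligible, n_de)] <- TRUE
    gene_lfc <- ifelse(de, lfc * rep_len(c(1, -1), n_genes), 0)

    second_group <- names(groups)[2L]
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$group[j] == second_group) base_mean * 2^gene_lfc
            else base_mean
      counts[, j] <- if (is.null(dispersion) || dispersion > 0)
        rnbinom(n_genes, mu = mu, size = 1 / phi)
      else rpois(n_genes, mu)
    }
    list(counts = counts, samples = samples,
         truth = data.frame(gene = genes, de = de, lfc = gene_lfc,
                            noise_biased = noise_biased,
                            base_mean = base_mean,
                            stringsAsFactors = FALSE))
  })
}
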