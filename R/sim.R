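#' Simulation configuration for the synthetic study generator
#'
#' Builds and validates the single configuration object consumed by
#' [simulate_motif_tables()], [simulate_expression()] and
#' [simulate_clinical_cohort()]. Defaults reproduce the study design the
#' pipeline targets: three cell-line groups (parental `Ag` and two resistant
#' sublines `D8`, `D12`) with four replicates each, promoter motif counts at
#' the four PSSM thresholds 0.70/0.75/0.80/0.85, and a 42-patient metastatic
#' cohort with bone and soft-tissue sites scored 0-3 by IHC.
#'
#' @param n_genes number of genes shared by the expression and motif tables.
#' @param n_motifs number of motifs (TFBS) in each frequency table.
#' @param thresholds strictly increasing PSSM thresholds in (0, 1]; one motif
#'   table is generated per threshold.
#' @param groups named integer vector of replicate counts per group
#'   (names are group labels); every group needs >= 2 replicates.
#' @param resistant_groups labels of the groups carrying the planted effect.
#' @param active_motifs either a character vector of motif identifiers or a
#'   single count; a count is resolved to a seeded random draw of motif ids.
#' @param effect_size mean log2 expression shift per active-motif promoter
#'   occurrence in resistant samples.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param baseline_mean log2-scale mean baseline intensity.
#' @param baseline_sd gene-to-gene standard deviation of the baseline on the
#'   log2 scale (default 2, the wide spread real intensity data shows; a
#'   near-zero value makes all genes share one baseline, which is unrealistic
#'   and makes quantile normalization aggressive).
#' @param motif_rate mean total motif occurrences per promoter (summed over
#'   all motifs) at the loosest threshold; each gene-by-motif cell is Poisson
#'   with mean `motif_rate / n_motifs`, giving the sparse tables real
#'   promoter scans produce.
#' @param retention per-threshold-step probability that a motif occurrence
#'   survives the stricter match cutoff (binomial thinning); values in
#'   \[0, 1\], where 0 degenerates to an all-zero table and is rejected at
#'   generation time.
#' @param intensity_scale how the log2 matrix is mapped to the non-negative
#'   intensity scale required by correspondence analysis: `"exp2"` (2^y,
#'   default) or `"shift"` (y + `shift_constant`, rejected if still negative).
#' @param shift_constant additive constant for `intensity_scale = "shift"`.
#' @param n_patients cohort size for the clinical arm.
#' @param sites_range integer range of metastatic sites per patient.
#' @param p_bone probability a site is a bone (vs soft-tissue) metastasis.
#' @param p_srf_high prevalence of the latent marker-high patient class.
#' @param score_probs_low,score_probs_high length-4 probability vectors over
#'   IHC scores 0..3 for marker-low and marker-high patients.
#' @param p_unusable probability a tissue core is unusable (score missing,
#'   flagged, never silently dropped).
#' @param treated_frac fraction of patients exposed to docetaxel.
#' @param base_rates named exponential event rates (per year) for the three
#'   survival baselines: diagnosis, castration resistance, first bone
#'   metastasis.
#' @param hazard_ratio hazard multiplier applied to marker-high patients.
#' @param censor_rate independent exponential censoring rate (0 = no
#'   censoring).
#' @param on_degenerate `"regenerate"` (redraw, bounded attempts) or `"error"`
#'   when a motif table contains an all-zero row or column.
#' @param seed integer seed; all sub-generators derive deterministic streams
#'   from it.
#'
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_motifs = 20, seed = 1)
#' tabs <- simulate_motif_tables(cfg)
#' sapply(tabs, function(t) mean(t$counts))
#' @export
sim_config <- function(n_genes = 2000,
                       n_motifs = 100,
                       thresholds = c(0.70, 0.75, 0.80, 0.85),
                       groups = c(Ag = 4L, D8 = 4L, D12 = 4L),
                       resistant_groups = c("D8", "D12"),
                       active_motifs = 5,
                       effect_size = 1.0,
                       noise_sd = 0.5,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       motif_rate = 2,
                       retention = 0.8,
                       intensity_scale = c("exp2", "shift"),
                       shift_constant = 0,
                       n_patients = 42,
                       sites_range = c(1L, 6L),
                       p_bone = 0.65,
                       p_srf_high = 0.4,
                       score_probs_low = c(0.45, 0.35, 0.12, 0.08),
                       score_probs_high = c(0.10, 0.20, 0.35, 0.35),
                       p_unusable = 0,
                       treated_frac = 23 / 42,
                       base_rates = c(diagnosis = 0.14, crpc = 0.23, bonemet = 0.32),
                       hazard_ratio = 3,
                       censor_rate = 0.05,
                       on_degenerate = c("regenerate", "error"),
                       seed = 1L) {
  intensity_scale <- match.arg(intensity_scale)
  on_degenerate <- match.arg(on_degenerate)
  if (n_genes < 1 || n_motifs < 1 || n_patients < 1)
    ct_validation_error("n_genes, n_motifs and n_patients must be positive")
  if (length(thresholds) < 1 || any(thresholds <= 0) || any(thresholds > 1))
    ct_validation_error("thresholds must lie in (0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE))
    ct_validation_error("thresholds must be strictly increasing")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    ct_validation_error("groups must be a named vector of replicate counts")
  if (any(groups < 2))
    ct_validation_error("every group needs >= 2 replicates (variance must be estimable)")
  if (!all(resistant_groups %in% names(groups)))
    ct_validation_error("resistant_groups must be a subset of group labels")
  if (retention < 0 || retention > 1)
    ct_validation_error("retention must lie in [0, 1]")
  if (noise_sd < 0 || baseline_sd < 0 || motif_rate <= 0)
    ct_validation_error("noise_sd/baseline_sd must be >= 0 and motif_rate > 0")
  for (p in list(score_probs_low, score_probs_high)) {
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      ct_validation_error("score probability vectors must be length 4 and sum to 1")
  }
  if (hazard_ratio <= 0 || censor_rate < 0 || any(base_rates <= 0))
    ct_validation_error("hazard_ratio and base_rates must be positive, censor_rate >= 0")
  if (length(base_rates) != 3 || is.null(names(base_rates)))
    ct_validation_error("base_rates must name three baselines")
  seed <- as.integer(seed)

  cfg <- list(
    n_genes = as.integer(n_genes), n_motifs = as.integer(n_motifs),
    thresholds = thresholds, groups = groups,
    resistant_groups = resistant_groups, active_motifs = active_motifs,
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    motif_rate = motif_rate,
    retention = retention, intensity_scale = intensity_scale,
    shift_constant = shift_constant,
    n_patients = as.integer(n_patients), sites_range = as.integer(sites_range),
    p_bone = p_bone, p_srf_high = p_srf_high,
    score_probs_low = score_probs_low, score_probs_high = score_probs_high,
    p_unusable = p_unusable, treated_frac = treated_frac,
    base_rates = base_rates, hazard_ratio = hazard_ratio,
    censor_rate = censor_rate, on_degenerate = on_degenerate, seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids  <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))
sim_motif_ids <- function(cfg) sprintf("M%04d", seq_len(cfg$n_motifs))

# Active-motif identifiers are resolved once, on their own seed stream, so the
# same config always plants the same motifs regardless of which sub-generator
# runs first.
resolve_active_motifs <- function(cfg) {
  ids <- sim_motif_ids(cfg)
  am <- cfg$active_motifs
  if (is.character(am)) {
    if (!all(am %in% ids))
      ct_validation_error("active_motifs not among simulated motif identifiers: %s",
                          paste(setdiff(am, ids), collapse = ", "))
    return(sort(am))
  }
  am <- as.integer(am)
  if (length(am) != 1 || am < 0 || am > cfg$n_motifs)
    ct_validation_error("active_motifs count must be in [0, n_motifs]")
  if (am == 0) return(character(0))
  set.seed(ct_subseed(cfg$seed, 5L))
  sort(sample(ids, am))
}

#' Simulate threshold-nested gene-by-motif frequency tables
#'
#' Counts at the loosest PSSM threshold are Poisson with per-cell mean
#' `cfg$motif_rate / cfg$n_motifs` (so each promoter carries `motif_rate`
#' occurrences in expectation, spread sparsely over motifs); each stricter
#' table is a binomial thinning of its predecessor with probability
#' `cfg$retention`, so counts are element-wise non-increasing with threshold
#' by construction — the nesting the published per-threshold frequency tables
#' have. All-zero motif columns (whose profiles would be undefined in the
#' downstream correspondence analysis) trigger regeneration or an error per
#' `cfg$on_degenerate`; all-zero gene rows are expected under a sparse model
#' and harmless (they carry zero mass downstream).
#'
#' @param cfg a [sim_config()] object.
#' @return a list of `GeneMotifTable` objects (one per threshold, loosest
#'   first), each with fields `counts`, `gene_ids`, `motif_ids`, `threshold`.
#' @export
simulate_motif_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg)
  motifs <- sim_motif_ids(cfg)
  n <- cfg$n_genes * cfg$n_motifs
  max_attempts <- if (cfg$on_degenerate == "regenerate") 5L else 1L

  for (attempt in seq_len(max_attempts)) {
    set.seed(ct_subseed(cfg$seed, 1L) + (attempt - 1L))
    cell_rate <- cfg$motif_rate / cfg$n_motifs
    base <- matrix(stats::rpois(n, cell_rate), cfg$n_genes, cfg$n_motifs,
                   dimnames = list(genes, motifs))
    tabs <- vector("list", length(cfg$thresholds))
    tabs[[1]] <- base
    for (t in seq_along(cfg$thresholds)[-1]) {
      prev <- tabs[[t - 1]]
      thin <- stats::rbinom(n, size = as.vector(prev), prob = cfg$retention)
      tabs[[t]] <- matrix(thin, cfg$n_genes, cfg$n_motifs,
                          dimnames = dimnames(prev))
    }
    bad <- any(vapply(tabs, function(m) any(colSums(m) == 0), logical(1)))
    if (!bad) {
      return(lapply(seq_along(tabs), function(t) {
        gene_motif_table(tabs[[t]], threshold = cfg$thresholds[t])
      }))
    }
  }
  ct_validation_error(
    "degenerate motif tables: an all-zero column persisted after %d attempt(s); %s",
    max_attempts, "increase motif_rate/retention or table dimensions")
}

#' Simulate a group-structured expression matrix with planted motif effects
#'
#' The log2-scale value for gene g in sample s is
#' `b_g + effect_size * A_g * 1[s resistant] + N(0, noise_sd)`, with a
#' per-gene baseline `b_g ~ N(baseline_mean, baseline_sd)`,
#' where `A_g` is the total promoter occurrence count of the planted active
#' motifs in gene g (taken from the loosest-threshold table). The matrix is
#' returned on a strictly non-negative intensity scale (`2^y` by default) so
#' correspondence-analysis preconditions hold. Both resistant groups receive
#' the same planted effect, so the two resistant-vs-parental comparisons have
#' a nonempty consistent-overlap truth.
#'
#' @param cfg a [sim_config()] object.
#' @param loosest_table the first table from [simulate_motif_tables()]; its
#'   gene set must equal the configured gene set.
#' @return list with `expr` (an `ExpressionMatrix`) and `truth` (a
#'   `SyntheticTruth` recording active motifs and per-gene differential
#'   status/sign, identical for both resistant-vs-parental comparisons).
#' @export
simulate_expression <- function(cfg, loosest_table) {
  stopifnot(inherits(cfg, "sim_config"), inherits(loosest_table, "GeneMotifTable"))
  genes <- sim_gene_ids(cfg)
  if (!identical(loosest_table$gene_ids, genes))
    ct_validation_error("loosest_table gene set does not match the configured gene set")

  active <- resolve_active_motifs(cfg)
  a_count <- if (length(active))
    rowSums(loosest_table$counts[, active, drop = FALSE]) else rep(0, cfg$n_genes)

  labels <- rep(names(cfg$groups), cfg$groups)
  sample_ids <- unlist(lapply(names(cfg$groups), function(g)
    paste0(g, "_", seq_len(cfg$groups[[g]]))), use.names = FALSE)
  resistant <- labels %in% cfg$resistant_groups

  set.seed(ct_subseed(cfg$seed, 2L))
  n_s <- length(sample_ids)
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  eff <- outer(cfg$effect_size * a_count, as.numeric(resistant))
  y <- baseline + eff +
    matrix(stats::rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd), cfg$n_genes, n_s)
  vals <- if (cfg$intensity_scale == "exp2") 2^y else y + cfg$shift_constant
  if (any(vals < 0))
    ct_validation_error("shifted intensities are negative; increase shift_constant")
  dimnames(vals) <- list(genes, sample_ids)

  group_of <- stats::setNames(labels, sample_ids)
  expr <- expression_matrix(vals, group_of)

  diff <- cfg$effect_size != 0 & a_count > 0
  truth <- list(
    active_motifs = active,
    differential = data.frame(
      gene = genes,
      active_sites = as.integer(a_count),
      differential = diff,
      sign = ifelse(diff, sign(cfg$effect_size), 0),
      stringsAsFactors = FALSE
    ),
    comparisons = lapply(cfg$resistant_groups, function(g) c("Ag"[1], g))
  )
  class(truth) <- "SyntheticTruth"
  list(expr = expr, truth = truth)
}

#' Simulate a metastatic cohort with IHC scores and survival
#'
#' Each patient carries a latent marker-high/low class (prevalence
#' `p_srf_high`); per-site IHC scores 0-3 are drawn from the class-specific
#' distribution, sites split bone/soft with probability `p_bone`, and the
#' three survival durations (from diagnosis, from castration resistance, from
#' first bone metastasis) are exponential with the baseline hazard multiplied
#' by `hazard_ratio` for marker-high patients. Censoring is independent
#' exponential; the observed time is the minimum with the matching event flag.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `clinical` (a `ClinicalTable`) and `truth` (per-patient
#'   latent marker class).
#' @export
simulate_clinical_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(ct_subseed(cfg$seed, 3L))
  np <- cfg$n_patients
  pid <- sprintf("P%03d", seq_len(np))
  high <- stats::runif(np) < cfg$p_srf_high
  treated <- stats::runif(np) < cfg$treated_frac

  n_sites <- sample(seq(cfg$sites_range[1], cfg$sites_range[2]), np, replace = TRUE)
  sites <- do.call(rbind, lapply(seq_len(np), function(i) {
    k <- n_sites[i]
    probs <- if (high[i]) cfg$score_probs_high else cfg$score_probs_low
    data.frame(
      patient_id = pid[i],
      site_id = sprintf("%s_s%d", pid[i], seq_len(k)),
      site_type = ifelse(stats::runif(k) < cfg$p_bone, "bone", "soft"),
      ihc_score = sample(0:3, k, replace = TRUE, prob = probs),
      usable = stats::runif(k) >= cfg$p_unusable,
      stringsAsFactors = FALSE
    )
  }))
  sites$ihc_score[!sites$usable] <- NA_integer_

  hr <- ifelse(high, cfg$hazard_ratio, 1)
  pat <- data.frame(patient_id = pid, docetaxel_treated = treated,
                    stringsAsFactors = FALSE)
  for (b in names(cfg$base_rates)) {
    te <- stats::rexp(np, rate = cfg$base_rates[[b]] * hr)
    tc <- if (cfg$censor_rate > 0) stats::rexp(np, rate = cfg$censor_rate) else Inf
    pat[[paste0("time_", b)]] <- pmin(te, tc)
    pat[[paste0("event_", b)]] <- te <= tc
  }

  truth <- list(srf_class = stats::setNames(ifelse(high, "high", "low"), pid))
  class(truth) <- "SyntheticTruth"
  list(clinical = clinical_table(sites, pat), truth = truth)
}
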