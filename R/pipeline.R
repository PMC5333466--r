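# End-to-end orchestration: simulate (or accept) inputs, normalize, run
# differential expression with consistent overlap, unsupervised and
# supervised co-inertia per PSSM threshold, rank-product aggregation, the
# cross-comparison consensus, and the clinical validation arm. Every random
# component derives from the single config seed, so a rerun with the same
# config is byte-identical on disk (the manifest timestamp aside).

#' Run the full transcription-factor discovery pipeline
#'
#' Stage order: quantile normalization, per-comparison moderated differential
#' expression and consistent overlap; unsupervised co-inertia of the
#' expression table with the strictest-threshold motif table (exploration);
#' supervised co-inertia (between-group constrained) per comparison at every
#' PSSM threshold; rank products across thresholds within each comparison;
#' consensus overlap of the two rank-product heads; clinical validation. The
#' clinical arm is independent of the discovery arm.
#'
#' @param config a [run_config()].
#' @param expr optional `ExpressionMatrix`; simulated from `config$sim` when
#'   NULL.
#' @param motif_tables optional list of `GeneMotifTable`s (loosest first);
#'   simulated when NULL.
#' @param clinical optional `ClinicalTable`; simulated when NULL.
#' @param outdir optional output directory; when given, all result tables
#'   and a JSON manifest are written via [write_results()].
#' @return a list with every stage's result (`expr`, `motif_tables`, `de`,
#'   `overlap`, `unsupervised` (CIA + RV), `supervised`, `rankings`,
#'   `rank_products`, `consensus`, `clinical`, `clinical_stats`, `truth`
#'   when simulated, `seed`, `config_snapshot`).
#' @export
run_tf_pipeline <- function(config = run_config(), expr = NULL,
                            motif_tables = NULL, clinical = NULL,
                            outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  truth <- list()

  if (is.null(motif_tables)) {
    motif_tables <- simulate_motif_tables(sim)
  }
  if (is.null(expr)) {
    se <- simulate_expression(sim, motif_tables[[1]])
    expr <- se$expr
    truth$expression <- se$truth
  }
  if (is.null(clinical)) {
    sc <- simulate_clinical_cohort(sim)
    clinical <- sc$clinical
    truth$clinical <- sc$truth
  }

  # one alignment defines the gene universe for every coupling
  al <- align_to_expression(expr, motif_tables[[1]])
  expr <- al$expr
  motif_tables <- lapply(motif_tables, function(t)
    gene_motif_table(t$counts[expr$gene_ids, , drop = FALSE], t$threshold))

  expr_qn <- quantile_normalize(expr)

  groups <- unique(unname(expr_qn$group_of))
  parental <- setdiff(groups, sim$resistant_groups)
  if (length(parental) != 1)
    ct_validation_error("expected exactly one parental group, found: %s",
                        paste(parental, collapse = ", "))
  comparisons <- lapply(sim$resistant_groups, function(g) c(parental, g))
  names(comparisons) <- vapply(comparisons, paste, "", collapse = "_vs_")

  de <- lapply(comparisons, function(cmp) {
    fit <- fit_group_model(expr_qn, cmp)
    res <- ebayes_moderate(fit)
    list(fit = fit, table = res)
  })
  overlap <- consistent_overlap(de[[1]]$table, de[[2]]$table,
                                cutoff = config$adjp_cutoff,
                                require_sign = config$require_sign)

  motif_ords <- lapply(motif_tables, function(t) nsca(t, n_axes = config$n_axes))
  names(motif_ords) <- as.character(sim$thresholds)

  expr_ord <- nsca(expr_qn, n_axes = config$n_axes)
  strict <- length(motif_ords)
  unsup <- coinertia(expr_ord, motif_ords[[strict]], n_axes = config$n_axes)

  supervised <- list(); rankings <- list()
  for (cmp_name in names(comparisons)) {
    cmp <- comparisons[[cmp_name]]
    supervised[[cmp_name]] <- list()
    rankings[[cmp_name]] <- list()
    for (th in names(motif_ords)) {
      sc <- supervised_cia(expr_qn, motif_ords[[th]], cmp)
      rl <- rank_motifs(sc, threshold = th)
      supervised[[cmp_name]][[th]] <- sc
      rankings[[cmp_name]][[th]] <- rl
    }
  }
  rank_products <- lapply(names(comparisons), function(cmp_name)
    rank_product(rankings[[cmp_name]], B = config$B,
                 seed = ct_subseed(config$seed, 7L)))
  names(rank_products) <- names(comparisons)

  M <- length(motif_tables[[1]]$motif_ids)
  k_eff <- min(config$k, M)
  if (k_eff < config$k)
    message(sprintf("consensus head size clamped to the motif count (%d)", M))
  consensus <- consensus_tfs(rank_products[[1]], rank_products[[2]],
                             k = k_eff,
                             deA = de[[1]]$table, deB = de[[2]]$table)

  cval <- clinical_validation(clinical)

  results <- list(
    expr = expr, expr_qn = expr_qn, motif_tables = motif_tables,
    comparisons = comparisons,
    de = lapply(de, function(x) list(table = x$table)),
    overlap = overlap,
    expr_ord = expr_ord, motif_ords = motif_ords,
    unsupervised = unsup,
    supervised = supervised,
    rankings = rankings,
    rank_products = rank_products,
    consensus = consensus,
    clinical = clinical,
    clinical_validation = cval,
    clinical_stats = cval$stats,
    truth = truth,
    seed = config$seed,
    config_snapshot = config_snapshot(config)
  )
  if (!is.null(outdir)) {
    results$km_tables <- do.call(rbind, lapply(names(cval$survival), function(b) {
      km <- cval$survival[[b]]$km
      if (is.null(km)) return(NULL)
      cbind(baseline = b, km$curves)
    }))
    results$files <- write_results(results, outdir)
  }
  results
}

config_snapshot <- function(config) {
  sim <- config$sim
  list(adjp_cutoff = config$adjp_cutoff, n_axes = config$n_axes,
       B = config$B, k = config$k, require_sign = config$require_sign,
       seed = config$seed,
       sim = sim[setdiff(names(sim), c("score_probs_low", "score_probs_high"))])
}
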