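# Containers and on-disk formats. Matrices travel as TSV (genes as rows,
# header row of sample/motif identifiers), sample annotations as two-column
# TSV, the clinical table as one site-level CSV with patient columns repeated,
# run metadata as JSON. Readers validate and reject; they never coerce.

#' Construct a validated expression matrix
#'
#' @param values non-negative numeric gene-by-sample matrix with unique row
#'   (gene) and column (sample) names.
#' @param group_of named character vector mapping every sample to its group.
#' @return object of class `ExpressionMatrix` with fields `values`,
#'   `gene_ids`, `sample_ids`, `group_of`.
#' @export
expression_matrix <- function(values, group_of) {
  if (!is.matrix(values) || !is.numeric(values))
    ct_validation_error("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ct_validation_error("expression matrix needs gene row names and sample column names")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    ct_validation_error("negative expression value at gene '%s', sample '%s'",
                        rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]])
  if (anyDuplicated(rownames(values)))
    ct_validation_error("duplicate gene identifier: '%s'",
                        rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    ct_validation_error("duplicate sample identifier: '%s'",
                        colnames(values)[duplicated(colnames(values))][1])
  miss <- setdiff(colnames(values), names(group_of))
  if (length(miss))
    ct_validation_error("sample without group annotation: '%s'", miss[1])
  obj <- list(values = values,
              gene_ids = rownames(values),
              sample_ids = colnames(values),
              group_of = group_of[colnames(values)])
  class(obj) <- "ExpressionMatrix"
  obj
}

#' Construct a validated gene-by-motif frequency table
#'
#' @param counts non-negative numeric gene-by-motif matrix with unique
#'   dimnames.
#' @param threshold PSSM threshold label attached to the table.
#' @return object of class `GeneMotifTable`.
#' @export
gene_motif_table <- function(counts, threshold) {
  if (!is.matrix(counts) || !is.numeric(counts))
    ct_validation_error("motif counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ct_validation_error("motif table needs gene row names and motif column names")
  if (any(counts < 0)) {
    neg <- which(counts < 0, arr.ind = TRUE)
    ct_validation_error("negative motif count at gene '%s', motif '%s'",
                        rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]])
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    ct_validation_error("duplicate gene or motif identifier in motif table")
  obj <- list(counts = counts, gene_ids = rownames(counts),
              motif_ids = colnames(counts), threshold = threshold)
  class(obj) <- "GeneMotifTable"
  obj
}

#' Construct a validated clinical table
#'
#' Site-level IHC records plus patient-level treatment and survival columns.
#' Unusable cores are flagged (`usable = FALSE`, score `NA`), never dropped.
#'
#' @param sites data frame with columns `patient_id`, `site_id`, `site_type`
#'   (`"bone"`/`"soft"`), `ihc_score` (0-3 or NA), `usable` (logical).
#' @param patients data frame with `patient_id`, `docetaxel_treated`, and for
#'   each baseline b in diagnosis/crpc/bonemet a `time_b` (years, >= 0) and
#'   logical `event_b` column.
#' @return object of class `ClinicalTable`.
#' @export
clinical_table <- function(sites, patients) {
  need_s <- c("patient_id", "site_id", "site_type", "ihc_score", "usable")
  if (!all(need_s %in% names(sites)))
    ct_validation_error("sites table missing column(s): %s",
                        paste(setdiff(need_s, names(sites)), collapse = ", "))
  if (!all(sites$site_type %in% c("bone", "soft")))
    ct_validation_error("site_type must be 'bone' or 'soft'")
  sc <- sites$ihc_score[!is.na(sites$ihc_score)]
  if (any(!(sc %in% 0:3)))
    ct_validation_error("IHC scores must lie in {0,1,2,3}; found %s",
                        paste(unique(sc[!(sc %in% 0:3)]), collapse = ", "))
  if (any(is.na(sites$ihc_score) & sites$usable))
    ct_validation_error("usable site with missing score (flag it unusable instead)")
  if (anyDuplicated(sites$site_id))
    ct_validation_error("duplicate site identifier")
  tcols <- grep("^time_", names(patients), value = TRUE)
  if (!length(tcols))
    ct_validation_error("patients table needs at least one time_/event_ column pair")
  for (tc in tcols) {
    if (any(patients[[tc]] < 0, na.rm = TRUE))
      ct_validation_error("negative duration in column '%s'", tc)
    ec <- sub("^time_", "event_", tc)
    if (!ec %in% names(patients))
      ct_validation_error("missing event flag column '%s'", ec)
  }
  if (anyDuplicated(patients$patient_id))
    ct_validation_error("duplicate patient identifier")
  if (!all(sites$patient_id %in% patients$patient_id))
    ct_validation_error("site rows reference unknown patient(s)")
  obj <- list(sites = sites, patients = patients,
              baselines = sub("^time_", "", tcols))
  class(obj) <- "ClinicalTable"
  obj
}

#' Read an expression matrix and its sample annotation from TSV
#'
#' @param path TSV with a header row of sample identifiers and gene
#'   identifiers in the first column.
#' @param annotation_path two-column TSV (`sample`, `group`) annotating every
#'   sample.
#' @return an `ExpressionMatrix`; genes and samples keep their on-disk order.
#' @export
read_expression <- function(path, annotation_path) {
  if (!file.exists(path)) ct_io_error("expression file not found: %s", path)
  if (!file.exists(annotation_path))
    ct_io_error("annotation file not found: %s", annotation_path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) ct_validation_error("expression TSV needs >= 1 sample column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) ct_validation_error("non-numeric expression value in %s", path)
  rownames(m) <- genes
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (ncol(ann) < 2) ct_validation_error("annotation TSV needs sample and group columns")
  group_of <- stats::setNames(as.character(ann[[2]]), as.character(ann[[1]]))
  expression_matrix(m, group_of)
}

#' Write an expression matrix (and annotation) to TSV
#' @param expr an `ExpressionMatrix`.
#' @param path output TSV for the matrix.
#' @param annotation_path optional output TSV for the sample-to-group map.
#' @export
write_expression <- function(expr, path, annotation_path = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene = expr$gene_ids,
                   apply(expr$values, 2, ct_format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", expr$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(
      data.frame(sample = expr$sample_ids, group = unname(expr$group_of)),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write one gene-by-motif table to TSV
#' @param tab a `GeneMotifTable`.
#' @param path output path.
#' @export
write_motif_table <- function(tab, path) {
  stopifnot(inherits(tab, "GeneMotifTable"))
  df <- data.frame(gene = tab$gene_ids, tab$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", tab$motif_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-threshold gene-by-motif frequency tables
#'
#' @param paths character vector of TSV paths, one per threshold, named by
#'   threshold (or accompanied by `thresholds`).
#' @param thresholds numeric thresholds matching `paths` (defaults to the
#'   names of `paths`).
#' @param mode `"strict"` requires identical gene and motif sets across
#'   tables; `"intersect"` restricts all tables to the common sets
#'   (lexicographic gene order) and errors only when an intersection is empty.
#' @return list of aligned `GeneMotifTable` objects, loosest threshold first.
#' @export
read_motif_tables <- function(paths, thresholds = as.numeric(names(paths)),
                              mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  if (length(paths) < 1) ct_validation_error("no motif table paths given")
  if (length(thresholds) != length(paths) || any(is.na(thresholds)))
    ct_validation_error("each motif table path needs a numeric threshold")
  if (is.unsorted(thresholds, strictly = TRUE))
    ct_validation_error("motif table thresholds must be strictly increasing")
  raw <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (!file.exists(p)) ct_io_error("motif table not found: %s", p)
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    gene_motif_table(m, threshold = thresholds[i])
  })
  genes <- Reduce(intersect, lapply(raw, `[[`, "gene_ids"))
  motifs <- Reduce(intersect, lapply(raw, `[[`, "motif_ids"))
  if (mode == "strict") {
    same <- all(vapply(raw, function(t)
      setequal(t$gene_ids, raw[[1]]$gene_ids) &&
        setequal(t$motif_ids, raw[[1]]$motif_ids), logical(1)))
    if (!same)
      ct_validation_error("motif tables disagree on gene/motif sets (strict mode)")
  }
  if (!length(genes)) ct_validation_error("empty gene intersection across motif tables")
  if (!length(motifs)) ct_validation_error("empty motif intersection across motif tables")
  genes <- sort(genes); motifs <- sort(motifs)
  lapply(raw, function(t)
    gene_motif_table(t$counts[genes, motifs, drop = FALSE], t$threshold))
}

#' Restrict an expression matrix and a motif table to their common genes
#'
#' Both outputs use the same lexicographic gene order regardless of input
#' order; the number of genes dropped from each side is reported via
#' `message()`.
#'
#' @param expr an `ExpressionMatrix`.
#' @param motifs a `GeneMotifTable`.
#' @return list with elements `expr` and `motifs` on the common gene set.
#' @export
align_to_expression <- function(expr, motifs) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(motifs, "GeneMotifTable"))
  common <- sort(intersect(expr$gene_ids, motifs$gene_ids))
  if (!length(common)) ct_validation_error("no genes shared by expression and motif table")
  message(sprintf("align_to_expression: kept %d genes (dropped %d expression, %d motif)",
                  length(common),
                  length(expr$gene_ids) - length(common),
                  length(motifs$gene_ids) - length(common)))
  list(
    expr = expression_matrix(expr$values[common, , drop = FALSE], expr$group_of),
    motifs = gene_motif_table(motifs$counts[common, , drop = FALSE], motifs$threshold)
  )
}

#' Read a clinical cohort CSV
#'
#' One row per metastatic site; patient-level columns (treatment flag, the
#' three survival durations and event flags) are repeated across a patient's
#' rows and must agree.
#'
#' @param path CSV path.
#' @return a `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) ct_io_error("clinical file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scols <- c("patient_id", "site_id", "site_type", "ihc_score", "usable")
  if (!all(scols %in% names(df)))
    ct_validation_error("clinical CSV missing column(s): %s",
                        paste(setdiff(scols, names(df)), collapse = ", "))
  pcols <- setdiff(names(df), setdiff(scols, "patient_id"))
  pat <- unique(df[, pcols, drop = FALSE])
  if (anyDuplicated(pat$patient_id))
    ct_validation_error("patient-level columns disagree across a patient's site rows")
  df$usable <- as.logical(df$usable)
  for (ec in grep("^event_", names(pat), value = TRUE))
    pat[[ec]] <- as.logical(pat[[ec]])
  pat$docetaxel_treated <- as.logical(pat$docetaxel_treated)
  clinical_table(df[, scols], pat)
}

#' Write a clinical cohort to CSV
#' @param ct a `ClinicalTable`.
#' @param path output CSV path.
#' @export
write_clinical <- function(ct, path) {
  stopifnot(inherits(ct, "ClinicalTable"))
  df <- merge(ct$sites, ct$patients, by = "patient_id", sort = FALSE)
  df <- df[order(df$patient_id, df$site_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param adjp_cutoff adjusted-P significance cutoff for differential
#'   expression (default 0.01).
#' @param n_axes ordination axes retained (default 5; displays use 2).
#' @param B permutations for rank-product / RV significance; >= 100 required
#'   when permutation significance is requested.
#' @param k head size of each comparison's rank-product list entering the
#'   consensus overlap.
#' @param require_sign whether consistent overlap demands concordant
#'   fold-change direction (default TRUE).
#' @param seed integer seed driving every random component.
#' @param sim a [sim_config()] used when inputs are simulated rather than
#'   read from disk (its seed is overridden by `seed`).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(adjp_cutoff = 0.01, n_axes = 5, B = 1000, k = 20,
                       require_sign = TRUE, seed = 1L, sim = NULL) {
  if (adjp_cutoff <= 0 || adjp_cutoff >= 1)
    ct_validation_error("adjp_cutoff must lie in (0, 1)")
  if (B < 100)
    ct_validation_error("B must be >= 100 when permutation significance is requested")
  if (k < 1) ct_validation_error("k must be positive")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  cfg <- list(adjp_cutoff = adjp_cutoff, n_axes = n_axes, B = as.integer(B),
              k = as.integer(k), require_sign = require_sign,
              seed = as.integer(seed), sim = sim)
  class(cfg) <- "run_config"
  cfg
}

write_tsv_6sig <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- ct_format_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all pipeline result tables to a directory
#'
#' Emits differential-expression tables, per-threshold motif rankings, the
#' rank-product tables, the consensus TF list (symbol, description, log
#' fold change, P-value when a matching transcript was measured), clinical
#' statistics, and a JSON run manifest with config, seed, package version and
#' a content hash per file. An empty consensus yields a header-only TSV.
#'
#' @param results list produced by [run_tf_pipeline()].
#' @param outdir output directory (created if absent).
#' @return invisible character vector of written paths.
#' @export
write_results <- function(results, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    ct_io_error("cannot create output directory: %s", outdir)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  for (cmp in names(results$de)) {
    p <- file.path(outdir, sprintf("de_%s.tsv", cmp))
    add(write_tsv_6sig(results$de[[cmp]]$table, p))
  }
  if (!is.null(results$overlap)) {
    p <- file.path(outdir, "consistent_overlap.tsv")
    add(write_tsv_6sig(results$overlap$table, p))
  }
  for (cmp in names(results$rankings %||% list())) {
    for (th in names(results$rankings[[cmp]])) {
      p <- file.path(outdir, sprintf("ranking_%s_thr%s.tsv", cmp, th))
      add(write_tsv_6sig(results$rankings[[cmp]][[th]], p))
    }
  }
  for (cmp in names(results$rank_products %||% list())) {
    p <- file.path(outdir, sprintf("rank_product_%s.tsv", cmp))
    add(write_tsv_6sig(results$rank_products[[cmp]], p))
  }
  if (!is.null(results$consensus)) {
    p <- file.path(outdir, "consensus_tf.tsv")
    add(write_tsv_6sig(results$consensus, p))
  }
  if (!is.null(results$clinical_stats)) {
    p <- file.path(outdir, "clinical_stats.tsv")
    add(write_tsv_6sig(results$clinical_stats, p))
  }
  if (!is.null(results$km_tables)) {
    p <- file.path(outdir, "km_tables.tsv")
    add(write_tsv_6sig(results$km_tables, p))
  }

  manifest <- list(
    package = "cointf",
    version = as.character(utils::packageVersion("cointf")),
    seed = results$seed,
    config = results$config_snapshot,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(paths, basename(paths)), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p)))
  )
  mpath <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mpath))
}
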