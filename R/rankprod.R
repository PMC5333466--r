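# Rank aggregation: per-threshold motif rankings from the supervised
# co-inertia axis, rank-product aggregation across PSSM thresholds, and the
# cross-comparison consensus list.

#' Rank motifs by association with the resistant pole
#'
#' Motifs are sorted by descending signed loading on the oriented
#' discriminating axis; ties are broken lexicographically by motif id, and
#' ranks 1..M are assigned. With `direction = "absolute"` motifs are ranked
#' by |loading| for direction-agnostic discovery.
#'
#' @param scia a `SupervisedCIA` (or any named loading vector via
#'   `loadings`).
#' @param threshold PSSM threshold label carried into the output.
#' @param direction `"resistant"` (signed, default) or `"absolute"`.
#' @return data frame of class `RankedMotifList` with columns `motif`,
#'   `loading`, `rank`; attributes `comparison`, `threshold`.
#' @export
rank_motifs <- function(scia, threshold = NA,
                        direction = c("resistant", "absolute")) {
  direction <- match.arg(direction)
  if (inherits(scia, "SupervisedCIA")) {
    loadings <- scia$motif_loadings
    comparison <- scia$comparison
  } else if (is.numeric(scia) && !is.null(names(scia))) {
    loadings <- scia
    comparison <- NA
  } else {
    ct_validation_error("rank_motifs needs a SupervisedCIA or a named loading vector")
  }
  key <- if (direction == "resistant") loadings else abs(loadings)
  ord <- order(-key, names(loadings))
  out <- data.frame(motif = names(loadings)[ord],
                    loading = unname(loadings[ord]),
                    rank = seq_along(loadings),
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  attr(out, "threshold") <- threshold
  class(out) <- c("RankedMotifList", class(out))
  out
}

rank_matrix_from_lists <- function(lists) {
  motifs <- sort(lists[[1]]$motif)
  for (l in lists) {
    if (!setequal(l$motif, motifs))
      ct_validation_error("ranked lists cover different motif sets")
  }
  R <- vapply(lists, function(l) l$rank[match(motifs, l$motif)],
              numeric(length(motifs)))
  rownames(R) <- motifs
  R
}

#' Rank-product aggregation across ranked lists
#'
#' For motif m with ranks `r_{m,t}` across the T lists,
#' `RP_m = (prod_t r_{m,t})^(1/T)` (the geometric mean). Significance is
#' permutation-based: under the null each list is an independent uniform
#' random permutation, so a motif's T ranks are independent uniform on
#' `1..M`. When `M^T <= B` the null distribution is enumerated exactly;
#' otherwise `B` seeded Monte-Carlo permutation draws are used and
#' `p_m = (1 + #{RP_null <= RP_m}) / (B + 1)`. The estimated percentage of
#' false predictions is `pfp_m = p_m * M / rank(p_m)`.
#'
#' @param lists list of >= 2 `RankedMotifList` objects over the same motifs.
#' @param B permutation budget (and exact-enumeration cutoff).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return data frame of class `RankProductResult` with columns `motif`,
#'   `RP`, `p`, `pfp`, `rank` (final rank, ties broken by motif id);
#'   attributes `T`, `M`, `B`, `method` (`"exact"` or `"montecarlo"`).
#' @export
rank_product <- function(lists, B = 1000, seed = 1L) {
  if (length(lists) < 2)
    ct_validation_error("rank_product needs >= 2 ranked lists")
  R <- rank_matrix_from_lists(lists)
  M <- nrow(R); T <- ncol(R)
  RP <- exp(rowMeans(log(R)))

  if (M^T <= B) {
    grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(M)), T)))
    null_rp <- exp(rowMeans(log(grid)))
    p <- vapply(RP, function(x) mean(null_rp <= x * (1 + 1e-12)), numeric(1))
    method <- "exact"
  } else {
    set.seed(as.integer(seed))
    exceed <- numeric(M)
    for (b in seq_len(B)) {
      Rb <- vapply(seq_len(T), function(t) sample.int(M), numeric(M))
      rp_b <- exp(rowMeans(log(Rb)))
      exceed <- exceed + (rp_b <= RP * (1 + 1e-12))
    }
    p <- (1 + exceed) / (B + 1)
    method <- "montecarlo"
  }
  pfp <- p * M / rank(p, ties.method = "min")
  final <- order(RP, rownames(R))
  rk <- integer(M); rk[final] <- seq_len(M)
  out <- data.frame(motif = rownames(R), RP = RP, p = p, pfp = pfp,
                    rank = rk, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "T") <- T
  attr(out, "M") <- M
  attr(out, "B") <- B
  attr(out, "method") <- method
  class(out) <- c("RankProductResult", class(out))
  out
}

#' Consensus motifs across two comparisons' rank-product lists
#'
#' The motifs present in the top-k of both comparisons, ordered by the sum of
#' their final ranks (ties broken by motif id). Optionally annotates each
#' consensus motif with the differential-expression evidence of its own
#' transcript when one was measured.
#'
#' @param rpA,rpB `RankProductResult` objects over the same motif universe.
#' @param k head size taken from each list (`k <= M`).
#' @param deA,deB optional `DEResult` objects supplying logFC / adjusted P.
#' @param motif_to_gene optional named vector mapping motif ids to gene ids
#'   for the DE lookup.
#' @return data frame of class `ConsensusTFList` with both ranks and RP
#'   values (and `logFC_A`, `adjP_A`, `logFC_B`, `adjP_B` when DE evidence is
#'   given). An empty intersection yields a zero-row frame with a warning.
#' @export
consensus_tfs <- function(rpA, rpB, k = 20, deA = NULL, deB = NULL,
                          motif_to_gene = NULL) {
  if (!setequal(rpA$motif, rpB$motif))
    ct_validation_error("the two rank-product lists cover different motifs")
  M <- nrow(rpA)
  if (k > M) ct_validation_error("k (%d) exceeds the number of motifs (%d)", k, M)
  topA <- rpA$motif[rpA$rank <= k]
  topB <- rpB$motif[rpB$rank <= k]
  inter <- intersect(topA, topB)
  if (!length(inter)) warning("empty consensus: the two top-k sets are disjoint")
  ia <- match(inter, rpA$motif)
  ib <- match(inter, rpB$motif)
  out <- data.frame(motif = inter,
                    rank_A = rpA$rank[ia], rank_B = rpB$rank[ib],
                    RP_A = rpA$RP[ia], RP_B = rpB$RP[ib],
                    rank_sum = rpA$rank[ia] + rpB$rank[ib],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_sum, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(deA) && !is.null(deB)) {
    gene <- if (is.null(motif_to_gene)) out$motif else
      unname(motif_to_gene[out$motif])
    out$gene <- gene
    out$logFC_A <- deA$logFC[match(gene, deA$gene)]
    out$adjP_A <- deA$adj.P.Val[match(gene, deA$gene)]
    out$logFC_B <- deB$logFC[match(gene, deB$gene)]
    out$adjP_B <- deB$adj.P.Val[match(gene, deB$gene)]
  }
  class(out) <- c("ConsensusTFList", class(out))
  out
}
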