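# Duality-diagram ordinations. Non-symmetric correspondence analysis (NSCA)
# decomposes the dependence of genes (rows) on samples or motifs (columns);
# co-inertia analysis (CIA) couples two such ordinations over their shared
# gene index; between-group analysis (BGA) supervises the expression side.

axis_tol <- 1e-12

# deterministic sign convention: make the largest-|x| entry positive
fix_sign <- function(x) {
  i <- which.max(abs(x))
  if (length(i) && x[i] < 0) -1 else 1
}

#' Non-symmetric correspondence analysis
#'
#' With `P = table / grand total`, row masses `r_i` and column masses `c_j`,
#' the transformed table has entries `q_ij = p_ij / c_j - r_i` (column
#' profiles centred by the row masses). The decomposition is the SVD of `Q`
#' with columns scaled by `sqrt(c_j)` and rows unweighted; the eigenvalues
#' (squared singular values) sum to the total inertia
#' `sum_j c_j sum_i q_ij^2`, the numerator of the Goodman-Kruskal tau with
#' columns as predictors.
#'
#' @param x non-negative numeric matrix (genes as rows) with a nonzero grand
#'   total and no all-zero column.
#' @param n_axes maximum number of axes to retain (default 5).
#' @return object of class `Ordination`: the raw and transformed tables, row
#'   and column masses, eigenvalues, row and column principal scores, the raw
#'   SVD factors, and the total inertia. Axis signs are fixed so the
#'   largest-|loading| column entry is positive, making repeated runs
#'   bit-identical.
#' @examples
#' ord <- nsca(matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("g1","g2"), c("a","b"))))
#' ord$inertia  # 0.5
#' @export
nsca <- function(x, n_axes = 5) {
  if (inherits(x, "ExpressionMatrix")) x <- x$values
  if (inherits(x, "GeneMotifTable")) x <- x$counts
  if (!is.matrix(x) || !is.numeric(x))
    ct_validation_error("nsca needs a numeric matrix")
  if (any(x < 0)) ct_validation_error("nsca input must be non-negative")
  N <- sum(x)
  if (N <= 0) ct_validation_error("nsca input has zero grand total")
  cs <- colSums(x)
  if (any(cs == 0)) {
    j <- which(cs == 0)[1]
    ct_validation_error("all-zero column '%s': column profile undefined",
                        colnames(x)[j] %||% as.character(j))
  }
  P <- x / N
  r <- rowSums(P)
  cw <- colSums(P)
  Q <- sweep(P, 2, cw, "/") - r          # q_ij = p_ij / c_j - r_i
  Qw <- sweep(Q, 2, sqrt(cw), "*")
  sv <- svd(Qw)
  eig <- sv$d^2
  pos <- eig > axis_tol * max(eig, 1)
  k <- as.integer(min(n_axes, sum(pos)))
  if (k < 1) k <- 1L
  for (a in seq_len(k)) {
    s <- fix_sign(sv$v[, a])
    sv$u[, a] <- s * sv$u[, a]
    sv$v[, a] <- s * sv$v[, a]
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  row_scores <- u %*% diag(d, k)
  col_scores <- sweep(v, 1, sqrt(cw), "/") %*% diag(d, k)
  rownames(row_scores) <- rownames(x)
  rownames(col_scores) <- colnames(x)
  obj <- list(table = x, P = P, row_masses = r, col_masses = cw, Q = Q,
              eig = eig[eig > axis_tol * max(eig, 1)],
              svd = list(u = u, v = v, d = d),
              row_scores = row_scores, col_scores = col_scores,
              inertia = sum(cw * colSums(Q^2)), n_axes = k)
  class(obj) <- "Ordination"
  obj
}

# Coupling representation with uniform gene weights: column profile minus the
# uniform expectation 1/G, columns scaled by the table's own column masses.
# NSCA's natural row masses differ between the two coupled tables, so both
# sides are re-expressed on this common (uniform) row metric; a column
# constant across genes maps to exactly zero.
uniform_rep <- function(ord) {
  x <- ord$table
  prof <- sweep(x, 2, colSums(x), "/")
  Qu <- prof - 1 / nrow(x)
  sweep(Qu, 2, sqrt(ord$col_masses), "*")
}

#' Co-inertia analysis of two ordinations sharing their gene index
#'
#' Builds the cross-covariance matrix `Z = t(A) D B / 1` from the two
#' column-weighted transformed tables under the shared uniform row-weight
#' diagonal `D = I/G`, and decomposes it by SVD: the paired left/right axes
#' maximize squared co-variance of the gene scores. Total co-inertia is the
#' squared Frobenius norm of `Z`; the RV coefficient normalizes it by the
#' self-co-inertias, so `RV(A, A) = 1` and `RV` lies in `[0, 1]`.
#'
#' @param ordA,ordB `Ordination` objects with identical gene ids in the same
#'   order (expression side first by convention).
#' @param n_axes axes to retain.
#' @return object of class `CoinertiaResult`: singular values, left/right
#'   column loadings, total co-inertia, RV, and gene scores projected on each
#'   side's axes.
#' @export
coinertia <- function(ordA, ordB, n_axes = 5) {
  stopifnot(inherits(ordA, "Ordination"), inherits(ordB, "Ordination"))
  if (!identical(rownames(ordA$table), rownames(ordB$table)))
    ct_validation_error("coupled ordinations must share gene ids and row order")
  G <- nrow(ordA$table)
  Aw <- uniform_rep(ordA)
  Bw <- uniform_rep(ordB)
  selfA <- sum((crossprod(Aw) / G)^2)
  selfB <- sum((crossprod(Bw) / G)^2)
  if (selfA <= 0 || selfB <= 0)
    ct_validation_error("zero-inertia input table; nothing to couple")
  Z <- crossprod(Aw, Bw) / G
  sv <- svd(Z)
  total <- sum(Z^2)
  k <- as.integer(min(n_axes, sum(sv$d^2 > axis_tol * max(sv$d^2, 1))))
  if (k < 1) k <- 1L
  for (a in seq_len(k)) {
    s <- fix_sign(sv$u[, a])
    sv$u[, a] <- s * sv$u[, a]
    sv$v[, a] <- s * sv$v[, a]
  }
  axes_A <- sv$u[, seq_len(k), drop = FALSE]
  axes_B <- sv$v[, seq_len(k), drop = FALSE]
  rownames(axes_A) <- colnames(ordA$table)
  rownames(axes_B) <- colnames(ordB$table)
  rsA <- Aw %*% axes_A
  rsB <- Bw %*% axes_B
  obj <- list(svals = sv$d, axes_A = axes_A, axes_B = axes_B, n_axes = k,
              total_coinertia = total,
              RV = total / sqrt(selfA * selfB),
              row_scores_A = rsA, row_scores_B = rsB, n_genes = G)
  class(obj) <- "CoinertiaResult"
  obj
}

#' Row-permutation significance for the RV coefficient
#'
#' Monte-Carlo p-value for the strength of coupling: the gene rows of table A
#' are randomly permuted `B` times and the RV recomputed; the p-value is
#' `(1 + #{RV_perm >= RV_obs}) / (B + 1)`.
#'
#' @param ordA,ordB as in [coinertia()].
#' @param B number of permutations (>= 99 recommended).
#' @param seed RNG seed.
#' @return list with `RV`, `p.value`, and the permutation RVs.
#' @export
coinertia_perm_test <- function(ordA, ordB, B = 999, seed = 1L) {
  obs <- coinertia(ordA, ordB)
  G <- obs$n_genes
  Aw <- uniform_rep(ordA)
  Bw <- uniform_rep(ordB)
  selfA <- sum((crossprod(Aw) / G)^2)
  selfB <- sum((crossprod(Bw) / G)^2)
  set.seed(as.integer(seed))
  rv_perm <- vapply(seq_len(B), function(b) {
    Zp <- crossprod(Aw[sample.int(G), , drop = FALSE], Bw) / G
    sum(Zp^2) / sqrt(selfA * selfB)
  }, numeric(1))
  list(RV = obs$RV,
       p.value = (1 + sum(rv_perm >= obs$RV)) / (B + 1),
       perm = rv_perm)
}

#' Between-group analysis of an ordination
#'
#' Supervised ordination of the group means: columns (samples) of the NSCA
#' transformed table are averaged within groups using their column masses,
#' and the resulting group-mean table is decomposed under the group-mass
#' weighting. At most K-1 discriminating axes exist for K groups, and the
#' between-group inertia never exceeds the ordination's total inertia.
#' Samples are projected onto the discriminating axes supplementarily.
#'
#' @param ord an `Ordination` whose columns are samples.
#' @param groups named character vector mapping each sample (column id) to a
#'   group; every group must be non-empty.
#' @return object of class `BGAResult`: group centroids, discriminating axes,
#'   eigenvalues, supplementary sample scores, and the between/total inertia
#'   ratio.
#' @export
bga <- function(ord, groups) {
  stopifnot(inherits(ord, "Ordination"))
  samples <- colnames(ord$table)
  if (!all(samples %in% names(groups)))
    ct_validation_error("every ordination column needs a group label")
  g <- factor(groups[samples])
  if (any(table(g) == 0))
    ct_validation_error("group with zero samples: '%s'",
                        names(which(table(g) == 0))[1])
  K <- nlevels(g)
  if (K < 2) ct_validation_error("between-group analysis needs >= 2 groups")
  cw <- ord$col_masses
  Q <- ord$Q
  w <- tapply(cw, g, sum)
  qbar <- sapply(levels(g), function(lv) {
    m <- g == lv
    Q[, m, drop = FALSE] %*% (cw[m] / sum(cw[m]))
  })
  rownames(qbar) <- rownames(Q)
  QBw <- sweep(qbar, 2, sqrt(w), "*")
  sv <- svd(QBw)
  eig <- sv$d^2
  keep <- which(eig > axis_tol * max(eig, 1))
  k <- as.integer(min(length(keep), K - 1))
  if (k < 1) k <- 1L
  for (a in seq_len(k)) {
    s <- fix_sign(sv$u[, a])
    sv$u[, a] <- s * sv$u[, a]
    sv$v[, a] <- s * sv$v[, a]
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  sample_scores <- crossprod(Q, U)
  centroids <- crossprod(qbar, U)
  rownames(sample_scores) <- samples
  rownames(centroids) <- levels(g)
  between <- sum(w * colSums(qbar^2))
  obj <- list(centroids = centroids, axes = U, eig = eig[seq_len(k)],
              sample_scores = sample_scores, groups = g,
              group_masses = w,
              between_inertia = between, total_inertia = ord$inertia,
              ratio = between / ord$inertia, n_axes = k)
  class(obj) <- "BGAResult"
  obj
}

#' Supervised co-inertia analysis of one pairwise comparison
#'
#' Restricts the expression table to the two compared groups, constrains its
#' ordination by between-group analysis (one discriminating axis for two
#' groups), and couples that constrained side with the motif-table
#' ordination. The single paired axis is oriented so the resistant group's
#' centroid has a positive coordinate: motif loadings with large positive
#' values point toward the resistant pole, and swapping the two group labels
#' negates every loading exactly.
#'
#' @param expr an `ExpressionMatrix` (non-negative intensity scale).
#' @param motif_ord `Ordination` of a gene-by-motif table over the same genes
#'   (same order).
#' @param comparison length-2 character vector `c(parental, resistant)`.
#' @param resistant which comparison label is the resistant pole (defaults to
#'   the second).
#' @return object of class `SupervisedCIA`: oriented motif loadings on the
#'   paired axis, group centroid coordinates, the singular value, and the
#'   underlying pieces.
#' @export
supervised_cia <- function(expr, motif_ord, comparison,
                           resistant = comparison[2]) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(motif_ord, "Ordination"))
  if (length(comparison) != 2 || !resistant %in% comparison)
    ct_validation_error("comparison must give two group labels including the resistant one")
  groups <- expr$group_of
  for (gl in comparison) {
    if (!any(groups == gl))
      ct_validation_error("comparison group missing from expression data: '%s'", gl)
  }
  if (!identical(expr$gene_ids, rownames(motif_ord$table)))
    ct_validation_error("expression and motif ordination must share gene ids and order")

  keep <- names(groups)[groups %in% comparison]
  sub <- expr$values[, keep, drop = FALSE]
  g <- factor(groups[keep], levels = comparison)

  # BGA-constrained expression side on the uniform gene metric: column
  # profiles minus 1/G, averaged within groups with the sub-table's column
  # masses, then weighted by the group masses.
  G <- nrow(sub)
  cs <- colSums(sub)
  if (any(cs == 0)) ct_validation_error("all-zero sample column in comparison subset")
  cw <- cs / sum(cs)
  Qu <- sweep(sub, 2, cs, "/") - 1 / G
  w <- tapply(cw, g, sum)
  qbar <- sapply(levels(g), function(lv) {
    m <- g == lv
    Qu[, m, drop = FALSE] %*% (cw[m] / sum(cw[m]))
  })
  qbar <- qbar - (qbar %*% w)[, 1]        # centre by the weighted grand mean
  Aw <- sweep(qbar, 2, sqrt(w), "*")      # G x 2, rank 1 after centring
  Bw <- uniform_rep(motif_ord)
  Z <- crossprod(Aw, Bw) / G              # 2 x M, rank 1
  sv <- svd(Z, nu = 2, nv = min(ncol(Bw), 2))
  d1 <- sv$d[1]
  u1 <- sv$u[, 1]
  v1 <- sv$v[, 1]
  # orient: resistant centroid positive on the discriminating axis
  names(u1) <- levels(g)
  if (u1[resistant] < 0) { u1 <- -u1; v1 <- -v1 }
  loadings <- stats::setNames(v1 * d1, colnames(motif_ord$table))
  gene_scores <- (Aw %*% u1)[, 1]
  obj <- list(comparison = comparison, resistant = resistant,
              motif_loadings = loadings,
              group_coords = u1 * d1,
              singular_value = d1,
              gene_scores = gene_scores,
              group_masses = w)
  class(obj) <- "SupervisedCIA"
  obj
}
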