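# NSCA, co-inertia, BGA and the supervised coupling: inertia conservation,
# RV identities, axis-count bounds, orientation conventions.

test_that("NSCA of an independence table has zero inertia", {
  r <- c(0.2, 0.3, 0.5)
  cw <- c(0.4, 0.6)
  x <- outer(r, cw) * 1000
  dimnames(x) <- list(paste0("g", 1:3), paste0("c", 1:2))
  ord <- nsca(x)
  expect_lt(ord$inertia, 1e-20)
  expect_true(all(ord$eig < 1e-20))
})

test_that("NSCA inertia matches the closed 2x2 formula and the eigenvalue sum", {
  x <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  ord <- nsca(x)
  expect_equal(ord$inertia, 0.5)
  expect_equal(sum(ord$eig), 0.5)
  # random small tables: sum of eigenvalues equals the direct double sum
  set.seed(21)
  for (i in 1:200) {
    nr <- sample(3:9, 1); nc <- sample(2:6, 1)
    y <- matrix(rpois(nr * nc, 2), nr, nc,
                dimnames = list(paste0("g", 1:nr), paste0("c", 1:nc)))
    zero <- colSums(y) == 0
    y[1, zero] <- 1
    o <- nsca(y, n_axes = 10)
    P <- y / sum(y); rm <- rowSums(P); cm <- colSums(P)
    direct <- sum(vapply(seq_len(nc), function(j)
      cm[j] * sum((P[, j] / cm[j] - rm)^2), numeric(1)))
    expect_equal(sum(o$eig), direct, tolerance = 1e-10)
  }
})

test_that("NSCA rejects degenerate inputs, naming the offender", {
  x <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("g1", "g2"), c("ok", "empty")))
  err <- expect_error(nsca(x), class = "cointf_validation_error")
  expect_match(conditionMessage(err), "empty")
  expect_error(nsca(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("c", "d")))),
               class = "cointf_validation_error")
  expect_error(nsca(matrix(c(-1, 2, 3, 4), 2, 2,
                           dimnames = list(c("a", "b"), c("c", "d")))),
               class = "cointf_validation_error")
})

test_that("coinertia: self-coupling RV is 1, permuting genes jointly is invariant", {
  cfg <- sim_config(n_genes = 80, n_motifs = 8, seed = 13)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  oA <- nsca(se$expr$values)
  oB <- nsca(tabs[[1]]$counts)
  ci <- coinertia(oA, oB)
  expect_equal(coinertia(oA, oA)$RV, 1)
  expect_gte(ci$RV, 0); expect_lte(ci$RV, 1)
  expect_equal(sum(ci$svals^2), ci$total_coinertia, tolerance = 1e-8)
  expect_true(all(diff(ci$svals) <= 1e-12))
  # joint row permutation leaves the coupling unchanged
  perm <- sample(nrow(se$expr$values))
  oA2 <- nsca(se$expr$values[perm, ])
  oB2 <- nsca(tabs[[1]]$counts[perm, ])
  ci2 <- coinertia(oA2, oB2)
  expect_equal(ci2$RV, ci$RV, tolerance = 1e-12)
  expect_equal(ci2$svals, ci$svals, tolerance = 1e-12)
  expect_equal(ci2$axes_B, ci$axes_B, tolerance = 1e-9)
  # row mismatch is rejected
  expect_error(coinertia(oA, oB2), class = "cointf_validation_error")
})

test_that("uncoupled tables give small RV with a non-significant permutation p", {
  cfg <- sim_config(n_genes = 50, n_motifs = 6, effect_size = 0, seed = 17)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  set.seed(99)
  shuffled <- tabs[[1]]$counts[sample(nrow(tabs[[1]]$counts)), ]
  rownames(shuffled) <- tabs[[1]]$gene_ids
  pt <- coinertia_perm_test(nsca(se$expr$values), nsca(shuffled), B = 199, seed = 5)
  expect_gt(pt$p.value, 0.05)
})

test_that("planted coupling beats its row-permutation null", {
  cfg <- sim_config(n_genes = 400, n_motifs = 30, effect_size = 2, seed = 23)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  pt <- coinertia_perm_test(nsca(se$expr$values), nsca(tabs[[1]]$counts),
                            B = 99, seed = 5)
  expect_lte(pt$p.value, 0.01)
  expect_gt(pt$RV, quantile(pt$perm, 0.99))
})

test_that("BGA yields at most K-1 axes and bounded between-inertia", {
  cfg <- sim_config(n_genes = 120, n_motifs = 10, seed = 31)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  ord <- nsca(se$expr$values)
  bg <- bga(ord, se$expr$group_of)           # K = 3
  expect_lte(bg$n_axes, 2)
  expect_lte(bg$between_inertia, bg$total_inertia + 1e-12)
  expect_gte(bg$ratio, 0); expect_lte(bg$ratio, 1)
  # K = 2: exactly one axis
  keep <- names(se$expr$group_of)[se$expr$group_of %in% c("Ag", "D8")]
  sub <- expression_matrix(se$expr$values[, keep], se$expr$group_of)
  bg2 <- bga(nsca(sub$values), sub$group_of)
  expect_identical(bg2$n_axes, 1L)
  expect_error(bga(ord, stats::setNames(rep("one", 12), colnames(ord$table))),
               class = "cointf_validation_error")
})

test_that("BGA between-inertia ratio sits at chance level when groups share a mean", {
  # under exchangeable samples the between/total ratio concentrates at
  # (K-1)/(n_samples-1); bound frozen from a 40-replicate null run
  # (mean 0.1818, sd 0.0053)
  set.seed(41)
  n <- 1000
  m <- matrix(2^rnorm(n * 12, 7, 1), n, 12,
              dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:12)))
  g <- stats::setNames(rep(c("A", "B", "C"), each = 4), colnames(m))
  bg <- bga(nsca(m), g)
  expect_lt(abs(bg$ratio - 2 / 11), 0.022)
})

test_that("BGA separates groups with distinct planted means", {
  cfg <- sim_config(n_genes = 300, n_motifs = 20, effect_size = 2, seed = 37)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  bg <- bga(nsca(se$expr$values), se$expr$group_of)
  sc <- bg$sample_scores[, 1:min(2, ncol(bg$sample_scores)), drop = FALSE]
  g <- as.character(se$expr$group_of[rownames(sc)])
  resist <- g %in% c("D8", "D12")
  # silhouette-style check on axis 1: within-class spread below between-class gap
  d1 <- sc[, 1]
  expect_gt(abs(mean(d1[resist]) - mean(d1[!resist])),
            max(sd(d1[resist]), sd(d1[!resist])))
})

test_that("supervised coupling orients to the resistant pole and is antisymmetric", {
  cfg <- sim_config(n_genes = 200, n_motifs = 15, seed = 43)
  tabs <- simulate_motif_tables(cfg)
  se <- simulate_expression(cfg, tabs[[1]])
  mo <- nsca(tabs[[4]]$counts)
  s1 <- supervised_cia(se$expr, mo, c("Ag", "D8"))
  expect_gt(s1$group_coords["D8"], 0)
  s2 <- supervised_cia(se$expr, mo, c("D8", "Ag"), resistant = "Ag")
  expect_equal(s2$motif_loadings, -s1$motif_loadings, tolerance = 1e-12)
  # a motif constant across genes has exactly zero loading
  cc <- tabs[[4]]$counts
  cc[, 3] <- 2
  s3 <- supervised_cia(se$expr, nsca(cc), c("Ag", "D8"))
  expect_lt(abs(s3$motif_loadings[3]), 1e-12)
  expect_error(supervised_cia(se$expr, mo, c("Ag", "DX")),
               class = "cointf_validation_error")
})

test_that("planted active motifs load in the top decile of |loading|", {
  top_decile <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = s)
    tabs <- simulate_motif_tables(cfg)
    se <- simulate_expression(cfg, tabs[[1]])
    sc <- supervised_cia(quantile_normalize(se$expr), nsca(tabs[[1]]$counts),
                         c("Ag", "D8"))
    cut <- quantile(abs(sc$motif_loadings), 0.9)
    top_decile <- top_decile +
      all(abs(sc$motif_loadings[se$truth$active_motifs]) >= cut)
  }
  expect_gte(top_decile, 9)
})
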