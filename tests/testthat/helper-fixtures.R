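# Shared fixtures, all built in code.

# tiny expression matrix with two groups of two samples
tiny_expr <- function(values = NULL) {
  if (is.null(values))
    values <- matrix(c(1, 2, 3, 1, 2, 3, 3, 5, 7, 3, 5, 9), nrow = 3,
                     dimnames = list(c("g1", "g2", "g3"),
                                     c("A_1", "A_2", "B_1", "B_2")))
  expression_matrix(values, c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B"))
}

# a ranked motif list from explicit ranks
mk_ranked <- function(ranks, motifs = letters[seq_along(ranks)]) {
  df <- data.frame(motif = motifs, loading = max(ranks) - ranks, rank = ranks,
                   stringsAsFactors = FALSE)
  class(df) <- c("RankedMotifList", "data.frame")
  df
}

# cohort of docetaxel-treated patients realising given site counts:
# n high-scoring (2) and low-scoring (1) bone and soft-tissue sites spread
# round-robin over n_patients; survival columns are inert placeholders.
cohort_from_site_counts <- function(bone_pos, bone_neg, soft_pos, soft_neg,
                                    n_patients = 23) {
  score <- c(rep(2, bone_pos), rep(1, bone_neg), rep(2, soft_pos), rep(1, soft_neg))
  type <- c(rep("bone", bone_pos + bone_neg), rep("soft", soft_pos + soft_neg))
  n <- length(score)
  pid <- sprintf("P%02d", rep_len(seq_len(n_patients), n))
  sites <- data.frame(patient_id = pid,
                      site_id = sprintf("s%03d", seq_len(n)),
                      site_type = type, ihc_score = score, usable = TRUE,
                      stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                         docetaxel_treated = TRUE,
                         time_diagnosis = seq_len(n_patients),
                         event_diagnosis = TRUE,
                         stringsAsFactors = FALSE)
  clinical_table(sites, patients)
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * sp[i] / i)
    adj[i] <- running
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact rank-product null probability P(RP <= x) for ranks iid uniform 1..M
rp_exact_p <- function(x, M, T) {
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(M)), T)))
  mean(exp(rowMeans(log(grid))) <= x + 1e-12)
}

# all permutations of a small vector
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}
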