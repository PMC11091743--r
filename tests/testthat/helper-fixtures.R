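# Shared fixtures, generated in code.

# tiny deterministic count matrix with two clear groups
tiny_cm <- function(n_per = 5, seed = 7) {
  set.seed(seed)
  a <- matrix(rpois(n_per * 6, lambda = rep(c(20, 20, 20, 1, 1, 1),
                                            each = n_per)), n_per, 6)
  b <- matrix(rpois(n_per * 6, lambda = rep(c(1, 1, 1, 20, 20, 20),
                                            each = n_per)), n_per, 6)
  count_matrix(rbind(a, b),
               cell_ids = sprintf("c%02d", seq_len(2 * n_per)),
               gene_ids = sprintf("g%d", 1:6),
               labels = rep(c("A", "B"), each = n_per))
}

# the splat1-like reduced simulation used by the training tests:
# 500 cells x 500 genes, 4 imbalanced groups, strong DE, library size
# scaled to the 500-gene panel
small_sim <- function(seed = 101) {
  simulate_splat(splat_params(n_cells = 500, n_genes = 500,
                              group_prob = c(0.05, 0.1, 0.2, 0.65),
                              de_fac_loc = 1.0, lib_loc = 8, seed = seed))
}

# two well-separated 2-D Gaussian blobs (n = 200, sd = 0.1, centers 4 apart)
blob_data <- function(seed = 0) {
  set.seed(seed)
  z <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
             matrix(rnorm(200, 4, 0.1), 100, 2))
  list(z = z, truth = rep(1:2, each = 100))
}

# brute-force clustering accuracy by enumerating all one-to-one matchings
acc_brute <- function(truth, pred) {
  ct <- table(as.character(truth), as.character(pred))
  r <- nrow(ct); c <- ncol(ct)
  k <- max(r, c)
  sq <- matrix(0, k, k)
  sq[seq_len(r), seq_len(c)] <- ct
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, sum(sq[cbind(seq_len(k), p)]))
  best / sum(ct)
}
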