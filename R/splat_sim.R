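#' Parameters for the splat-style count simulator
#'
#' A simplified splat-type generative model for group-structured scRNA-seq
#' counts: gamma-distributed gene base means, per-group log-normal
#' differential-expression factors, log-normal library sizes, negative
#' binomial counts, and a logistic mean-dependent dropout curve. Single batch,
#' groups mode only.
#'
#' @param n_cells,n_genes dimensions of the simulated matrix.
#' @param group_prob probability vector over groups (sums to 1).
#' @param mean_shape,mean_rate gamma parameters for gene base means.
#' @param lib_loc,lib_scale log-normal parameters for library sizes.
#' @param de_prob fraction of genes differentially expressed per group.
#' @param de_fac_loc,de_fac_scale log-normal parameters for DE factors; a DE
#'   gene gets factor \code{exp(rnorm(loc, scale))}, inverted with probability
#'   1/2 (down-regulation).
#' @param bcv biological coefficient of variation; NB dispersion size =
#'   \code{1/bcv^2}.
#' @param dropout_mid,dropout_shape logistic dropout: an entry with expected
#'   count \code{m} is zeroed with probability
#'   \code{plogis(dropout_shape * (dropout_mid - log1p(m)))}.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return a validated list of class \code{SimParams}.
#' @export
splat_params <- function(n_cells, n_genes, group_prob,
                         mean_shape = 0.6, mean_rate = 0.3,
                         lib_loc = 11, lib_scale = 0.2,
                         de_prob = 0.1, de_fac_loc = 0.1, de_fac_scale = 0.4,
                         bcv = 0.2, dropout_mid = 1.0, dropout_shape = 1.0,
                         seed = 0) {
  p <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
            group_prob = as.numeric(group_prob),
            mean_shape = mean_shape, mean_rate = mean_rate,
            lib_loc = lib_loc, lib_scale = lib_scale,
            de_prob = de_prob, de_fac_loc = de_fac_loc,
            de_fac_scale = de_fac_scale, bcv = bcv,
            dropout_mid = dropout_mid, dropout_shape = dropout_shape,
            seed = as.integer(seed))
  if (p$n_cells < 1 || p$n_genes < 1) stop("n_cells and n_genes must be >= 1")
  if (any(p$group_prob < 0)) stop("group_prob entries must be >= 0")
  if (abs(sum(p$group_prob) - 1) > 1e-9)
    stop("group_prob must sum to 1 (got ", sum(p$group_prob), ")")
  if (p$de_prob < 0 || p$de_prob > 1) stop("de_prob must be in [0, 1]")
  if (p$bcv <= 0) stop("bcv must be > 0")
  structure(p, class = "SimParams")
}

#' Preset simulation configurations
#'
#' Named presets splat1..splat5 covering 4, 6, and 10 groups at 2000-10000
#' cells and 10000 genes, with imbalanced group probabilities down to 2%.
#' Parameters not fixed by the preset take the documented
#' \code{\link{splat_params}} defaults.
#'
#' @param name one of \code{"splat1"} .. \code{"splat5"}.
#' @param ... overrides passed on to \code{\link{splat_params}}.
#' @return a \code{SimParams}.
#' @export
splat_preset <- function(name, ...) {
  presets <- list(
    splat1 = list(n_genes = 10000L, n_cells = 2000L,
                  group_prob = c(0.05, 0.1, 0.2, 0.65)),
    splat2 = list(n_genes = 10000L, n_cells = 5000L,
                  group_prob = c(0.05, 0.1, 0.2, 0.65)),
    splat3 = list(n_genes = 10000L, n_cells = 10000L,
                  group_prob = c(0.05, 0.1, 0.2, 0.65)),
    splat4 = list(n_genes = 10000L, n_cells = 2000L,
                  group_prob = c(0.02, 0.03, 0.2, 0.65, 0.03, 0.07)),
    splat5 = list(n_genes = 10000L, n_cells = 2000L,
                  group_prob = c(0.02, 0.02, 0.03, 0.05, 0.08,
                                 0.1, 0.1, 0.15, 0.15, 0.3)))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(splat_params, args)
}

#' Simulate a group-structured count matrix
#'
#' @param params a \code{\link{splat_params}} object.
#' @return a \code{\link{count_matrix}} with true group labels attached
#'   (\code{"Group1"} .. \code{"GroupK"}) and, as attribute
#'   \code{"group_means"}, the genes x groups matrix of normalized group mean
#'   profiles used.
#' @export
simulate_splat <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  n <- params$n_cells
  g <- params$n_genes
  K <- length(params$group_prob)

  base_means <- stats::rgamma(g, shape = params$mean_shape,
                              rate = params$mean_rate)
  base_means[base_means < 1e-10] <- 1e-10

  # per-group multiplicative DE factors; reciprocal with prob 1/2 (down-reg)
  group_means <- matrix(base_means, nrow = g, ncol = K)
  for (k in seq_len(K)) {
    is_de <- stats::runif(g) < params$de_prob
    fac <- exp(stats::rnorm(g, params$de_fac_loc, params$de_fac_scale))
    flip <- stats::runif(g) < 0.5
    fac[flip] <- 1 / fac[flip]
    fac[!is_de] <- 1
    group_means[, k] <- base_means * fac
  }
  # normalize each group profile so library size sets the expected total
  profile <- sweep(group_means, 2, colSums(group_means), "/")

  groups <- sample.int(K, n, replace = TRUE, prob = params$group_prob)
  lib <- stats::rlnorm(n, meanlog = params$lib_loc, sdlog = params$lib_scale)

  # expected count per entry: lib_i * profile[j, group_i]
  lambda <- t(profile[, groups, drop = FALSE]) * lib  # n x g
  size <- 1 / params$bcv^2
  counts <- matrix(stats::rnbinom(n * g, mu = as.vector(lambda), size = size),
                   nrow = n, ncol = g)

  p_drop <- stats::plogis(params$dropout_shape *
                            (params$dropout_mid - log1p(lambda)))
  dropped <- matrix(stats::runif(n * g) < as.vector(p_drop), nrow = n)
  counts[dropped] <- 0

  cm <- count_matrix(counts,
                     cell_ids = sprintf("cell%d", seq_len(n)),
                     gene_ids = sprintf("gene%d", seq_len(g)),
                     labels = paste0("Group", groups))
  attr(cm, "group_means") <- profile
  cm
}
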