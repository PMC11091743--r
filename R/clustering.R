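# Latent-space deep-clustering machinery: weighted soft K-means with a
# Gaussian kernel and annealed temperature, Student's-t soft assignments (Q),
# the DEC squared-frequency target distribution (P), and the KL clustering
# loss. Gradient helpers back-propagate any dL/dQ to the latent points and
# the cluster centers.

sqdist <- function(z, centers) {
  # cells x K matrix of squared Euclidean distances
  d2 <- outer(rowSums(z^2), rowSums(centers^2), "+") - 2 * tcrossprod(z, centers)
  pmax(d2, 0)
}

#' Initialize cluster centers in the latent space
#'
#' K-means with a fixed seed; when labeled cells are supplied, each labeled
#' class's latent centroid replaces its nearest unsupervised center (greedy
#' one-to-one by distance), anchoring cluster indices to classes.
#'
#' @param z cells x d latent matrix.
#' @param K number of clusters (>= 2, <= number of cells).
#' @param seed RNG seed for the K-means initialization.
#' @param labeled optional list with \code{idx} (cell indices) and
#'   \code{labels} (class per labeled cell).
#' @return K x d matrix of centers.
#' @export
init_centers <- function(z, K, seed = 0, labeled = NULL) {
  if (K > nrow(z)) stop("K (", K, ") exceeds number of cells (", nrow(z), ")")
  set.seed(seed)
  km <- stats::kmeans(z, centers = K, nstart = 10, iter.max = 100)
  centers <- km$centers
  if (!is.null(labeled) && length(labeled$idx) > 0) {
    labs <- as.character(labeled$labels)
    classes <- unique(labs)
    centroids <- t(vapply(classes, function(cl) {
      colMeans(z[labeled$idx[labs == cl], , drop = FALSE])
    }, numeric(ncol(z))))
    # greedy one-to-one: closest (class centroid, center) pair first
    d <- sqdist(centroids, centers)
    taken_class <- rep(FALSE, nrow(centroids))
    taken_center <- rep(FALSE, K)
    for (s in seq_len(min(nrow(centroids), K))) {
      d_masked <- d
      d_masked[taken_class, ] <- Inf
      d_masked[, taken_center] <- Inf
      ij <- arrayInd(which.min(d_masked), dim(d))
      centers[ij[2], ] <- centroids[ij[1], ]
      taken_class[ij[1]] <- TRUE
      taken_center[ij[2]] <- TRUE
    }
  }
  unname(centers)
}

#' Weighted soft K-means loss
#'
#' Gaussian-kernel weights \code{omega_ij = exp(-||z_i - phi_j||^2 /
#' temperature)} normalized over clusters; the loss is the weight-averaged
#' squared distance, mean over cells. Shrinking the temperature (annealing)
#' sharpens the weights toward hard K-means.
#'
#' @param z cells x d latent matrix.
#' @param centers K x d centers.
#' @param temperature positive kernel bandwidth.
#' @return list with \code{loss} and the row-stochastic weight matrix
#'   \code{omega} (treated as constant within a gradient step).
#' @export
soft_kmeans_loss <- function(z, centers, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  d2 <- sqdist(z, centers)
  lw <- -d2 / temperature
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  omega <- w / rowSums(w)
  list(loss = sum(omega * d2) / nrow(z), omega = omega)
}

# gradient of soft_kmeans_loss w.r.t. z and centers (omega held constant)
soft_kmeans_grad <- function(z, centers, omega) {
  n <- nrow(z)
  # dL/dz_i = (2/n) sum_j omega_ij (z_i - phi_j)
  dz <- 2 / n * (z * rowSums(omega) - omega %*% centers)
  dcenters <- 2 / n * (colSums(omega) * centers - crossprod(omega, z))
  list(dz = dz, dcenters = dcenters)
}

#' Student's-t soft assignment
#'
#' \code{q_ij = (1 + ||z_i - phi_j||^2)^-1}, normalized per cell (one degree
#' of freedom).
#'
#' @inheritParams soft_kmeans_loss
#' @return cells x K row-stochastic matrix Q.
#' @export
soft_assign <- function(z, centers) {
  u <- 1 / (1 + sqdist(z, centers))
  u / rowSums(u)
}

# backprop dL/dQ to (dz, dcenters) through the Student's-t kernel
soft_assign_grad <- function(z, centers, dQ) {
  d2 <- sqdist(z, centers)
  u <- 1 / (1 + d2)
  s <- rowSums(u)
  q <- u / s
  # dL/du_ij = (dQ_ij - sum_j' dQ_ij' q_ij') / s_i ; du/dd2 = -u^2
  dU <- (dQ - rowSums(dQ * q)) / s
  dd2 <- -dU * u^2
  dz <- 2 * (z * rowSums(dd2) - dd2 %*% centers)
  dcenters <- 2 * (colSums(dd2) * centers - crossprod(dd2, z))
  list(dz = dz, dcenters = dcenters)
}

#' DEC target distribution
#'
#' \code{p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')} with cluster
#' frequencies \code{f_j = sum_i q_ij}; sharpens confident assignments while
#' normalizing away cluster-size bias.
#'
#' @param Q cells x K row-stochastic soft assignments.
#' @return cells x K row-stochastic target matrix P.
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  if (any(f == 0)) stop("empty cluster (zero soft frequency) at column(s) ",
                        paste(which(f == 0), collapse = ", "))
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' KL clustering loss
#'
#' Mean over cells of \code{KL(p_i || q_i)}; P is treated as a constant
#' target between refreshes.
#'
#' @param P,Q cells x K row-stochastic matrices (clipped at 1e-12).
#' @return nonnegative scalar.
#' @export
kl_loss <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("P and Q shapes differ")
  P <- pmax(P, 1e-12)
  Q <- pmax(Q, 1e-12)
  sum(P * (log(P) - log(Q))) / nrow(P)
}

# dL/dQ for kl_loss (mean over cells)
kl_loss_qgrad <- function(P, Q) {
  -pmax(P, 1e-12) / pmax(Q, 1e-12) / nrow(P)
}

#' Combined deep-clustering loss
#'
#' \code{L_DC = L_SoftK + L_KL} with Q recomputed from the current latent
#' points and centers.
#'
#' @inheritParams soft_kmeans_loss
#' @param P target distribution (held fixed).
#' @return scalar loss.
#' @export
deep_cluster_loss <- function(z, centers, temperature, P) {
  skm <- soft_kmeans_loss(z, centers, temperature)
  Q <- soft_assign(z, centers)
  skm$loss + kl_loss(P, Q)
}

#' Optimize the deep-clustering loss on fixed-dimension points
#'
#' Gradient refinement of latent points and centers under L_DC alone (no
#' autoencoder), using AdaDelta. Useful for low-dimensional toy problems and
#' as a building block sanity check; P is refreshed every step.
#'
#' @param z starting points (n x d), treated as free parameters.
#' @param K number of clusters.
#' @param steps gradient steps.
#' @param temperature0,decay,floor geometric temperature annealing.
#' @param seed seed for center initialization.
#' @return list with final \code{z}, \code{centers}, \code{Q},
#'   \code{hard_labels}, \code{loss_history}.
#' @export
optimize_deep_cluster <- function(z, K, steps = 50, temperature0 = 1,
                                  decay = 0.95, floor = 0.1, seed = 0) {
  z <- as.matrix(z)
  centers <- init_centers(z, K, seed = seed)
  params <- list(z = z, centers = centers)
  opt <- adadelta_new(params)
  temp <- temperature0
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    Q <- soft_assign(params$z, params$centers)
    P <- target_distribution(Q)
    skm <- soft_kmeans_loss(params$z, params$centers, temp)
    hist[s] <- skm$loss + kl_loss(P, Q)
    gs <- soft_kmeans_grad(params$z, params$centers, skm$omega)
    ga <- soft_assign_grad(params$z, params$centers, kl_loss_qgrad(P, Q))
    grads <- list(z = gs$dz + ga$dz, centers = gs$dcenters + ga$dcenters)
    st <- adadelta_step(opt, params, grads)
    params <- st$params; opt <- st$opt
    temp <- max(floor, temp * decay)
  }
  Q <- soft_assign(params$z, params$centers)
  list(z = params$z, centers = params$centers, Q = Q,
       hard_labels = max.col(Q), loss_history = hist)
}
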