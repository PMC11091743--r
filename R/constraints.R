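# Semisupervised machinery: stratified labeled-cell masking, triplet sampling
# and hinge loss on soft-assignment similarities, must-link/cannot-link
# pairwise loss on cosine similarities, and class-imbalance weighted
# cross-entropy routed through a cluster-to-class alignment.

#' Stratified labeled-cell mask
#'
#' Samples ceil(r * n_c) cells from every class c (at least one per class
#' when r > 0), so rare types keep representation in the labeled set.
#'
#' @param labels all-cell labels.
#' @param r labeled fraction in [0, 1] (default 0.10).
#' @param seed RNG seed.
#' @return integer vector of labeled cell indices (sorted).
#' @export
make_labeled_mask <- function(labels, r = 0.10, seed = 0) {
  if (r < 0 || r > 1) stop("labeled fraction r must be in [0, 1]")
  if (r == 0) return(integer(0))
  set.seed(seed)
  labels <- as.character(labels)
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    k <- max(1L, ceiling(r * length(ix)))
    if (k >= length(ix)) ix else sample(ix, k)
  }), use.names = FALSE)
  sort(idx)
}

#' Sample (anchor, positive, negative) triplets from labeled cells
#'
#' Anchors are uniform over labeled cells whose class has at least two
#' members; positives uniform over same-class other cells; negatives uniform
#' over labeled cells of any other class. Sampled once per run.
#'
#' @param labeled_idx labeled cell indices.
#' @param labels labels for the labeled cells (same length/order as
#'   \code{labeled_idx}).
#' @param n_triplets number of triplets (default 10000).
#' @param seed RNG seed.
#' @return n_triplets x 3 integer matrix of cell indices (columns anchor,
#'   positive, negative).
#' @export
sample_triplets <- function(labeled_idx, labels, n_triplets = 10000,
                            seed = 0) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(labeled_idx))
  if (length(unique(labels)) < 2)
    stop("triplet sampling needs at least 2 labeled classes ",
         "(no valid negatives otherwise)")
  by_class <- split(seq_along(labeled_idx), labels)
  eligible <- names(by_class)[lengths(by_class) >= 2]
  if (length(eligible) == 0)
    stop("no class has >= 2 labeled members; cannot form positives")
  set.seed(seed)
  anchor_pool <- unlist(by_class[eligible], use.names = FALSE)
  A <- sample(anchor_pool, n_triplets, replace = TRUE)
  P <- vapply(A, function(a) {
    peers <- by_class[[labels[a]]]
    peers <- peers[peers != a]
    peers[sample.int(length(peers), 1)]
  }, integer(1))
  N <- vapply(A, function(a) {
    others <- which(labels != labels[a])
    others[sample.int(length(others), 1)]
  }, integer(1))
  cbind(anchor = labeled_idx[A], positive = labeled_idx[P],
        negative = labeled_idx[N])
}

#' Triplet hinge loss on soft assignments
#'
#' With similarity \code{s(a, b) = sum_j q_aj q_bj} (dot product of
#' assignment rows), the default \code{form = "corrected"} hinge is
#' \code{max(s(A,N) - s(A,P) + margin, 0)}: it drives the anchor-positive
#' similarity above the anchor-negative similarity by the margin.
#' \code{form = "literal"} applies the hinge with the opposite sign,
#' \code{max(s(A,P) - s(A,N) + margin, 0)}, treating the dot product as if it
#' were a distance; it is provided for comparison only.
#'
#' @param Q cells x K row-stochastic soft assignments (all cells).
#' @param triplets matrix from \code{\link{sample_triplets}}.
#' @param margin hinge margin alpha (default 0.1).
#' @param form \code{"corrected"} (default) or \code{"literal"}.
#' @return mean hinge over triplets (nonnegative).
#' @export
triplet_loss <- function(Q, triplets, margin = 0.1,
                         form = c("corrected", "literal")) {
  triplet_loss_grad(Q, triplets, margin, form, want_grad = FALSE)$loss
}

triplet_loss_grad <- function(Q, triplets, margin = 0.1,
                              form = c("corrected", "literal"),
                              want_grad = TRUE) {
  form <- match.arg(form)
  if (is.null(triplets) || nrow(triplets) == 0) {
    warning("empty triplet list; triplet loss is 0")
    return(list(loss = 0, dQ = if (want_grad) Q * 0 else NULL))
  }
  qa <- Q[triplets[, 1], , drop = FALSE]
  qp <- Q[triplets[, 2], , drop = FALSE]
  qn <- Q[triplets[, 3], , drop = FALSE]
  s_ap <- rowSums(qa * qp)
  s_an <- rowSums(qa * qn)
  h <- if (form == "corrected") s_an - s_ap + margin else s_ap - s_an + margin
  active <- h > 0
  loss <- sum(h[active]) / nrow(triplets)
  if (!want_grad) return(list(loss = loss, dQ = NULL))
  dQ <- Q * 0
  if (any(active)) {
    sgn <- if (form == "corrected") 1 else -1
    w <- sgn / nrow(triplets)
    ia <- triplets[active, 1]; ip <- triplets[active, 2]
    in_ <- triplets[active, 3]
    # d h / d qa = qn - qp ; d h / d qn = qa ; d h / d qp = -qa  (corrected)
    add_rows <- function(dQ, rows, vals) {
      for (k in seq_along(rows)) dQ[rows[k], ] <- dQ[rows[k], ] + vals[k, ]
      dQ
    }
    dQ <- add_rows(dQ, ia, w * (qn[active, , drop = FALSE] -
                                  qp[active, , drop = FALSE]))
    dQ <- add_rows(dQ, in_, w * qa[active, , drop = FALSE])
    dQ <- add_rows(dQ, ip, -w * qa[active, , drop = FALSE])
  }
  list(loss = loss, dQ = dQ)
}

#' Cosine similarity between assignment rows
#'
#' @param Q_labeled labeled-cells x K matrix of assignment probabilities
#'   (rows must be nonzero).
#' @return symmetric matrix S with unit diagonal; entries in [0, 1] for
#'   nonnegative rows.
#' @export
pairwise_similarity <- function(Q_labeled) {
  nrm <- sqrt(rowSums(Q_labeled^2))
  if (any(nrm == 0)) stop("zero assignment row(s): ",
                          paste(which(nrm == 0), collapse = ", "))
  S <- tcrossprod(Q_labeled / nrm)
  diag(S) <- 1
  pmin(pmax(S, 0), 1)
}

#' Build the must-link/cannot-link label matrix
#'
#' @param labels labels of the labeled cells.
#' @return binary symmetric matrix with unit diagonal; \code{Y_ij = 1} iff
#'   the labels agree.
#' @export
pairwise_label_matrix <- function(labels) {
  labels <- as.character(labels)
  outer(labels, labels, "==") * 1
}

#' Pairwise must-link/cannot-link loss
#'
#' Mean binary cross-entropy between the label matrix Y and the cosine
#' similarity S over off-diagonal labeled pairs; S is clipped to
#' (1e-12, 1 - 1e-12).
#'
#' @param S similarity matrix from \code{\link{pairwise_similarity}}.
#' @param Y label matrix from \code{\link{pairwise_label_matrix}}.
#' @return nonnegative scalar.
#' @export
pairwise_loss <- function(S, Y) {
  if (!all(dim(S) == dim(Y))) stop("S and Y shapes differ")
  n <- nrow(S)
  if (n < 2) return(0)
  off <- !diag(n)
  Sc <- pmin(pmax(S[off], 1e-12), 1 - 1e-12)
  Yv <- Y[off]
  -mean(Yv * log(Sc) + (1 - Yv) * log(1 - Sc))
}

# pairwise BCE loss and its gradient w.r.t. the labeled Q rows
pairwise_loss_grad <- function(Q_labeled, Y) {
  n <- nrow(Q_labeled)
  nrm <- sqrt(rowSums(Q_labeled^2))
  R <- Q_labeled / nrm
  S <- tcrossprod(R)
  diag(S) <- 1
  off <- !diag(n)
  Sc <- pmin(pmax(S, 1e-12), 1 - 1e-12)
  m <- sum(off)
  loss <- -sum((Y * log(Sc) + (1 - Y) * log(1 - Sc))[off]) / m
  # dL/dS on off-diagonal, zero where the clip is active
  dS <- matrix(0, n, n)
  inr <- off & (S > 1e-12) & (S < 1 - 1e-12)
  dS[inr] <- (-Y[inr] / Sc[inr] + (1 - Y[inr]) / (1 - Sc[inr])) / m
  # S = R R^T with R = row-normalized Q; dL/dR = (dS + dS^T)/.. rows
  dR <- dS %*% R + t(dS) %*% R
  diag_term <- rowSums(dR * R)
  dQ <- (dR - R * diag_term) / nrm
  list(loss = loss, dQ = dQ)
}

#' Align clusters to classes by maximum agreement
#'
#' Builds the class x cluster contingency of hard assignments over labeled
#' cells and solves the one-to-one maximum-agreement assignment.
#'
#' @param Q_labeled labeled-cells x K soft assignments.
#' @param labels labels of the labeled cells.
#' @return list of class \code{ClusterClassMap}: \code{classes} (names),
#'   \code{cluster} (integer cluster per class), \code{agreement} (matched
#'   count).
#' @export
align_clusters <- function(Q_labeled, labels) {
  labels <- factor(labels)
  hard <- max.col(Q_labeled)
  K <- ncol(Q_labeled)
  ct <- matrix(0, nlevels(labels), K,
               dimnames = list(levels(labels), NULL))
  for (i in seq_along(hard))
    ct[as.integer(labels[i]), hard[i]] <- ct[as.integer(labels[i]), hard[i]] + 1
  assign <- solve_assignment(ct, maximize = TRUE)
  structure(list(classes = levels(labels),
                 cluster = as.integer(assign),
                 agreement = attr(assign, "cost")),
            class = "ClusterClassMap")
}

#' Inverse-frequency class weights
#'
#' \code{w_j = n_r / (K_t * n_j)}: rare classes get proportionally larger
#' weights, and the frequency-weighted mean of the weights is 1.
#'
#' @param labels_labeled labels of the labeled cells.
#' @return named numeric vector of positive weights, one per class.
#' @export
class_weights <- function(labels_labeled) {
  labels_labeled <- as.character(labels_labeled)
  n_j <- table(labels_labeled)
  if (any(n_j == 0)) stop("empty class")
  n_r <- length(labels_labeled)
  w <- n_r / (length(n_j) * as.numeric(n_j))
  names(w) <- names(n_j)
  w
}

#' Class-weighted cross-entropy over labeled cells
#'
#' Each labeled cell's predicted class probability is its soft-assignment
#' mass on the cluster its class maps to, renormalized over the mapped
#' clusters; the loss is the weight-scaled mean negative log of that
#' probability.
#'
#' @param Q_labeled labeled-cells x K soft assignments.
#' @param labels labels of the labeled cells.
#' @param mapping a \code{\link{align_clusters}} result.
#' @param weights class weights from \code{\link{class_weights}}.
#' @return nonnegative scalar.
#' @export
weighted_ce_loss <- function(Q_labeled, labels, mapping, weights) {
  weighted_ce_grad(Q_labeled, labels, mapping, weights,
                   want_grad = FALSE)$loss
}

weighted_ce_grad <- function(Q_labeled, labels, mapping, weights,
                             want_grad = TRUE) {
  labels <- as.character(labels)
  cls <- match(labels, mapping$classes)
  if (anyNA(cls))
    stop("unmapped class(es): ",
         paste(unique(labels[is.na(cls)]), collapse = ", "))
  if (!all(labels %in% names(weights))) stop("missing class weight")
  mapped <- mapping$cluster            # cluster per class
  cols <- mapped[!is.na(mapped)]
  n_r <- nrow(Q_labeled)
  qm <- Q_labeled[, cols, drop = FALSE]       # mass on mapped clusters
  r <- rowSums(qm)
  own_col <- mapped[cls]                      # cluster of each cell's class
  q_own <- Q_labeled[cbind(seq_len(n_r), own_col)]
  p <- pmax(q_own / r, 1e-12)
  w <- as.numeric(weights[labels])
  loss <- sum(w * -log(p)) / n_r
  if (!want_grad) return(list(loss = loss, dQ = NULL))
  # -log p = -log q_own + log r ; d/dq_j = -1/q_own [j = own] + 1/r [j mapped]
  dQ <- Q_labeled * 0
  scale <- w / n_r
  dQ[, cols] <- dQ[, cols, drop = FALSE] + scale / r
  ix <- cbind(seq_len(n_r), own_col)
  dQ[ix] <- dQ[ix] - scale / pmax(q_own, 1e-12)
  list(loss = loss, dQ = dQ)
}

#' Bundle the semisupervised constraint set
#'
#' Convenience constructor: stratified labeled mask, triplets, pairwise label
#' matrix, and class weights from a full label vector.
#'
#' @param labels all-cell labels.
#' @param labeled_fraction fraction r of cells whose labels are treated as
#'   known (default 0.10).
#' @param n_triplets number of triplets (default 10000).
#' @param margin triplet margin alpha (default 0.1).
#' @param seed RNG seed for mask and triplet sampling.
#' @param triplet_form \code{"corrected"} or \code{"literal"} (see
#'   \code{\link{triplet_loss}}).
#' @return list of class \code{ConstraintSet} with \code{labeled_idx},
#'   \code{labels} (labeled cells, in \code{labeled_idx} order),
#'   \code{triplets}, \code{Y}, \code{class_weights}, \code{margin},
#'   \code{triplet_form}; or an empty set when \code{labeled_fraction = 0}.
#' @export
constraint_set <- function(labels, labeled_fraction = 0.10,
                           n_triplets = 10000, margin = 0.1, seed = 0,
                           triplet_form = c("corrected", "literal")) {
  triplet_form <- match.arg(triplet_form)
  idx <- make_labeled_mask(labels, labeled_fraction, seed)
  if (length(idx) == 0) {
    return(structure(list(labeled_idx = integer(0), labels = character(0),
                          triplets = NULL, Y = NULL, class_weights = NULL,
                          margin = margin, triplet_form = triplet_form),
                     class = "ConstraintSet"))
  }
  labs <- as.character(labels)[idx]
  triplets <- if (length(unique(labs)) >= 2 && n_triplets > 0)
    sample_triplets(idx, labs, n_triplets, seed) else NULL
  structure(list(labeled_idx = idx, labels = labs, triplets = triplets,
                 Y = pairwise_label_matrix(labs),
                 class_weights = class_weights(labs),
                 margin = margin, triplet_form = triplet_form),
            class = "ConstraintSet")
}
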