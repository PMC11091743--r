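test_that("labeled mask is stratified, bounded, and reproducible", {
  labels <- rep(c("big", "small"), c(900, 100))
  idx <- make_labeled_mask(labels, 0.1, seed = 1)
  expect_length(idx, 100)
  expect_equal(sum(labels[idx] == "big"), 90)
  expect_equal(sum(labels[idx] == "small"), 10)
  expect_identical(idx, make_labeled_mask(labels, 0.1, seed = 1))
  expect_length(make_labeled_mask(labels, 0), 0)
  expect_length(make_labeled_mask(labels, 1), 1000)
  # rare class keeps at least one representative
  rare <- rep(c("a", "b"), c(999, 1))
  expect_true(1000 %in% make_labeled_mask(rare, 0.01, seed = 2) ||
                any(rare[make_labeled_mask(rare, 0.01, seed = 2)] == "b"))
  expect_error(make_labeled_mask(labels, 1.2), "\\[0, 1\\]")
})

test_that("triplets respect the anchor/positive/negative contract", {
  labs <- rep(c("a", "b"), each = 2)
  tri <- sample_triplets(1:4, labs, 500, seed = 3)
  expect_equal(nrow(tri), 500)
  expect_true(all(labs[tri[, 1]] == labs[tri[, 2]]))
  expect_true(all(tri[, 1] != tri[, 2]))
  expect_true(all(labs[tri[, 1]] != labs[tri[, 3]]))
  expect_identical(tri, sample_triplets(1:4, labs, 500, seed = 3))
  expect_error(sample_triplets(1:3, rep("a", 3), 10), "2 labeled classes")
})

test_that("triplet hinge arithmetic matches hand computation", {
  # engineered Q rows realizing s(A,P) and s(A,N):
  # rows: anchor (1,0), positive (0.9,0.1) -> s=0.9; negative (0.5,0.5) -> 0.5
  Q <- rbind(c(1, 0), c(0.9, 0.1), c(0.5, 0.5))
  t1 <- matrix(c(1, 2, 3), 1)
  expect_equal(triplet_loss(Q, t1, margin = 0.1), 0)       # margin satisfied
  # s(A,P)=0.5, s(A,N)=0.6 with margin 0.1 -> hinge 0.2
  Q2 <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.6, 0.4))
  s_ap <- sum(Q2[1, ] * Q2[2, ]); s_an <- sum(Q2[1, ] * Q2[3, ])
  expect_equal(triplet_loss(Q2, t1, margin = 0.1),
               max(s_an - s_ap + 0.1, 0), tolerance = 1e-9)
  # identical anchor/positive, orthogonal one-hot negative -> 0
  Q3 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(triplet_loss(Q3, t1, margin = 0.1), 0)
  # literal form flips the hinge sign
  expect_gt(triplet_loss(Q3, t1, margin = 0.1, form = "literal"), 0)
  expect_warning(v <- triplet_loss(Q3, matrix(0, 0, 3)), "empty")
  expect_equal(v, 0)
})

test_that("pairwise similarity is cosine with unit diagonal", {
  Q <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.2, 0.8))
  S <- pairwise_similarity(Q)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], 1, tolerance = 1e-12)     # identical rows
  expect_equal(S[1, 3], 0.32 / sum(Q[1, ]^2), tolerance = 1e-9)  # 0.4706
  one_hot <- rbind(c(1, 0), c(0, 1))
  expect_equal(pairwise_similarity(one_hot)[1, 2], 0)
  expect_error(pairwise_similarity(rbind(c(1, 0), c(0, 0))), "zero")
})

test_that("pairwise BCE loss hits its closed-form anchors", {
  Y <- pairwise_label_matrix(c("a", "a", "b"))
  expect_true(isSymmetric(Y))
  expect_equal(diag(Y), rep(1, 3))
  # perfect separation -> 0
  S_perfect <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  expect_equal(pairwise_loss(S_perfect, Y), 0, tolerance = 1e-9)
  # uninformative S = 0.5 -> log 2
  S_half <- matrix(0.5, 3, 3); diag(S_half) <- 1
  expect_equal(pairwise_loss(S_half, Y), log(2), tolerance = 1e-9)
  # permutation invariance
  perm <- c(3, 1, 2)
  set.seed(7)
  S <- pairwise_similarity(matrix(runif(9) + 0.1, 3))
  expect_equal(pairwise_loss(S, Y),
               pairwise_loss(S[perm, perm], Y[perm, perm]), tolerance = 1e-12)
  expect_error(pairwise_loss(S, Y[1:2, 1:2]), "shapes")
})

test_that("cluster-class alignment maximizes agreement", {
  # contingency [[5,0],[1,4]]: identity mapping, agreement 9
  Q <- rbind(matrix(rep(c(0.9, 0.1), 5), 5, 2, byrow = TRUE),
             c(0.9, 0.1),
             matrix(rep(c(0.1, 0.9), 4), 4, 2, byrow = TRUE))
  labs <- rep(c("c0", "c1"), c(5, 5))
  mp <- align_clusters(Q, labs)
  expect_equal(mp$cluster, c(1L, 2L))
  expect_equal(mp$agreement, 9)
  # K > K_t: labeled cells never hit cluster 3 -> mapping avoids it
  Q3 <- cbind(Q, 0.0)
  Q3 <- Q3 / rowSums(Q3)
  mp3 <- align_clusters(Q3, labs)
  expect_true(all(mp3$cluster %in% 1:2))
})

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(class_weights(rep(c("a", "b"), each = 5))), c(1, 1))
  w <- class_weights(rep(c("big", "small"), c(90, 10)))
  expect_equal(unname(w), c(100 / 180, 100 / 20), tolerance = 1e-9)
  freq <- c(90, 10) / 100
  expect_equal(sum(w * freq), 1)
})

test_that("weighted cross-entropy matches direct evaluation", {
  labs <- c("a", "b")
  mp <- structure(list(classes = c("a", "b"), cluster = c(1L, 2L),
                       agreement = 2), class = "ClusterClassMap")
  w <- class_weights(labs)
  # perfect one-hot -> 0
  expect_equal(weighted_ce_loss(rbind(c(1, 0), c(0, 1)), labs, mp, w), 0,
               tolerance = 1e-9)
  # uniform rows -> log 2
  expect_equal(weighted_ce_loss(matrix(0.5, 2, 2), labs, mp, w), log(2),
               tolerance = 1e-9)
  # up-weighting the minority strictly increases loss when only the
  # minority cell is misassigned
  labs2 <- c("maj", "maj", "min")
  Q <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1))  # min cell wrong
  mp2 <- structure(list(classes = c("maj", "min"), cluster = c(1L, 2L),
                        agreement = 2), class = "ClusterClassMap")
  w_flat <- c(maj = 1, min = 1)
  w_up <- c(maj = 1, min = 3)
  expect_gt(weighted_ce_loss(Q, labs2, mp2, w_up),
            weighted_ce_loss(Q, labs2, mp2, w_flat))
  expect_error(weighted_ce_loss(Q, c("maj", "maj", "ghost"), mp2, w_flat),
               "unmapped|missing")
})

test_that("constraint losses vanish together in the perfect limit", {
  # perfectly clustered labeled set: one-hot Q matching the labels
  labs <- rep(c("a", "b"), each = 3)
  Q <- rbind(matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE))
  tri <- sample_triplets(1:6, labs, 200, seed = 1)
  expect_equal(triplet_loss(Q, tri, margin = 0), 0)
  S <- pairwise_similarity(Q)
  expect_equal(pairwise_loss(S, pairwise_label_matrix(labs)), 0,
               tolerance = 1e-9)
  mp <- align_clusters(Q, labs)
  expect_equal(weighted_ce_loss(Q, labs, mp, class_weights(labs)), 0,
               tolerance = 1e-9)
})

test_that("constraint_set bundles a consistent semisupervised state", {
  labels <- rep(c("a", "b", "c"), c(50, 30, 20))
  cs <- constraint_set(labels, labeled_fraction = 0.1, n_triplets = 300,
                       seed = 4)
  expect_s3_class(cs, "ConstraintSet")
  expect_length(cs$labeled_idx, 10)
  expect_equal(cs$labels, labels[cs$labeled_idx])
  expect_equal(dim(cs$Y), c(10, 10))
  expect_true(all(cs$class_weights > 0))
  expect_equal(nrow(cs$triplets), 300)
  empty <- constraint_set(labels, labeled_fraction = 0)
  expect_length(empty$labeled_idx, 0)
})
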