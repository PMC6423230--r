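test_that("allele-sharing distances enumerate pairings correctly", {
  a1 <- rbind(i1 = c(1L, 1L), i2 = c(1L, 1L))
  a2 <- rbind(i1 = c(1L, 2L), i2 = c(1L, 2L))
  g <- make_genotypes(a1, a2)
  expect_equal(unname(genetic_distance_matrix(g)), matrix(0, 2, 2))

  # one locus: {a,a} vs {b,b} -> 2; {a,b} vs {a,c} -> 1
  g2 <- make_genotypes(rbind(x = 1L, y = 2L), rbind(x = 1L, y = 2L),
                       n_alleles = 3L)
  expect_equal(genetic_distance_matrix(g2)["x", "y"], 2)
  g3 <- make_genotypes(rbind(x = 1L, y = 1L), rbind(x = 2L, y = 3L),
                       n_alleles = 3L)
  expect_equal(genetic_distance_matrix(g3)["x", "y"], 1)
})

test_that("the genetic distance is a metric on random genotype matrices", {
  set.seed(21)
  for (r in 1:100) {
    n <- sample(3:6, 1); L <- sample(2:5, 1)
    a1 <- matrix(sample(1:3, n * L, TRUE), n, L)
    a2 <- matrix(sample(1:3, n * L, TRUE), n, L)
    D <- genetic_distance_matrix(make_genotypes(a1, a2, rep(3L, L)))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("classical scaling recovers block structure and distances", {
  # two blocks of mutually identical individuals: PC1 carries all variance
  D <- matrix(0, 6, 6, dimnames = list(paste0("i", 1:6), paste0("i", 1:6)))
  D[1:3, 4:6] <- 4; D[4:6, 1:3] <- 4
  p <- pca_from_distance(D)
  expect_equal(p$variance[1], 1)
  expect_true(all(p$coordinates[1:3, 1] * p$coordinates[4:6, 1] < 0))

  expect_true(is.na(pca_from_distance(matrix(0, 4, 4))$variance[1]))

  # Euclidean-embeddable distances are reproduced by the coordinates
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2)
  De <- as.matrix(dist(X))
  p2 <- pca_from_distance(De)
  Dr <- as.matrix(dist(p2$coordinates))
  expect_lt(max(abs(De - Dr)), 1e-8)
  # and the decomposition matches classical MDS from stats::cmdscale
  cm <- stats::cmdscale(De, k = 2, eig = TRUE)
  expect_equal(abs(p2$coordinates[, 1:2]), abs(cm$points), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("K = 1 forces degenerate admixture proportions", {
  g <- diagnostic_genotypes(n_ref = 5, n_f1 = 0, n_loci = 4)
  run <- admixture_gibbs(g, K = 1, iters = 50, burnin = 10, seed = 1)
  expect_true(all(run$Q == 1))
})

test_that("diagnostic loci give confident clusters and 50/50 hybrids", {
  g <- diagnostic_genotypes(n_ref = 20, n_f1 = 10, n_loci = 10)
  run <- admixture_gibbs(g, K = 2, iters = 600, burnin = 200, seed = 2)
  expect_true(all(abs(rowSums(run$Q) - 1) < 1e-9))
  own <- apply(run$Q[1:40, ], 1, max)
  expect_true(all(own >= 0.95))
  f1q <- run$Q[41:50, 1]
  expect_true(all(abs(f1q - 0.5) <= 0.1))
})

test_that("the correlated-frequency model variant also separates clusters", {
  g <- diagnostic_genotypes(n_ref = 10, n_f1 = 4, n_loci = 8)
  run <- admixture_gibbs(g, K = 2, iters = 400, burnin = 150, seed = 3,
                         correlated = TRUE)
  expect_true(all(apply(run$Q[1:20, ], 1, max) >= 0.9))
})

test_that("delta-K reproduces hand arithmetic and endpoint rules", {
  tab <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                    lnPD = c(-100, -100, -50, -52, -49, -51))
  dk <- evanno_delta_k(tab)
  # second difference at K = 2: |(-50) - 2*(-51) + (-100)| / sd(-50, -52)
  expect_equal(dk$deltaK[dk$K == 2], 48 / stats::sd(c(-50, -52)))
  expect_true(is.na(dk$deltaK[dk$K == 1]))
  expect_true(is.na(dk$deltaK[dk$K == 3]))

  # linear lnPD: second difference is zero up to noise
  set.seed(6)
  lin <- data.frame(K = rep(1:5, each = 4), replicate = rep(1:4, 5),
                    lnPD = -100 + 10 * rep(1:5, each = 4) + rnorm(20, 0, 1))
  kink <- data.frame(K = rep(1:5, each = 4), replicate = rep(1:4, 5),
                     lnPD = c(rep(-200, 4), rep(-100, 4), rep(-95, 4),
                              rep(-94, 4), rep(-93, 4)) + rnorm(20, 0, 1))
  expect_lt(max(evanno_delta_k(lin)$deltaK, na.rm = TRUE),
            max(evanno_delta_k(kink)$deltaK, na.rm = TRUE))
  expect_error(evanno_delta_k(tab[tab$K < 3, ]), "at least 3")
})

test_that("label alignment undoes column permutations", {
  g <- diagnostic_genotypes(n_ref = 8, n_f1 = 4, n_loci = 6)
  runA <- admixture_gibbs(g, K = 3, iters = 200, burnin = 80, seed = 4)
  runB <- runA
  perm <- c(3, 1, 2)
  runB$Q <- runA$Q[, perm]
  runB$P <- lapply(runA$P, function(p) p[perm, , drop = FALSE])
  al <- align_cluster_labels(list(runA, runB))
  expect_equal(al$runs[[2]]$Q, runA$Q)
  self <- align_cluster_labels(list(runA, runA))
  expect_equal(self$permutations[[2]], 1:3)
  expect_equal(self$mean_Q, runA$Q)
  runC <- runA; runC$K <- 2L
  expect_error(align_cluster_labels(list(runA, runC)), "differ in K")
})

test_that("clustering is insensitive to duplicated individuals after collapsing", {
  g <- diagnostic_genotypes(n_ref = 10, n_f1 = 5, n_loci = 8)
  run1 <- admixture_gibbs(g, K = 2, iters = 400, burnin = 150, seed = 8)
  # append exact copies of the first four reference individuals
  dup <- make_genotypes(rbind(g$a1, g$a1[1:4, ]), rbind(g$a2, g$a2[1:4, ]),
                        g$n_alleles)
  rownames(dup$a1) <- rownames(dup$a2) <- dup$individuals <-
    c(g$individuals, paste0("dup", 1:4))
  run2 <- admixture_gibbs(dup, K = 2, iters = 400, burnin = 150, seed = 8)
  al <- align_cluster_labels(list(run1, structure(
    list(K = 2L, Q = run2$Q[g$individuals, ], P = run2$P),
    class = "hyb_clusterrun")))
  expect_lt(max(abs(al$runs[[2]]$Q - run1$Q)), 0.1)
})
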