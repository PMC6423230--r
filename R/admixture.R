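# Genetic-distance PCA, admixture-model Gibbs sampling, Evanno delta-K model
# choice, and replicate label alignment.

#' Haplotype-allele genotype matrix
#'
#' Codes each individual's genotype per locus as haplotype ids from
#' [collapse_haplotypes()]: an unordered allele pair for nuclear loci, a single
#' allele for chloroplast loci. Missing loci are `NA`.
#'
#' @param dataset A `hyb_dataset`.
#' @param marker Marker kind.
#' @param individuals Individuals to include (default: all in the sample table).
#' @return Object of class `hyb_genotypes`: integer matrices `a1`, `a2`
#'   (individuals x loci; `a2` is `NA` throughout for haploid markers),
#'   `n_alleles` per locus, plus `individuals` and `loci`.
#' @export
genotype_matrix <- function(dataset, marker = "nuclear", individuals = NULL) {
  individuals <- individuals %||% dataset$samples$individual_id
  alns <- Filter(function(a) attr(a, "marker") == marker, dataset$alignments)
  if (!length(alns)) stop("no ", marker, " loci in dataset")
  nL <- length(alns); n <- length(individuals)
  a1 <- matrix(NA_integer_, n, nL, dimnames = list(individuals, names(alns)))
  a2 <- a1
  n_alleles <- integer(nL)
  for (l in seq_len(nL)) {
    hap <- collapse_haplotypes(alns[[l]])
    n_alleles[l] <- nrow(hap$haplotypes)
    key2hap <- integer(0)
    for (h in seq_along(hap$members))
      key2hap[hap$members[[h]]] <- match(names(hap$members)[h], hap$haplotypes$haplotype_id)
    keys <- rownames(alns[[l]])
    kind <- .key_individual(keys)
    for (i in seq_len(n)) {
      rows <- keys[kind == individuals[i]]
      if (!length(rows)) next
      a1[i, l] <- key2hap[rows[1L]]
      if (length(rows) > 1L) a2[i, l] <- key2hap[rows[2L]]
    }
  }
  structure(list(a1 = a1, a2 = a2, n_alleles = n_alleles,
                 individuals = individuals, loci = names(alns)),
            class = "hyb_genotypes")
}

#' Allele-sharing genetic distance matrix
#'
#' Per-locus distance between two individuals is the number of allele copies
#' not shared under optimal pairing (0, 1 or 2 for diploids); the total is the
#' sum over loci scored in both individuals.
#'
#' @param g A `hyb_genotypes`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
genetic_distance_matrix <- function(g) {
  n <- length(g$individuals)
  if (n < 2L) stop("need at least 2 individuals")
  scored <- rowSums(!is.na(g$a1))
  if (any(scored == 0L))
    stop("individual(s) with no scored loci: ",
         paste(g$individuals[scored == 0L], collapse = ", "))
  D <- matrix(0, n, n, dimnames = list(g$individuals, g$individuals))
  for (l in seq_along(g$loci)) {
    x1 <- g$a1[, l]; x2 <- g$a2[, l]
    if (all(is.na(x2))) x2 <- x1  # haploid locus: treat as homozygote
    ok <- !is.na(x1)
    for (i in which(ok)) {
      for (j in which(ok)) {
        if (j <= i) next
        # only two pairings of two allele copies: straight and crossed
        shared <- (x1[i] == x1[j]) + (x2[i] == x2[j])
        alt <- (x1[i] == x2[j]) + (x2[i] == x1[j])
        D[i, j] <- D[i, j] + 2L - max(shared, alt)
        D[j, i] <- D[i, j]
      }
    }
  }
  D
}

#' Principal components from a distance matrix
#'
#' Classical (metric) scaling: Gower double-centering of `-0.5 * D^2` followed
#' by an eigendecomposition; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues.
#'
#' @param Dm Symmetric distance matrix.
#' @return List with `coordinates` (columns `PC1..`), `variance` (fractions of
#'   positive eigenvalue mass; `NA` when all eigenvalues vanish) and
#'   `eigenvalues`.
#' @export
pca_from_distance <- function(Dm) {
  Dm <- as.matrix(Dm)
  n <- nrow(Dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (Dm^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values[1L], 0) * 1e-12 & e$values > 0
  if (!any(pos)) {
    coords <- matrix(0, n, 1L, dimnames = list(rownames(Dm), "PC1"))
    return(list(coordinates = coords, variance = NA_real_, eigenvalues = e$values))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  dimnames(coords) <- list(rownames(Dm), paste0("PC", seq_len(ncol(coords))))
  list(coordinates = coords, variance = e$values[pos] / sum(e$values[pos]),
       eigenvalues = e$values)
}

# flatten genotypes into per-locus copy vectors (indices of non-missing copies)
.copy_layout <- function(g) {
  n <- length(g$individuals)
  lapply(seq_along(g$loci), function(l) {
    x <- c(g$a1[, l], g$a2[, l])
    ind <- rep(seq_len(n), 2L)
    keep <- !is.na(x)
    list(allele = x[keep], ind = ind[keep], A = g$n_alleles[l])
  })
}

#' Bayesian admixture-model clustering by Gibbs sampling
#'
#' Each allele copy carries a latent cluster of origin; individual admixture
#' proportions get a symmetric Dirichlet(alpha) prior whose alpha has a
#' uniform(0, `alpha_max`) hyperprior updated by Metropolis steps; cluster
#' allele frequencies get Dirichlet(`lambda`) priors (independent-frequency
#' model). With `correlated = TRUE` the correlated-frequency variant is used:
#' cluster frequencies are shrunk toward a latent ancestral frequency vector
#' with per-cluster drift parameters under uniform(0,1) priors.
#'
#' @param g A `hyb_genotypes`.
#' @param K Number of clusters.
#' @param iters Total sweeps.
#' @param burnin Burn-in sweeps discarded from all summaries.
#' @param seed RNG seed.
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param alpha_max Upper bound of the uniform hyperprior on alpha.
#' @param correlated Use the correlated-frequency (F-model) variant.
#' @return Object of class `hyb_clusterrun`: posterior-mean `Q` (individuals x
#'   K, rows sum to 1), posterior-mean allele frequencies `P`, the model
#'   log-evidence estimate `lnPD` (`mean(lnL) - var(lnL)/2` over retained
#'   sweeps), traces, and run metadata.
#' @export
admixture_gibbs <- function(g, K, iters = 600L, burnin = 200L, seed = NULL,
                            lambda = 1, alpha_max = 10, correlated = FALSE) {
  K <- as.integer(K)
  stopifnot(K >= 1L, iters > burnin)
  .maybe_seed(seed)
  n <- length(g$individuals)
  layout <- .copy_layout(g)
  nL <- length(layout)
  Q <- matrix(1 / K, n, K)
  P <- lapply(layout, function(lo) matrix(1 / lo$A, K, lo$A))
  alpha <- 1
  Fdrift <- rep(0.5, K)
  P0 <- lapply(layout, function(lo) rep(1 / lo$A, lo$A))
  Qsum <- matrix(0, n, K)
  Psum <- lapply(layout, function(lo) matrix(0, K, lo$A))
  lnL_trace <- numeric(iters)
  alpha_trace <- numeric(iters)
  kept <- 0L
  for (it in seq_len(iters)) {
    nik <- matrix(0, n, K)
    lnL <- 0
    for (l in seq_len(nL)) {
      lo <- layout[[l]]
      W <- Q[lo$ind, , drop = FALSE] * t(P[[l]])[lo$allele, , drop = FALSE]
      tot <- rowSums(W)
      lnL <- lnL + sum(log(pmax(tot, 1e-300)))
      u <- stats::runif(length(tot)) * tot
      z <- rep(1L, length(tot))
      if (K > 1L) {
        cum <- W[, 1L]
        for (k in seq_len(K - 1L)) {
          z <- z + (u > cum)
          if (k < K - 1L) cum <- cum + W[, k + 1L]
        }
      }
      cnt <- vapply(seq_len(K),
                    function(k) tabulate(lo$allele[z == k], lo$A), numeric(lo$A))
      cnt <- matrix(cnt, nrow = lo$A)  # A x K
      if (!correlated) {
        P[[l]] <- .rdirichlet_rows(t(cnt) + lambda)
      } else {
        shape <- t(cnt) + matrix(P0[[l]], K, lo$A, byrow = TRUE) *
          ((1 - Fdrift) / Fdrift)
        P[[l]] <- .rdirichlet_rows(shape)
      }
      nik <- nik + matrix(tabulate((z - 1L) * n + lo$ind, n * K), n, K)
    }
    Q <- .rdirichlet_rows(nik + alpha)
    # Metropolis update of the Dirichlet hyperparameter alpha
    prop <- alpha + stats::rnorm(1L, 0, 0.25)
    if (prop > 0 && prop < alpha_max) {
      slg <- sum(log(pmax(Q, 1e-300)))
      la <- n * (lgamma(K * prop) - K * lgamma(prop) -
                   lgamma(K * alpha) + K * lgamma(alpha)) + (prop - alpha) * slg
      if (log(stats::runif(1L)) < la) alpha <- prop
    }
    if (correlated) {
      # Metropolis on drift parameters and ancestral frequencies
      for (k in seq_len(K)) {
        fp <- Fdrift[k] + stats::rnorm(1L, 0, 0.05)
        if (fp > 0.001 && fp < 0.999) {
          la <- 0
          for (l in seq_len(nL)) {
            s_new <- P0[[l]] * (1 - fp) / fp
            s_old <- P0[[l]] * (1 - Fdrift[k]) / Fdrift[k]
            la <- la + lgamma(sum(s_new)) - sum(lgamma(s_new)) +
              sum((s_new - 1) * log(pmax(P[[l]][k, ], 1e-300))) -
              (lgamma(sum(s_old)) - sum(lgamma(s_old)) +
                 sum((s_old - 1) * log(pmax(P[[l]][k, ], 1e-300))))
          }
          if (log(stats::runif(1L)) < la) Fdrift[k] <- fp
        }
      }
      for (l in seq_len(nL)) {
        lo <- layout[[l]]
        prop0 <- .rdirichlet_rows(matrix(P0[[l]] * 50 + 0.5, 1L))[1L, ]
        la <- 0
        for (k in seq_len(K)) {
          s_new <- prop0 * (1 - Fdrift[k]) / Fdrift[k]
          s_old <- P0[[l]] * (1 - Fdrift[k]) / Fdrift[k]
          la <- la + lgamma(sum(s_new)) - sum(lgamma(s_new)) +
            sum((s_new - 1) * log(pmax(P[[l]][k, ], 1e-300))) -
            (lgamma(sum(s_old)) - sum(lgamma(s_old)) +
               sum((s_old - 1) * log(pmax(P[[l]][k, ], 1e-300))))
        }
        la <- la +  # symmetric-ish proposal correction
          (lgamma(sum(prop0 * 50 + 0.5)) - sum(lgamma(P0[[l]] * 50 + 0.5)) +
             sum((P0[[l]] * 50 + 0.5 - 1) * log(pmax(prop0, 1e-300)))) -
          (lgamma(sum(P0[[l]] * 50 + 0.5)) - sum(lgamma(prop0 * 50 + 0.5)) +
             sum((prop0 * 50 + 0.5 - 1) * log(pmax(P0[[l]], 1e-300))))
        if (log(stats::runif(1L)) < la) P0[[l]] <- prop0
      }
    }
    lnL_trace[it] <- lnL
    alpha_trace[it] <- alpha
    if (it > burnin) {
      kept <- kept + 1L
      Qsum <- Qsum + Q
      for (l in seq_len(nL)) Psum[[l]] <- Psum[[l]] + P[[l]]
    }
  }
  post <- lnL_trace[(burnin + 1L):iters]
  Qm <- Qsum / kept
  rownames(Qm) <- g$individuals
  structure(list(K = K, Q = Qm, P = lapply(Psum, function(p) p / kept),
                 lnPD = mean(post) - stats::var(post) / 2,
                 lnL_trace = lnL_trace, alpha_trace = alpha_trace,
                 iters = iters, burnin = burnin, seed = seed,
                 correlated = correlated),
            class = "hyb_clusterrun")
}

#' @export
print.hyb_clusterrun <- function(x, ...) {
  cat("<hyb_clusterrun> K =", x$K, "|", nrow(x$Q), "individuals | lnPD =",
      round(x$lnPD, 2), "\n")
  invisible(x)
}

#' Replicate admixture runs over a range of K
#'
#' Replicate `r` of a given `K` uses seed `seed + r`, mirroring the usual
#' replicate-run protocol; the returned table feeds [evanno_delta_k()].
#'
#' @inheritParams admixture_gibbs
#' @param K_range Integer vector of K values.
#' @param replicates Runs per K.
#' @param seed Base seed.
#' @param ... Passed on to [admixture_gibbs()].
#' @return List with `runs` (nested by K) and `lnPD`, a data frame
#'   (`K`, `replicate`, `lnPD`).
#' @export
admixture_replicates <- function(g, K_range, replicates = 3L, seed = 1L, ...) {
  runs <- list()
  tab <- list()
  for (K in K_range) {
    runs[[as.character(K)]] <- lapply(seq_len(replicates), function(r)
      admixture_gibbs(g, K, seed = seed + r + 1000L * K, ...))
    tab[[as.character(K)]] <- data.frame(
      K = K, replicate = seq_len(replicates),
      lnPD = vapply(runs[[as.character(K)]], function(x) x$lnPD, 0))
  }
  list(runs = runs, lnPD = do.call(rbind, tab))
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` over
#' replicate log-evidence values; defined only for interior K with positive
#' replicate standard deviation.
#'
#' @param lnPD Data frame with columns `K`, `replicate`, `lnPD` (as produced
#'   by [admixture_replicates()]).
#' @return Data frame per K: `mean_lnPD`, `sd_lnPD`, `deltaK` (`NA` at the
#'   endpoints and where `sd = 0`).
#' @export
evanno_delta_k <- function(lnPD) {
  Ks <- sort(unique(lnPD$K))
  if (length(Ks) < 3L) stop("delta-K needs at least 3 consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mean_l <- tapply(lnPD$lnPD, lnPD$K, mean)[as.character(Ks)]
  sd_l <- tapply(lnPD$lnPD, lnPD$K, stats::sd)[as.character(Ks)]
  reps <- tapply(lnPD$lnPD, lnPD$K, length)
  if (any(reps < 2L)) stop("delta-K needs >= 2 replicates per K")
  dK <- rep(NA_real_, length(Ks))
  for (i in seq(2L, length(Ks) - 1L)) {
    if (!is.na(sd_l[i]) && sd_l[i] > 0)
      dK[i] <- abs(mean_l[i + 1L] - 2 * mean_l[i] + mean_l[i - 1L]) / sd_l[i]
  }
  data.frame(K = Ks, mean_lnPD = as.numeric(mean_l), sd_lnPD = as.numeric(sd_l),
             deltaK = dK, row.names = NULL)
}

#' Align cluster labels across replicate runs
#'
#' Greedy column matching that maximises the Frobenius inner product of each
#' run's Q matrix with the first run's, then averages the aligned Q matrices.
#'
#' @param runs List of `hyb_clusterrun` objects at the same K over the same
#'   individuals.
#' @return List with `runs` (relabelled), `permutations`, and `mean_Q`.
#' @export
align_cluster_labels <- function(runs) {
  K <- runs[[1L]]$K
  if (any(vapply(runs, function(r) as.integer(r$K), 0L) != K)) stop("runs differ in K")
  ref <- runs[[1L]]$Q
  perms <- list(seq_len(K))
  out <- runs
  for (r in seq_along(runs)[-1L]) {
    Q <- runs[[r]]$Q
    sim <- crossprod(Q, ref)  # sim[j, k] = <Q[, j], ref[, k]>
    perm <- integer(K)
    avail_j <- seq_len(K); avail_k <- seq_len(K)
    while (length(avail_j)) {
      idx <- which(sim == max(sim[avail_j, avail_k, drop = FALSE]), arr.ind = TRUE)
      idx <- idx[idx[, 1L] %in% avail_j & idx[, 2L] %in% avail_k, , drop = FALSE][1L, ]
      perm[idx[2L]] <- idx[1L]
      avail_j <- setdiff(avail_j, idx[1L])
      avail_k <- setdiff(avail_k, idx[2L])
      sim[idx[1L], ] <- -Inf; sim[, idx[2L]] <- -Inf
    }
    out[[r]]$Q <- Q[, perm, drop = FALSE]
    out[[r]]$P <- lapply(runs[[r]]$P, function(p) p[perm, , drop = FALSE])
    perms[[r]] <- perm
  }
  meanQ <- Reduce(`+`, lapply(out, function(x) x$Q)) / length(out)
  list(runs = out, permutations = perms, mean_Q = meanQ)
}

#' Write a Q matrix as tab-separated text
#' @param run A `hyb_clusterrun` (or a matrix).
#' @param path Output path.
#' @export
write_q_matrix <- function(run, path) {
  Q <- if (inherits(run, "hyb_clusterrun")) run$Q else run
  utils::write.table(round(Q, 6), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
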