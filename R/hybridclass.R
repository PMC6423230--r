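# Bayesian assignment of individuals to six genotype classes (two pure
# parents, F1, F2, and the two first-generation backcrosses) from two-parent
# genotype data, via Gibbs sampling over class labels, gene-copy origins,
# class mixing proportions and parental allele frequencies.

.HYB_CLASSES <- c("Pure1", "Pure2", "F1", "F2", "BC1", "BC2")

#' Expected gene-copy origin frequencies of the six genotype classes
#'
#' For each class, the probability that at a locus both gene copies derive
#' from parent species 1 (`p11`), one from each (`p12`), or both from species
#' 2 (`p22`); these follow from Mendelian segregation of copy origins.
#'
#' @return 6 x 3 numeric matrix with rows `Pure1, Pure2, F1, F2, BC1, BC2`.
#' @export
class_frequencies <- function() {
  m <- rbind(Pure1 = c(1, 0, 0),
             Pure2 = c(0, 0, 1),
             F1    = c(0, 1, 0),
             F2    = c(1 / 4, 1 / 2, 1 / 4),
             BC1   = c(1 / 2, 1 / 2, 0),
             BC2   = c(0, 1 / 2, 1 / 2))
  colnames(m) <- c("p11", "p12", "p22")
  m
}

#' Likelihood of one genotype under a genotype class
#'
#' Mixture over gene-copy origins:
#' `P = p11 * HW(g | f1) + p12 * M(g | f1, f2) + p22 * HW(g | f2)` with
#' `HW({a,a} | f) = f(a)^2`, `HW({a,b} | f) = 2 f(a) f(b)`,
#' `M({a,a}) = f1(a) f2(a)` and `M({a,b}) = f1(a) f2(b) + f1(b) f2(a)`.
#'
#' @param genotype Length-2 vector of allele indices (unordered pair).
#' @param class One of `Pure1, Pure2, F1, F2, BC1, BC2`.
#' @param f1,f2 Allele-frequency vectors of the two parent species over the
#'   locus allele catalogue.
#' @return Probability of the genotype.
#' @export
genotype_likelihood <- function(genotype, class, f1, f2) {
  if (!class %in% .HYB_CLASSES) stop("unknown class: ", class)
  a <- genotype[1L]; b <- genotype[2L]
  if (a > length(f1) || b > length(f1) || a > length(f2) || b > length(f2))
    stop("allele index outside the locus catalogue")
  het <- a != b
  hw1 <- f1[a] * f1[b] * (1 + het)
  hw2 <- f2[a] * f2[b] * (1 + het)
  mx <- f1[a] * f2[b] + if (het) f1[b] * f2[a] else 0
  w <- class_frequencies()[class, ]
  unname(w["p11"] * hw1 + w["p12"] * mx + w["p22"] * hw2)
}

# per-locus class likelihood components for all individuals at once:
# returns n x 3 matrix of (HW1, M, HW2); NA rows for missing loci
.geno_lik_parts <- function(a, b, f1, f2) {
  het <- (a != b)
  cbind(hw1 = f1[a] * f1[b] * (1 + het),
        mx = f1[a] * f2[b] + ifelse(het, f1[b] * f2[a], 0),
        hw2 = f2[a] * f2[b] * (1 + het))
}

#' Six-class hybrid-genotype assignment by Gibbs sampling
#'
#' Latent variables are each individual's genotype class, each gene copy's
#' parental origin, the class mixing proportions (Dirichlet(1) prior over the
#' six classes) and the two parental allele-frequency vectors per locus
#' (Dirichlet prior chosen by `prior`). Individuals listed in `z_fixed` keep
#' their known pure class throughout but still inform the frequency updates;
#' individuals in `s_excluded` never contribute to frequency updates.
#'
#' @param g A `hyb_genotypes` restricted to the two parental taxa and the
#'   candidate individuals.
#' @param prior `"jeffreys"` (Dirichlet(1/A) per locus, A = allele count) or
#'   `"uniform"` (Dirichlet(1)).
#' @param z_fixed Named character vector: individual id -> `"Pure1"` or
#'   `"Pure2"`.
#' @param s_excluded Individual ids excluded from allele-frequency estimation.
#' @param sweeps Total sweeps.
#' @param burnin Burn-in sweeps.
#' @param seed RNG seed.
#' @return Object of class `hyb_classposterior`: matrix `posterior`
#'   (individuals x 6 classes, rows sum to 1), modal class, and run metadata.
#' @export
newhybrids_mcmc <- function(g, prior = c("jeffreys", "uniform"),
                            z_fixed = character(0), s_excluded = character(0),
                            sweeps = 2000L, burnin = 500L, seed = NULL) {
  prior <- match.arg(prior)
  .maybe_seed(seed)
  stopifnot(sweeps > burnin)
  n <- length(g$individuals)
  nL <- length(g$loci)
  if (length(z_fixed)) {
    if (is.null(names(z_fixed)) || !all(names(z_fixed) %in% g$individuals))
      stop("z_fixed must be named by known individual ids")
    if (!all(z_fixed %in% c("Pure1", "Pure2")))
      stop("z_fixed classes must be Pure1 or Pure2")
  }
  if (!all(s_excluded %in% g$individuals)) stop("unknown id in s_excluded")
  fixed_class <- match(z_fixed[g$individuals], .HYB_CLASSES)  # NA if free
  include_freq <- !(g$individuals %in% s_excluded)
  W <- class_frequencies()
  lam <- switch(prior, jeffreys = 1 / g$n_alleles, uniform = rep(1, nL))
  # initial frequencies: overall counts
  f1 <- f2 <- vector("list", nL)
  for (l in seq_len(nL)) {
    cnt <- tabulate(c(g$a1[, l], g$a2[, l])[!is.na(c(g$a1[, l], g$a2[, l]))],
                    g$n_alleles[l])
    f1[[l]] <- f2[[l]] <- (cnt + 1) / sum(cnt + 1)
  }
  cls <- ifelse(is.na(fixed_class), sample.int(6L, n, replace = TRUE), fixed_class)
  pi6 <- rep(1 / 6, 6L)
  post_cnt <- matrix(0, n, 6L, dimnames = list(g$individuals, .HYB_CLASSES))
  origin_w <- rbind(  # class -> weight of ordered origin pairs (11, 12, 21, 22)
    W[, "p11"], W[, "p12"] / 2, W[, "p12"] / 2, W[, "p22"])
  for (it in seq_len(sweeps)) {
    logL <- matrix(0, n, 6L)
    cnt1 <- vector("list", nL); cnt2 <- vector("list", nL)
    for (l in seq_len(nL)) {
      a <- g$a1[, l]; b <- g$a2[, l]
      ok <- !is.na(a) & !is.na(b)
      parts <- .geno_lik_parts(a[ok], b[ok], f1[[l]], f2[[l]])
      lik <- parts %*% t(W)  # n_ok x 6
      logL[ok, ] <- logL[ok, ] + log(pmax(lik, 1e-300))
      # gene-copy origins given current classes
      aw <- a[ok]; bw <- b[ok]
      cw <- cls[ok]
      w4 <- t(origin_w[, cw, drop = FALSE]) *
        cbind(f1[[l]][aw] * f1[[l]][bw], f1[[l]][aw] * f2[[l]][bw],
              f2[[l]][aw] * f1[[l]][bw], f2[[l]][aw] * f2[[l]][bw])
      tot <- rowSums(w4)
      u <- stats::runif(length(tot)) * tot
      o <- rep(1L, length(tot))
      cum <- w4[, 1L]
      for (j in 1:3) { o <- o + (u > cum); if (j < 3) cum <- cum + w4[, j + 1L] }
      use <- include_freq[ok]
      org1 <- o %in% c(1L, 2L)  # copy 1 origin: parent 1
      org2 <- o %in% c(1L, 3L)  # copy 2 origin: parent 1
      cnt1[[l]] <- tabulate(c(aw[use & org1], bw[use & org2]), g$n_alleles[l])
      cnt2[[l]] <- tabulate(c(aw[use & !org1], bw[use & !org2]), g$n_alleles[l])
    }
    # class update
    lp <- sweep(logL, 2L, log(pi6), `+`)
    lp <- lp - apply(lp, 1L, max)
    pr <- exp(lp); pr <- pr / rowSums(pr)
    u <- stats::runif(n)
    newc <- rep(1L, n); cum <- pr[, 1L]
    for (k in 1:5) { newc <- newc + (u > cum); if (k < 5) cum <- cum + pr[, k + 1L] }
    cls <- ifelse(is.na(fixed_class), newc, fixed_class)
    pi6 <- as.numeric(.rdirichlet_rows(matrix(1 + tabulate(cls, 6L), 1L)))
    for (l in seq_len(nL)) {
      f1[[l]] <- as.numeric(.rdirichlet_rows(matrix(cnt1[[l]] + lam[l], 1L)))
      f2[[l]] <- as.numeric(.rdirichlet_rows(matrix(cnt2[[l]] + lam[l], 1L)))
    }
    if (it > burnin) post_cnt[cbind(seq_len(n), cls)] <- post_cnt[cbind(seq_len(n), cls)] + 1
  }
  post <- post_cnt / (sweeps - burnin)
  structure(list(posterior = post,
                 modal = .HYB_CLASSES[max.col(post, ties.method = "first")],
                 prior = prior, sweeps = sweeps, burnin = burnin, seed = seed,
                 z_fixed = z_fixed, s_excluded = s_excluded),
            class = "hyb_classposterior")
}

#' @export
print.hyb_classposterior <- function(x, ...) {
  cat("<hyb_classposterior>", nrow(x$posterior), "individuals |", x$prior,
      "prior |", x$sweeps, "sweeps\n")
  print(table(modal_class = x$modal))
  invisible(x)
}

#' Cross-checked hybrid classification under both priors
#'
#' Runs [newhybrids_mcmc()] once under the Jeffreys-like prior and once under
#' the uniform prior, warns when the runs disagree (maximum per-class
#' posterior difference above `tol`), and returns both runs plus their mean
#' posterior.
#'
#' @inheritParams newhybrids_mcmc
#' @param tol Disagreement threshold triggering a convergence warning.
#' @return List with `runs` (both `hyb_classposterior`s), `posterior` (mean),
#'   `modal`, and `max_disagreement`.
#' @export
classify_hybrids <- function(g, z_fixed = character(0), s_excluded = character(0),
                             sweeps = 2000L, burnin = 500L, seed = 1L, tol = 0.1) {
  r1 <- newhybrids_mcmc(g, "jeffreys", z_fixed, s_excluded, sweeps, burnin, seed)
  r2 <- newhybrids_mcmc(g, "uniform", z_fixed, s_excluded, sweeps, burnin, seed + 1L)
  dis <- max(abs(r1$posterior - r2$posterior))
  if (dis > tol)
    warning("replicate runs disagree (max per-class posterior difference ",
            round(dis, 3), " > ", tol, "); consider longer chains")
  post <- (r1$posterior + r2$posterior) / 2
  list(runs = list(jeffreys = r1, uniform = r2), posterior = post,
       modal = .HYB_CLASSES[max.col(post, ties.method = "first")],
       max_disagreement = dis)
}
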