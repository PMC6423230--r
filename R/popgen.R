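# Per-locus polymorphism and neutrality statistics: segregating sites,
# haplotype counts, nucleotide diversity, Watterson's theta, Tajima's D,
# Fu & Li's D* and F*, and a maximum-likelihood HKA test.

# pairwise difference counts between all rows of a character matrix
.pairwise_diffs <- function(m) {
  n <- nrow(m)
  matches <- matrix(0, n, n)
  for (ch in c("A", "C", "G", "T")) {
    b <- m == ch
    storage.mode(b) <- "numeric"
    matches <- matches + tcrossprod(b)
  }
  d <- ncol(m) - matches
  d[upper.tri(d)]
}

# per-column counts of each base (rows = columns of m)
.base_counts <- function(m) {
  vapply(c("A", "C", "G", "T"), function(ch) colSums(m == ch), numeric(ncol(m)))
}

# total mutations eta (states - 1 per column) and singleton mutations eta_s
.eta_counts <- function(m) {
  cnt <- .base_counts(m)
  states <- rowSums(cnt > 0)
  singles <- rowSums(cnt == 1)
  c(eta = sum(states - 1L),
    eta_s = sum(pmin(singles, states - 1L)))  # all-distinct column: k-1 singletons
}

#' Per-locus diversity and neutrality statistics
#'
#' Columns containing gaps or ambiguous bases are removed first
#' (complete deletion); all per-site quantities use the retained length.
#'
#' @param aln A `hyb_alignment` holding the haplotypes of one taxon at one
#'   locus (n >= 2 rows).
#' @param taxon Optional taxon label carried into the output.
#' @return One-row data frame: `locus_id`, `taxon`, `n`, `L` (analysed sites),
#'   `S`, `eta`, `eta_s`, `Nh`, `k` (mean pairwise differences, count),
#'   `pi`, `theta_w` (per site), `D`, `Dstar`, `Fstar` and `tests_defined`
#'   (FALSE when S = 0, in which case the test statistics are `NA`).
#' @export
diversity_stats <- function(aln, taxon = NA_character_) {
  if (nrow(aln) < 2L) stop("diversity statistics need at least 2 sequences")
  m <- unclass(mask_ambiguous_columns(aln))
  n <- nrow(m); L <- ncol(m)
  if (L == 0L) stop("no fully resolved columns left after complete deletion")
  d <- .pairwise_diffs(m)
  k <- mean(d)
  S <- sum(rowSums(.base_counts(m) > 0) > 1L)
  Nh <- nrow(unique(m))
  eta <- .eta_counts(m)
  a1 <- .a1(n)
  defined <- S > 0L
  data.frame(
    locus_id = attr(aln, "locus_id"), taxon = taxon, n = n, L = L,
    S = as.integer(S), eta = unname(eta["eta"]), eta_s = unname(eta["eta_s"]),
    Nh = as.integer(Nh), k = k, pi = k / L, theta_w = S / (a1 * L),
    D = if (defined) tajimas_d(S, k, n) else NA_real_,
    Dstar = if (defined && n >= 4L) fu_li_star_from_counts(eta["eta"], eta["eta_s"], k, n)[["Dstar"]] else NA_real_,
    Fstar = if (defined && n >= 4L) fu_li_star_from_counts(eta["eta"], eta["eta_s"], k, n)[["Fstar"]] else NA_real_,
    tests_defined = defined, row.names = NULL)
}

#' Tajima's D
#'
#' Standard normalised difference between the mean number of pairwise
#' differences and `S/a1`.
#'
#' @param S Number of segregating sites.
#' @param k Mean pairwise difference count.
#' @param n Sample size (number of sequences).
#' @return The statistic, or `NA` when `S = 0` (undefined).
#' @export
tajimas_d <- function(S, k, n) {
  if (n < 2L) stop("n must be >= 2")
  if (S == 0) return(NA_real_)
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* and F* from mutation counts
#'
#' Within-species (no outgroup) versions, built from the total number of
#' mutations `eta`, the number of singleton mutations `eta_s`, and the mean
#' pairwise difference `k`, with the corrected variance constants.
#'
#' @param eta Total number of mutations.
#' @param eta_s Number of singleton mutations.
#' @param k Mean pairwise difference count.
#' @param n Sample size.
#' @return Named vector `c(Dstar =, Fstar =)`; `NA`s when `eta = 0`.
#' @export
fu_li_star_from_counts <- function(eta, eta_s, k, n) {
  if (n < 4L) stop("Fu & Li's starred statistics need n >= 4")
  if (eta == 0) return(c(Dstar = NA_real_, Fstar = NA_real_))
  an <- .a1(n); bn <- .a2(n); an1 <- an + 1 / n  # a_{n+1}
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an) - vF
  Fstar <- (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  c(Dstar = unname(Dstar), Fstar = unname(Fstar))
}

#' Fu and Li's D* and F* for an alignment
#'
#' @param aln A `hyb_alignment` (one taxon's haplotypes).
#' @return Named vector `c(Dstar =, Fstar =)`.
#' @export
fu_li_star <- function(aln) {
  m <- unclass(mask_ambiguous_columns(aln))
  eta <- .eta_counts(m)
  k <- mean(.pairwise_diffs(m))
  fu_li_star_from_counts(eta["eta"], eta["eta_s"], k, nrow(m))
}

#' Per-locus, per-taxon diversity report
#'
#' Runs [diversity_stats()] for every (locus, taxon) combination with at least
#' two sequenced haplotypes; mirrors the layout of the diversity software's
#' tabular output.
#'
#' @param dataset A `hyb_dataset`.
#' @param taxa Taxa to include (default: all).
#' @param marker Marker kind.
#' @return Data frame with one row per locus x taxon.
#' @export
diversity_table <- function(dataset, taxa = NULL, marker = "nuclear") {
  taxa <- taxa %||% unique(dataset$samples$taxon)
  alns <- Filter(function(a) attr(a, "marker") == marker, dataset$alignments)
  out <- list()
  for (aln in alns) {
    ind <- .key_individual(rownames(aln))
    for (tx in taxa) {
      keys <- rownames(aln)[ind %in% dataset$samples$individual_id[dataset$samples$taxon == tx]]
      if (length(keys) < 2L) next
      out[[length(out) + 1L]] <- diversity_stats(.subset_alignment(aln, keys), taxon = tx)
    }
  }
  do.call(rbind, out)
}

#' Assemble the data for a maximum-likelihood HKA test
#'
#' @param L Per-locus alignment lengths (bp).
#' @param n Per-locus sample sizes.
#' @param S Per-locus polymorphism counts.
#' @param div Per-locus divergence counts against a single outgroup sequence
#'   (raw differences on gap-free columns; no multiple-hit correction).
#' @param locus_id Optional locus labels.
#' @return Object of class `hyb_hka`.
#' @export
hka_model <- function(L, n, S, div, locus_id = NULL) {
  len <- length(L)
  if (!all(lengths(list(n, S, div)) == len)) stop("L, n, S, div must have equal length")
  if (len < 2L) stop("the HKA framework needs at least 2 loci")
  structure(list(L = as.numeric(L), n = as.integer(n), S = as.numeric(S),
                 div = as.numeric(div),
                 locus_id = locus_id %||% paste0("locus", seq_len(len))),
            class = "hyb_hka")
}

# log-likelihood of the Poisson HKA model at given theta (per site), T, k
.hka_loglik <- function(m, theta, Tdiv, k) {
  a <- vapply(m$n, .a1, 0)
  sum(stats::dpois(m$S, k * theta * m$L * a, log = TRUE)) +
    sum(stats::dpois(m$div, theta * m$L * (Tdiv + 1), log = TRUE))
}

# profile log-likelihood over T: given T, each locus theta (and candidate k)
# has a closed-form maximiser, so the full fit is a 1-D optimisation.
.hka_profile <- function(m, Tdiv, candidate) {
  a <- vapply(m$n, .a1, 0)
  theta <- (m$S + m$div) / (m$L * (a + Tdiv + 1))      # neutral (shared) MLE
  k <- rep(1, length(m$L))
  if (any(candidate)) {
    # candidate loci: theta from divergence alone, k absorbs the polymorphism
    theta[candidate] <- m$div[candidate] / (m$L[candidate] * (Tdiv + 1))
    theta[candidate] <- pmax(theta[candidate], 1e-12)
    k[candidate] <- m$S[candidate] / (theta[candidate] * m$L[candidate] * a[candidate])
  }
  theta <- pmax(theta, 1e-12)
  list(logL = .hka_loglik(m, theta, Tdiv, k), theta = theta, k = k, T = Tdiv)
}

#' Maximum-likelihood HKA test
#'
#' Fits the Poisson polymorphism/divergence model in which locus `i`
#' contributes `Pois(S_i; k_i * theta_i * L_i * a_{n_i})` for polymorphism and
#' `Pois(div_i; theta_i * L_i * (T + 1))` for divergence. Under the neutral
#' model all selection multipliers `k_i = 1`; under the selection model the
#' `k_i` of the candidate loci are free. Both fits profile out `theta` (and
#' `k`) in closed form and maximise over `T` numerically, so the result is
#' deterministic.
#'
#' @param model A `hyb_hka` from [hka_model()].
#' @param candidate_loci Labels (or indices) of loci whose `k` is freed.
#' @return List with `lnL_neutral`, `lnL_selection`, `LRT`, `df`, `p`, and the
#'   fitted parameters of both models.
#' @export
mlhka_test <- function(model, candidate_loci = character(0)) {
  if (!inherits(model, "hyb_hka")) stop("`model` must come from hka_model()")
  candidate <- if (is.character(candidate_loci)) model$locus_id %in% candidate_loci
               else seq_along(model$L) %in% candidate_loci
  if (is.character(candidate_loci) && sum(candidate) != length(unique(candidate_loci)))
    stop("unknown candidate locus label(s)")
  fit1 <- function(cand) {
    opt <- stats::optimize(function(lt) .hka_profile(model, exp(lt), cand)$logL,
                           c(log(1e-4), log(1e6)), maximum = TRUE, tol = 1e-10)
    .hka_profile(model, exp(opt$maximum), cand)
  }
  neu <- fit1(rep(FALSE, length(model$L)))
  if (!any(candidate)) {
    return(list(lnL_neutral = neu$logL, lnL_selection = neu$logL, LRT = 0,
                df = 0L, p = 1, neutral = neu, selection = neu))
  }
  sel <- fit1(candidate)
  lrt <- max(0, 2 * (sel$logL - neu$logL))
  df <- sum(candidate)
  list(lnL_neutral = neu$logL, lnL_selection = sel$logL, LRT = lrt, df = df,
       p = stats::pchisq(lrt, df, lower.tail = FALSE),
       neutral = neu, selection = sel)
}

#' Raw divergence counts against one outgroup sequence
#'
#' Differences between each ingroup haplotype's majority-rule consensus and a
#' single outgroup row, on columns free of gaps and ambiguities.
#'
#' @param aln A `hyb_alignment` containing ingroup rows and the outgroup row.
#' @param outgroup Sample key of the outgroup row.
#' @return Integer divergence count.
#' @export
divergence_count <- function(aln, outgroup) {
  m <- unclass(mask_ambiguous_columns(aln))
  if (!outgroup %in% rownames(m)) stop("outgroup '", outgroup, "' not in alignment")
  ing <- m[setdiff(rownames(m), outgroup), , drop = FALSE]
  cons <- apply(ing, 2L, function(col) names(which.max(table(col))))
  sum(cons != m[outgroup, ])
}
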