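# Shared fixtures and independent oracles, all built in code.

aln_from_strings <- function(x, locus = "L1", marker = "nuclear") {
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x) %||% paste0("s", seq_along(x))
  alignment(m, locus_id = locus, marker = marker)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# the 4 x 8 toy alignment: S = 2, Nh = 3, k = 7/6
toy_aln <- function() {
  aln_from_strings(c(s1 = "AAAAAAAA", s2 = "AAAAAAAT",
                     s3 = "AAAAAATT", s4 = "AAAAAAAA"),
                   marker = "nuclear")
}

# independent constant-by-constant recomputation of Tajima's D
oracle_tajima_d <- function(S, k, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# brute-force pairwise enumeration of diversity statistics
oracle_diversity <- function(strings) {
  m <- do.call(rbind, strsplit(strings, ""))
  n <- nrow(m); L <- ncol(m)
  d <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
    d <- c(d, sum(m[i, ] != m[j, ]))
  list(S = sum(apply(m, 2, function(col) length(unique(col)) > 1)),
       Nh = nrow(unique(m)), k = mean(d),
       pi = mean(d) / L, theta_w = sum(apply(m, 2, function(col)
         length(unique(col)) > 1)) / (sum(1 / seq_len(n - 1)) * L))
}

# hand-built genotype container (individuals x loci allele-pair matrices)
make_genotypes <- function(a1, a2, n_alleles = NULL) {
  ind <- rownames(a1) %||% paste0("i", seq_len(nrow(a1)))
  loci <- colnames(a1) %||% paste0("L", seq_len(ncol(a1)))
  rownames(a1) <- rownames(a2) <- ind
  structure(list(a1 = a1, a2 = a2,
                 n_alleles = n_alleles %||%
                   apply(rbind(a1, a2), 2, max, na.rm = TRUE),
                 individuals = ind, loci = loci),
            class = "hyb_genotypes")
}

# two-parent diagnostic genotypes: refs fixed for alleles 1 / 2, plus hybrids
diagnostic_genotypes <- function(n_ref = 20, n_f1 = 10, n_loci = 10,
                                 extra = NULL) {
  rows <- list()
  ids <- c()
  add <- function(nm, g1, g2) {
    rows[[length(rows) + 1]] <<- list(g1, g2)
    ids <<- c(ids, nm)
  }
  for (i in seq_len(n_ref)) add(paste0("P1_", i), rep(1L, n_loci), rep(1L, n_loci))
  for (i in seq_len(n_ref)) add(paste0("P2_", i), rep(2L, n_loci), rep(2L, n_loci))
  for (i in seq_len(n_f1)) add(paste0("F1_", i), rep(1L, n_loci), rep(2L, n_loci))
  if (!is.null(extra)) for (nm in names(extra))
    add(nm, extra[[nm]][[1]], extra[[nm]][[2]])
  a1 <- do.call(rbind, lapply(rows, `[[`, 1))
  a2 <- do.call(rbind, lapply(rows, `[[`, 2))
  rownames(a1) <- rownames(a2) <- ids
  make_genotypes(a1, a2, n_alleles = rep(2L, n_loci))
}

ref_z <- function(n_ref = 20) {
  c(stats::setNames(rep("Pure1", n_ref), paste0("P1_", seq_len(n_ref))),
    stats::setNames(rep("Pure2", n_ref), paste0("P2_", seq_len(n_ref))))
}

# asymmetric three-population fixture used for the delta-K checks: unequal
# effective sizes and sample counts (delta-K is degenerate under perfect
# symmetry because replicate runs at K = 2 then all find the same merge)
threeway_fixture <- function(seed = 3) {
  ev <- data.frame(time = 60000, type = "split", a = 1:3, b = 4)
  scen <- scenario_spec(c(2000, 5000, 10000, 5000), ev, "threeway")
  simulate_scenario(scen, samples = c(16L, 24L, 32L),
                    loci = data.frame(length = rep(500L, 10), mu = 2.5e-7),
                    seed = seed, diploid = TRUE)
}

test_loci <- function(n = 10, length = 500L, mu = 2.5e-7)
  data.frame(length = rep(length, n), mu = mu)
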