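test_that("diversity statistics match brute-force enumeration on the toy alignment", {
  st <- diversity_stats(toy_aln())
  expect_equal(st$S, 2L)
  expect_equal(st$Nh, 3L)
  expect_equal(st$k, 7 / 6)
  expect_equal(st$pi, (7 / 6) / 8)
  expect_equal(st$theta_w, 2 / ((11 / 6) * 8))
  orc <- oracle_diversity(c("AAAAAAAA", "AAAAAAAT", "AAAAAATT", "AAAAAAAA"))
  expect_equal(st$k, orc$k)
  expect_equal(st$pi, orc$pi)
  expect_equal(st$theta_w, orc$theta_w)
})

test_that("degenerate alignments give the expected statistics", {
  same <- diversity_stats(aln_from_strings(rep("ACGTACGT", 4)))
  expect_equal(same$S, 0L)
  expect_equal(same$pi, 0)
  expect_equal(same$Nh, 1L)
  expect_false(same$tests_defined)
  expect_true(is.na(same$D))

  # n = 2: a1 = 1 forces pi = theta_w
  two <- diversity_stats(aln_from_strings(
    c(strrep("A", 100), paste0(strrep("A", 99), "T"))))
  expect_equal(two$pi, 0.01)
  expect_equal(two$theta_w, 0.01)
  expect_error(diversity_stats(aln_from_strings("ACGT")[1, , drop = FALSE]),
               "at least 2")
})

test_that("statistics are invariant to row order and column duplication", {
  x <- c("ACGTACGT", "ACGAACGT", "TCGTACGA", "ACGTACGA")
  a <- diversity_stats(aln_from_strings(x))
  b <- diversity_stats(aln_from_strings(x[c(3, 1, 4, 2)]))
  expect_equal(a$pi, b$pi)
  expect_equal(a$theta_w, b$theta_w)
  doubled <- diversity_stats(aln_from_strings(paste0(x, x)))
  expect_equal(doubled$pi, a$pi)       # per-site values unchanged
  expect_equal(doubled$theta_w, a$theta_w)
})

test_that("Tajima's D agrees with the constant-by-constant oracle", {
  # numerator vanishes when k = S / a1
  n <- 10; S <- 7; a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(S, S / a1, n), 0)
  st <- diversity_stats(toy_aln())
  expect_equal(st$D, oracle_tajima_d(2, 7 / 6, 4))
  for (case in list(c(12, 3.1, 8), c(40, 11, 25), c(1, 0.2, 4)))
    expect_equal(tajimas_d(case[1], case[2], case[3]),
                 oracle_tajima_d(case[1], case[2], case[3]))
  expect_true(is.na(tajimas_d(0, 0, 10)))
})

test_that("Fu & Li's D* and F* behave sensibly and flag S = 0", {
  expect_true(all(is.na(fu_li_star_from_counts(0, 0, 0, 10))))
  # no singletons and balanced k: finite values, negative singleton deficit
  # pushes both statistics positive
  v <- fu_li_star_from_counts(eta = 10, eta_s = 0, k = 10 / sum(1 / (1:19)), n = 20)
  expect_true(all(is.finite(v)))
  expect_true(all(v > 0))
  # an excess of singletons drives both statistics negative
  v2 <- fu_li_star_from_counts(eta = 10, eta_s = 9, k = 1.2, n = 20)
  expect_true(all(v2 < 0))
  aln <- aln_from_strings(c("AAAA", "AAAT", "AATA", "AAAA", "CAAA"))
  v3 <- fu_li_star(aln)
  expect_true(all(is.finite(v3)))
})

test_that("neutral coalescent means of D, D* and F* are near zero", {
  # n = 20, theta = 5 per locus, 2000 replicates
  N <- 5000; L <- 1000L; mu <- 5 / (4 * N * L)
  scen <- scenario_spec(N, data.frame(time = numeric(0), type = character(0),
                                      a = integer(0), b = integer(0)))
  set.seed(42)
  D <- Ds <- Fs <- rep(NA_real_, 2000)
  for (r in 1:2000) {
    ds <- simulate_scenario(scen, samples = 20L,
                            loci = data.frame(length = L, mu = mu),
                            diploid = FALSE)
    st <- diversity_stats(ds$alignments[[1]])
    D[r] <- st$D; Ds[r] <- st$Dstar; Fs[r] <- st$Fstar
  }
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.1)
  expect_lt(abs(mean(Ds, na.rm = TRUE)), 0.15)
  expect_lt(abs(mean(Fs, na.rm = TRUE)), 0.15)
})

test_that("divergence counting uses the ingroup consensus on clean columns", {
  aln <- aln_from_strings(c(i1 = "AACGT", i2 = "AACGT", i3 = "AACTT",
                            out = "TACTA"))
  expect_equal(divergence_count(aln, "out"), 3L)
  expect_error(divergence_count(aln, "nope"), "not in alignment")
})

test_that("the ML-HKA test is exact for nested degenerate cases", {
  m <- hka_model(L = rep(500, 4), n = rep(10, 4), S = c(7, 8, 6, 40),
                 div = rep(8, 4))
  none <- mlhka_test(m, character(0))
  expect_equal(none$LRT, 0)
  expect_equal(none$p, 1)
  res <- mlhka_test(m, "locus4")
  expect_gte(res$LRT, 0)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 0.05)  # 5x polymorphism excess at locus 4
  expect_gt(res$selection$k[4], 2)
  expect_error(mlhka_test(m, "nolocus"), "unknown candidate")
})

test_that("the LRT is non-negative on random data", {
  set.seed(99)
  for (r in 1:25) {
    S <- rpois(5, 8); dv <- rpois(5, 8)
    m <- hka_model(rep(400, 5), rep(8, 5), S, dv)
    expect_gte(mlhka_test(m, sample(m$locus_id, 2))$LRT, -1e-9)
  }
})

test_that("the ML-HKA test is calibrated and has power", {
  theta <- 0.005; L <- 500; n <- 10; Tdiv <- 2
  a <- sum(1 / seq_len(n - 1))
  set.seed(7)
  rej <- 0L
  for (r in 1:200) {
    m <- hka_model(rep(L, 10), rep(n, 10), rpois(10, theta * L * a),
                   rpois(10, theta * L * (Tdiv + 1)))
    if (mlhka_test(m, "locus1")$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.08)
  set.seed(8)
  pow <- 0L
  for (r in 1:200) {
    m <- hka_model(rep(L, 10), rep(n, 10),
                   rpois(10, theta * L * a * c(5, rep(1, 9))),
                   rpois(10, theta * L * (Tdiv + 1)))
    if (mlhka_test(m, "locus1")$p < 0.05) pow <- pow + 1L
  }
  expect_gte(pow / 200, 0.8)
})
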