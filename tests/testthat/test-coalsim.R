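test_that("scenario validation catches structural violations", {
  # admixture rate outside [0, 1]
  ev_bad_r <- data.frame(time = 100, type = "admix", a = 3, b = 1, c = 2,
                         rate = 1.3)
  expect_match(paste(validate_scenario(list(pop_sizes = rep(100, 4),
                                            events = ev_bad_r)), collapse = ";"),
               "rates")
  # admixture older than the parents' merge into a common ancestor strands
  # the hybrid lineages
  ev_strand <- data.frame(time = c(50, 50, 200),
                          type = c("split", "split", "admix"),
                          a = c(1, 2, 3), b = c(4, 4, 1), c = c(NA, NA, 2),
                          rate = c(NA, NA, 0.5))
  expect_match(paste(validate_scenario(list(pop_sizes = rep(100, 4),
                                            events = ev_strand)), collapse = ";"),
               "single root")
  # hybrid-origin scenario is valid
  ev_ok <- data.frame(time = c(10, 100, 100),
                      type = c("admix", "split", "split"),
                      a = c(3, 1, 2), b = c(1, 4, 4), c = c(2, NA, NA),
                      rate = c(0.5, NA, NA))
  expect_length(validate_scenario(list(pop_sizes = rep(100, 4),
                                       events = ev_ok)), 0)
  expect_s3_class(scenario_spec(rep(100, 4), ev_ok), "hyb_scenario")
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  ev <- data.frame(time = c(100, 500, 500), type = c("admix", "split", "split"),
                   a = c(3, 1, 2), b = c(1, 4, 4), c = c(2, NA, NA),
                   rate = c(0.3, NA, NA))
  scen <- scenario_spec(rep(1000, 4), ev)
  d1 <- simulate_scenario(scen, samples = c(4L, 4L, 4L), loci = test_loci(3),
                          seed = 11, diploid = TRUE)
  d2 <- simulate_scenario(scen, samples = c(4L, 4L, 4L), loci = test_loci(3),
                          seed = 11, diploid = TRUE)
  expect_identical(lapply(d1$alignments, unclass), lapply(d2$alignments, unclass))
})

test_that("mean TMRCA of two lineages is close to 2N generations", {
  tm <- sim_tmrca(N = 1000, n = 2, reps = 5000, seed = 5)
  expect_lt(abs(mean(tm) / 2000 - 1), 0.05)
})

test_that("pairwise diversity and segregating sites match coalescent expectations", {
  # E[pi] = theta per site; E[S] = a_n * theta * L
  N <- 5000; L <- 300L; theta <- 0.005; mu <- theta / (4 * N); n <- 10
  scen <- scenario_spec(N, data.frame(time = numeric(0), type = character(0),
                                      a = integer(0), b = integer(0)))
  set.seed(9)
  pis <- Ss <- numeric(5000)
  for (r in 1:5000) {
    ds <- simulate_scenario(scen, samples = n,
                            loci = data.frame(length = L, mu = mu),
                            diploid = FALSE)
    st <- diversity_stats(ds$alignments[[1]])
    pis[r] <- st$pi; Ss[r] <- st$S
  }
  expect_lt(abs(mean(pis) / theta - 1), 0.05)
  expect_lt(abs(mean(Ss) / (sum(1 / seq_len(n - 1)) * theta * L) - 1), 0.05)
})

test_that("an admixture pulse with r = 1 behaves like a pure split", {
  # pop 3 fully sourced from pop 1 vs the same history written as a split
  loci <- test_loci(1, length = 500L)
  ev_admix <- data.frame(time = c(200, 4000, 4000),
                         type = c("admix", "split", "split"),
                         a = c(3, 1, 2), b = c(1, 4, 4), c = c(2, NA, NA),
                         rate = c(1, NA, NA))
  ev_split <- data.frame(time = c(200, 4000, 4000), type = "split",
                         a = c(3, 1, 2), b = c(1, 4, 4))
  k_of <- function(ev, seed) {
    scen <- scenario_spec(rep(1000, 4), ev)
    vapply(1:400, function(r) {
      ds <- simulate_scenario(scen, samples = c(0L, 0L, 4L), loci = loci,
                              seed = seed + r, diploid = FALSE)
      diversity_stats(ds$alignments[[1]])$k
    }, 0)
  }
  ks1 <- k_of(ev_admix, 1000)
  ks2 <- k_of(ev_split, 9000)
  expect_gt(suppressWarnings(stats::ks.test(ks1, ks2)$p.value), 0.01)
})

test_that("a split at effectively zero time equals panmixia", {
  loci <- test_loci(1, length = 500L)
  ev <- data.frame(time = 1e-9, type = "split", a = 1, b = 2)
  split0 <- scenario_spec(c(1000, 1000), ev)
  pan <- scenario_spec(1000, data.frame(time = numeric(0), type = character(0),
                                        a = integer(0), b = integer(0)))
  k1 <- vapply(1:400, function(r) {
    ds <- simulate_scenario(split0, samples = c(3L, 3L), loci = loci,
                            seed = r, diploid = FALSE)
    diversity_stats(ds$alignments[[1]])$k
  }, 0)
  k2 <- vapply(1:400, function(r) {
    ds <- simulate_scenario(pan, samples = 6L, loci = loci,
                            seed = 5000 + r, diploid = FALSE)
    diversity_stats(ds$alignments[[1]])$k
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(k1, k2)$p.value), 0.01)
})

test_that("stranded lineages are reported, not looped on", {
  ev <- data.frame(time = c(50, 50, 200), type = c("split", "split", "admix"),
                   a = c(1, 2, 3), b = c(4, 4, 1), c = c(NA, NA, 2),
                   rate = c(NA, NA, 0.5))
  bad <- structure(list(name = "bad", pop_sizes = rep(100, 4), events = ev),
                   class = "hyb_scenario")
  expect_error(simulate_scenario(bad, samples = c(2L, 2L, 2L),
                                 loci = test_loci(1), seed = 1,
                                 diploid = FALSE),
               "stranded")
})
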