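test_that("scenario libraries have the documented structure", {
  trio <- scenario_library("trio")
  quartet <- scenario_library("quartet")
  expect_length(trio, 7L)
  expect_length(quartet, 7L)
  expect_equal(sum(trio[[1]]$events$type == "admix"), 0L)
  # the two-step trihybrid scenario: two admixture pulses, the more recent
  # one founding the focal population from the intermediate lineage
  q6 <- quartet[[6]]
  adm <- q6$events[q6$events$type == "admix", ]
  expect_equal(nrow(adm), 2L)
  expect_equal(adm$t_param, c("t3", "t2"))
  expect_equal(adm$a, c(4, 5))
  # every template instantiates to a valid scenario
  for (tpl in c(trio, quartet)) {
    pars <- sample_priors(default_priors(tpl), 1, seed = 1)[1, ]
    expect_length(validate_scenario(instantiate_scenario(tpl, pars)), 0)
  }
  expect_error(scenario_library("duo"))
})

test_that("prior sampling respects bounds, constraints, and means", {
  tpl <- scenario_library("trio")[[5]]
  pr <- default_priors(tpl, N_bounds = c(100, 10000))
  x <- sample_priors(pr, 10000, seed = 2)
  expect_true(all(x[, "N1"] >= 100 & x[, "N1"] <= 10000))
  expect_true(all(x[, "t1"] < x[, "t0"]))
  expect_true(all(x[, "r1"] >= 0.05 & x[, "r1"] <= 0.95))
  # uniform times: mean of the min/max pair still checkable on the raw draw
  u <- sample_priors(structure(list(params = data.frame(
    name = "t", dist = "unif", min = 10, max = 1010), constraints = list()),
    class = "hyb_priors"), 20000, seed = 3)
  expect_lt(abs(mean(u) - 510) / 510, 0.01)
  # unsatisfiable constraint
  bad <- structure(list(params = data.frame(
    name = c("a", "b"), dist = "unif", min = c(10, 0), max = c(20, 1)),
    constraints = list(c("a", "b"))), class = "hyb_priors")
  expect_error(sample_priors(bad, 10, seed = 1, max_attempts = 5),
               "unsatisfiable")
})

test_that("summary statistics agree with the diversity module and count correctly", {
  strings <- c("AAAAAAAA", "AAAAAAAT", "AAAAAATT", "AAAAAAAA")
  aln <- aln_from_strings(setNames(strings, paste0("i", 1:4)),
                          marker = "nuclear")
  samples <- sample_table(data.frame(individual_id = paste0("i", 1:4),
                                     taxon = "t", population = "p"))
  ds <- multilocus_dataset(list(aln), samples)
  st <- summary_statistics(ds, list(pop1 = paste0("i", 1:4)))
  expect_length(st, 5L)
  expect_equal(unname(st["pop1_S"]), 2)
  expect_equal(unname(st["pop1_k"]), 7 / 6)
  expect_equal(unname(st["pop1_Nh"]), 3)
  expect_equal(unname(st["pop1_D"]), oracle_tajima_d(2, 7 / 6, 4))

  # vector length is 5P + 2 C(P,2); monomorphic data give zeros and a mask
  aln0 <- aln_from_strings(setNames(rep("ACGTACGT", 6), paste0("i", 1:6)))
  ds0 <- multilocus_dataset(
    list(aln0), sample_table(data.frame(individual_id = paste0("i", 1:6),
                                        taxon = "t", population = "p")))
  pops <- list(a = paste0("i", 1:2), b = paste0("i", 3:4), c = paste0("i", 5:6))
  st0 <- summary_statistics(ds0, pops)
  expect_length(st0, 5 * 3 + 2 * 3)
  # monomorphic data: one haplotype per population, every other entry zero
  expect_equal(unname(st0[grep("_Nh$", names(st0))]), rep(1, 3))
  expect_true(all(st0[-grep("_Nh$", names(st0))] == 0))
  expect_true(all(attr(st0, "mask")[grep("_D$|_fst$", names(st0))]))
})

test_that("rejection retains the closest records like a full sort", {
  set.seed(12)
  stats <- matrix(rnorm(1000 * 4), 1000, 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
  obs <- rnorm(4)
  rej <- abc_rejection(obs, stats, tolerance = 0.05)
  # brute-force standardised-distance sort
  sds <- apply(stats, 2, sd)
  d <- sqrt(colSums(((t(stats) - obs) / sds)^2))
  expect_equal(sort(rej$index), sort(order(d)[1:50]))
  # the row equal to the observation ranks first
  stats2 <- rbind(stats, obs)
  expect_equal(abc_rejection(obs, stats2, 0.01)$index[1], 1001L)
  # tolerance 1 retains everything
  expect_length(abc_rejection(obs, stats, 1)$index, 1000L)
  expect_error(abc_rejection(obs, stats, 0), "tolerance")
  # rescaling any statistic does not change the retained set
  stats3 <- stats; stats3[, 2] <- stats3[, 2] * 1000
  obs3 <- obs; obs3[2] <- obs3[2] * 1000
  expect_equal(abc_rejection(obs3, stats3, 0.05)$index, rej$index)
  # zero-variance columns are dropped with a warning
  stats4 <- cbind(stats, flat = 1)
  expect_warning(abc_rejection(c(obs, 1), stats4, 0.05), "zero-variance")
})

test_that("scenario posteriors handle degenerate and symmetric cases", {
  set.seed(13)
  one <- scenario_posterior(rep(2L, 50), matrix(rnorm(100), 50, 2), c(0, 0),
                            n_scenarios = 3, ci_boot = 0)
  expect_equal(one$table$posterior, c(0, 1, 0))
  # two scenarios with identically distributed statistics: each near 0.5
  st <- matrix(rnorm(800), 400, 2)
  res <- scenario_posterior(rep(1:2, each = 200), st, c(0, 0),
                            n_scenarios = 2, ci_boot = 100, seed = 14)
  expect_equal(sum(res$table$posterior), 1, tolerance = 1e-6)
  expect_true(all(res$table$lo95 <= res$table$posterior + 1e-9))
  expect_true(all(res$table$hi95 >= res$table$posterior - 1e-9))
  expect_true(res$table$lo95[1] < 0.5 & res$table$hi95[1] > 0.5)
})

test_that("posterior probabilities are invariant to scenario ordering", {
  set.seed(15)
  st <- rbind(matrix(rnorm(300, 0), 150, 2), matrix(rnorm(300, 3), 150, 2))
  sc <- rep(1:2, each = 150)
  obs <- c(2.5, 2.5)
  a <- scenario_posterior(sc, st, obs, n_scenarios = 2, ci_boot = 0)
  b <- scenario_posterior(3L - sc, st, obs, n_scenarios = 2, ci_boot = 0)
  expect_equal(a$table$posterior, rev(b$table$posterior), tolerance = 1e-6)
})

test_that("run_abc wires the table, rejection and regression together", {
  loci <- test_loci(4)
  tab <- abc_reference_table(scenario_library("trio")[c(1, 5)],
                             samples = rep(6L, 3), loci = loci, n_sims = 300,
                             seed = 16)
  expect_equal(dim(tab$stats), c(600L, 5 * 3 + 2 * 3))
  scen <- instantiate_scenario(
    scenario_library("trio")[[5]],
    c(N1 = 5000, N2 = 5000, N3 = 5000, Na = 5000, t0 = 30000, t1 = 1000,
      r1 = 0.5))
  pod <- simulate_scenario(scen, samples = rep(6L, 3), loci = loci, seed = 17,
                           diploid = TRUE)
  obs <- summary_statistics(pod, split(pod$samples$individual_id,
                                       pod$samples$taxon)[paste0("pop", 1:3)])
  res <- suppressWarnings(run_abc(obs, table = tab, tolerance = 0.05,
                                  ci_boot = 0, seed = 18))
  expect_equal(sum(res$table$posterior), 1, tolerance = 1e-6)
  expect_gt(res$table$posterior[2], res$table$posterior[1])
  expect_error(abc_reference_table("trio", rep(6L, 3), loci, n_sims = 0),
               "n_sims")
})
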