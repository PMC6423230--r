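# R-side interface to the coalescent engine: demographic scenarios as data,
# validation, and simulation of multilocus datasets.
#
# A scenario is a demographic DAG read backward in time. Populations are
# integers 1..n_pops. Two event kinds:
#   split(t, a -> b):       all lineages of population a move into b;
#   admix(t, a; b, c, r):   each lineage of hybrid population a moves to
#                           parent b with probability r, else to parent c.
# Times are generations; the within-population pair-coalescence rate is
# k(k-1)/2 per 2N generations.

#' Construct a concrete demographic scenario
#'
#' @param pop_sizes Numeric vector of effective population sizes, one per
#'   population (index = population id).
#' @param events Data frame with columns `time`, `type` (`"split"` or
#'   `"admix"`), `a`, `b`, `c` (`NA` for splits) and `rate` (`NA` for splits);
#'   see the package vignette for the conventions.
#' @param name Optional label.
#' @return Object of class `hyb_scenario`.
#' @export
scenario_spec <- function(pop_sizes, events, name = "scenario") {
  if (is.null(events$c)) events$c <- rep(NA_integer_, nrow(events))
  if (is.null(events$rate)) events$rate <- rep(NA_real_, nrow(events))
  out <- structure(list(name = name, pop_sizes = as.numeric(pop_sizes),
                        events = events), class = "hyb_scenario")
  v <- validate_scenario(out)
  if (length(v)) stop("invalid scenario '", name, "': ", paste(v, collapse = "; "))
  out
}

#' Validate a demographic scenario
#'
#' Checks positivity of sizes and times, admixture rates in `[0, 1]`, and that
#' the event sequence funnels every population holding lineages into a single
#' root (no stranded lineages).
#'
#' @param scenario A `hyb_scenario` (or an unvalidated list with the same
#'   fields).
#' @return Character vector of violations; empty when the scenario is valid.
#' @export
validate_scenario <- function(scenario) {
  bad <- character(0)
  N <- scenario$pop_sizes
  ev <- scenario$events
  if (any(!is.finite(N)) || any(N <= 0)) bad <- c(bad, "all population sizes must be > 0")
  if (nrow(ev)) {
    if (any(!is.finite(ev$time)) || any(ev$time <= 0))
      bad <- c(bad, "event times must be strictly positive")
    if (!all(ev$type %in% c("split", "admix")))
      bad <- c(bad, "event type must be 'split' or 'admix'")
    adm <- ev$type == "admix"
    if (any(adm) && (any(is.na(ev$rate[adm])) || any(ev$rate[adm] < 0 | ev$rate[adm] > 1)))
      bad <- c(bad, "admixture rates must lie in [0, 1]")
    pops <- seq_along(N)
    used <- c(ev$a, ev$b, ev$c[adm])
    if (any(!used %in% pops)) bad <- c(bad, "event references an unknown population")
  }
  if (length(bad)) return(bad)
  # reachability: process events oldest-last and track which populations can
  # still hold lineages; a valid scenario ends with exactly one
  alive <- seq_along(N)
  if (nrow(ev)) {
    ord <- order(ev$time)
    for (i in ord) {
      if (!(ev$a[i] %in% alive)) next
      alive <- setdiff(alive, ev$a[i])
      alive <- union(alive, ev$b[i])
      if (ev$type[i] == "admix") alive <- union(alive, ev$c[i])
    }
  }
  if (length(alive) != 1L)
    bad <- c(bad, paste0("lineages cannot all reach a single root (terminal populations: ",
                         paste(sort(alive), collapse = ", "), ")"))
  bad
}

# encode events for the C++ engine
.encode_events <- function(events) {
  type <- ifelse(events$type == "split", 0L, 1L)
  code <- cbind(type, as.integer(events$a), as.integer(events$b),
                ifelse(is.na(events$c), 0L, as.integer(events$c)))
  storage.mode(code) <- "integer"
  list(code = code, t = as.numeric(events$time),
       r = ifelse(is.na(events$rate), 0, as.numeric(events$rate)))
}

.int_to_base <- c("A", "C", "G", "T")

#' Simulate a multilocus dataset under a demographic scenario
#'
#' Runs the structured coalescent with instantaneous split/admixture events,
#' drops Jukes-Cantor mutations on the genealogy (Poisson with rate
#' `mu * length` per branch generation), and packages the result in the same
#' alignment/metadata containers the rest of the package consumes. Loci are
#' unlinked and free of intralocus recombination.
#'
#' @param scenario A `hyb_scenario`.
#' @param samples Integer vector: haploid sample count per population
#'   (`samples[p]` lineages from population `p`; 0 allowed).
#' @param loci Data frame with columns `length` (bp) and `mu` (mutation rate
#'   per site per generation); one row per locus.
#' @param seed Optional RNG seed; given the same scenario, loci and seed the
#'   output is bit-identical.
#' @param marker Marker kind of the emitted alignments.
#' @param diploid For nuclear markers, pair consecutive lineages into diploid
#'   individuals (`ind<j>/1`, `ind<j>/2`); otherwise one row per lineage.
#' @param prefix Prefix for generated individual ids.
#' @return A `hyb_dataset`; the sample table's `taxon` is `pop<p>`.
#' @export
simulate_scenario <- function(scenario, samples, loci, seed = NULL,
                              marker = "nuclear", diploid = (marker == "nuclear"),
                              prefix = "sim") {
  .maybe_seed(seed)
  if (length(samples) < length(scenario$pop_sizes))
    samples <- c(samples, rep(0L, length(scenario$pop_sizes) - length(samples)))
  samp_pop <- rep(seq_along(samples), samples)
  if (length(samp_pop) < 2L) stop("need at least 2 sampled lineages")
  if (diploid && any(samples %% 2L != 0L))
    stop("diploid output needs an even haploid sample count per population")
  enc <- .encode_events(scenario$events)
  mats <- .sim_dataset_cpp(scenario$pop_sizes, enc$code, enc$t, enc$r,
                           as.integer(samp_pop), as.integer(loci$length),
                           as.numeric(loci$mu))
  if (diploid) {
    ind <- paste0(prefix, rep(seq_len(length(samp_pop) / 2L), each = 2L))
    keys <- paste0(ind, "/", rep(1:2, length.out = length(samp_pop)))
    ind_pop <- samp_pop[seq(1L, length(samp_pop), by = 2L)]
    ids <- unique(ind)
  } else {
    keys <- paste0(prefix, seq_along(samp_pop))
    ind_pop <- samp_pop
    ids <- keys
  }
  alns <- lapply(seq_along(mats), function(l) {
    m <- matrix(.int_to_base[mats[[l]] + 1L], nrow(mats[[l]]), ncol(mats[[l]]))
    rownames(m) <- keys
    alignment(m, locus_id = paste0("locus", l), marker = marker)
  })
  samples_df <- sample_table(data.frame(
    individual_id = ids, taxon = paste0("pop", ind_pop),
    population = paste0("pop", ind_pop), role = "candidate_hybrid",
    stringsAsFactors = FALSE))
  multilocus_dataset(alns, samples_df)
}

#' Simulated TMRCA of a panmictic sample
#'
#' Convenience wrapper used to check the engine against coalescent closed
#' forms (for `n = 2` the expectation is `2N` generations).
#'
#' @param N Effective population size.
#' @param n Haploid sample size.
#' @param reps Number of replicate genealogies.
#' @param seed Optional seed.
#' @return Numeric vector of root ages in generations.
#' @export
sim_tmrca <- function(N, n, reps, seed = NULL) {
  .maybe_seed(seed)
  .sim_tmrca_cpp(N, as.integer(n), as.integer(reps))
}
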