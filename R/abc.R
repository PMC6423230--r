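# Approximate Bayesian computation scenario comparison: scenario libraries
# for the trio (two parents + putative hybrid) and quartet (three parents +
# putative trihybrid) designs, prior sampling, summary statistics, rejection,
# and logistic-regression posterior probabilities.

.template <- function(name, description, pop_size_params, events, constraints) {
  structure(list(name = name, description = description,
                 pop_size_params = pop_size_params, events = events,
                 constraints = constraints),
            class = "hyb_scenario_template")
}

.ev <- function(type, a, b, c = NA_integer_, t_param, r_param = NA_character_) {
  data.frame(type = type, a = a, b = b, c = c, t_param = t_param,
             r_param = r_param, stringsAsFactors = FALSE)
}

#' Scenario libraries for hybrid-origin model choice
#'
#' `"trio"`: seven scenarios over two candidate parent species (populations 1
#' and 2) and one putative hybrid taxon (population 3): (1) a simultaneous
#' three-way split at `t0`; (2)-(4) a split at `t0` followed by one lineage
#' splitting again at `t1`, one scenario per topology; (5)-(7) two species
#' splitting at `t0` with a new lineage generated by an admixture pulse at
#' `t1`, one scenario per choice of hybrid population (scenario 5: population
#' 3 is the hybrid of 1 and 2).
#'
#' `"quartet"`: seven scenarios over three parent species (1 and 2 sister,
#' diverging at `t1` with their ancestor separating from species 3 at `t0`)
#' and one putative trihybrid taxon (population 4): (1) population 4 branches
#' from the root ancestor at `t0`; (2) it descends from species 3 at `t2`;
#' (3) it descends from the ancestor of 1 and 2 at `t2`; (4) it is the hybrid
#' of species 3 and the 1/2 ancestor at `t2`; (5)-(7) two-step trihybrid
#' scenarios in which a first cross at `t2` forms an intermediate lineage
#' that crosses again at `t3` to found population 4 — scenario 5: (1 x 2)
#' then x 3; scenario 6: (1 x 3) then x 2; scenario 7: (2 x 3) then x 1.
#'
#' @param name `"trio"` or `"quartet"`.
#' @return List of 7 scenario templates carrying parameter names, events and
#'   ordering constraints; combine with [default_priors()] and [run_abc()].
#' @export
scenario_library <- function(name = c("trio", "quartet")) {
  name <- match.arg(name)
  if (name == "trio") {
    N123 <- c("N1", "N2", "N3")
    list(
      .template("trio1", "simultaneous three-way split at t0",
                c(N123, "Na"),
                rbind(.ev("split", 1, 4, t_param = "t0"),
                      .ev("split", 2, 4, t_param = "t0"),
                      .ev("split", 3, 4, t_param = "t0")),
                list()),
      .template("trio2", "split at t0; populations 1 and 2 split at t1",
                c(N123, "Nb", "Na"),
                rbind(.ev("split", 1, 4, t_param = "t1"),
                      .ev("split", 2, 4, t_param = "t1"),
                      .ev("split", 4, 5, t_param = "t0"),
                      .ev("split", 3, 5, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("trio3", "split at t0; populations 1 and 3 split at t1",
                c(N123, "Nb", "Na"),
                rbind(.ev("split", 1, 4, t_param = "t1"),
                      .ev("split", 3, 4, t_param = "t1"),
                      .ev("split", 4, 5, t_param = "t0"),
                      .ev("split", 2, 5, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("trio4", "split at t0; populations 2 and 3 split at t1",
                c(N123, "Nb", "Na"),
                rbind(.ev("split", 2, 4, t_param = "t1"),
                      .ev("split", 3, 4, t_param = "t1"),
                      .ev("split", 4, 5, t_param = "t0"),
                      .ev("split", 1, 5, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("trio5", "populations 1 and 2 split at t0; 3 is their hybrid (rate r1 from 1)",
                c(N123, "Na"),
                rbind(.ev("admix", 3, 1, 2, t_param = "t1", r_param = "r1"),
                      .ev("split", 1, 4, t_param = "t0"),
                      .ev("split", 2, 4, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("trio6", "populations 2 and 3 split at t0; 1 is their hybrid",
                c(N123, "Na"),
                rbind(.ev("admix", 1, 2, 3, t_param = "t1", r_param = "r1"),
                      .ev("split", 2, 4, t_param = "t0"),
                      .ev("split", 3, 4, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("trio7", "populations 1 and 3 split at t0; 2 is their hybrid",
                c(N123, "Na"),
                rbind(.ev("admix", 2, 1, 3, t_param = "t1", r_param = "r1"),
                      .ev("split", 1, 4, t_param = "t0"),
                      .ev("split", 3, 4, t_param = "t0")),
                list(c("t1", "t0"))))
  } else {
    bg <- rbind(.ev("split", 1, 5, t_param = "t1"),
                .ev("split", 2, 5, t_param = "t1"),
                .ev("split", 5, 6, t_param = "t0"),
                .ev("split", 3, 6, t_param = "t0"))
    N14 <- c("N1", "N2", "N3", "N4")
    # pops: 1,2,3 parents; 4 focal taxon; 5 ancestor of 1+2; 6 root
    # (scenarios 5-7 insert the intermediate hybrid as pop 5 and shift
    #  the ancestors to 6 and 7)
    bg7 <- rbind(.ev("split", 1, 6, t_param = "t1"),
                 .ev("split", 2, 6, t_param = "t1"),
                 .ev("split", 6, 7, t_param = "t0"),
                 .ev("split", 3, 7, t_param = "t0"))
    list(
      .template("quartet1", "population 4 branches from the root ancestor at t0",
                c(N14, "Nb", "Na"),
                rbind(bg, .ev("split", 4, 6, t_param = "t0")),
                list(c("t1", "t0"))),
      .template("quartet2", "population 4 descends from species 3 at t2",
                c(N14, "Nb", "Na"),
                rbind(.ev("split", 4, 3, t_param = "t2"), bg),
                list(c("t2", "t1"), c("t1", "t0"))),
      .template("quartet3", "population 4 descends from the ancestor of 1 and 2 at t2",
                c(N14, "Nb", "Na"),
                rbind(.ev("split", 4, 5, t_param = "t2"), bg),
                list(c("t1", "t2"), c("t2", "t0"))),
      .template("quartet4", "population 4 is the hybrid of species 3 and the 1/2 ancestor",
                c(N14, "Nb", "Na"),
                rbind(.ev("admix", 4, 3, 5, t_param = "t2", r_param = "r1"), bg),
                list(c("t1", "t2"), c("t2", "t0"))),
      .template("quartet5", "(1 x 2) at t2, then x 3 at t3 founds population 4",
                c(N14, "Ni", "Nb", "Na"),
                rbind(.ev("admix", 4, 5, 3, t_param = "t3", r_param = "r2"),
                      .ev("admix", 5, 1, 2, t_param = "t2", r_param = "r1"),
                      bg7),
                list(c("t3", "t2"), c("t2", "t1"), c("t1", "t0"))),
      .template("quartet6", "(1 x 3) at t2, then x 2 at t3 founds population 4",
                c(N14, "Ni", "Nb", "Na"),
                rbind(.ev("admix", 4, 5, 2, t_param = "t3", r_param = "r2"),
                      .ev("admix", 5, 1, 3, t_param = "t2", r_param = "r1"),
                      bg7),
                list(c("t3", "t2"), c("t2", "t1"), c("t1", "t0"))),
      .template("quartet7", "(2 x 3) at t2, then x 1 at t3 founds population 4",
                c(N14, "Ni", "Nb", "Na"),
                rbind(.ev("admix", 4, 5, 1, t_param = "t3", r_param = "r2"),
                      .ev("admix", 5, 2, 3, t_param = "t2", r_param = "r1"),
                      bg7),
                list(c("t3", "t2"), c("t2", "t1"), c("t1", "t0"))))
  }
}

.template_params <- function(tpl) {
  unique(c(tpl$pop_size_params, tpl$events$t_param,
           tpl$events$r_param[!is.na(tpl$events$r_param)]))
}

#' Default priors for a scenario template
#'
#' Effective sizes: log-uniform on `[1e2, 1e5]`; event times: uniform on
#' `[10, 1e5]` generations, subject to the template's ordering constraints;
#' admixture rates: uniform on `[0.05, 0.95]`. All bounds can be overridden.
#'
#' @param template A scenario template from [scenario_library()].
#' @param N_bounds,t_bounds,r_bounds Length-2 numeric bounds.
#' @return Object of class `hyb_priors` (parameter table + constraints).
#' @export
default_priors <- function(template, N_bounds = c(1e2, 1e5),
                           t_bounds = c(10, 1e5), r_bounds = c(0.05, 0.95)) {
  pars <- .template_params(template)
  kind <- ifelse(pars %in% template$pop_size_params, "N",
                 ifelse(grepl("^r", pars), "r", "t"))
  tab <- data.frame(
    name = pars,
    dist = ifelse(kind == "N", "logunif", "unif"),
    min = ifelse(kind == "N", N_bounds[1], ifelse(kind == "r", r_bounds[1], t_bounds[1])),
    max = ifelse(kind == "N", N_bounds[2], ifelse(kind == "r", r_bounds[2], t_bounds[2])),
    stringsAsFactors = FALSE)
  structure(list(params = tab, constraints = template$constraints),
            class = "hyb_priors")
}

#' Sample parameter draws from a prior specification
#'
#' Independent draws per parameter; ordering constraints (`a < b`) are
#' enforced by resampling violating rows.
#'
#' @param priors A `hyb_priors`.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param max_attempts Resampling rounds before giving up.
#' @return Numeric matrix `n x n_params` with parameter names as columns.
#' @export
sample_priors <- function(priors, n, seed = NULL, max_attempts = 1000L) {
  .maybe_seed(seed)
  tab <- priors$params
  draw <- function(m) {
    out <- matrix(0, m, nrow(tab), dimnames = list(NULL, tab$name))
    for (j in seq_len(nrow(tab))) {
      out[, j] <- if (tab$dist[j] == "logunif")
        exp(stats::runif(m, log(tab$min[j]), log(tab$max[j])))
      else stats::runif(m, tab$min[j], tab$max[j])
    }
    out
  }
  x <- draw(n)
  ok <- function(m) {
    good <- rep(TRUE, nrow(m))
    for (cs in priors$constraints) good <- good & (m[, cs[1]] < m[, cs[2]])
    good
  }
  good <- ok(x)
  attempts <- 0L
  while (any(!good)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("prior constraints unsatisfiable after ", max_attempts, " attempts")
    x[!good, ] <- draw(sum(!good))
    good <- ok(x)
  }
  x
}

#' Instantiate a scenario template at concrete parameter values
#'
#' @param template A scenario template.
#' @param params Named numeric vector covering the template's parameters.
#' @return A concrete `hyb_scenario` for [simulate_scenario()].
#' @export
instantiate_scenario <- function(template, params) {
  pars <- .template_params(template)
  miss <- setdiff(pars, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  ev <- data.frame(time = as.numeric(params[template$events$t_param]),
                   type = template$events$type,
                   a = template$events$a, b = template$events$b,
                   c = template$events$c,
                   rate = ifelse(is.na(template$events$r_param), NA_real_,
                                 as.numeric(params[template$events$r_param])))
  scenario_spec(as.numeric(params[template$pop_size_params]), ev,
                name = template$name)
}

#' Summary-statistic vector of a multilocus dataset
#'
#' Per population: number of distinct haplotypes, segregating sites, mean and
#' variance of pairwise difference counts, Tajima's D; per population pair:
#' mean between-population pairwise differences and Hudson's FST
#' (`1 - Hw/Hb`). All statistics are computed per locus after complete
#' deletion of gapped/ambiguous columns and averaged over loci. Undefined
#' entries (D with `S = 0`, FST with no between-population differences) are
#' imputed as 0 and recorded in the `mask` attribute.
#'
#' @param dataset A `hyb_dataset`.
#' @param populations Named list: population label -> individual ids.
#' @param marker Marker kind to use.
#' @return Named numeric vector of length `5 P + 2 C(P, 2)` with a logical
#'   `mask` attribute marking imputed entries.
#' @export
summary_statistics <- function(dataset, populations, marker = "nuclear") {
  P <- length(populations)
  if (P < 1L) stop("need at least one population")
  alns <- Filter(function(a) attr(a, "marker") == marker, dataset$alignments)
  labs <- names(populations)
  stat_names <- c(
    as.vector(t(outer(labs, c("Nh", "S", "k", "varK", "D"), paste, sep = "_"))),
    if (P > 1L) as.vector(t(outer(
      utils::combn(labs, 2L, paste, collapse = "."), c("kb", "fst"),
      paste, sep = "_"))))
  acc <- numeric(length(stat_names))
  imputed <- logical(length(stat_names))
  for (aln in alns) {
    m <- unclass(mask_ambiguous_columns(aln))
    ind <- .key_individual(rownames(m))
    rows <- lapply(populations, function(ids) which(ind %in% ids))
    if (any(lengths(rows) < 2L)) stop("every population needs >= 2 sampled haplotypes")
    kw <- numeric(P)
    pos <- 0L
    for (p in seq_len(P)) {
      mp <- m[rows[[p]], , drop = FALSE]
      d <- .pairwise_diffs(mp)
      S <- sum(rowSums(.base_counts(mp) > 0) > 1L)
      kw[p] <- mean(d)
      D <- if (S > 0) tajimas_d(S, kw[p], nrow(mp)) else NA_real_
      vals <- c(nrow(unique(mp)), S, kw[p],
                if (length(d) > 1L) stats::var(d) else 0, D)
      imp <- is.na(vals)
      vals[imp] <- 0
      acc[pos + 1:5] <- acc[pos + 1:5] + vals
      imputed[pos + 1:5] <- imputed[pos + 1:5] | imp
      pos <- pos + 5L
    }
    if (P > 1L) {
      for (p in seq_len(P - 1L)) for (q in seq((p + 1L), P)) {
        mp <- m[rows[[p]], , drop = FALSE]; mq <- m[rows[[q]], , drop = FALSE]
        matches <- matrix(0, nrow(mp), nrow(mq))
        for (ch in c("A", "C", "G", "T")) {
          bp <- mp == ch; bq <- mq == ch
          storage.mode(bp) <- "numeric"; storage.mode(bq) <- "numeric"
          matches <- matches + tcrossprod(bp, bq)
        }
        kb <- mean(ncol(m) - matches)
        fst <- if (kb > 0) 1 - 0.5 * (kw[p] + kw[q]) / kb else NA_real_
        imp <- is.na(fst)
        acc[pos + 1:2] <- acc[pos + 1:2] + c(kb, if (imp) 0 else fst)
        imputed[pos + 2L] <- imputed[pos + 2L] | imp
        pos <- pos + 2L
      }
    }
  }
  out <- acc / length(alns)
  names(out) <- stat_names
  attr(out, "mask") <- stats::setNames(imputed, stat_names)
  out
}

#' Simulate an ABC reference table for a scenario library
#'
#' Allocates `n_sims` prior draws to every scenario, simulates each draw's
#' multilocus dataset under the coalescent engine, and records its
#' summary-statistic vector.
#'
#' @param library List of scenario templates (or a library name for
#'   [scenario_library()]).
#' @param samples Haploid sample counts for the sampled populations.
#' @param loci Data frame with columns `length` and `mu`.
#' @param n_sims Simulations per scenario.
#' @param priors Optional list of `hyb_priors`, one per scenario
#'   (default: [default_priors()]).
#' @param seed Seed.
#' @return List of class `hyb_abc_table`: `scenario` (integer vector),
#'   `params` (per-scenario draw matrices), `stats` (matrix), `templates`.
#' @export
abc_reference_table <- function(library, samples, loci, n_sims,
                                priors = NULL, seed = NULL) {
  if (is.character(library)) library <- scenario_library(library)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  .maybe_seed(seed)
  priors <- priors %||% lapply(library, default_priors)
  n_sampled <- length(samples)
  samp_pop <- rep(seq_len(n_sampled), samples)
  stats <- vector("list", length(library))
  params <- vector("list", length(library))
  for (s in seq_along(library)) {
    tpl <- library[[s]]
    draws <- sample_priors(priors[[s]], n_sims)
    enc_t <- ifelse(tpl$events$type == "split", 0L, 1L)
    ev_code <- cbind(enc_t, tpl$events$a, tpl$events$b,
                     ifelse(is.na(tpl$events$c), 0L, tpl$events$c))
    storage.mode(ev_code) <- "integer"
    stats[[s]] <- .sim_stats_batch_cpp(
      match(tpl$pop_size_params, colnames(draws)),
      ev_code, match(tpl$events$t_param, colnames(draws)),
      ifelse(is.na(tpl$events$r_param), 0L,
             match(tpl$events$r_param, colnames(draws))),
      draws, as.integer(samp_pop), as.integer(loci$length),
      as.numeric(loci$mu), n_sampled)
    params[[s]] <- draws
  }
  structure(list(scenario = rep(seq_along(library), each = n_sims),
                 params = params, stats = do.call(rbind, stats),
                 templates = library, samples = samples, loci = loci),
            class = "hyb_abc_table")
}

#' Rejection step of ABC
#'
#' Euclidean distance on summary statistics standardised by the reference
#' table's per-statistic standard deviations; the closest
#' `ceiling(tolerance * n)` rows are retained. Zero-variance statistics are
#' dropped from the distance with a warning.
#'
#' @param observed Observed summary-statistic vector.
#' @param stats Simulated statistics matrix (rows = simulations).
#' @param tolerance Fraction of rows to retain, in `(0, 1]`.
#' @return List: `index` (retained row indices, closest first), `distance`,
#'   `dropped` (columns excluded).
#' @export
abc_rejection <- function(observed, stats, tolerance) {
  if (!nrow(stats)) stop("empty simulation table")
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  sds <- apply(stats, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep))
    warning("dropping zero-variance statistic(s): ",
            paste(colnames(stats)[!keep], collapse = ", "))
  z <- sweep(stats[, keep, drop = FALSE], 2L, sds[keep], `/`)
  zo <- observed[keep] / sds[keep]
  d <- sqrt(colSums((t(z) - zo)^2))
  n_keep <- ceiling(tolerance * nrow(stats))
  idx <- order(d)[seq_len(n_keep)]
  list(index = idx, distance = d[idx], dropped = colnames(stats)[!keep],
       tolerance = tolerance)
}

#' Scenario posterior probabilities from retained simulations
#'
#' Multinomial logistic regression of the scenario indicator on the retained
#' statistics centred at the observed vector; posterior probabilities are the
#' fitted class probabilities at the origin, with nonparametric-bootstrap 95%
#' confidence intervals. Falls back to retained-count proportions (with a
#' warning) if the regression cannot be fitted.
#'
#' @param scenario Integer/factor scenario labels of the retained rows.
#' @param stats Retained statistics matrix.
#' @param observed Observed summary-statistic vector.
#' @param n_scenarios Total number of scenarios (labels may be absent from
#'   the retained set; absent scenarios get probability 0).
#' @param ci_boot Bootstrap resamples for the CIs (0 skips CI computation).
#' @param seed Optional seed.
#' @return Object of class `hyb_abc`: data frame with `scenario`,
#'   `posterior`, `lo95`, `hi95`, plus diagnostics.
#' @export
scenario_posterior <- function(scenario, stats, observed, n_scenarios = NULL,
                               ci_boot = 200L, seed = NULL) {
  .maybe_seed(seed)
  scenario <- as.integer(scenario)
  n_scenarios <- n_scenarios %||% max(scenario)
  fit_pp <- function(sc, st) {
    present <- sort(unique(sc))
    if (length(present) == 1L) {
      pp <- numeric(n_scenarios); pp[present] <- 1
      return(pp)
    }
    X <- sweep(st, 2L, observed)
    # drop collinear-safe: multinom handles it; silence its console output
    fit <- tryCatch(
      nnet::multinom(factor(sc, levels = present) ~ X, trace = FALSE,
                     MaxNWts = 5000),
      error = function(e) NULL)
    pp <- numeric(n_scenarios)
    if (is.null(fit)) {
      warning("logistic regression failed; falling back to retained proportions")
      tab <- tabulate(sc, n_scenarios)
      return(tab / sum(tab))
    }
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
    eta <- c(0, co[, 1L])  # linear predictors at the origin (X = 0)
    pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
    pp[present] <- pr
    pp
  }
  point <- fit_pp(scenario, stats)
  lo <- hi <- rep(NA_real_, n_scenarios)
  if (ci_boot > 0L) {
    boots <- matrix(0, ci_boot, n_scenarios)
    for (b in seq_len(ci_boot)) {
      take <- sample.int(length(scenario), replace = TRUE)
      boots[b, ] <- suppressWarnings(fit_pp(scenario[take], stats[take, , drop = FALSE]))
    }
    lo <- apply(boots, 2L, stats::quantile, 0.025)
    hi <- apply(boots, 2L, stats::quantile, 0.975)
    # the bootstrap envelope must bracket the point estimate
    lo <- pmin(lo, point); hi <- pmax(hi, point)
  }
  structure(list(table = data.frame(scenario = seq_len(n_scenarios),
                                    posterior = point, lo95 = lo, hi95 = hi),
                 retained = length(scenario), ci_boot = ci_boot),
            class = "hyb_abc")
}

#' @export
print.hyb_abc <- function(x, ...) {
  cat("<hyb_abc> posterior scenario probabilities (", x$retained,
      " retained simulations)\n", sep = "")
  print(transform(x$table, posterior = round(posterior, 4),
                  lo95 = round(lo95, 4), hi95 = round(hi95, 4)))
  invisible(x)
}

#' Full ABC scenario comparison
#'
#' Simulates `n_sims` datasets per scenario from the priors, computes their
#' summary statistics, performs rejection at the given tolerance, and fits
#' the logistic-regression posterior.
#'
#' @inheritParams abc_reference_table
#' @param observed Observed summary-statistic vector (see
#'   [summary_statistics()]), computed over the same populations and loci.
#' @param tolerance Retained fraction for the rejection step.
#' @param ci_boot Bootstrap resamples for the posterior CIs.
#' @param table Optional pre-computed `hyb_abc_table` to reuse (the reference
#'   table does not depend on the observed data); when supplied, `library`,
#'   `samples`, `loci`, `n_sims` and `priors` are ignored.
#' @return A `hyb_abc` (see [scenario_posterior()]).
#' @export
run_abc <- function(observed, library = "trio", samples = NULL, loci = NULL,
                    n_sims = 1000L, tolerance = 0.01, priors = NULL,
                    seed = NULL, ci_boot = 200L, table = NULL) {
  .maybe_seed(seed)
  if (is.null(table))
    table <- abc_reference_table(library, samples, loci, n_sims, priors)
  rej <- abc_rejection(observed, table$stats, tolerance)
  res <- scenario_posterior(table$scenario[rej$index],
                            table$stats[rej$index, , drop = FALSE],
                            observed, n_scenarios = length(table$templates),
                            ci_boot = ci_boot)
  res$rejection <- rej[c("tolerance", "dropped")]
  res
}
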