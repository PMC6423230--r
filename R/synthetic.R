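# Fully labelled synthetic datasets emulating a three-species hybrid-zone
# study: parental species simulated under the coalescent, hybrids constructed
# mechanically from parental haplotypes (exact truth labels), chloroplast
# haplotypes inherited from the designated maternal species. Chloroplast loci
# are simulated as one completely linked block (a single non-recombining
# molecule) and then cut into per-locus alignments.

#' Configuration of the synthetic study fixture
#'
#' Defaults emulate the data structure of a multilocus hybrid-zone study:
#' 10 nuclear loci of 400-800 bp, 6 chloroplast loci of 900-2500 bp,
#' per-site nuclear diversity around 0.005 with chloroplast diversity an
#' order of magnitude lower, three parental species (two sisters and one
#' more distant), and 20 diploid individuals per species.
#'
#' @param n_ind Diploid individuals per parental species.
#' @param n_nuclear,nuclear_lengths Nuclear locus count and lengths (bp).
#' @param n_cp,cp_lengths Chloroplast locus count and lengths (bp).
#' @param theta_nuc,theta_cp Target per-site diversity (`4 N mu`) of nuclear
#'   and chloroplast sequence.
#' @param N Effective population size used in the coalescent.
#' @param t_split Split time (generations) of the sister species A and C.
#' @param t_root Split time of their ancestor from species B.
#' @param seed Seed.
#' @return List of class `hyb_fixtureconfig`.
#' @export
fixture_config <- function(n_ind = 20L, n_nuclear = 10L,
                           nuclear_lengths = round(seq(400, 800, length.out = n_nuclear)),
                           n_cp = 6L,
                           cp_lengths = round(seq(900, 2500, length.out = n_cp)),
                           theta_nuc = 0.005, theta_cp = 5e-4, N = 5000,
                           t_split = 40000, t_root = 80000, seed = 1L) {
  stopifnot(n_ind > 0, all(nuclear_lengths > 0), all(cp_lengths > 0),
            theta_nuc > 0, theta_cp > 0, N > 0, t_split < t_root)
  structure(list(n_ind = as.integer(n_ind), n_nuclear = as.integer(n_nuclear),
                 nuclear_lengths = as.integer(nuclear_lengths),
                 n_cp = as.integer(n_cp), cp_lengths = as.integer(cp_lengths),
                 theta_nuc = theta_nuc, theta_cp = theta_cp, N = N,
                 t_split = t_split, t_root = t_root, seed = as.integer(seed)),
            class = "hyb_fixtureconfig")
}

.SPECIES <- c("speciesA", "speciesB", "speciesC")

#' Simulate the three parental species
#'
#' Species tree `((A, C), B)`: A and C split at `t_split`, their ancestor
#' and B at `t_root`. Nuclear loci are unlinked; the six chloroplast loci are
#' one linked block with reduced diversity, one haplotype per individual.
#'
#' @param config A `hyb_fixtureconfig`.
#' @return List with `dataset` (a `hyb_dataset`) and `truth` (one row per
#'   individual: `individual_id`, `taxon`, `population`, `category`,
#'   `parents`, `maternal`).
#' @export
generate_parents <- function(config = fixture_config()) {
  set.seed(config$seed)
  mu_nuc <- config$theta_nuc / (4 * config$N)
  mu_cp <- config$theta_cp / (4 * config$N)
  # pops: 1 = A, 2 = B, 3 = C, 4 = anc(A,C), 5 = root
  ev <- data.frame(time = c(config$t_split, config$t_split,
                            config$t_root, config$t_root),
                   type = "split", a = c(1, 3, 4, 2), b = c(4, 4, 5, 5),
                   c = NA_integer_, rate = NA_real_)
  scen <- scenario_spec(rep(config$N, 5L), ev, name = "three_species")
  nuc <- simulate_scenario(scen, samples = rep(2L * config$n_ind, 3L),
                           loci = data.frame(length = config$nuclear_lengths,
                                             mu = mu_nuc),
                           marker = "nuclear", diploid = TRUE, prefix = "P")
  cp <- simulate_scenario(scen, samples = rep(config$n_ind, 3L),
                          loci = data.frame(length = sum(config$cp_lengths),
                                            mu = mu_cp),
                          marker = "chloroplast", diploid = FALSE, prefix = "P")
  # relabel individuals species-wise: A1..A20, B1..B20, C1..C20
  ids <- as.vector(t(outer(c("A", "B", "C"), seq_len(config$n_ind), paste0)))
  taxa <- rep(.SPECIES, each = config$n_ind)
  locnum <- rep(rep(1:2, each = ceiling(config$n_ind / 2))[seq_len(config$n_ind)], 3L)
  pops <- paste0(substr(taxa, 8L, 8L), "_loc", locnum)
  old_ids <- nuc$samples$individual_id
  alns <- lapply(nuc$alignments, function(a) {
    keys <- rownames(a)
    rownames(a) <- paste0(ids[match(.key_individual(keys), old_ids)],
                          sub("^.*(/[12])$", "\\1", keys))
    a
  })
  # cut the linked chloroplast block into the per-locus alignments
  cp_block <- cp$alignments[[1L]]
  rownames(cp_block) <- ids[match(rownames(cp_block), cp$samples$individual_id)]
  ends <- cumsum(config$cp_lengths)
  starts <- ends - config$cp_lengths + 1L
  cp_alns <- lapply(seq_len(config$n_cp), function(l) {
    alignment(unclass(cp_block)[, starts[l]:ends[l], drop = FALSE],
              locus_id = paste0("cp", l), marker = "chloroplast")
  })
  names(alns) <- paste0("nuc", seq_along(alns))
  for (i in seq_along(alns)) attr(alns[[i]], "locus_id") <- names(alns)[i]
  samples <- sample_table(data.frame(
    individual_id = ids, taxon = taxa, population = pops,
    role = "reference_parent", stringsAsFactors = FALSE))
  truth <- data.frame(individual_id = ids, taxon = taxa, population = pops,
                      category = paste0("pure", substr(taxa, 8L, 8L)),
                      parents = taxa, maternal = taxa, stringsAsFactors = FALSE)
  list(dataset = multilocus_dataset(c(alns, cp_alns), samples), truth = truth)
}

# rows of a nuclear locus belonging to one species
.taxon_rows <- function(dataset, locus, taxon) {
  ids <- dataset$samples$individual_id[dataset$samples$taxon == taxon]
  keys <- rownames(dataset$alignments[[locus]])
  keys[.key_individual(keys) %in% ids]
}

# one haploid nuclear genome drawn from a species (random haplotype per locus)
.pure_gamete <- function(dataset, taxon, nuc_loci) {
  lapply(nuc_loci, function(l) {
    keys <- .taxon_rows(dataset, l, taxon)
    unclass(dataset$alignments[[l]])[sample(keys, 1L), ]
  })
}

# gamete of a diploid genome (list per locus of 2-row matrices)
.gamete <- function(genome) {
  lapply(genome, function(m) m[sample.int(2L, 1L), ])
}

.pair_genome <- function(g1, g2) {
  mapply(function(a, b) rbind(a, b), g1, g2, SIMPLIFY = FALSE)
}

.f1_genome <- function(dataset, p1, p2, nuc_loci) {
  .pair_genome(.pure_gamete(dataset, p1, nuc_loci),
               .pure_gamete(dataset, p2, nuc_loci))
}

#' Construct hybrid individuals from simulated parents
#'
#' Constructions (all per nuclear locus, loci independent): `F1` — one random
#' haplotype from each parent species; `F2` — random gametes of two
#' independently constructed F1s; `BC` — an F1 gamete plus a pure gamete of
#' `parents[1]`; `trihybrid` — a gamete of an F1 between `parents[1]` and
#' `parents[2]` plus a pure gamete of `parents[3]`; `introgressed` — the BC
#' construction, labelling an introgressed individual residing in
#' `parents[1]`'s gene pool. Each hybrid's chloroplast haplotype is copied
#' from one random individual of its designated maternal species.
#'
#' @param parents Output of [generate_parents()].
#' @param groups List of group specs: `list(taxon =, category =, n =,
#'   parents = c(...), maternal =, population =, prefix =)`.
#' @param seed Seed.
#' @return List with `dataset` (hybrids only) and `truth`.
#' @export
make_hybrids <- function(parents, groups, seed = 1L) {
  set.seed(seed)
  ds <- parents$dataset
  nuc_loci <- names(Filter(function(a) attr(a, "marker") == "nuclear", ds$alignments))
  cp_loci <- names(Filter(function(a) attr(a, "marker") == "chloroplast", ds$alignments))
  new_rows <- stats::setNames(vector("list", length(nuc_loci)), nuc_loci)
  cp_rows <- stats::setNames(vector("list", length(cp_loci)), cp_loci)
  truth <- list()
  for (grp in groups) {
    n_avail <- sum(ds$samples$taxon == grp$maternal)
    if (grp$n > 50L * n_avail) stop("composition exceeds parental pool capacity")
    for (i in seq_len(grp$n)) {
      id <- paste0(grp$prefix, i)
      genome <- switch(grp$category,
        F1 = .f1_genome(ds, grp$parents[1L], grp$parents[2L], nuc_loci),
        F2 = .pair_genome(
          .gamete(.f1_genome(ds, grp$parents[1L], grp$parents[2L], nuc_loci)),
          .gamete(.f1_genome(ds, grp$parents[1L], grp$parents[2L], nuc_loci))),
        BC = ,
        introgressed = .pair_genome(
          .gamete(.f1_genome(ds, grp$parents[1L], grp$parents[2L], nuc_loci)),
          .pure_gamete(ds, grp$parents[1L], nuc_loci)),
        trihybrid = .pair_genome(
          .gamete(.f1_genome(ds, grp$parents[1L], grp$parents[2L], nuc_loci)),
          .pure_gamete(ds, grp$parents[3L], nuc_loci)),
        stop("unknown hybrid category: ", grp$category))
      for (l in nuc_loci) {
        m <- genome[[match(l, nuc_loci)]]
        rownames(m) <- paste0(id, "/", 1:2)
        new_rows[[l]] <- rbind(new_rows[[l]], m)
      }
      donor_pool <- ds$samples$individual_id[ds$samples$taxon == grp$maternal]
      donor <- sample(donor_pool, 1L)
      for (l in cp_loci) {
        row <- unclass(ds$alignments[[l]])[donor, , drop = FALSE]
        rownames(row) <- id
        cp_rows[[l]] <- rbind(cp_rows[[l]], row)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        individual_id = id, taxon = grp$taxon, population = grp$population,
        category = grp$category, parents = paste(grp$parents, collapse = "x"),
        maternal = grp$maternal, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  alns <- c(
    lapply(nuc_loci, function(l) alignment(new_rows[[l]], l, "nuclear")),
    lapply(cp_loci, function(l) alignment(cp_rows[[l]], l, "chloroplast")))
  samples <- sample_table(data.frame(
    individual_id = truth$individual_id, taxon = truth$taxon,
    population = truth$population, role = "candidate_hybrid",
    stringsAsFactors = FALSE))
  list(dataset = multilocus_dataset(alns, samples), truth = truth)
}

#' Merge multilocus datasets sharing the same loci
#' @param ... `hyb_dataset` objects with identical locus sets.
#' @return A single `hyb_dataset`.
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  loci <- names(parts[[1L]]$alignments)
  alns <- lapply(loci, function(l) {
    m <- do.call(rbind, lapply(parts, function(p) unclass(p$alignments[[l]])))
    alignment(m, l, attr(parts[[1L]]$alignments[[l]], "marker"))
  })
  samples <- sample_table(do.call(rbind, lapply(parts, function(p)
    as.data.frame(p$samples))))
  multilocus_dataset(alns, samples)
}

#' The packaged synthetic study fixture
#'
#' Three parental species (20 diploid individuals each) plus: a hybrid swarm
#' `hybridAB` of 18 F1s (A x B, maternal B) and 2 F2s; a second swarm
#' `hybridCA` of 24 F1s (C x A, maternal C) and 2 trihybrids ((C x A) x B,
#' maternal B) — the trihybrids are 2/26 = 7.7% of that taxon; and 4
#' introgressed individuals inside species C (backcross construction C x B,
#' maternal B). Regeneration with the same seed is bit-identical.
#'
#' @param seed Seed (drives both the coalescent and the hybrid construction).
#' @param config Optional `hyb_fixtureconfig` (its own seed is overridden).
#' @return List of class `hyb_fixture`: `dataset`, `truth`, `config`.
#' @export
study_fixture <- function(seed = 1L, config = NULL) {
  config <- config %||% fixture_config()
  config$seed <- as.integer(seed)
  parents <- generate_parents(config)
  groups <- list(
    list(taxon = "hybridAB", category = "F1", n = 18L,
         parents = c("speciesA", "speciesB"), maternal = "speciesB",
         population = "AB_loc1", prefix = "HAB"),
    list(taxon = "hybridAB", category = "F2", n = 2L,
         parents = c("speciesA", "speciesB"), maternal = "speciesB",
         population = "AB_loc2", prefix = "HABF2_"),
    list(taxon = "hybridCA", category = "F1", n = 24L,
         parents = c("speciesC", "speciesA"), maternal = "speciesC",
         population = "CA_loc1", prefix = "HCA"),
    list(taxon = "hybridCA", category = "trihybrid", n = 2L,
         parents = c("speciesC", "speciesA", "speciesB"),
         maternal = "speciesB", population = "CA_loc2", prefix = "TH"),
    list(taxon = "speciesC", category = "introgressed", n = 4L,
         parents = c("speciesC", "speciesB"), maternal = "speciesB",
         population = "C_loc3", prefix = "IC"))
  hyb <- make_hybrids(parents, groups, seed = seed + 1L)
  truth <- rbind(parents$truth, hyb$truth)
  dataset <- combine_datasets(parents$dataset, hyb$dataset)
  structure(list(dataset = dataset, truth = truth, config = config,
                 seed = seed),
            class = "hyb_fixture")
}

#' Fraction of diagnostic (fixed-different) sites between two taxa
#'
#' @param dataset A `hyb_dataset`.
#' @param taxon1,taxon2 Taxon labels.
#' @param marker Marker kind.
#' @return Fraction of fully resolved columns fixed for different states.
#' @export
diagnostic_site_fraction <- function(dataset, taxon1, taxon2, marker = "nuclear") {
  tot <- 0L; diag <- 0L
  for (aln in Filter(function(a) attr(a, "marker") == marker, dataset$alignments)) {
    m <- unclass(mask_ambiguous_columns(aln))
    ind <- .key_individual(rownames(m))
    id1 <- dataset$samples$individual_id[dataset$samples$taxon == taxon1]
    id2 <- dataset$samples$individual_id[dataset$samples$taxon == taxon2]
    m1 <- m[ind %in% id1, , drop = FALSE]
    m2 <- m[ind %in% id2, , drop = FALSE]
    tot <- tot + ncol(m)
    for (j in seq_len(ncol(m))) {
      u1 <- unique(m1[, j]); u2 <- unique(m2[, j])
      if (length(u1) == 1L && length(u2) == 1L && u1 != u2) diag <- diag + 1L
    }
  }
  diag / tot
}
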