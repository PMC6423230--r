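# Pipeline orchestration: runs the analysis stages in dependency order on a
# dataset (or the packaged synthetic fixture), writes tab-separated reports
# plus a JSON run manifest recording versions, seeds, parameters and input
# checksums. The stage functions themselves are the package's API; this layer
# only sequences them and handles I/O.

.PIPE_STAGES <- c("fixture", "stats", "pca", "structure", "classify",
                  "cptype", "discordance")

#' Run the analysis pipeline
#'
#' Stages: `fixture` (generate the synthetic study dataset), `stats`
#' (per-locus, per-taxon diversity and neutrality report), `pca`
#' (genetic-distance principal components), `structure` (admixture Gibbs runs
#' over a K range plus the delta-K table), `classify` (six-class hybrid
#' assignment for each configured trio), `cptype` (chloroplast typing and the
#' locality count table), `discordance` (cytonuclear-discordance report).
#' Stage failure aborts the stages that depend on it; completed outputs are
#' preserved.
#'
#' @param config Named list (or path to a YAML file) with entries: `outdir`
#'   (required), `seed`, `stages` (subset of the above; default all),
#'   `fixture` (list passed to [study_fixture()]), `structure`
#'   (`K_range`, `replicates`, `iters`, `burnin`), `classify` (list of trios:
#'   `taxon`, `parent1`, `parent2`, `sweeps`, `burnin`), `cptype`
#'   (`references`: type label -> taxon).
#' @return Invisibly, the manifest list (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  known <- c("outdir", "seed", "stages", "fixture", "structure", "classify", "cptype")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop("config$outdir is required")
  stages <- config$stages %||% .PIPE_STAGES
  bad <- setdiff(stages, .PIPE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "hybridorigin",
                   version = as.character(utils::packageVersion("hybridorigin")),
                   seed = seed, stages = stages, outputs = list())
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  fx <- study_fixture(seed = seed)
  ds <- fx$dataset
  if ("fixture" %in% stages) {
    for (l in names(ds$alignments))
      emit(paste0(l, ".fasta"), function(p) write_alignment(ds$alignments[[l]], p))
    emit("samples.tsv", function(p) write_sample_table(ds$samples, p))
    emit("truth.tsv", function(p)
      utils::write.table(fx$truth, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if ("stats" %in% stages) {
    emit("diversity.tsv", function(p)
      utils::write.table(diversity_table(ds), p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }
  gm <- NULL
  if (any(c("pca", "structure", "discordance") %in% stages))
    gm <- genotype_matrix(ds)
  if ("pca" %in% stages) {
    pca <- pca_from_distance(genetic_distance_matrix(gm))
    emit("pca.tsv", function(p)
      utils::write.table(cbind(as.data.frame(pca$coordinates[, 1:2]),
                               individual = rownames(pca$coordinates)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    manifest$pca_variance <- pca$variance[1:2]
  }
  runs3 <- NULL
  if (any(c("structure", "discordance") %in% stages)) {
    sc <- config$structure %||% list()
    reps <- admixture_replicates(gm, K_range = sc$K_range %||% 1:5,
                                 replicates = sc$replicates %||% 3L,
                                 seed = seed,
                                 iters = sc$iters %||% 400L,
                                 burnin = sc$burnin %||% 150L)
    runs3 <- align_cluster_labels(reps$runs[["3"]])
    if ("structure" %in% stages) {
      emit("q_matrix_K3.tsv", function(p) write_q_matrix(runs3$mean_Q, p))
      emit("delta_k.tsv", function(p)
        utils::write.table(evanno_delta_k(reps$lnPD), p, sep = "\t",
                           quote = FALSE, row.names = FALSE))
    }
  }
  if ("classify" %in% stages) {
    trios <- config$classify %||% list(
      list(taxon = "hybridAB", parent1 = "speciesA", parent2 = "speciesB"),
      list(taxon = "hybridCA", parent1 = "speciesC", parent2 = "speciesA"))
    for (tr in trios) {
      ids <- ds$samples$individual_id[ds$samples$taxon %in%
                                        c(tr$taxon, tr$parent1, tr$parent2)]
      gmt <- genotype_matrix(ds, individuals = ids)
      zf <- c(stats::setNames(rep("Pure1", sum(ds$samples$taxon == tr$parent1)),
                              ds$samples$individual_id[ds$samples$taxon == tr$parent1]),
              stats::setNames(rep("Pure2", sum(ds$samples$taxon == tr$parent2)),
                              ds$samples$individual_id[ds$samples$taxon == tr$parent2]))
      res <- newhybrids_mcmc(gmt, z_fixed = zf,
                             sweeps = tr$sweeps %||% 1500L,
                             burnin = tr$burnin %||% 500L, seed = seed)
      emit(paste0("classes_", tr$taxon, ".tsv"), function(p)
        utils::write.table(cbind(individual = rownames(res$posterior),
                                 as.data.frame(round(res$posterior, 4)),
                                 modal = res$modal),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
    }
  }
  cp_assign <- NULL
  if (any(c("cptype", "discordance") %in% stages)) {
    refmap <- config$cptype$references %||%
      list(cpC = "speciesC", cpB = "speciesB", cpA = "speciesA")
    cp_cat <- concatenate_loci(ds, "chloroplast", fill_missing = TRUE)
    refs <- lapply(refmap, function(tx)
      ds$samples$individual_id[ds$samples$taxon == tx &
                                 ds$samples$role == "reference_parent"])
    cand <- ds$samples$individual_id
    cp_assign <- assign_cp_type(cp_cat, cand, refs)
    if ("cptype" %in% stages) {
      emit("cp_types.tsv", function(p)
        utils::write.table(cp_assign, p, sep = "\t", quote = FALSE, row.names = FALSE))
      hyb_ids <- ds$samples$individual_id[ds$samples$role == "candidate_hybrid"]
      ct <- count_table(cp_assign[cp_assign$individual %in% hyb_ids, ], ds$samples)
      emit("cp_count_table.tsv", function(p) write_count_table(ct, p))
    }
  }
  if ("discordance" %in% stages) {
    rep_report <- discordance_report(
      structure(list(K = 3L, Q = runs3$mean_Q), class = "hyb_clusterrun"),
      cp_assign)
    emit("discordance.tsv", function(p)
      utils::write.table(rep_report, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
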