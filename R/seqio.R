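# Alignment and sample-table input/output, haplotype collapsing, locus
# concatenation and simple indel coding.
#
# An alignment is a character matrix over {A,C,G,T,-,N} with one row per
# haplotype (nuclear markers: two rows per diploid individual, sample keys
# "<individual>/1" and "<individual>/2") or per individual (chloroplast).
# Coordinates are 0-based half-open internally; user-facing reports are
# 1-based.

.DNA_CHARS <- c("A", "C", "G", "T", "-", "N")

#' Construct an alignment object
#'
#' @param x Character matrix of single characters over `{A,C,G,T,-,N}`,
#'   one row per sequence; rownames are sample keys.
#' @param locus_id Locus label.
#' @param marker `"nuclear"` (two rows per diploid individual) or
#'   `"chloroplast"` (one row per individual).
#' @return An object of class `hyb_alignment`.
#' @export
alignment <- function(x, locus_id, marker = c("nuclear", "chloroplast")) {
  marker <- match.arg(marker)
  if (!is.matrix(x) || !is.character(x)) stop("`x` must be a character matrix")
  if (ncol(x) < 1L) stop("alignment length must be > 0")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("rows must carry unique sample keys")
  bad <- !(x %in% .DNA_CHARS)
  if (any(bad)) {
    warning(sum(bad), " unknown character(s) in locus '", locus_id,
            "' mapped to N")
    x[bad] <- "N"
  }
  structure(x, class = "hyb_alignment", locus_id = locus_id, marker = marker)
}

#' @export
print.hyb_alignment <- function(x, ...) {
  cat("<hyb_alignment> locus", attr(x, "locus_id"), "(", attr(x, "marker"), "):",
      nrow(x), "sequences x", ncol(x), "bp\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Validates that all records have identical length, uppercases, and maps any
#' character outside `{A,C,G,T,-,N}` (including IUPAC ambiguity codes) to `N`
#' with a warning.
#'
#' @param path Path to a FASTA file with at least two records.
#' @param marker Marker kind, passed to [alignment()].
#' @param locus_id Locus label; defaults to the file name without extension.
#' @return A `hyb_alignment`.
#' @export
read_alignment <- function(path, marker = c("nuclear", "chloroplast"),
                           locus_id = sub("\\.[^.]*$", "", basename(path))) {
  marker <- match.arg(marker)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("empty or unreadable FASTA file: ", path)
  if (length(recs) < 2L) stop("alignment needs at least 2 records: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop("ragged alignment in ", path, ": record '", names(recs)[off],
         "' has length ", lens[off], ", expected ", lens[1L])
  }
  m <- toupper(do.call(rbind, lapply(as.character(recs), as.vector)))
  rownames(m) <- names(recs)
  m[m == "?"] <- "N"
  alignment(m, locus_id = locus_id, marker = marker)
}

#' Write an alignment to FASTA
#'
#' Round-trips losslessly through [read_alignment()] (sequences, order and
#' sample keys preserved).
#'
#' @param aln A `hyb_alignment`.
#' @param path Output file path.
#' @export
write_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(tolower(unclass(aln)))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a tab-separated sample-metadata table
#'
#' Expected header columns: `individual_id`, `taxon`, `population`, and
#' optionally `role` (one of `candidate_hybrid`, `reference_parent`,
#' `outgroup`).
#'
#' @param path Path to a TSV file with header.
#' @return A validated `data.frame` of class `hyb_samples`.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a sample-metadata table
#' @param df Data frame with columns `individual_id`, `taxon`, `population`
#'   and optionally `role`.
#' @return `df` with class `hyb_samples` prepended.
#' @export
sample_table <- function(df) {
  need <- c("individual_id", "taxon", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id))
    stop("duplicated individual_id: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "))
  if (is.null(df$role)) df$role <- "candidate_hybrid"
  ok <- df$role %in% c("candidate_hybrid", "reference_parent", "outgroup")
  if (!all(ok)) stop("unknown role(s): ", paste(unique(df$role[!ok]), collapse = ", "))
  class(df) <- c("hyb_samples", class(df))
  df
}

#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sample key -> individual id ("ind/1", "ind/2" -> "ind"; cp keys map to self)
.key_individual <- function(keys) sub("/[12]$", "", keys)

#' Bundle alignments and sample metadata into a multilocus dataset
#'
#' Checks that every alignment row resolves to a listed individual, that
#' nuclear loci carry exactly two rows per scored individual and chloroplast
#' loci exactly one, and tracks per-locus missing individuals.
#'
#' @param alignments List of `hyb_alignment` objects.
#' @param samples A `hyb_samples` table (see [sample_table()]).
#' @return An object of class `hyb_dataset` with elements `alignments`,
#'   `samples` and `missing` (locus -> individuals without data).
#' @export
multilocus_dataset <- function(alignments, samples) {
  if (!inherits(samples, "hyb_samples")) samples <- sample_table(samples)
  ids <- unlist(lapply(alignments, function(a) attr(a, "locus_id")))
  if (anyDuplicated(ids)) stop("duplicated locus_id among alignments")
  names(alignments) <- ids
  missing <- list()
  for (aln in alignments) {
    ind <- .key_individual(rownames(aln))
    unknown <- setdiff(ind, samples$individual_id)
    if (length(unknown))
      stop("locus ", attr(aln, "locus_id"), " has sample keys for unknown individual(s): ",
           paste(unknown, collapse = ", "))
    cnt <- table(ind)
    want <- if (attr(aln, "marker") == "nuclear") 2L else 1L
    # nuclear loci: two rows per diploid individual, or a uniformly
    # haplotype-level alignment (one row per sampled lineage)
    haploid_ok <- attr(aln, "marker") == "nuclear" && all(cnt == 1L)
    if (any(cnt != want) && !haploid_ok)
      stop("locus ", attr(aln, "locus_id"), " (", attr(aln, "marker"),
           ") must have ", want, " row(s) per individual; offending: ",
           paste(names(cnt)[cnt != want], collapse = ", "))
    missing[[attr(aln, "locus_id")]] <- setdiff(samples$individual_id, ind)
  }
  structure(list(alignments = alignments, samples = samples, missing = missing),
            class = "hyb_dataset")
}

#' @export
print.hyb_dataset <- function(x, ...) {
  mk <- vapply(x$alignments, attr, "", "marker")
  cat("<hyb_dataset>", nrow(x$samples), "individuals;",
      sum(mk == "nuclear"), "nuclear and", sum(mk == "chloroplast"),
      "chloroplast loci\n")
  invisible(x)
}

#' Collapse an alignment to its distinct haplotypes
#'
#' Haplotypes are numbered `H1, H2, ...` by first occurrence.
#'
#' @param aln A `hyb_alignment`.
#' @return A list of class `hyb_haplotypes` with `locus_id`, a data frame
#'   `haplotypes` (`haplotype_id`, `sequence`, `count`) and `members`, the
#'   sample keys carrying each haplotype.
#' @export
collapse_haplotypes <- function(aln) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  idx <- match(seqs, uniq)
  ids <- paste0("H", seq_along(uniq))
  members <- split(rownames(aln), ids[idx])[ids]
  out <- list(locus_id = attr(aln, "locus_id"),
              haplotypes = data.frame(haplotype_id = ids, sequence = uniq,
                                      count = as.integer(tabulate(idx, length(uniq))),
                                      row.names = NULL),
              members = members)
  class(out) <- "hyb_haplotypes"
  out
}

#' Concatenate the loci of one marker into a single alignment
#'
#' Row (individual) order follows first appearance across loci. With
#' `fill_missing = TRUE`, individuals absent from a locus receive `N` across
#' that locus; otherwise their absence is an error.
#'
#' @param dataset A `hyb_dataset`.
#' @param marker Which marker's loci to concatenate.
#' @param fill_missing Fill absent individuals with `N` instead of failing.
#' @return A `hyb_alignment` whose length is the sum of the per-locus lengths,
#'   with a `boundaries` attribute (0-based half-open per-locus intervals).
#' @export
concatenate_loci <- function(dataset, marker = c("nuclear", "chloroplast"),
                             fill_missing = FALSE) {
  marker <- match.arg(marker)
  alns <- Filter(function(a) attr(a, "marker") == marker, dataset$alignments)
  if (!length(alns)) stop("no ", marker, " loci in dataset")
  keys <- unique(unlist(lapply(alns, rownames)))
  blocks <- vector("list", length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    block <- matrix("N", length(keys), ncol(a), dimnames = list(keys, NULL))
    present <- intersect(keys, rownames(a))
    absent <- setdiff(keys, rownames(a))
    if (length(absent) && !fill_missing)
      stop("individual(s) missing from locus ", attr(a, "locus_id"), ": ",
           paste(unique(.key_individual(absent)), collapse = ", "),
           " (set fill_missing = TRUE to pad with N)")
    block[present, ] <- unclass(a)[present, , drop = FALSE]
    blocks[[i]] <- block
  }
  out <- do.call(cbind, blocks)
  ends <- cumsum(vapply(alns, ncol, 0L))
  bounds <- cbind(start = c(0L, utils::head(ends, -1L)), end = ends)
  rownames(bounds) <- names(alns)
  res <- alignment(out, locus_id = paste0("concat_", marker), marker = marker)
  attr(res, "boundaries") <- bounds
  res
}

#' Simple indel coding
#'
#' Implements simple indel coding: every distinct maximal gap run (identical
#' start and end) becomes one presence/absence character. A sequence whose own
#' gap strictly contains a shorter character's span is scored missing (`NA`)
#' for that character; sequences without such a gap score 0.
#'
#' @param aln A `hyb_alignment` with gaps coded as `-`.
#' @return Integer matrix (samples x indel characters; entries 0/1/`NA`) with
#'   columns named by 1-based inclusive gap coordinates.
#' @export
code_indels <- function(aln) {
  m <- unclass(aln) == "-"
  runs_per_row <- lapply(seq_len(nrow(m)), function(i) {
    r <- rle(m[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  })
  all_runs <- unique(do.call(rbind, runs_per_row))
  if (is.null(all_runs) || nrow(all_runs) == 0L) {
    out <- matrix(integer(0), nrow(m), 0L)
    rownames(out) <- rownames(aln)
    return(out)
  }
  all_runs <- all_runs[order(all_runs[, 1L], all_runs[, 2L]), , drop = FALSE]
  out <- matrix(0L, nrow(m), nrow(all_runs))
  rownames(out) <- rownames(aln)
  colnames(out) <- paste0("g", all_runs[, 1L], "-", all_runs[, 2L])
  for (i in seq_len(nrow(m))) {
    rr <- runs_per_row[[i]]
    if (nrow(rr) == 0L) next
    for (j in seq_len(nrow(all_runs))) {
      s <- all_runs[j, 1L]; e <- all_runs[j, 2L]
      exact <- any(rr[, 1L] == s & rr[, 2L] == e)
      if (exact) {
        out[i, j] <- 1L
      } else if (any(rr[, 1L] <= s & rr[, 2L] >= e)) {
        out[i, j] <- NA_integer_  # strictly containing gap: inapplicable
      }
    }
  }
  out
}

#' @export
write_indel_matrix <- function(x, path) {
  y <- ifelse(is.na(x), "?", as.character(x))
  utils::write.table(y, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Drop alignment columns containing gaps or ambiguous bases
#'
#' Complete-deletion policy used before computing polymorphism statistics:
#' any column with `-` or `N` in any row is excluded.
#'
#' @param aln A `hyb_alignment`.
#' @return A `hyb_alignment` restricted to fully resolved columns.
#' @export
mask_ambiguous_columns <- function(aln) {
  m <- unclass(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  res <- m[, keep, drop = FALSE]
  structure(res, class = "hyb_alignment", locus_id = attr(aln, "locus_id"),
            marker = attr(aln, "marker"))
}

# subset an alignment's rows, keeping attributes
.subset_alignment <- function(aln, keys) {
  m <- unclass(aln)[keys, , drop = FALSE]
  structure(m, class = "hyb_alignment", locus_id = attr(aln, "locus_id"),
            marker = attr(aln, "marker"))
}
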