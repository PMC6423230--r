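# Chloroplast genetic typing of candidate hybrids, locality count tables,
# and cytonuclear-discordance reporting. Typing is distance-based: a
# candidate takes the label of the reference set containing its
# minimum-Hamming-distance chloroplast haplotype (ties across sets are
# flagged ambiguous), which reproduces clade membership for well-separated
# haplotype groups without tree inference.

#' Assign chloroplast genetic types by nearest reference haplotype
#'
#' Hamming distances are computed on the concatenated chloroplast alignment
#' after complete deletion of gapped/ambiguous columns.
#'
#' @param aln Chloroplast `hyb_alignment` (e.g. from [concatenate_loci()])
#'   containing both candidates and references.
#' @param candidates Sample keys of the individuals to type.
#' @param references Named list: type label -> sample keys of that reference
#'   set.
#' @return Data frame of class `hyb_cptypes`: `individual`, `type` (`NA` when
#'   ambiguous), `nearest_ref`, `distance`, `ambiguous`.
#' @export
assign_cp_type <- function(aln, candidates, references) {
  if (length(references) < 2L) stop("need at least 2 reference sets")
  if (any(lengths(references) == 0L)) stop("empty reference set")
  m <- unclass(mask_ambiguous_columns(aln))
  all_keys <- c(candidates, unlist(references))
  miss <- setdiff(all_keys, rownames(m))
  if (length(miss)) stop("sample key(s) not in alignment: ", paste(miss, collapse = ", "))
  codes <- matrix(match(m, .DNA_CHARS), nrow(m), dimnames = dimnames(m))
  out <- data.frame(individual = .key_individual(candidates),
                    type = NA_character_, nearest_ref = NA_character_,
                    distance = NA_real_, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    cand <- codes[candidates[i], ]
    best <- vapply(references, function(keys) {
      min(colSums(t(codes[keys, , drop = FALSE]) != cand))
    }, 0)
    d <- min(best)
    winners <- names(best)[best == d]
    out$distance[i] <- d
    if (length(winners) > 1L) {
      out$ambiguous[i] <- TRUE
    } else {
      out$type[i] <- winners
      keys <- references[[winners]]
      dref <- colSums(t(codes[keys, , drop = FALSE]) != cand)
      out$nearest_ref[i] <- keys[which.min(dref)]
    }
  }
  class(out) <- c("hyb_cptypes", class(out))
  out
}

#' Cross-tabulate chloroplast types by locality
#'
#' Builds the type x locality count table with row totals, the overall total
#' of typed individuals, and each type's percentage share (rounded half-up to
#' one decimal). Unassigned (ambiguous) individuals are excluded and counted
#' in the diagnostics. When `printed_total` is supplied and disagrees with
#' the computed total, the discrepancy is flagged rather than adopted.
#'
#' @param x A `hyb_cptypes` assignment, or a ready type x locality count
#'   matrix.
#' @param samples A `hyb_samples` table (required when `x` is an assignment)
#'   supplying each individual's locality.
#' @param printed_total Optional externally stated overall total to check.
#' @return List of class `hyb_counttable`: `counts`, `row_totals`, `total`,
#'   `percent`, `excluded`, `total_discrepancy`.
#' @export
count_table <- function(x, samples = NULL, printed_total = NULL) {
  if (is.matrix(x)) {
    counts <- x
    excluded <- 0L
  } else {
    if (is.null(samples)) stop("`samples` is required to resolve localities")
    typed <- x[!is.na(x$type), , drop = FALSE]
    excluded <- sum(is.na(x$type))
    loc <- samples$population[match(typed$individual, samples$individual_id)]
    if (anyNA(loc)) stop("individual(s) without locality in the sample table")
    counts <- as.matrix(table(type = typed$type, locality = loc))
  }
  row_totals <- rowSums(counts)
  total <- sum(row_totals)
  percent <- if (total > 0) round_half_up(100 * row_totals / total, 1L) else row_totals
  disc <- NULL
  if (!is.null(printed_total) && printed_total != total)
    disc <- c(computed = total, printed = printed_total)
  structure(list(counts = counts, row_totals = row_totals, total = total,
                 percent = percent, excluded = excluded,
                 total_discrepancy = disc),
            class = "hyb_counttable")
}

#' @export
print.hyb_counttable <- function(x, ...) {
  tab <- cbind(x$counts, Total = x$row_totals, `%` = x$percent)
  print(tab)
  cat("Overall total of typed individuals:", x$total, "\n")
  if (x$excluded > 0L) cat("Excluded (ambiguous/untyped):", x$excluded, "\n")
  if (!is.null(x$total_discrepancy))
    cat("NOTE: computed total ", x$total_discrepancy["computed"],
        " differs from the stated total ", x$total_discrepancy["printed"],
        "; computed totals are reported.\n", sep = "")
  invisible(x)
}

#' @export
write_count_table <- function(x, path) {
  tab <- cbind(x$counts, Total = x$row_totals, percent = x$percent)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Cytonuclear-discordance report
#'
#' Compares each individual's modal nuclear cluster with its chloroplast
#' type. The expected chloroplast type of a cluster is the majority type
#' among individuals confidently assigned to it (modal Q at or above
#' `threshold`). Reported (flagged) individuals are those with an admixed
#' nuclear genome (modal Q below `threshold`; the hybrid pattern, whose
#' chloroplast necessarily matches only its maternal parent) and those
#' confidently assigned to a cluster whose expected chloroplast side differs
#' from their own (the introgression pattern).
#'
#' @param run A `hyb_clusterrun` (admixture result over the same individuals).
#' @param cp A `hyb_cptypes` assignment.
#' @param threshold Modal-Q cutoff separating confident from admixed nuclear
#'   assignments.
#' @return Data frame with one row per shared individual: modal cluster and
#'   Q, chloroplast type, expected type, `pattern`
#'   (`"concordant"`, `"hybrid"`, `"introgression"`), `flagged`.
#' @export
discordance_report <- function(run, cp, threshold = 0.9) {
  shared <- intersect(rownames(run$Q), cp$individual)
  Q <- run$Q[shared, , drop = FALSE]
  modal <- max.col(Q, ties.method = "first")
  maxq <- Q[cbind(seq_along(shared), modal)]
  type <- cp$type[match(shared, cp$individual)]
  # majority chloroplast type of confidently assigned members per cluster
  expected <- rep(NA_character_, ncol(Q))
  for (k in seq_len(ncol(Q))) {
    members <- type[modal == k & maxq >= threshold & !is.na(type)]
    if (length(members)) expected[k] <- names(which.max(table(members)))
  }
  exp_type <- expected[modal]
  pattern <- ifelse(maxq < threshold, "hybrid",
                    ifelse(!is.na(type) & !is.na(exp_type) & type != exp_type,
                           "introgression", "concordant"))
  data.frame(individual = shared, modal_cluster = modal,
             modal_Q = round(maxq, 4), cp_type = type,
             expected_cp_type = exp_type, pattern = pattern,
             flagged = pattern != "concordant", stringsAsFactors = FALSE)
}
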