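# Remote structural homology filtering: a hit against a PDB chain is
# accepted when at least 3 annotated TM segments of the chain are contained
# in the aligned region and the hit E-value is strictly below 1e-4.

#' Accept or reject one structural hit
#'
#' @param hit One-row data.frame (or list) with `pdb_chain_id`, `evalue`,
#'   `target_aln_from`, `target_aln_to`.
#' @param tm Named list mapping PDB chain ids to two-column (start, end)
#'   TM-segment matrices.
#' @param min_tm Minimum number of TM segments fully contained in the
#'   aligned region.
#' @param max_e E-value threshold (strict `<`).
#' @param allow_partial If `TRUE`, count segments that merely overlap the
#'   aligned region (sensitivity analysis); default requires full
#'   containment.
#' @return `TRUE` or `FALSE`. Chains with no TM annotation reject with a
#'   warning.
#' @export
accept_hit <- function(hit, tm, min_tm = 3L, max_e = 1e-4,
                       allow_partial = FALSE) {
  seg <- tm[[hit$pdb_chain_id]]
  if (is.null(seg)) {
    warning("no TM annotation for chain ", hit$pdb_chain_id,
            "; hit rejected")
    return(FALSE)
  }
  if (allow_partial) {
    covered <- sum(seg[, 2] >= hit$target_aln_from &
                     seg[, 1] <= hit$target_aln_to)
  } else {
    covered <- sum(seg[, 1] >= hit$target_aln_from &
                     seg[, 2] <= hit$target_aln_to)
  }
  covered >= min_tm && hit$evalue < max_e
}

#' Filter a table of structural hits
#'
#' @param hits Data.frame with columns `protein_id`, `pdb_chain_id`,
#'   `evalue`, `target_aln_from`, `target_aln_to`.
#' @param tm TM-annotation list (see [accept_hit()]).
#' @param min_tm,max_e,allow_partial Passed to [accept_hit()].
#' @return The input with a logical `accepted` column appended.
#' @export
filter_structural_hits <- function(hits, tm, min_tm = 3L, max_e = 1e-4,
                                   allow_partial = FALSE) {
  hits$accepted <- vapply(seq_len(nrow(hits)), function(i)
    accept_hit(hits[i, ], tm, min_tm, max_e, allow_partial), logical(1))
  hits
}

#' Best accepted structural homolog per protein
#'
#' Minimal E-value among accepted hits; ties broken by lexicographically
#' smallest chain id. Proteins with no accepted hit are absent.
#'
#' @param hits Structural hit data.frame.
#' @param tm TM-annotation list.
#' @param min_tm,max_e,allow_partial Passed to [accept_hit()].
#' @return Data.frame (one row per protein with an accepted hit).
#' @export
best_structural_homolog <- function(hits, tm, min_tm = 3L, max_e = 1e-4,
                                    allow_partial = FALSE) {
  acc <- filter_structural_hits(hits, tm, min_tm, max_e, allow_partial)
  acc <- acc[acc$accepted, , drop = FALSE]
  if (!nrow(acc)) return(acc[, setdiff(names(acc), "accepted"), drop = FALSE])
  acc <- acc[order(acc$protein_id, acc$evalue, acc$pdb_chain_id), ,
             drop = FALSE]
  best <- acc[!duplicated(acc$protein_id), , drop = FALSE]
  rownames(best) <- NULL
  best[, setdiff(names(best), "accepted"), drop = FALSE]
}

#' Families with no accepted structural homolog
#'
#' @param assignment A `family_assignment`.
#' @param best_hits Data.frame from [best_structural_homolog()].
#' @return Character vector of family ids in which no member has an
#'   accepted hit ("structural orphan" families).
#' @export
structural_orphans <- function(assignment, best_hits) {
  with_hit <- unique(best_hits$protein_id)
  orphan <- vapply(assignment$families, function(members)
    !any(members %in% with_hit), logical(1))
  names(assignment$families)[orphan]
}

#' Read structural hits from a normalized TSV
#'
#' Columns: `protein_id`, `pdb_chain_id`, `evalue`, `target_aln_from`,
#' `target_aln_to` (extra columns pass through).
#'
#' @param path Input path.
#' @return Data.frame of structural hits.
#' @export
read_structural_hits <- function(path) {
  out <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("protein_id", "pdb_chain_id", "evalue", "target_aln_from",
            "target_aln_to")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("structural hit table missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(out$target_aln_from <= out$target_aln_to),
            all(out$evalue >= 0))
  out
}

#' Read PDB-chain TM-segment annotations from TSV
#'
#' Columns: `pdb_chain_id`, `tm_segments` (`;`-joined `start-end` ranges).
#'
#' @param path Input path.
#' @return Named list of two-column (start, end) matrices.
#' @export
read_tm_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c(tm_segments = "character"))
  segs <- lapply(df$tm_segments, .parse_segments)
  stats::setNames(segs, df$pdb_chain_id)
}

#' Write TM annotations in the layout read by [read_tm_annotations()]
#' @param tm Named list of segment matrices.
#' @param path Output path.
#' @export
write_tm_annotations <- function(tm, path) {
  df <- data.frame(pdb_chain_id = names(tm),
                   tm_segments = vapply(tm, .fmt_segments, character(1)),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
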