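# HMM fingerprints: per-protein vectors of bit scores against the HMM panel.
# Hits above the 50-bit search threshold define the candidate protein set;
# HMMs whose best hit exceeds 25 bits define the fingerprint columns.

#' Threshold configuration for candidate selection and fingerprints
#'
#' Defaults encode the study thresholds: proteins are retained when some hit
#' scores strictly more than 50 bits, and an HMM contributes a fingerprint
#' column when its best hit scores strictly more than 25 bits. Region
#' exclusion rules discard hits confined to non-transmembrane stretches of
#' four known multi-domain models.
#'
#' @param search_min_bits Candidate threshold in bits (strict `>`).
#' @param fingerprint_min_bits Column-retention threshold in bits (strict `>`).
#' @param region_exclusions Data.frame from [region_exclusion_rules()].
#' @param cells_min_bits If `TRUE`, zero out matrix cells at or below
#'   `fingerprint_min_bits` (the stricter reading); default keeps every
#'   reported score to a retained model.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(search_min_bits = 50,
                             fingerprint_min_bits = 25,
                             region_exclusions = region_exclusion_rules(),
                             cells_min_bits = FALSE) {
  stopifnot(search_min_bits >= fingerprint_min_bits,
            fingerprint_min_bits > 0)
  structure(list(search_min_bits = search_min_bits,
                 fingerprint_min_bits = fingerprint_min_bits,
                 region_exclusions = region_exclusions,
                 cells_min_bits = cells_min_bits),
            class = "threshold_config")
}

#' Default model-region exclusion rules
#'
#' Hits that fall entirely inside non-TM regions of these models are
#' discarded: TC# 2.A.19.3 positions 250-725, TC# 9.B.64.1 positions above
#' 200, Pfam OST3_OST6 positions below 200, and Pfam RBP_receptor positions
#' above 400.
#'
#' @return Data.frame with columns `model_id`, `lo`, `hi` (model coordinates,
#'   `hi = Inf` for open-ended windows).
#' @export
region_exclusion_rules <- function() {
  data.frame(
    model_id = c("2.A.19.3", "9.B.64.1", "OST3_OST6", "RBP_receptor"),
    lo = c(250, 201, 1, 401),
    hi = c(725, Inf, 199, Inf),
    stringsAsFactors = FALSE)
}

#' Merge per-domain hits to one row per (protein, model) pair
#'
#' Thresholds act per protein-model pair, so multi-domain rows are merged:
#' the pair keeps the maximum full-sequence bit score and minimum E-value,
#' and the union of its domain coordinate ranges for region-exclusion checks.
#'
#' @param hits Data.frame from [parse_domtblout()] (per-domain rows).
#' @return Data.frame with one row per pair: `protein_id`, `model_id`,
#'   `bit_score`, `evalue`, and a `domains` list-column of coordinate
#'   data.frames.
#' @export
merge_hits <- function(hits) {
  if (!nrow(hits)) {
    out <- data.frame(protein_id = character(0), model_id = character(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
    out$domains <- list()
    return(out)
  }
  key <- paste(hits$protein_id, hits$model_id, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  ord <- order(vapply(groups, function(i) hits$protein_id[i[1]], character(1)),
               vapply(groups, function(i) hits$model_id[i[1]], character(1)))
  groups <- groups[ord]
  out <- data.frame(
    protein_id = vapply(groups, function(i) hits$protein_id[i[1]], character(1)),
    model_id = vapply(groups, function(i) hits$model_id[i[1]], character(1)),
    bit_score = vapply(groups, function(i) max(hits$bit_score[i]), numeric(1)),
    evalue = vapply(groups, function(i) min(hits$evalue[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out$domains <- lapply(groups, function(i)
    hits[i, c("model_from", "model_to", "target_from", "target_to"),
         drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Apply model-region exclusion rules to merged hits
#'
#' A (protein, model) hit is removed iff a rule targets its model and every
#' one of the hit's domain segments lies entirely inside the excluded window;
#' partial overlap retains the hit.
#'
#' @param hits Merged hits from [merge_hits()].
#' @param rules Data.frame as from [region_exclusion_rules()].
#' @return Filtered merged-hit data.frame.
#' @export
apply_region_exclusions <- function(hits, rules = region_exclusion_rules()) {
  if (!nrow(hits) || is.null(rules) || !nrow(rules)) return(hits)
  unknown <- setdiff(rules$model_id, hits$model_id)
  if (length(unknown)) {
    warning("region-exclusion rule(s) for unknown model(s) ignored: ",
            paste(unknown, collapse = ", "))
  }
  drop <- logical(nrow(hits))
  for (k in seq_len(nrow(rules))) {
    m <- which(hits$model_id == rules$model_id[k])
    for (i in m) {
      dom <- hits$domains[[i]]
      inside <- dom$model_from >= rules$lo[k] & dom$model_to <= rules$hi[k]
      if (all(inside)) drop[i] <- TRUE
    }
  }
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate proteins by the search bit-score threshold
#'
#' @param hits Merged hits (after region exclusions, normally).
#' @param config A [threshold_config()].
#' @return Sorted character vector of protein accessions having at least one
#'   hit with bit score strictly above `search_min_bits`.
#' @export
select_candidates <- function(hits, config = threshold_config()) {
  if (!nrow(hits)) return(character(0))
  sort(unique(hits$protein_id[hits$bit_score > config$search_min_bits]))
}

#' Build the HMM fingerprint matrix
#'
#' Rows are candidate proteins, columns are HMMs whose best hit among the
#' candidates scores strictly above `fingerprint_min_bits`; a cell holds the
#' pair's bit score, or 0 where no hit was reported. Row and column order is
#' lexicographic. Candidates whose row would be all zero (every hit lost to
#' column selection) are dropped with a warning.
#'
#' @param hits Merged hits.
#' @param candidates Accessions from [select_candidates()].
#' @param config A [threshold_config()].
#' @return Numeric matrix with protein row names and model column names.
#' @export
build_fingerprints <- function(hits, candidates,
                               config = threshold_config()) {
  stopifnot(all(candidates %in% hits$protein_id))
  candidates <- sort(unique(candidates))
  h <- hits[hits$protein_id %in% candidates, , drop = FALSE]
  best <- tapply(h$bit_score, h$model_id, max)
  models <- sort(names(best)[best > config$fingerprint_min_bits])
  fp <- matrix(0, nrow = length(candidates), ncol = length(models),
               dimnames = list(candidates, models))
  keep <- h$model_id %in% models
  fp[cbind(match(h$protein_id[keep], candidates),
           match(h$model_id[keep], models))] <- h$bit_score[keep]
  if (config$cells_min_bits) fp[fp <= config$fingerprint_min_bits] <- 0
  zero <- rowSums(fp) == 0
  if (any(zero)) {
    warning("candidate(s) with all-zero fingerprint dropped: ",
            paste(rownames(fp)[zero], collapse = ", "))
    fp <- fp[!zero, , drop = FALSE]
  }
  fp
}

#' Write a fingerprint matrix as TSV
#'
#' @param fp Matrix from [build_fingerprints()].
#' @param path Output path.
#' @export
write_fingerprints <- function(fp, path) {
  df <- data.frame(protein_id = rownames(fp), fp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprints()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_fingerprints <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fp <- as.matrix(df[, -1, drop = FALSE])
  rownames(fp) <- df[[1]]
  fp
}
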