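# Collapse redundant sequences (fragments, predicted ORFs) to one
# representative per gene via a shared-annotation / high-identity-HSP graph,
# then apply the transmembrane-helix-count sanitization filter.

#' Collapse configuration
#'
#' Defaults encode the study rules: two sequences belong to the same gene
#' cluster when they share a gene annotation in one of six namespaces or an
#' HSP with strictly more than 95% identity; representatives must carry at
#' least 3 annotated TM helices unless rescued by name.
#'
#' @param min_hsp_identity Percent identity threshold (strict `>`).
#' @param annotation_namespaces Namespaces considered for label edges.
#' @param min_tmh Minimum TM helix count for the structural filter.
#' @param rescue_list Accessions exempt from the TMH filter.
#' @return A list of class `collapse_config`.
#' @export
collapse_config <- function(min_hsp_identity = 95,
                            annotation_namespaces = c("GN", "HGNC", "GeneID",
                                                      "UniGene", "FlyBase",
                                                      "KEGG"),
                            min_tmh = 3L,
                            rescue_list = character(0)) {
  stopifnot(min_hsp_identity > 0, min_hsp_identity < 100, min_tmh >= 0)
  structure(list(min_hsp_identity = min_hsp_identity,
                 annotation_namespaces = annotation_namespaces,
                 min_tmh = as.integer(min_tmh),
                 rescue_list = rescue_list),
            class = "collapse_config")
}

#' Build the redundancy graph over protein records
#'
#' Undirected edges: a `label` edge joins two records sharing at least one
#' identical (namespace, value) annotation in the configured namespaces; an
#' `hsp` edge joins two records linked by an HSP with identity strictly
#' above the threshold. HSPs mentioning unknown accessions are skipped with
#' a warning.
#'
#' @param records Record table ([protein_records()]).
#' @param hsps HSP data.frame ([parse_blast_tab()] layout).
#' @param config A [collapse_config()].
#' @return Data.frame of edges: `a`, `b`, `reason`.
#' @export
build_redundancy_graph <- function(records, hsps,
                                   config = collapse_config()) {
  acc <- records$accession
  edges <- data.frame(a = character(0), b = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  # label edges: group accessions by (namespace, value) key
  keys <- lapply(records$gene_labels, function(g) {
    ns <- sub(":.*$", "", g)
    g[ns %in% config$annotation_namespaces]
  })
  flat <- data.frame(acc = rep(acc, lengths(keys)),
                     key = unlist(keys), stringsAsFactors = FALSE)
  if (nrow(flat)) {
    for (members in split(flat$acc, flat$key)) {
      members <- sort(unique(members))
      if (length(members) > 1) {
        pr <- t(utils::combn(members, 2))
        edges <- rbind(edges, data.frame(a = pr[, 1], b = pr[, 2],
                                         reason = "shared-label",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(hsps)) {
    unknown <- !(hsps$query_id %in% acc) | !(hsps$subject_id %in% acc)
    if (any(unknown)) {
      warning("HSP(s) referencing unknown accession(s) skipped: ",
              paste(utils::head(unique(
                c(hsps$query_id[unknown], hsps$subject_id[unknown])), 5),
                collapse = ", "))
      hsps <- hsps[!unknown, , drop = FALSE]
    }
    strong <- hsps[hsps$pct_identity > config$min_hsp_identity, ,
                   drop = FALSE]
    if (nrow(strong)) {
      a <- pmin(strong$query_id, strong$subject_id)
      b <- pmax(strong$query_id, strong$subject_id)
      edges <- rbind(edges, data.frame(a = a, b = b, reason = "hsp",
                                       stringsAsFactors = FALSE))
    }
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  edges
}

#' Connected components of the redundancy graph
#'
#' @param nodes Character vector of accessions (singletons included).
#' @param edges Edge data.frame with columns `a`, `b`.
#' @return List of character vectors (sorted members), ordered by smallest
#'   member.
#' @export
connected_components <- function(nodes, edges) {
  if (!length(nodes)) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  out <- lapply(split(names(comp), comp), sort)
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Choose the representative of a gene cluster
#'
#' Exactly one reviewed (curated) member: that member. No reviewed member:
#' the longest sequence, ties broken by smallest accession. Two or more
#' reviewed members: the cluster is flagged `REVIEW` for manual splitting.
#'
#' @param members Character vector of cluster member accessions.
#' @param records Record table covering the members.
#' @return List with `members`, `representative` (accession or `NA` when
#'   flagged), and `review` (logical).
#' @export
select_representative <- function(members, records) {
  idx <- match(members, records$accession)
  stopifnot(!anyNA(idx))
  rev_members <- members[records$reviewed[idx]]
  if (length(rev_members) == 1L) {
    rep_acc <- rev_members
    review <- FALSE
  } else if (length(rev_members) == 0L) {
    len <- records$sequence_length[idx]
    best <- members[len == max(len)]
    rep_acc <- min(best)
    review <- FALSE
  } else {
    rep_acc <- NA_character_
    review <- TRUE
  }
  list(members = sort(members), representative = rep_acc, review = review)
}

# cross-namespace annotation conflict: >= 2 distinct values in one namespace
.has_label_conflict <- function(members, records,
                                namespaces) {
  idx <- match(members, records$accession)
  labs <- unlist(records$gene_labels[idx])
  if (!length(labs)) return(FALSE)
  ns <- sub(":.*$", "", labs)
  keep <- ns %in% namespaces
  labs <- unique(labs[keep]); ns <- sub(":.*$", "", labs)
  any(table(ns) > 1)
}

#' Collapse records to one representative per gene cluster
#'
#' Builds the redundancy graph, takes connected components, picks
#' representatives, and routes ambiguous clusters (multiple reviewed
#' members, or conflicting annotation values within a namespace) to the
#' review report.
#'
#' @param records Record table.
#' @param hsps HSP data.frame.
#' @param config A [collapse_config()].
#' @return List with `clusters` (list of cluster objects as from
#'   [select_representative()], plus `evidence` and `conflict` flags),
#'   `representatives` (accessions of auto-resolved clusters) and `review`
#'   (data.frame of clusters needing manual attention).
#' @export
collapse_fragments <- function(records, hsps, config = collapse_config()) {
  edges <- build_redundancy_graph(records, hsps, config)
  comps <- connected_components(records$accession, edges)
  clusters <- lapply(comps, function(members) {
    cl <- select_representative(members, records)
    cl$conflict <- .has_label_conflict(members, records,
                                       config$annotation_namespaces)
    ekeep <- edges$a %in% members & edges$b %in% members
    cl$evidence <- unique(edges$reason[ekeep])
    cl
  })
  needs_review <- vapply(clusters, function(cl) cl$review || cl$conflict,
                         logical(1))
  reps <- vapply(clusters[!needs_review], `[[`, character(1),
                 "representative")
  review <- data.frame(
    members = vapply(clusters[needs_review], function(cl)
      paste(cl$members, collapse = ";"), character(1)),
    reason = vapply(clusters[needs_review], function(cl)
      if (cl$review) "multiple-reviewed" else "annotation-conflict",
      character(1)),
    stringsAsFactors = FALSE)
  list(clusters = clusters, representatives = sort(reps), review = review)
}

#' Partition records by the TM-helix-count criterion
#'
#' Keeps records with at least `min_tmh` annotated TM segments or listed in
#' the rescue list; excludes annotated records below the threshold; records
#' with no TM annotation at all go to review.
#'
#' @param records Record table (normally restricted to representatives).
#' @param config A [collapse_config()].
#' @return List of accession vectors: `kept`, `excluded`, `review`.
#' @export
sanitize_by_tmh <- function(records, config = collapse_config()) {
  acc <- records$accession
  n_tm <- vapply(records$tm_segments, function(tm)
    if (is.null(tm)) NA_integer_ else nrow(tm), integer(1))
  rescued <- acc %in% config$rescue_list
  review <- is.na(n_tm) & !rescued
  kept <- !review & (rescued | n_tm >= config$min_tmh)
  list(kept = acc[kept],
       excluded = acc[!review & !kept],
       review = acc[review])
}
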