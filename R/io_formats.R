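#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames rnorm runif
NULL

#' Read a protein FASTA file
#'
#' Accessions are the first whitespace-delimited token of each header;
#' UniProt-style `db|ACC|name` headers are reduced to the central accession.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names = accessions).
#'   An empty file yields an empty vector.
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  bar <- grepl("^[^|]+\\|[^|]+\\|", acc)
  acc[bar] <- vapply(strsplit(acc[bar], "|", fixed = TRUE), `[`, character(1), 2L)
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(acc[!nzchar(seqs)], collapse = ", "))
  }
  setNames(seqs, acc)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector (names = accessions).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), filepath = path, width = 60L)
  invisible(path)
}

# domtblout column indices (HMMER 3 per-domain table):
# 1 target, 4 query(model), 7 full-seq E-value, 8 full-seq score,
# 16/17 hmm from/to, 18/19 ali from/to; >= 22 columns expected.
.DOMTBL_MIN_COLS <- 22L

#' Parse HMMER-3 per-domain tabular output (domtblout)
#'
#' One row is returned per domain line. The full-sequence bit score and
#' E-value are attached to every domain row of that (protein, model) pair;
#' coordinates come from the hmm-from/to and ali-from/to columns.
#'
#' @param path Path to a domtblout file ('#'-prefixed comment lines allowed).
#' @return A data.frame of HMM hits with columns `protein_id`, `model_id`,
#'   `bit_score`, `evalue`, `model_from`, `model_to`, `target_from`,
#'   `target_to`.
#' @export
parse_domtblout <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_hits())
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < .DOMTBL_MIN_COLS) {
      stop("domtblout line ", i, ": expected >= ", .DOMTBL_MIN_COLS,
           " columns, got ", length(f))
    }
    data.frame(
      protein_id = f[1], model_id = f[4],
      bit_score = as.numeric(f[8]), evalue = as.numeric(f[7]),
      model_from = as.integer(f[16]), model_to = as.integer(f[17]),
      target_from = as.integer(f[18]), target_to = as.integer(f[19]),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  bad <- which(hits$model_from > hits$model_to |
                 hits$target_from > hits$target_to)
  if (length(bad)) {
    stop("domtblout line ", idx[bad[1]],
         ": coordinate range reversed (from > to)")
  }
  if (any(!is.finite(hits$bit_score)) || any(hits$evalue < 0, na.rm = TRUE)) {
    stop("domtblout: non-finite bit score or negative E-value")
  }
  hits
}

empty_hits <- function() {
  data.frame(protein_id = character(0), model_id = character(0),
             bit_score = numeric(0), evalue = numeric(0),
             model_from = integer(0), model_to = integer(0),
             target_from = integer(0), target_to = integer(0),
             stringsAsFactors = FALSE)
}

#' Write hits in the domtblout dialect
#'
#' Emits a minimal HMMER-3 per-domain table (23 whitespace-separated
#' columns, '#' header comments) round-trippable by [parse_domtblout()].
#'
#' @param hits Data.frame as returned by [parse_domtblout()].
#' @param path Output path.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ----------"), con)
  if (nrow(hits)) {
    per_pair <- stats::ave(seq_len(nrow(hits)),
                    paste(hits$protein_id, hits$model_id, sep = "\r"),
                    FUN = seq_along)
    n_pair <- stats::ave(seq_len(nrow(hits)),
                  paste(hits$protein_id, hits$model_id, sep = "\r"),
                  FUN = length)
    lines <- sprintf(
      "%s - %d %s - %d %.3g %.1f 0.0 %d %d %.3g %.3g %.1f 0.0 %d %d %d %d %d %d 0.90 -",
      hits$protein_id, hits$target_to + 10L, hits$model_id,
      hits$model_to + 5L, hits$evalue, hits$bit_score,
      per_pair, n_pair, hits$evalue, hits$evalue, hits$bit_score,
      hits$model_from, hits$model_to, hits$target_from, hits$target_to,
      hits$target_from, hits$target_to)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' @param path Path to a 12-column BLAST tabular file.
#' @return A data.frame of HSPs (`query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`); self-hits (query == subject) are dropped.
#' @export
parse_blast_tab <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_length = integer(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t|\\s+")
  nc <- lengths(f)
  if (any(nc < 12L)) {
    stop("BLAST tabular line ", which(nc < 12L)[1], ": expected 12 columns")
  }
  m <- t(vapply(f, `[`, character(12L), 1:12))
  pid <- suppressWarnings(as.numeric(m[, 3]))
  len <- suppressWarnings(as.integer(m[, 4]))
  if (any(is.na(pid)) || any(is.na(len))) {
    stop("BLAST tabular line ", which(is.na(pid) | is.na(len))[1],
         ": non-numeric identity or alignment length")
  }
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    pct_identity = pid, aln_length = len,
                    stringsAsFactors = FALSE)
  out <- out[out$query_id != out$subject_id, , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("BLAST tabular: percent identity outside [0, 100]")
  }
  out
}

#' Parse a Newick tree
#'
#' Leaf labels of the form `gene<delim>species` are split into gene and
#' species components, returned in the `leaf_info` attribute.
#'
#' @param text Newick string (or a file path if `is_file = TRUE`).
#' @param delim Delimiter between gene and species in leaf labels.
#' @param is_file Treat `text` as a path.
#' @return An [ape::phylo] object with a `leaf_info` data.frame attribute
#'   (`label`, `gene`, `species`).
#' @export
parse_newick <- function(text, delim = "__", is_file = FALSE) {
  tr <- tryCatch(
    if (is_file) ape::read.tree(file = text) else ape::read.tree(text = text),
    error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf name(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  attr(tr, "leaf_info") <- split_leaf_labels(tr$tip.label, delim)
  tr
}

#' Split composite gene/species leaf labels
#'
#' @param labels Character vector of leaf labels.
#' @param delim Delimiter; text after the last occurrence is the species.
#' @return Data.frame with columns `label`, `gene`, `species` (`NA` species
#'   where the delimiter is absent).
#' @export
split_leaf_labels <- function(labels, delim = "__") {
  has <- grepl(delim, labels, fixed = TRUE)
  gene <- labels
  species <- rep(NA_character_, length(labels))
  if (any(has)) {
    # split on the LAST delimiter so gene names may themselves contain it
    parts <- strsplit(labels[has], delim, fixed = TRUE)
    species[has] <- vapply(parts, function(p) p[length(p)], character(1))
    gene[has] <- vapply(parts, function(p)
      paste(p[-length(p)], collapse = delim), character(1))
  }
  data.frame(label = labels, gene = gene, species = species,
             stringsAsFactors = FALSE)
}

#' Write a tab-separated table with header
#'
#' Fields must be tab-free; row and column order are preserved as given.
#'
#' @param rows Data.frame to write.
#' @param path Output path.
#' @param schema Optional character vector of required column names, in order.
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (!is.null(schema)) {
    if (!identical(names(rows), schema)) {
      stop("rows do not conform to schema: expected columns ",
           paste(schema, collapse = ", "))
    }
  }
  chr <- vapply(rows, function(col) is.character(col) || is.factor(col),
                logical(1))
  for (j in which(chr)) {
    if (any(grepl("[\t\n]", as.character(rows[[j]])))) {
      stop("field with embedded tab/newline in column '", names(rows)[j], "'")
    }
  }
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#'
#' @param path Input path.
#' @return Data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# ---- protein metadata (records) serialization -------------------------------

#' Construct a protein record table
#'
#' @param accession,species,sequence_length,reviewed Per-protein vectors.
#' @param gene_labels List of character vectors, entries `"namespace:value"`.
#' @param tm_segments List of two-column matrices (start, end), 1-based
#'   inclusive, sorted and non-overlapping; `NULL` = no TM annotation.
#' @return Data.frame with list-columns `gene_labels` and `tm_segments`.
#' @export
protein_records <- function(accession, species, sequence_length, reviewed,
                            gene_labels = NULL, tm_segments = NULL) {
  n <- length(accession)
  stopifnot(all(sequence_length > 0), !anyDuplicated(accession))
  if (is.null(gene_labels)) gene_labels <- rep(list(character(0)), n)
  if (is.null(tm_segments)) tm_segments <- rep(list(NULL), n)
  for (tm in tm_segments) {
    if (!is.null(tm) && nrow(tm) > 1) {
      stopifnot(all(tm[, 1] <= tm[, 2]),
                all(tm[-1, 1] > tm[-nrow(tm), 2]))
    }
  }
  out <- data.frame(accession = accession, species = species,
                    sequence_length = as.integer(sequence_length),
                    reviewed = as.logical(reviewed),
                    stringsAsFactors = FALSE)
  out$gene_labels <- gene_labels
  out$tm_segments <- tm_segments
  out
}

.fmt_segments <- function(tm) {
  if (is.null(tm) || nrow(tm) == 0L) return(NA_character_)
  paste(sprintf("%d-%d", tm[, 1], tm[, 2]), collapse = ";")
}

.parse_segments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

#' Write protein metadata as TSV
#'
#' `gene_labels` are `;`-joined `namespace:value` pairs; `tm_segments` are
#' `;`-joined `start-end` ranges (empty cell = no TM annotation).
#'
#' @param records Record table from [protein_records()].
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  flat <- data.frame(
    accession = records$accession, species = records$species,
    sequence_length = records$sequence_length, reviewed = records$reviewed,
    gene_labels = vapply(records$gene_labels,
                         function(g) paste(g, collapse = ";"), character(1)),
    tm_segments = vapply(records$tm_segments, .fmt_segments, character(1)),
    stringsAsFactors = FALSE)
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read protein metadata written by [write_records()]
#'
#' @param path Input path.
#' @return Record table in the [protein_records()] layout.
#' @export
read_records <- function(path) {
  flat <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE,
                     colClasses = c(gene_labels = "character",
                                    tm_segments = "character"))
  labs <- lapply(flat$gene_labels, function(s)
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]])
  tms <- lapply(flat$tm_segments, .parse_segments)
  protein_records(flat$accession, flat$species, flat$sequence_length,
                  flat$reviewed, labs, tms)
}
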