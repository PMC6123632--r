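## Readers and writers for the external formats the pipeline touches.
## Everything downstream consumes the in-memory forms returned here
## (sequence tables, ape phylo trees, incidence matrices, hit tables);
## no other module reads files directly.

.meta_keys <- c("phylum", "species", "site", "abundance")

#' Read sequences with in-band metadata from FASTA
#'
#' The description line may carry whitespace-separated \code{key=value}
#' metadata after the id; recognised keys are \code{phylum}, \code{species},
#' \code{site} and \code{abundance} (unknown keys are ignored). This keeps
#' truth labels of synthetic data in-band without a sidecar file.
#'
#' @param path FASTA file.
#' @return a data.frame with columns \code{id}, \code{seq}, \code{phylum},
#'   \code{species}, \code{site} (character, \code{NA} when absent) and
#'   \code{abundance} (integer, \code{NA} when absent). An empty file gives
#'   a zero-row table, not an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) mb_stop("file not found: ", path)
  if (file.size(path) == 0)
    return(sequence_table(character(), character()))
  dss <- Biostrings::readDNAStringSet(path)
  headers <- names(dss)
  tok <- strsplit(headers, "[ \t]+")
  ids <- vapply(tok, `[[`, "", 1L)
  if (anyDuplicated(ids))
    mb_stop("duplicate sequence id: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- lapply(tok, function(tt) {
    kv <- tt[-1][grepl("=", tt[-1], fixed = TRUE)]
    if (!length(kv)) return(character())
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    setNames(vals, keys)
  })
  pick <- function(key) vapply(meta, function(m)
    if (key %in% names(m)) unname(m[[key]]) else NA_character_, "")
  out <- sequence_table(ids, toupper(as.character(dss)),
                        phylum = pick("phylum"), species = pick("species"),
                        site = pick("site"),
                        abundance = suppressWarnings(as.integer(pick("abundance"))))
  validate_sequences(out)
  out
}

#' @rdname read_fasta
#' @param seqs a sequence table as returned by \code{read_fasta} (extra
#'   columns are ignored; \code{NA} metadata fields are omitted).
#' @param width line-wrap width for the sequence body.
#' @return \code{write_fasta} returns \code{path} invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- as_sequence_table(seqs)
  validate_sequences(seqs)
  headers <- vapply(seq_len(nrow(seqs)), function(i) {
    parts <- seqs$id[i]
    for (key in .meta_keys) {
      v <- seqs[[key]][i]
      if (!is.na(v)) parts <- c(parts, paste0(key, "=", v))
    }
    paste(parts, collapse = " ")
  }, "")
  dss <- Biostrings::DNAStringSet(seqs$seq)
  names(dss) <- headers
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Construct a sequence table
#'
#' The common in-memory currency for amplicons and reads: one row per
#' sequence with optional truth/location metadata.
#'
#' @param id unique ids.
#' @param seq nucleotide strings over A, C, G, T, N.
#' @param phylum,species,site optional character metadata.
#' @param abundance optional positive integer counts.
#' @return a data.frame with the six canonical columns.
#' @export
sequence_table <- function(id, seq, phylum = NA, species = NA, site = NA,
                           abundance = NA) {
  n <- length(id)
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    phylum = rep_len(as.character(phylum), n),
                    species = rep_len(as.character(species), n),
                    site = rep_len(as.character(site), n),
                    abundance = rep_len(as.integer(abundance), n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

as_sequence_table <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x)))
    mb_stop("expected a sequence table with columns id and seq")
  for (key in .meta_keys) if (is.null(x[[key]])) x[[key]] <- NA
  sequence_table(x$id, x$seq, x$phylum, x$species, x$site, x$abundance)
}

validate_sequences <- function(seqs) {
  if (!nrow(seqs)) return(invisible(seqs))
  if (any(!nzchar(seqs$id)) || anyNA(seqs$id))
    mb_stop("sequence ids must be non-empty")
  if (anyDuplicated(seqs$id))
    mb_stop("duplicate sequence id: ",
            paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "))
  if (any(!nzchar(seqs$seq)))
    mb_stop("zero-length sequence for id ",
            paste(seqs$id[!nzchar(seqs$seq)], collapse = ", "))
  if (any(grepl("[^ACGTN]", seqs$seq)))
    mb_stop("sequences must be over A, C, G, T, N")
  ab <- seqs$abundance
  if (any(!is.na(ab) & ab < 1))
    mb_stop("abundance must be >= 1 when present")
  invisible(seqs)
}

## locate the first structural problem in a newick string, for error offsets
newick_syntax_offset <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth > 0L) return(length(chars) + 1L)
  if (!any(chars == ";")) return(length(chars) + 1L)
  1L
}

#' Read a rooted tree from Newick, checking ultrametricity
#'
#' Internal node labels are retained as support values. Tip depths are
#' compared against the tree height: if their spread exceeds
#' \code{tol * height} the tree is flagged non-ultrametric (attribute
#' \code{"ultrametric"}), not rejected, because time-calibrated trees from
#' Bayesian samplers carry rounding error while simulated trees are exact.
#'
#' @param path Newick file (or a literal string containing ";").
#' @param tol relative tip-depth tolerance, as a fraction of tree height.
#' @return an \code{ape} \code{phylo} with attributes \code{ultrametric}
#'   (logical), \code{height} (max tip depth) and \code{tip_depth_spread}.
#' @export
read_newick <- function(path, tol = 1e-6) {
  text <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) mb_stop("file not found: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    mb_stop("newick syntax error at character offset ",
            newick_syntax_offset(text))
  if (is.null(tree$edge.length))
    mb_stop("tree has no branch lengths")
  annotate_ultrametric(tree, tol)
}

annotate_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  spread <- max(depths) - min(depths)
  attr(tree, "height") <- h
  attr(tree, "tip_depth_spread") <- spread
  attr(tree, "ultrametric") <- spread <= tol * max(h, .Machine$double.eps)
  tree
}

#' @rdname read_newick
#' @param tree a \code{phylo}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Extract numeric node support values from a tree
#'
#' @param tree a \code{phylo} whose internal node labels hold support.
#' @return numeric vector of length \code{Nnode(tree)} (\code{NA} where a
#'   label is absent or non-numeric), in ape internal-node order.
#' @export
node_support <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Read or write a binary unit-by-site incidence matrix
#'
#' TSV with unit ids in the first column (\code{unit}) and one 0/1 column
#' per site. Incidence is the common currency of all diversity
#' descriptors here; abundances are deliberately not carried.
#'
#' @param path TSV file.
#' @return an integer matrix, units in rows, sites in columns.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) mb_stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) mb_stop("incidence table needs a unit column and >= 1 site")
  units <- as.character(tab[[1]])
  if (anyDuplicated(units))
    mb_stop("duplicate unit id: ",
            paste(unique(units[duplicated(units)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    v <- m[i, j]
    if (is.na(v) || !(v %in% c(0, 1)))
      mb_stop("non-binary incidence cell at row ", units[i], ", column ",
              colnames(m)[j], ": ", v)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- units
  m
}

#' @rdname read_incidence
#' @param mat binary matrix with unit rownames and site colnames.
#' @export
write_incidence <- function(mat, path) {
  validate_incidence(mat)
  out <- data.frame(unit = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_incidence <- function(mat) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat)))
    mb_stop("incidence must be a matrix with unit rownames and site colnames")
  if (anyNA(mat) || !all(mat %in% c(0L, 1L)))
    mb_stop("incidence cells must be 0 or 1")
  invisible(mat)
}

.hit_cols <- c("query", "pct_identity", "align_span",
               "phylum", "family", "species")

#' Read a ranked similarity-hit table
#'
#' TSV with columns \code{query}, \code{subject_lineage} (semicolon-delimited,
#' highest rank first), \code{pct_identity}, \code{align_span}; a header row
#' is optional. Lineages are truncated to the three decision ranks
#' phylum; family; species. Hits are sorted per query by descending percent
#' identity with ties kept in file order.
#'
#' @param path TSV file.
#' @return a data.frame with columns \code{query}, \code{pct_identity},
#'   \code{align_span}, \code{phylum}, \code{family}, \code{species}.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) mb_stop("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("^query\t", first)
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                    col.names = c("query", "subject_lineage",
                                  "pct_identity", "align_span"))
  hit_table(tab$query, tab$subject_lineage, tab$pct_identity, tab$align_span)
}

#' @rdname read_hits
#' @param query,subject_lineage,pct_identity,align_span hit fields.
#' @export
hit_table <- function(query, subject_lineage, pct_identity, align_span) {
  pct_identity <- as.numeric(pct_identity)
  if (any(is.na(pct_identity) | pct_identity < 0 | pct_identity > 100))
    mb_stop("pct_identity outside [0, 100]")
  align_span <- as.numeric(align_span)
  if (any(is.na(align_span) | align_span < 0))
    mb_stop("align_span must be >= 0")
  ranks <- strsplit(as.character(subject_lineage), ";", fixed = TRUE)
  rank_at <- function(i) vapply(ranks, function(r) {
    v <- if (length(r) >= i) trimws(r[[i]]) else NA_character_
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }, "")
  out <- data.frame(query = as.character(query),
                    pct_identity = pct_identity, align_span = align_span,
                    phylum = rank_at(1), family = rank_at(2),
                    species = rank_at(3), stringsAsFactors = FALSE)
  bad <- !is.na(out$species) & is.na(out$family)
  if (any(bad))
    mb_stop("inconsistent lineage (species without family) for query ",
            paste(unique(out$query[bad]), collapse = ", "))
  # stable sort: per query by descending identity, file order breaking ties
  out <- out[order(out$query, -out$pct_identity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_hits
#' @param hits a hit table.
#' @export
write_hits <- function(hits, path) {
  lineage <- vapply(seq_len(nrow(hits)), function(i) {
    r <- c(hits$phylum[i], hits$family[i], hits$species[i])
    paste(r[!is.na(r)], collapse = ";")
  }, "")
  out <- data.frame(query = hits$query, subject_lineage = lineage,
                    pct_identity = hits$pct_identity,
                    align_span = hits$align_span, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.covariate_cols <- c("site", "depth", "salinity", "mean_grain_size",
                     "sorting", "skewness", "kurtosis")

#' Read or write a site covariate table
#'
#' One row per site with depth (m), salinity (unitless), mean grain size
#' (micrometers) and the grain-size distribution statistics sorting,
#' skewness and kurtosis.
#'
#' @param path TSV file with a header.
#' @return a data.frame with the seven canonical columns.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) mb_stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.covariate_cols, names(tab))
  if (length(missing))
    mb_stop("covariate table missing columns: ",
            paste(missing, collapse = ", "))
  tab <- tab[, .covariate_cols]
  validate_covariates(tab)
  tab
}

#' @rdname read_covariates
#' @param covariates a covariate data.frame.
#' @export
write_covariates <- function(covariates, path) {
  validate_covariates(covariates)
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_covariates <- function(tab) {
  if (anyNA(tab$site) || any(!nzchar(tab$site)) || anyDuplicated(tab$site))
    mb_stop("covariate sites must be non-empty and unique")
  if (any(tab$depth < 0, na.rm = TRUE)) mb_stop("depth must be >= 0")
  if (any(tab$salinity < 0, na.rm = TRUE)) mb_stop("salinity must be >= 0")
  if (any(tab$mean_grain_size <= 0, na.rm = TRUE))
    mb_stop("mean_grain_size must be > 0")
  invisible(tab)
}
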