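## Consensus-taxonomy classification of query sequences from ranked
## similarity hits, plus the phylogenetic clade-rescue rule for queries
## the consensus leaves unassigned.

#' Filter ranked similarity hits for one query
#'
#' Hits with alignment span not exceeding \code{min_span} are dropped
#' first; the top hit is then determined among the survivors and hits
#' falling more than \code{top_window} identity points below it are
#' dropped; at most \code{k} hits are kept. Comparisons are strict
#' (span > 120 bp, identity within 0.5 of the top).
#'
#' @param hits data.frame of hits for a single query, sorted by descending
#'   \code{pct_identity} (as \code{\link{read_hits}} returns them).
#' @param top_window identity window below the top hit.
#' @param min_span minimum alignment span (strict).
#' @param k maximum number of retained hits.
#' @return the retained rows, in order; zero rows if none qualify.
#' @export
filter_hits <- function(hits, top_window = 0.5, min_span = 120, k = 5) {
  if (!nrow(hits)) return(hits)
  if (is.unsorted(rev(hits$pct_identity)))
    mb_stop("hits must be sorted by descending pct_identity")
  keep <- hits[hits$align_span > min_span, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  top <- keep$pct_identity[1]
  keep <- keep[keep$pct_identity >= top - top_window, , drop = FALSE]
  head(keep, k)
}

.rank_order <- c("phylum", "family", "species")

#' Consensus taxonomy from filtered hits
#'
#' The best-hit identity sets a ceiling rank (species if > 97, family if
#' > 93, phylum if > 90, otherwise unassigned); the assignment is the
#' deepest rank at or above that ceiling on which \emph{all} retained hits
#' agree (the lowest common lineage prefix). If the hits do not even agree
#' at phylum the query stays unassigned.
#'
#' @param filtered_hits output of \code{\link{filter_hits}} for one query.
#' @param thresholds identity ceilings, named or ordered
#'   (species, family, phylum).
#' @param query query id to record (defaults to the hits' query).
#' @return one-row data.frame: \code{query}, \code{rank} (species, family,
#'   phylum or unassigned), \code{label}, \code{phylum} (the agreed phylum
#'   when any), \code{basis}.
#' @export
consensus_taxonomy <- function(filtered_hits, thresholds = c(97, 93, 90),
                               query = NULL) {
  if (is.null(query))
    query <- if (nrow(filtered_hits)) filtered_hits$query[1] else NA_character_
  unassigned <- data.frame(query = query, rank = "unassigned", label = "",
                           phylum = NA_character_, basis = "consensus",
                           stringsAsFactors = FALSE)
  if (!nrow(filtered_hits)) return(unassigned)
  best <- filtered_hits$pct_identity[1]
  ceiling_rank <- if (best > thresholds[1]) 3L else
    if (best > thresholds[2]) 2L else
      if (best > thresholds[3]) 1L else 0L
  if (ceiling_rank == 0L) return(unassigned)
  agree_at <- function(col) {
    v <- filtered_hits[[col]]
    if (anyNA(v) || length(unique(v)) != 1L) NA_character_ else v[1]
  }
  depth <- 0L
  label <- NA_character_
  agreed_phylum <- NA_character_
  for (d in seq_len(ceiling_rank)) {
    v <- agree_at(.rank_order[d])
    if (is.na(v)) break
    depth <- d
    label <- v
    if (d == 1L) agreed_phylum <- v
  }
  if (depth == 0L) return(unassigned)
  data.frame(query = query, rank = .rank_order[depth], label = label,
             phylum = agreed_phylum, basis = "consensus",
             stringsAsFactors = FALSE)
}

#' Classify every query in a hit table
#'
#' Applies \code{\link{filter_hits}} then \code{\link{consensus_taxonomy}}
#' per query.
#'
#' @param hits a hit table (\code{\link{read_hits}}).
#' @param cfg a \code{\link{pipeline_config}} supplying the thresholds.
#' @return an assignment data.frame, one row per query, in query order.
#' @export
classify_hits <- function(hits, cfg = pipeline_config()) {
  queries <- unique(hits$query)
  out <- lapply(queries, function(q) {
    hq <- hits[hits$query == q, , drop = FALSE]
    fh <- filter_hits(hq, cfg$top_window, cfg$min_span, cfg$top_k)
    consensus_taxonomy(fh, thresholds = cfg$rank_thresholds, query = q)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Phylum rescue of unassigned tips via supported clades
#'
#' For each unassigned query that is a tip of the tree, the smallest
#' ancestral clade with support at least \code{support_min} is located; if
#' that clade contains at least \code{min_clade} \emph{other} tips, all of
#' them assigned and all to one phylum, the query is assigned that phylum
#' (basis \code{"clade_rescue"}). Previously assigned tips are never
#' changed. Nodes without a numeric support value are treated as
#' unsupported.
#'
#' @param tree a rooted \code{phylo} whose tips include all queries and
#'   whose internal node labels carry support values.
#' @param assignments assignment data.frame (\code{\link{classify_hits}}).
#' @param min_clade minimum number of other qualifying tips.
#' @param support_min minimum node support.
#' @return the assignments with rescued rows updated.
#' @export
clade_rescue <- function(tree, assignments, min_clade = 5,
                         support_min = 0.95) {
  missing <- setdiff(assignments$query, tree$tip.label)
  if (length(missing))
    mb_stop("query tips absent from tree: ", paste(missing, collapse = ", "))
  ntip <- ape::Ntip(tree)
  support <- node_support(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  tipsets <- c(as.list(seq_len(ntip)), vector("list", tree$Nnode))
  for (e in seq_len(nrow(po))) {
    tipsets[[po[e, 1]]] <- c(tipsets[[po[e, 1]]], tipsets[[po[e, 2]]])
  }
  phylum_of <- setNames(assignments$phylum, assignments$query)
  assigned <- setNames(assignments$rank != "unassigned", assignments$query)
  for (i in which(!assigned[assignments$query])) {
    q <- assignments$query[i]
    tip <- match(q, tree$tip.label)
    nd <- parent[tip]
    clade <- 0L
    while (nd != 0L) {
      sup <- support[nd - ntip]
      if (!is.na(sup) && sup >= support_min) { clade <- nd; break }
      nd <- parent[nd]
    }
    if (clade == 0L) next
    others <- setdiff(tree$tip.label[tipsets[[clade]]], q)
    if (length(others) < min_clade) next
    known <- others %in% names(assigned)
    if (!all(known) || !all(assigned[others])) next
    ph <- unique(phylum_of[others])
    ph <- ph[!is.na(ph)]
    if (length(ph) != 1L || length(ph) != length(unique(phylum_of[others])))
      next
    assignments$rank[i] <- "phylum"
    assignments$label[i] <- ph
    assignments$phylum[i] <- ph
    assignments$basis[i] <- "clade_rescue"
  }
  assignments
}

#' Naive top-k similarity search against a lineage-labelled reference
#'
#' A self-contained stand-in for an external similarity search: every
#' query is globally aligned (\code{\link{percent_identity}}) against every
#' reference and the top \code{k} references by identity are returned as a
#' hit table, ties broken by reference id. The reported span is the number
#' of alignment columns.
#'
#' @param query_seqs sequence table of queries.
#' @param reference_seqs sequence table whose \code{phylum} (and optionally
#'   \code{species}) columns carry the lineage; a \code{family} column is
#'   honoured when present.
#' @param k hits per query.
#' @return a hit table data.frame (same shape as \code{\link{read_hits}}).
#' @export
naive_search <- function(query_seqs, reference_seqs, k = 5) {
  if (!nrow(reference_seqs)) mb_stop("empty reference set")
  query_seqs <- as_sequence_table_keep(query_seqs)
  # without family labels the species label is reused as its own family so
  # the phylum > family > species rank ladder stays consistent
  fam <- if (!is.null(reference_seqs$family)) reference_seqs$family
         else reference_seqs$species
  res <- vector("list", 0)
  for (i in seq_len(nrow(query_seqs))) {
    pid <- numeric(nrow(reference_seqs))
    span <- numeric(nrow(reference_seqs))
    for (j in seq_len(nrow(reference_seqs))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(query_seqs$seq[i]),
        Biostrings::DNAString(reference_seqs$seq[j]), type = "global",
        substitutionMatrix = .mb_submat(), gapOpening = 0, gapExtension = 2)
      pid[j] <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      span[j] <- Biostrings::nchar(aln)
    }
    ord <- order(-pid, reference_seqs$id)[seq_len(min(k, length(pid)))]
    res[[i]] <- data.frame(
      query = query_seqs$id[i],
      pct_identity = 100 * pid[ord], align_span = span[ord],
      phylum = reference_seqs$phylum[ord], family = fam[ord],
      species = reference_seqs$species[ord], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
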