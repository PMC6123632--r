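## Unit delimitation: exact dereplication with an abundance-ratio denoiser
## (sequence variants), greedy centroid clustering at an identity threshold
## (OTUs / eOTUs), and the shared pairwise-identity primitive.

.mb_submat <- function() {
  if (is.null(.mb_env$submat))
    .mb_env$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
  .mb_env$submat
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap cost of 2 per base; identity is matches divided by aligned
#' columns (a pairwise global alignment has no gap-gap columns; gap-base
#' columns count in the denominator). The scoring is pinned so that
#' identity thresholds have a fixed meaning.
#'
#' @param a,b non-empty nucleotide strings.
#' @return identity as a fraction in [0, 1]; symmetric in its arguments.
#' @export
percent_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) mb_stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .mb_submat(), gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Construct a unit set
#'
#' The result of one delimitation method: a partition of sequence ids into
#' units with per-site occurrence counts and (optionally) a phylum label
#' per unit.
#'
#' @param method one of \code{"morphotype"}, \code{"entity"}, \code{"otu"},
#'   \code{"eotu"}, \code{"sv"}.
#' @param units named list mapping unit id to member sequence ids.
#' @param site_counts units-by-sites integer matrix.
#' @param phylum optional named character vector (per unit).
#' @return a list of class \code{"unit_set"}.
#' @export
unit_set <- function(method, units, site_counts, phylum = NULL) {
  method <- match.arg(method, c("morphotype", "entity", "otu", "eotu", "sv"))
  members <- unlist(units, use.names = FALSE)
  if (anyDuplicated(members))
    mb_stop("unit members must partition the input ids (duplicated member)")
  if (length(units)) {
    stopifnot(is.matrix(site_counts),
              identical(rownames(site_counts), names(units)))
    if (any(rowSums(site_counts) < 1))
      mb_stop("every retained unit must occur at >= 1 site")
  }
  structure(list(method = method, units = units,
                 site_counts = site_counts, phylum = phylum),
            class = "unit_set")
}

#' @export
print.unit_set <- function(x, ...) {
  cat(sprintf("unit_set (%s): %d units, %d member sequences, %d sites\n",
              x$method, length(x$units),
              length(unlist(x$units, use.names = FALSE)),
              ncol(x$site_counts)))
  invisible(x)
}

## aggregate per-site occurrence counts for groups of member rows
site_count_matrix <- function(groups, seqs, unit_ids) {
  site <- seqs$site
  site[is.na(site)] <- "all"
  sites <- sort(unique(site))
  ab <- seqs$abundance
  ab[is.na(ab)] <- 1L
  m <- matrix(0L, length(groups), length(sites),
              dimnames = list(unit_ids, sites))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    tt <- tapply(ab[rows], site[rows], sum)
    m[i, names(tt)] <- as.integer(tt)
  }
  m
}

majority_phylum <- function(groups, seqs) {
  if (is.null(seqs$phylum) || all(is.na(seqs$phylum))) return(NULL)
  vapply(groups, function(rows) {
    ph <- seqs$phylum[rows]
    ph <- ph[!is.na(ph)]
    if (!length(ph)) return(NA_character_)
    names(sort(table(ph), decreasing = TRUE))[1]
  }, "")
}

#' Dereplicate reads and denoise into sequence variants
#'
#' Reads (same region, equal trimmed length) are first dereplicated
#' exactly. A unique sequence with total abundance below
#' \code{min_abundance} that lies within \code{max_err_links} substitutions
#' of a unique sequence at least ten times more abundant is treated as a
#' sequencing-error satellite and merged into that sequence (counts and
#' per-site occurrences carried over); remaining low-abundance uniques are
#' dropped. This abundance-ratio rule is a fully specified stand-in for
#' learned error models: it preserves the qualitative contrast that
#' denoised variant counts do not exceed clustered OTU counts on noisy
#' data.
#'
#' @param reads sequence table; \code{site} and \code{abundance} columns are
#'   honoured when present.
#' @param min_abundance minimum retained abundance.
#' @param max_err_links maximum substitutions to an error parent.
#' @return a \code{\link{unit_set}} with method \code{"sv"}, units ordered
#'   by decreasing abundance (ids \code{sv1}, \code{sv2}, ...). The
#'   representative sequence of each unit is in attribute
#'   \code{"centroid"}.
#' @export
dereplicate_and_denoise <- function(reads, min_abundance = 2,
                                    max_err_links = 1) {
  reads <- as_sequence_table_keep(reads)
  if (!nrow(reads))
    return(unit_set("sv", list(), matrix(0L, 0, 0)))
  lens <- nchar(reads$seq)
  if (length(unique(lens)) > 1)
    mb_stop("reads have unequal lengths; trim them to a common length ",
            "(e.g. truncate to 130 bp) before denoising")
  ab <- reads$abundance
  ab[is.na(ab)] <- 1L
  key <- reads$seq
  uniq <- sort(unique(key))
  rows_of <- split(seq_len(nrow(reads)), key)[uniq]
  tot <- vapply(rows_of, function(r) sum(ab[r]), 0)
  # deterministic processing order: abundance descending, sequence as tie-break
  ord <- order(-tot, uniq)
  uniq <- uniq[ord]; rows_of <- rows_of[ord]; tot <- tot[ord]
  alive <- rep(TRUE, length(uniq))
  # satellites processed from rarest upward so chains collapse onto parents
  for (i in rev(seq_along(uniq))) {
    if (tot[i] >= min_abundance) next
    cand <- which(alive & tot >= 10 * tot[i])
    cand <- cand[cand != i]
    hit <- NA_integer_
    for (j in cand) {  # cand is already in decreasing-abundance order
      if (hamming(uniq[i], uniq[j]) <= max_err_links) { hit <- j; break }
    }
    if (!is.na(hit)) {
      rows_of[[hit]] <- c(rows_of[[hit]], rows_of[[i]])
      tot[hit] <- tot[hit] + tot[i]
      alive[i] <- FALSE
    }
  }
  keep <- alive & tot >= min_abundance
  dropped <- sum(alive & !keep)
  if (dropped) mb_log("debug", dropped, " low-abundance uniques dropped")
  rows_of <- rows_of[keep]; uniq <- uniq[keep]; tot <- tot[keep]
  ord <- order(-tot, uniq)
  rows_of <- rows_of[ord]; uniq <- uniq[ord]; tot <- tot[ord]
  ids <- if (length(uniq)) paste0("sv", seq_along(uniq)) else character()
  units <- setNames(lapply(rows_of, function(r) reads$id[r]), ids)
  ph <- majority_phylum(rows_of, reads)
  if (!is.null(ph)) names(ph) <- ids
  us <- unit_set("sv", units, site_count_matrix(rows_of, reads, ids),
                 phylum = ph)
  attr(us, "centroid") <- setNames(uniq, ids)
  attr(us, "abundance") <- setNames(as.integer(tot), ids)
  us
}

as_sequence_table_keep <- function(x) {
  out <- as_sequence_table(x)
  validate_sequences(out)
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in order of decreasing abundance (ties broken by
#' id, lexicographically) and assigned to the first existing centroid whose
#' global pairwise identity (\code{\link{percent_identity}}) reaches the
#' threshold; otherwise they found a new centroid. Reverse-strand matches
#' are allowed: if the forward comparison fails, the reverse complement of
#' the sequence is tried.
#'
#' @param seqs sequence table; \code{site} and \code{abundance} honoured.
#' @param identity_threshold fraction in (0.5, 1].
#' @param method unit-set tag, \code{"otu"} (default) or \code{"eotu"}.
#' @return a \code{\link{unit_set}}; centroid sequences in attribute
#'   \code{"centroid"}.
#' @export
cluster_greedy <- function(seqs, identity_threshold = 0.99, method = "otu") {
  if (identity_threshold <= 0.5 || identity_threshold > 1)
    mb_stop("identity_threshold must be in (0.5, 1]")
  seqs <- as_sequence_table_keep(seqs)
  if (!nrow(seqs))
    return(unit_set(method, list(), matrix(0L, 0, 0)))
  ab <- seqs$abundance
  ab[is.na(ab)] <- 1L
  ord <- order(-ab, seqs$id)
  centroids <- character()
  assignment <- integer(nrow(seqs))
  for (i in ord) {
    s <- seqs$seq[i]
    rc <- NULL
    placed <- 0L
    for (k in seq_along(centroids)) {
      if (percent_identity(s, centroids[k]) >= identity_threshold) {
        placed <- k; break
      }
      if (is.null(rc)) rc <- revcomp(s)
      if (percent_identity(rc, centroids[k]) >= identity_threshold) {
        placed <- k; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, s)
      placed <- length(centroids)
    }
    assignment[i] <- placed
  }
  ids <- paste0(method, seq_along(centroids))
  groups <- split(seq_len(nrow(seqs)), assignment)[as.character(seq_along(centroids))]
  units <- setNames(lapply(groups, function(r) seqs$id[r]), ids)
  ph <- majority_phylum(groups, seqs)
  if (!is.null(ph)) names(ph) <- ids
  us <- unit_set(method, units, site_count_matrix(groups, seqs, ids),
                 phylum = ph)
  attr(us, "centroid") <- setNames(centroids, ids)
  us
}

#' Per-site unit richness
#'
#' @param x a \code{\link{unit_set}}.
#' @return named integer vector: number of units present at each site.
#' @export
richness_by_site <- function(x) {
  stopifnot(inherits(x, "unit_set"))
  if (!length(x$units)) return(setNames(integer(0), character(0)))
  colSums(x$site_counts >= 1)
}

#' Convert a unit set to a binary incidence matrix
#'
#' @param x a \code{\link{unit_set}}.
#' @return integer units-by-sites matrix of 0/1 occurrences.
#' @export
as_incidence <- function(x) {
  stopifnot(inherits(x, "unit_set"))
  m <- (x$site_counts >= 1) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write or read a unit set as TSV
#'
#' Columns: unit_id, method, phylum, member_ids (comma-separated), then one
#' count column per site.
#'
#' @param x a \code{\link{unit_set}}.
#' @param path TSV file.
#' @return \code{read_units} returns a \code{unit_set}.
#' @export
write_units <- function(x, path) {
  stopifnot(inherits(x, "unit_set"))
  ph <- if (is.null(x$phylum)) rep(NA_character_, length(x$units)) else
    unname(x$phylum[names(x$units)])
  out <- data.frame(
    unit_id = names(x$units), method = x$method, phylum = ph,
    member_ids = vapply(x$units, paste, "", collapse = ","),
    x$site_counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("unit_id", "method", "phylum", "member_ids")
  if (!all(need %in% names(tab)))
    mb_stop("unit table missing columns: ",
            paste(setdiff(need, names(tab)), collapse = ", "))
  counts <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$unit_id
  units <- setNames(strsplit(tab$member_ids, ",", fixed = TRUE), tab$unit_id)
  ph <- setNames(tab$phylum, tab$unit_id)
  if (all(is.na(ph))) ph <- NULL
  unit_set(unique(tab$method), units, counts, phylum = ph)
}

#' Per-method sequence-variant unit sets from a simulated survey
#'
#' Splits the survey reads by observation method and denoises each set
#' into sequence variants, giving directly comparable \code{unit_set}s
#' for \code{\link{compare_methods}}.
#'
#' @param survey an \code{mb_survey} (see \code{\link{simulate_survey}}).
#' @param min_abundance,max_err_links passed to
#'   \code{\link{dereplicate_and_denoise}}.
#' @return named list of \code{unit_set}s, one per method.
#' @export
survey_unit_sets <- function(survey, min_abundance = 2, max_err_links = 1) {
  stopifnot(inherits(survey, "mb_survey"))
  reads <- survey$reads
  methods <- unique(reads$method)
  sites <- colnames(survey$incidence_true)
  out <- lapply(methods, function(me) {
    us <- dereplicate_and_denoise(reads[reads$method == me, , drop = FALSE],
                                  min_abundance, max_err_links)
    # align site columns across methods (absent sites become zero columns)
    m <- matrix(0L, length(us$units), length(sites),
                dimnames = list(names(us$units), sites))
    common <- intersect(colnames(us$site_counts), sites)
    m[, common] <- us$site_counts[, common]
    us$site_counts <- m
    us
  })
  setNames(out, methods)
}
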