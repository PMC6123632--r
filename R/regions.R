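## Primer location, variable-region extraction and per-group divergence
## profiles (the V1-V2 versus V9 comparison). Primer matching is ungapped
## Hamming distance over sliding windows with IUPAC expansion: primers are
## short, so gapped placement adds ambiguity without benefit.

.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

## mismatch counts of `primer` (IUPAC) against every window of `seq`
primer_mismatch_profile <- function(seq, primer) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(primer), "")[[1]]
  L <- length(s); k <- length(p)
  if (k > L) return(integer(0))
  n_win <- L - k + 1L
  mm <- integer(n_win)
  for (i in seq_len(k)) {
    ok <- s[i:(i + n_win - 1L)] %in% .iupac[[p[i]]]
    mm <- mm + !ok
  }
  mm
}

region_hit <- function(seq_id = NA_character_, region_name = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_, fwd_mismatches = NA_integer_,
                       rev_mismatches = NA_integer_, found = FALSE) {
  data.frame(seq_id = seq_id, region_name = region_name,
             start = start, end = end, strand = strand,
             fwd_mismatches = fwd_mismatches,
             rev_mismatches = rev_mismatches, found = found,
             stringsAsFactors = FALSE)
}

#' Locate a primer pair and the region between them
#'
#' Searches for the forward primer and, downstream of it, the reverse
#' complement of the reverse primer, keeping the lowest-mismatch
#' (leftmost on ties) placements within \code{max_mismatch} each. Both
#' strands are searched; a minus-strand match is reported in forward
#' coordinates. The region is the 0-based half-open interval between the
#' forward primer's 3' end and the reverse primer's 5' start — primer
#' sites themselves are excluded.
#'
#' @param seq nucleotide string.
#' @param fwd_primer,rev_primer primers (IUPAC codes allowed).
#' @param max_mismatch maximum mismatches per primer.
#' @return a one-row data.frame: \code{start}, \code{end}, \code{strand},
#'   \code{fwd_mismatches}, \code{rev_mismatches}, \code{found}. A
#'   sequence without a qualifying placement gets \code{found = FALSE}
#'   (not an error).
#' @export
locate_primer_pair <- function(seq, fwd_primer, rev_primer,
                               max_mismatch = 2) {
  seq <- toupper(seq)
  hit_on <- function(s) {
    mm_f <- primer_mismatch_profile(s, fwd_primer)
    mm_r <- primer_mismatch_profile(s, revcomp(rev_primer))
    kf <- nchar(fwd_primer); kr <- nchar(rev_primer)
    best <- NULL
    cand_f <- which(mm_f <= max_mismatch)
    if (!length(cand_f)) return(NULL)
    # best = fewest total mismatches; ties to leftmost fwd then leftmost rev
    for (i in cand_f[order(mm_f[cand_f], cand_f)]) {
      jmin <- i + kf  # rev site must start at/after the fwd 3' end
      cand_r <- which(mm_r <= max_mismatch)
      cand_r <- cand_r[cand_r >= jmin]
      if (!length(cand_r)) next
      j <- cand_r[order(mm_r[cand_r], cand_r)][1]
      tot <- mm_f[i] + mm_r[j]
      if (is.null(best) || tot < best$tot) {
        best <- list(i = i, j = j, mmf = mm_f[i], mmr = mm_r[j], tot = tot)
        if (tot == 0) break
      }
    }
    best
  }
  fw <- hit_on(seq)
  if (!is.null(fw)) {
    return(region_hit(start = fw$i + nchar(fwd_primer) - 1L,
                      end = fw$j - 1L, strand = "+",
                      fwd_mismatches = fw$mmf, rev_mismatches = fw$mmr,
                      found = TRUE))
  }
  rc <- hit_on(revcomp(seq))
  if (!is.null(rc)) {
    L <- nchar(seq)
    # map the interval found on the reverse strand back to forward coords
    start_rc <- rc$i + nchar(fwd_primer) - 1L
    end_rc <- rc$j - 1L
    return(region_hit(start = L - end_rc, end = L - start_rc, strand = "-",
                      fwd_mismatches = rc$mmf, rev_mismatches = rc$mmr,
                      found = TRUE))
  }
  region_hit(found = FALSE)
}

#' Extract variable regions from sequences
#'
#' Locates each region's primer pair in every sequence and extracts the
#' between-primer interval (minus-strand hits are reverse-complemented so
#' all extracted regions are on the forward strand of the region).
#' Sequences lacking a region are omitted from that region's output with
#' a logged count.
#'
#' @param seqs sequence table.
#' @param region_specs list of \code{\link{region_spec}}s.
#' @param max_mismatch per-primer mismatch allowance.
#' @return named list (per region) of sequence tables; each also carries
#'   the per-sequence hits in attribute \code{"hits"}.
#' @export
extract_regions <- function(seqs, region_specs, max_mismatch = 2) {
  seqs <- as_sequence_table_keep(seqs)
  out <- list()
  for (rg in region_specs) {
    hits <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
      h <- locate_primer_pair(seqs$seq[i], rg$fwd_primer, rg$rev_primer,
                              max_mismatch)
      h$seq_id <- seqs$id[i]
      h$region_name <- rg$name
      h
    }))
    found <- hits$found
    if (any(!found))
      mb_log("info", sum(!found), " sequences lack region ", rg$name)
    sub <- seqs[found, , drop = FALSE]
    hh <- hits[found, , drop = FALSE]
    extr <- vapply(seq_len(nrow(sub)), function(i) {
      frag <- substr(sub$seq[i], hh$start[i] + 1L, hh$end[i])
      if (hh$strand[i] == "-") revcomp(frag) else frag
    }, "")
    reg <- sub
    reg$seq <- extr
    keep <- nchar(reg$seq) > 0
    reg <- reg[keep, , drop = FALSE]
    rownames(reg) <- NULL
    attr(reg, "hits") <- hits
    out[[rg$name]] <- reg
  }
  out
}

#' Per-group mean pairwise identity of extracted regions
#'
#' For every group (e.g. phylum) and region with at least two sequences,
#' the mean of \code{\link{percent_identity}} over all unordered pairs.
#' Singleton cells are reported with \code{n = 1} and an undefined mean.
#'
#' @param extracted named list of per-region sequence tables
#'   (\code{\link{extract_regions}}).
#' @param group_labels optional named vector mapping sequence id to group;
#'   defaults to each table's \code{phylum} column.
#' @return data.frame: \code{group}, \code{region}, \code{n},
#'   \code{mean_identity} (fraction in [0, 1], \code{NA} when n < 2).
#' @export
region_identity_profile <- function(extracted, group_labels = NULL) {
  rows <- list()
  for (rg in names(extracted)) {
    tab <- extracted[[rg]]
    groups <- if (is.null(group_labels)) tab$phylum
              else unname(group_labels[tab$id])
    for (g in sort(unique(groups[!is.na(groups)]))) {
      ss <- tab$seq[!is.na(groups) & groups == g]
      n <- length(ss)
      mi <- NA_real_
      if (n >= 2) {
        prs <- utils::combn(n, 2)
        mi <- mean(vapply(seq_len(ncol(prs)), function(k)
          percent_identity(ss[prs[1, k]], ss[prs[2, k]]), 0))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = rg, n = n, mean_identity = mi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
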