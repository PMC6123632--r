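## Incidence-based richness estimators and phylogenetic diversity
## descriptors. Conventions pinned here: Faith's PD excludes the edge
## above the tip set's MRCA (so PD of a single tip is 0), and the SES null
## shuffles tip labels uniformly without replacement.

incidence_stats <- function(incidence) {
  validate_incidence(incidence)
  freq <- rowSums(incidence)
  list(S_obs = sum(freq >= 1), Q1 = sum(freq == 1), Q2 = sum(freq == 2),
       m = ncol(incidence))
}

#' Chao2 incidence-based richness estimator
#'
#' \eqn{S_{obs} + \frac{m-1}{m} \frac{Q_1^2}{2 Q_2}} where \eqn{Q_1, Q_2}
#' are the numbers of units found in exactly one or two sites over m
#' sites. When \eqn{Q_2 = 0} the bias-corrected form
#' \eqn{S_{obs} + \frac{m-1}{m} Q_1 (Q_1 - 1) / 2} avoids division by
#' zero (logged at debug level when used).
#'
#' @param incidence binary units-by-sites matrix.
#' @return the richness estimate (always >= observed richness).
#' @examples
#' m <- matrix(c(1,1, 1,0, 0,1, 1,1, 1,1), 5, 2, byrow = TRUE,
#'             dimnames = list(paste0("u", 1:5), c("a", "b")))
#' chao2(m)
#' @export
chao2 <- function(incidence) {
  st <- incidence_stats(incidence)
  if (st$m < 1) mb_stop("need >= 1 site")
  corr <- if (st$Q2 > 0) {
    st$Q1^2 / (2 * st$Q2)
  } else {
    mb_log("debug", "chao2: Q2 = 0, using bias-corrected form")
    st$Q1 * (st$Q1 - 1) / 2
  }
  st$S_obs + (st$m - 1) / st$m * corr
}

#' First-order jackknife incidence-based richness estimator
#'
#' \eqn{S_{obs} + Q_1 (m-1)/m}.
#'
#' @inheritParams chao2
#' @return the richness estimate (always >= observed richness).
#' @export
jack1 <- function(incidence) {
  st <- incidence_stats(incidence)
  if (st$m < 1) mb_stop("need >= 1 site")
  st$S_obs + st$Q1 * (st$m - 1) / st$m
}

## edges on the path from each tip up to the root, as child-node sequences
check_tips <- function(tree, tip_set) {
  idx <- match(tip_set, tree$tip.label)
  if (anyNA(idx))
    mb_stop("unknown tips: ", paste(tip_set[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) mb_stop("duplicate tips in tip_set")
  idx
}

#' Faith's phylogenetic diversity
#'
#' The total branch length of the minimal subtree spanning the tip set:
#' the edges on the paths from each tip to the set's most recent common
#' ancestor. The edge above the MRCA is excluded and a single tip has
#' PD 0 (the convention matters when PD values are compared across sets).
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param tip_set non-empty character vector of tip labels.
#' @return summed branch length (>= 0).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))    # 2
#' faith_pd(tr, c("A", "B", "C"))  # 5
#' @export
faith_pd <- function(tree, tip_set) {
  idx <- check_tips(tree, tip_set)
  if (length(idx) == 1L) return(0)
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(length(parent))
  elen[tree$edge[, 2]] <- tree$edge.length
  # count how many focal tips lie below each node; edges with a count
  # strictly between 0 and |tip_set| are on the spanning subtree
  count <- integer(length(parent))
  count[idx] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    count[po[e, 1]] <- count[po[e, 1]] + count[po[e, 2]]
  span <- count > 0L & count < length(idx)
  sum(elen[span])
}

#' Mean pairwise and mean nearest-taxon patristic distance
#'
#' \code{mpd} averages the patristic distance over all unordered tip
#' pairs; \code{mntd} averages, over tips, the distance to the nearest
#' other tip in the set. Both need at least two tips.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param tip_set character vector of >= 2 tip labels.
#' @return a branch-length value.
#' @export
mpd <- function(tree, tip_set) {
  D <- patristic_submatrix(tree, tip_set)
  mean(D[lower.tri(D)])
}

#' @rdname mpd
#' @export
mntd <- function(tree, tip_set) {
  D <- patristic_submatrix(tree, tip_set)
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

patristic_submatrix <- function(tree, tip_set) {
  check_tips(tree, tip_set)
  if (length(tip_set) < 2) mb_stop("tip_set must contain >= 2 tips")
  ape::cophenetic.phylo(tree)[tip_set, tip_set]
}

#' Standardized effect size of a phylogenetic diversity metric
#'
#' Compares the observed metric against \code{null_reps} random tip sets
#' of equal size drawn uniformly without replacement from all tips of the
#' tree (unweighted tip-label shuffling). When the null has zero variance
#' (e.g. the tip set is all tips) the SES is undefined and flagged rather
#' than silently set to zero.
#'
#' @param metric \code{"mpd"}, \code{"mntd"}, \code{"pd"} or a function
#'   \code{f(tree, tip_set)}.
#' @param tree a \code{phylo}.
#' @param tip_set character vector of >= 2 tip labels.
#' @param null_reps number of null draws.
#' @param seed integer seed (runs are bit-reproducible).
#' @return a list of class \code{"pd_result"}: \code{observed},
#'   \code{null_mean}, \code{null_sd}, \code{ses} (NA when degenerate),
#'   \code{degenerate}, \code{null_reps}, \code{seed}.
#' @export
ses <- function(metric, tree, tip_set, null_reps = 999, seed = 1L) {
  f <- if (is.function(metric)) metric else
    switch(match.arg(metric, c("mpd", "mntd", "pd")),
           mpd = mpd, mntd = mntd, pd = faith_pd)
  check_tips(tree, tip_set)
  if (length(tip_set) < 2) mb_stop("tip_set must contain >= 2 tips")
  set.seed(as.integer(seed))
  obs <- f(tree, tip_set)
  nulls <- vapply(seq_len(null_reps), function(i)
    f(tree, sample(tree$tip.label, length(tip_set))), 0)
  mu <- mean(nulls)
  sdev <- sd(nulls)
  degenerate <- !is.finite(sdev) || sdev == 0
  if (degenerate)
    mb_log("warn", "SES null has zero variance; SES undefined")
  structure(list(observed = obs, null_mean = mu, null_sd = sdev,
                 ses = if (degenerate) NA_real_ else (obs - mu) / sdev,
                 degenerate = degenerate, null_reps = null_reps,
                 seed = as.integer(seed)),
            class = "pd_result")
}

#' @export
print.pd_result <- function(x, ...) {
  cat(sprintf("observed %.4f, null %.4f +/- %.4f (%d reps), SES %s\n",
              x$observed, x$null_mean, x$null_sd, x$null_reps,
              if (x$degenerate) "undefined (degenerate null)"
              else sprintf("%.3f", x$ses)))
  invisible(x)
}

#' Per-site diversity summary table
#'
#' Computes, for each site of an incidence matrix, the observed richness
#' and (from the units present there, when the tree covers them) Faith's
#' PD, MPD, MNTD and their standardized effect sizes; Chao2 and jack1 are
#' whole-matrix estimates repeated per row for reference.
#'
#' @param incidence binary units-by-sites matrix whose unit ids are tips
#'   of \code{tree} (units missing from the tree are skipped for the
#'   phylogenetic columns).
#' @param tree a \code{phylo}, or \code{NULL} to skip phylogenetic columns.
#' @param null_reps,seed passed to \code{\link{ses}}.
#' @return a data.frame, one row per site.
#' @export
diversity_table <- function(incidence, tree = NULL, null_reps = 999,
                            seed = 1L) {
  validate_incidence(incidence)
  sites <- colnames(incidence)
  out <- data.frame(site = sites,
                    S_obs = colSums(incidence >= 1),
                    chao2 = chao2(incidence), jack1 = jack1(incidence),
                    pd = NA_real_, mpd = NA_real_, mntd = NA_real_,
                    ses_mpd = NA_real_, ses_mntd = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.null(tree)) return(out)
  for (i in seq_along(sites)) {
    tips <- intersect(rownames(incidence)[incidence[, i] >= 1],
                      tree$tip.label)
    if (length(tips) >= 1) out$pd[i] <- faith_pd(tree, tips)
    if (length(tips) >= 2) {
      out$mpd[i] <- mpd(tree, tips)
      out$mntd[i] <- mntd(tree, tips)
      out$ses_mpd[i] <- ses("mpd", tree, tips, null_reps, seed)$ses
      out$ses_mntd[i] <- ses("mntd", tree, tips, null_reps, seed)$ses
    }
  }
  out
}
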