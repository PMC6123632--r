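## Beta-diversity, PERMANOVA and the cross-method bias comparison harness.
## PERMANOVA is implemented from the distance-partitioning definition
## (Gower-centered squared distances, sequential sums of squares, row-label
## permutation) so that the permutation scheme, p-value convention and
## exhaustive-enumeration variants are fully specified.

#' Jaccard dissimilarity between sites
#'
#' \eqn{d(i,j) = 1 - |A_i \cap A_j| / |A_i \cup A_j|} where \eqn{A_i} is
#' the set of units present at site i. A pair of sites that are both
#' empty gets distance 0 by convention; such pairs are counted in the
#' \code{"empty_pairs"} attribute and logged.
#'
#' @param incidence binary units-by-sites matrix with >= 2 sites.
#' @return symmetric site-by-site matrix with zero diagonal.
#' @export
jaccard_matrix <- function(incidence) {
  validate_incidence(incidence)
  if (ncol(incidence) < 2) mb_stop("need >= 2 sites")
  X <- t(incidence)
  inter <- X %*% t(X)
  sizes <- rowSums(X)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  empty <- un == 0
  d[empty] <- 0
  diag(d) <- 0
  n_empty <- (sum(empty) - sum(diag(empty))) / 2
  if (n_empty > 0)
    mb_log("warn", n_empty, " site pairs are both empty; distance set to 0")
  attr(d, "empty_pairs") <- n_empty
  d
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Sequential (Type-I) sums of squares from the Gower-centered matrix of
#' squared distances, with a pseudo-F per term and p-values from
#' permutation of the site labels. The observed statistic is included in
#' both numerator and denominator of the p-value, so p is never 0.
#' Sequential partitioning means term order changes the attribution of
#' shared variance, as in distance-based redundancy analysis.
#'
#' @param d symmetric distance matrix with site labels (or a \code{dist}).
#' @param covariates data.frame with a \code{site} column matching the
#'   labels of \code{d}.
#' @param terms character vector of covariate columns, fitted in order.
#' @param n_perm number of permutations (>= 1; 999 default).
#' @param seed integer seed.
#' @param permutations optional integer matrix (rows are permutations of
#'   \code{1:n}) replacing random permutations, e.g. for exhaustive
#'   enumeration on small designs.
#' @param strata optional factor (or covariate column name); permutations
#'   are then restricted to within-stratum shuffles.
#' @return a data.frame of class \code{"permanova"} with one row per term
#'   plus Residual and Total: \code{df}, \code{SS}, \code{R2},
#'   \code{pseudo_F}, \code{p}.
#' @export
permanova <- function(d, covariates, terms, n_perm = 999, seed = 1L,
                      permutations = NULL, strata = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) mb_stop("distance matrix must carry site labels")
  idx <- match(labels, covariates$site)
  if (anyNA(idx)) mb_stop("covariates missing sites: ",
                          paste(labels[is.na(idx)], collapse = ", "))
  cov <- covariates[idx, , drop = FALSE]
  for (tm in terms) {
    if (is.null(cov[[tm]])) mb_stop("unknown term: ", tm)
    v <- cov[[tm]]
    if (length(unique(v)) < 2) mb_stop("constant covariate: ", tm)
  }
  if (is.null(permutations) && n_perm < 1) mb_stop("n_perm must be >= 1")
  G <- gower_center(d)
  ss_total <- sum(diag(G))
  # cumulative hat matrices: intercept, then + each term in order
  Xc <- matrix(1, n, 1)
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms) + 1L)
  ranks[1] <- 1L
  for (k in seq_along(terms)) {
    Xc <- cbind(Xc, model.matrix(~ v - 1, data.frame(v = cov[[terms[k]]])))
    hats[[k]] <- hat_matrix(Xc)
    ranks[k + 1] <- qr(Xc)$rank
  }
  df_terms <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) mb_stop("no residual degrees of freedom")
  stat_f <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), 0)
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    (ss / df_terms) / (ss_res / df_res)
  }
  F_obs <- stat_f(G)
  tr_obs <- vapply(hats, function(H) sum(H * G), 0)
  ss_obs <- diff(c(0, tr_obs))
  ss_res <- ss_total - tr_obs[length(tr_obs)]
  if (is.null(permutations)) {
    set.seed(as.integer(seed))
    if (!is.null(strata)) {
      if (is.character(strata) && length(strata) == 1) strata <- cov[[strata]]
      groups <- split(seq_len(n), strata)
      permutations <- t(vapply(seq_len(n_perm), function(i) {
        p <- integer(n)
        for (g in groups) p[g] <- g[sample.int(length(g))]
        p
      }, integer(n)))
    } else {
      permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                               integer(n)))
    }
  }
  exceed <- numeric(length(terms))
  for (r in seq_len(nrow(permutations))) {
    p <- permutations[r, ]
    Fp <- stat_f(G[p, p, drop = FALSE])
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + nrow(permutations))
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(ss_obs, ss_res, ss_total),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    pseudo_F = c(F_obs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- nrow(permutations)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("permanova", "data.frame")
  out
}

gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "n_perm")))
  df <- as.data.frame(x)
  df$SS <- round(df$SS, 4)
  df$R2 <- round(df$R2, 4)
  df$pseudo_F <- round(df$pseudo_F, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-method richness and community-structure comparison
#'
#' Builds the per-method, per-site (and per-phylum, when unit phylum
#' labels are available) richness table; tests every pairwise method
#' contrast by site-stratified permutation (independent per-site swaps of
#' the two method labels, i.e. sign flips of the per-site richness
#' difference), Holm-corrected across contrasts; and, when covariates are
#' supplied, computes the Jaccard matrix and PERMANOVA per method.
#'
#' @param unitsets named list of \code{\link{unit_set}}s over identical
#'   site sets (names default to each set's method tag).
#' @param covariates optional covariate data.frame for the PERMANOVA leg.
#' @param terms covariate columns for PERMANOVA (default
#'   \code{c("depth", "mean_grain_size")}).
#' @param n_perm permutations for both test legs.
#' @param seed integer seed.
#' @param alpha significance level applied to Holm-adjusted p-values for
#'   the \code{flag} column.
#' @return a list of class \code{"method_comparison"}: \code{richness}
#'   (long data.frame method/phylum/site/richness), \code{contrasts}
#'   (method_a, method_b, phylum stratum, mean richness difference
#'   \code{delta}, \code{p}, \code{p_holm}, \code{flag}), \code{jaccard},
#'   \code{permanova}.
#' @export
compare_methods <- function(unitsets, covariates = NULL,
                            terms = c("depth", "mean_grain_size"),
                            n_perm = 999, seed = 1L, alpha = 0.05) {
  if (length(unitsets) < 2) mb_stop("need >= 2 unit sets")
  if (is.null(names(unitsets)) || any(!nzchar(names(unitsets))))
    names(unitsets) <- vapply(unitsets, `[[`, "", "method")
  sitesets <- lapply(unitsets, function(u) colnames(u$site_counts))
  sites <- sitesets[[1]]
  if (!all(vapply(sitesets, function(s) identical(sort(s), sort(sites)),
                  TRUE)))
    mb_stop("unit sets cover different site sets")
  sites <- sort(sites)
  methods <- names(unitsets)

  phyla <- sort(unique(unlist(lapply(unitsets, function(u)
    if (is.null(u$phylum)) character() else unname(u$phylum)))))
  phyla <- phyla[!is.na(phyla)]
  strata <- c("all", phyla)

  rich_of <- function(u, stratum) {
    keep <- if (stratum == "all") rep(TRUE, length(u$units))
      else if (is.null(u$phylum)) rep(FALSE, length(u$units))
      else (!is.na(u$phylum) & u$phylum == stratum)
    m <- u$site_counts[keep, sites, drop = FALSE]
    colSums(m >= 1)
  }
  richness <- do.call(rbind, lapply(methods, function(me)
    do.call(rbind, lapply(strata, function(st)
      data.frame(method = me, phylum = st, site = sites,
                 richness = as.integer(rich_of(unitsets[[me]], st)),
                 stringsAsFactors = FALSE)))))
  rownames(richness) <- NULL

  set.seed(as.integer(seed))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  rows <- list()
  for (st in strata) {
    for (pr in pairs) {
      ra <- richness$richness[richness$method == pr[1] &
                                richness$phylum == st]
      rb <- richness$richness[richness$method == pr[2] &
                                richness$phylum == st]
      dd <- ra - rb
      obs <- mean(dd)
      if (all(dd == 0)) {
        p <- 1
      } else {
        flips <- matrix(sample(c(-1, 1), n_perm * length(dd),
                               replace = TRUE), n_perm)
        null <- as.vector(flips %*% dd) / length(dd)
        p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phylum = st, method_a = pr[1], method_b = pr[2],
        delta = obs, p = p, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  contrasts$p_holm <- p.adjust(contrasts$p, method = "holm")
  contrasts$flag <- contrasts$p_holm < alpha
  rownames(contrasts) <- NULL

  jac <- lapply(unitsets, function(u) jaccard_matrix(as_incidence(u)))
  perm <- NULL
  if (!is.null(covariates)) {
    perm <- lapply(jac, function(J)
      permanova(J, covariates, terms, n_perm = n_perm, seed = seed))
  }
  structure(list(richness = richness, contrasts = contrasts,
                 jaccard = jac, permanova = perm,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Cross-method comparison of",
      length(unique(x$richness$method)), "unit sets\n")
  tot <- x$richness[x$richness$phylum == "all", ]
  tt <- tapply(tot$richness, tot$method, sum)
  cat("  summed per-site richness by method:\n")
  for (nm in names(tt)) cat(sprintf("    %-14s %d\n", nm, tt[[nm]]))
  sig <- x$contrasts[x$contrasts$flag, , drop = FALSE]
  cat(sprintf("  %d of %d contrasts significant after Holm correction\n",
              nrow(sig), nrow(x$contrasts)))
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Write a method-comparison report to a directory
#'
#' Emits \code{report.tsv} (contrast table), \code{report.json}
#' (richness, contrasts and PERMANOVA tables) and one
#' \code{jaccard_<method>.tsv} per method.
#'
#' @param x a \code{method_comparison}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_comparison <- function(x, dir) {
  stopifnot(inherits(x, "method_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$contrasts, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(x$jaccard)) {
    J <- x$jaccard[[nm]]
    write.table(data.frame(site = rownames(J), J, check.names = FALSE),
                file.path(dir, paste0("jaccard_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  payload <- list(richness = x$richness, contrasts = x$contrasts,
                  permanova = lapply(x$permanova, as.data.frame),
                  n_perm = x$n_perm, seed = x$seed)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
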