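## GMYC single-threshold species delimitation.
##
## On an ultrametric gene tree, branching events older than a threshold age
## T reflect speciation (Yule pure-birth over the species lineages,
## intensity lambda * n_species(t)) while events younger than T reflect
## within-species coalescence (intensity lambda_c * k(k-1)/2 per cluster of
## k lineages). The two processes are superimposed: between consecutive
## node ages the total branching intensity is
##   b(t) = lambda * A(t) + lambda_c * B(t),
## with A(t) the number of species lineages (the crossing-lineage count
## above T, constant at the entity count below it) and B(t) the summed
## per-cluster coalescent weight. The log-likelihood over the n-2 observed
## waiting times (the root is the starting condition, not an event) is
##   sum_i log b(t_i) - int b(t) dt,
## maximised numerically over (lambda, lambda_c) at every candidate
## threshold. The superposition form is used rather than separate per-class
## waiting-time products because the latter degenerates: a cluster's root
## event has forward intensity zero in its own class, and crediting events
## with class-specific backward intensities lets a single whole-tree
## coalescent absorb arbitrary deep structure.
##
## The null model is the single Yule-type branching process over the whole
## tree, which is exactly the mixed model at the youngest candidate
## threshold (no coalescent events, B identically 0), so the null is
## nested and logL_mixed >= logL_null holds by construction. The LR is
## referred to a chi-square with 2 df.

## closed-form profile logL for a pure exponential-waiting process with
## per-interval weights w, interval lengths len, events ending the first
## m intervals
profile_loglik <- function(w, len, m) {
  if (m == 0L) return(0)
  W <- sum(w * len)
  m * log(m / W) + sum(log(w[seq_len(m)])) - m
}

## numerically maximised superposition log-likelihood; A, B and len cover
## all intervals, events end intervals 1..(nint-1)
superposition_loglik <- function(A, B, len, mY, mC) {
  nint <- length(len)
  evA <- A[seq_len(nint - 1L)]
  evB <- B[seq_len(nint - 1L)]
  intA <- sum(A * len)
  intB <- sum(B * len)
  if (intB <= 0 || mC == 0L)  # no coalescent component: closed-form Yule
    return(list(logL = profile_loglik(A, len, nint - 1L),
                lambda = (nint - 1L) / intA, lambda_c = 0))
  negll <- function(par) {
    la <- exp(par[1]); lc <- exp(par[2])
    r <- la * evA + lc * evB
    -(sum(log(r)) - la * intA - lc * intB)
  }
  starts <- list(c(log(max(mY, 0.5) / intA), log(max(mC, 0.5) / intB)),
                 c(log((nint - 1L) / intA), log((nint - 1L) / intB)),
                 c(log((nint - 1L) / intA), log(1e-8 / intB)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, negll, method = "Nelder-Mead",
                               control = list(maxit = 5000,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  list(logL = -best$value, lambda = exp(best$par[1]),
       lambda_c = exp(best$par[2]))
}

#' GMYC single-threshold species delimitation
#'
#' Fits the mixed Yule-coalescent model at every candidate threshold (the
#' midpoints between consecutive distinct node ages, down to a threshold
#' younger than all internal nodes) and returns the maximum-likelihood fit
#' together with a likelihood-ratio test against the
#' single-branching-process null. Entities are the subtrees whose stem
#' crosses the fitted threshold, including singletons.
#'
#' @param tree an ultrametric \code{phylo} with >= 3 tips and strictly
#'   positive internal branch lengths.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @param seed seed for the documented tie-breaking jitter: exactly equal
#'   internal node ages are perturbed by uniform offsets smaller than
#'   1e-9 of the tree height before candidate thresholds are formed.
#' @return an object of class \code{"gmyc"}: list with \code{threshold}
#'   (age, tree-time units), \code{n_entities}, \code{entities} (list of
#'   tip-label sets), \code{clusters} (entities with >= 2 tips),
#'   \code{logL_mixed}, \code{logL_null}, \code{LR}, \code{p_value},
#'   \code{lambda} and \code{lambda_c} (rate estimates at the optimum),
#'   and \code{profile} (a data.frame over all candidate thresholds).
#' @examples
#' tr <- simulate_yule_tree(5, 1, seed = 2)
#' tr <- graft_coalescent_tips(tr, 4, 0.01 * attr(tr, "height"), seed = 2)
#' fit <- gmyc_single_threshold(tr)
#' fit$n_entities
#' @export
gmyc_single_threshold <- function(tree, tol = 1e-6, seed = 1L) {
  tree <- annotate_ultrametric(tree, tol)
  if (!attr(tree, "ultrametric"))
    mb_stop("tree is not ultrametric (tip-depth spread ",
            format(attr(tree, "tip_depth_spread")), ")")
  ntip <- ape::Ntip(tree)
  if (ntip < 3) mb_stop("GMYC needs >= 3 tips")
  height <- attr(tree, "height")
  depths <- ape::node.depth.edgelength(tree)
  age <- height - depths
  age[seq_len(ntip)] <- 0
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ages_int <- age[internal]
  if (any(duplicated(ages_int))) {
    set.seed(as.integer(seed))
    dup <- duplicated(ages_int)
    ages_int[dup] <- ages_int[dup] +
      runif(sum(dup), 0, 1e-9 * max(height, 1))
    age[internal] <- ages_int
  }
  if (min(ages_int) <= 0)
    mb_stop("internal branch lengths must be strictly positive")

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # postorder accumulation of descendant tips / descendant-internal nodes
  po <- ape::reorder.phylo(tree, "postorder")$edge
  tipsets <- vector("list", ntip + tree$Nnode)
  intsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  for (nd in internal) intsets[[nd]] <- nd
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
    if (ch > ntip) intsets[[p]] <- c(intsets[[p]], intsets[[ch]])
  }

  ord <- order(ages_int, decreasing = TRUE)
  a <- ages_int[ord]                       # a[1] = root age
  rank_of <- integer(ntip + tree$Nnode)    # node id -> age rank
  rank_of[internal[ord]] <- seq_along(a)
  n_nodes <- length(a)                     # = ntip - 1
  len <- c(a[-n_nodes] - a[-1], a[n_nodes])  # interval i = (a[i+1], a[i])

  cluster_roots <- function(T) {
    # nodes/tips whose stem crosses T: parent strictly older than T
    pa <- parent[internal]
    pa_age <- ifelse(pa == 0L, Inf, age[pmax(pa, 1L)])
    roots <- internal[age[internal] <= T & pa_age > T]
    singles <- seq_len(ntip)[age[parent[seq_len(ntip)]] > T]
    list(roots = roots, singles = singles)
  }

  prof <- data.frame(j = seq_len(n_nodes), threshold = NA_real_,
                     n_entities = NA_integer_, logL = NA_real_,
                     lambda = NA_real_, lambda_c = NA_real_)
  ent_cache <- vector("list", n_nodes)
  for (j in seq_len(n_nodes)) {
    T <- if (j < n_nodes) (a[j] + a[j + 1]) / 2 else a[j] / 2
    cr <- cluster_roots(T)
    n_ent <- length(cr$roots) + length(cr$singles)
    # A: crossing-lineage count above T (rank + 1), entity count below
    A <- pmin(seq_len(n_nodes) + 1L, n_ent)
    # B: per-interval summed coalescent weight, built incrementally:
    # when a cluster's k-th lineage appears at event rank r, B gains
    # choose(k+1,2) - choose(k,2) = k from interval r onwards
    B <- numeric(n_nodes)
    for (r in cr$roots) {
      ranks <- sort(rank_of[intsets[[r]]])    # cluster events, deep first
      k <- seq_along(ranks)                   # lineages after each event
      for (ii in seq_along(ranks)) B[ranks[ii]:n_nodes] <-
        B[ranks[ii]:n_nodes] + k[ii]
    }
    mY <- j - 1L
    mC <- n_nodes - j
    fit <- superposition_loglik(A, B, len, mY, mC)
    prof$threshold[j] <- T
    prof$n_entities[j] <- n_ent
    prof$logL[j] <- fit$logL
    prof$lambda[j] <- fit$lambda
    prof$lambda_c[j] <- fit$lambda_c
    ent_cache[[j]] <- cr
  }
  logL_null <- prof$logL[n_nodes]          # all-Yule threshold == null model
  jstar <- which.max(prof$logL)
  cr <- ent_cache[[jstar]]
  ents <- c(lapply(cr$roots, function(r) tree$tip.label[tipsets[[r]]]),
            lapply(cr$singles, function(i) tree$tip.label[i]))
  ents <- ents[order(vapply(ents, `[[`, "", 1))]
  LR <- max(0, 2 * (prof$logL[jstar] - logL_null))
  structure(list(
    threshold = prof$threshold[jstar],
    n_entities = prof$n_entities[jstar],
    entities = ents,
    clusters = ents[vapply(ents, length, 1L) >= 2],
    logL_mixed = prof$logL[jstar],
    logL_null = logL_null,
    LR = LR,
    p_value = pchisq(LR, df = 2, lower.tail = FALSE),
    lambda = prof$lambda[jstar],
    lambda_c = prof$lambda_c[jstar],
    profile = prof,
    tree = tree), class = "gmyc")
}

#' @export
print.gmyc <- function(x, ...) {
  cat("GMYC single-threshold species delimitation\n")
  cat(sprintf("  tips: %d   entities: %d (clusters: %d, singletons: %d)\n",
              ape::Ntip(x$tree), x$n_entities, length(x$clusters),
              x$n_entities - length(x$clusters)))
  cat(sprintf("  threshold age: %.6g\n", x$threshold))
  cat(sprintf("  logL mixed: %.4f   logL null: %.4f\n",
              x$logL_mixed, x$logL_null))
  cat(sprintf("  LR = %.4f, df = 2, p = %.4g\n", x$LR, x$p_value))
  invisible(x)
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  cat("  branching rates: lambda =", format(object$lambda, digits = 4),
      " lambda_c =", format(object$lambda_c, digits = 4), "\n")
  sizes <- vapply(object$entities, length, 1L)
  cat("  entity sizes:", paste(sort(sizes, decreasing = TRUE),
                               collapse = " "), "\n")
  invisible(object)
}

#' @export
logLik.gmyc <- function(object, ...) {
  structure(object$logL_mixed, df = 3, class = "logLik")
}

#' @export
coef.gmyc <- function(object, ...) {
  c(threshold = object$threshold, lambda = object$lambda,
    lambda_c = object$lambda_c)
}

#' @export
plot.gmyc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$profile$threshold, x$profile$logL, type = "b", pch = 16,
       xlab = "threshold age", ylab = "log-likelihood",
       main = "GMYC threshold profile", ...)
  graphics::abline(v = x$threshold, col = 2, lty = 2)
  ape::plot.phylo(x$tree, cex = 0.6,
                  main = sprintf("%d entities", x$n_entities))
  invisible(x)
}
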