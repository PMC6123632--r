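## Shared fixtures and independent oracles. Oracles recompute quantities
## from first principles (set algebra, path enumeration, exhaustive
## permutation) so they stay independent of the implementation paths they
## check.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

## a 100-mer and a copy with substitutions at the given 1-based positions
mutate_at <- function(seq, pos, to = "T") {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- if (s[p] == to) "G" else to
  paste(s, collapse = "")
}

base_100mer <- function() strrep("ACGTACGTAC", 10)

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## brute-force incidence statistics straight from the definitions
brute_incidence_stats <- function(mat) {
  per_unit_sites <- apply(mat, 1, function(r) sum(r == 1))
  list(S_obs = sum(per_unit_sites >= 1),
       Q1 = sum(per_unit_sites == 1),
       Q2 = sum(per_unit_sites == 2),
       m = ncol(mat))
}

brute_chao2 <- function(mat) {
  st <- brute_incidence_stats(mat)
  corr <- if (st$Q2 > 0) st$Q1^2 / (2 * st$Q2) else st$Q1 * (st$Q1 - 1) / 2
  st$S_obs + (st$m - 1) / st$m * corr
}

brute_jack1 <- function(mat) {
  st <- brute_incidence_stats(mat)
  st$S_obs + st$Q1 * (st$m - 1) / st$m
}

## naive patristic distance by path enumeration up to the root
brute_patristic <- function(tree, t1, t2) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v
    while (parent[v] != 0L) { v <- parent[v]; p <- c(p, v) }
    p
  }
  i <- match(t1, tree$tip.label); j <- match(t2, tree$tip.label)
  pi_ <- path_to_root(i); pj <- path_to_root(j)
  mrca <- intersect(pi_, pj)[1]
  sum(elen[pi_[seq_len(match(mrca, pi_) - 1)]]) +
    sum(elen[pj[seq_len(match(mrca, pj) - 1)]])
}

brute_pd <- function(tree, tips) {
  if (length(tips) == 1) return(0)
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- lapply(match(tips, tree$tip.label), function(v) {
    p <- v
    while (parent[v] != 0L) { v <- parent[v]; p <- c(p, v) }
    p
  })
  mrca <- Reduce(intersect, paths)[1]
  used <- unique(unlist(lapply(paths, function(p)
    p[seq_len(match(mrca, p) - 1)])))
  sum(elen[used])
}

brute_mpd <- function(tree, tips) {
  prs <- utils::combn(tips, 2)
  mean(vapply(seq_len(ncol(prs)), function(k)
    brute_patristic(tree, prs[1, k], prs[2, k]), 0))
}

brute_mntd <- function(tree, tips) {
  mean(vapply(tips, function(a)
    min(vapply(setdiff(tips, a), function(b)
      brute_patristic(tree, a, b), 0)), 0))
}

## jaccard from explicit set algebra
brute_jaccard <- function(mat) {
  sites <- colnames(mat)
  d <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    A <- rownames(mat)[mat[, i] == 1]
    B <- rownames(mat)[mat[, j] == 1]
    u <- union(A, B)
    d[i, j] <- if (!length(u)) 0 else 1 - length(intersect(A, B)) / length(u)
  }
  d
}

## all binary matrices with u units and s sites, as a list
enumerate_incidence <- function(u, s) {
  n <- u * s
  lapply(0:(2^n - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    matrix(bits, u, s, dimnames = list(paste0("u", seq_len(u)),
                                       paste0("s", seq_len(s))))
  })
}

## independent GMYC log-likelihood at threshold T: interval walk with
## direct lineage classification, then its own 2-parameter maximization
brute_gmyc_logL <- function(tree, T) {
  ntip <- ape::Ntip(tree)
  dep <- ape::node.depth.edgelength(tree)
  age <- max(dep[seq_len(ntip)]) - dep
  age[seq_len(ntip)] <- 0
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  cl_of <- sapply(seq_len(ntip + tree$Nnode), function(v) {
    cur <- v; best <- 0L
    while (cur != 0L) {
      if (cur > ntip && age[cur] <= T) best <- cur
      cur <- parent[cur]
    }
    best
  })
  n_ent <- length(unique(cl_of[cl_of > 0])) + sum(cl_of[seq_len(ntip)] == 0)
  bounds <- c(sort(age[nodes], decreasing = TRUE), 0)
  nint <- length(bounds) - 1
  A <- numeric(nint); B <- numeric(nint); len <- numeric(nint)
  for (i in seq_len(nint)) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    len[i] <- bounds[i] - bounds[i + 1]
    cross <- which(age < mid & c(-Inf, age)[parent + 1] > mid)
    if (mid > T) { A[i] <- length(cross); B[i] <- 0 }
    else {
      cl <- cl_of[cross]; cl <- cl[cl > 0]; cl <- cl[age[cl] > mid]
      kk <- as.integer(table(cl))
      A[i] <- n_ent
      B[i] <- if (length(kk)) sum(kk * (kk - 1) / 2) else 0
    }
  }
  evA <- A[seq_len(nint - 1)]; evB <- B[seq_len(nint - 1)]
  intA <- sum(A * len); intB <- sum(B * len)
  if (intB <= 0) {
    m <- nint - 1
    return(m * log(m / intA) + sum(log(evA)) - m)
  }
  negll <- function(par) {
    la <- exp(par[1]); lc <- exp(par[2])
    -(sum(log(la * evA + lc * evB)) - la * intA - lc * intB)
  }
  best <- Inf
  for (s in list(c(log(1 / intA), log(1 / intB)), c(0, 0),
                 c(log((nint - 1) / intA), log((nint - 1) / intB)))) {
    o <- try(stats::optim(s, negll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12)),
             silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best) best <- o$value
  }
  -best
}

## random hit table for classifier property tests
random_hits <- function(n, seed) {
  set.seed(seed)
  phyla <- c("Annelida", "Nematoda")
  fams <- c("F1", "F2")
  sps <- c("S1", "S2", "S3")
  hit_table(rep("q", n),
            paste(sample(phyla, n, TRUE), sample(fams, n, TRUE),
                  sample(sps, n, TRUE), sep = ";"),
            round(runif(n, 85, 100), 1),
            sample(c(100, 125, 150, 400), n, TRUE))
}

## the frozen bias-emulation survey configuration (documented in the
## methods vignette): 28 species over 7 phyla, 12 sites, occupancy 0.5,
## mean depth 6, error rate 0.002, detection 0.95 with the metabarcoding
## deficit for Gastrotricha
biased_metacommunity <- function(seed, gastrotricha_detection = 0.3) {
  det <- detection_model(0.95, read_depth_mean = 6, error_rate = 0.002)
  det$prob["Gastrotricha", "metabarcoding"] <- gastrotricha_detection
  simulate_metacommunity(n_species = 28, within_species_n = 1,
                         n_sites = 12, occupancy_prob = 0.5,
                         theta_frac = 0.01, detection = det, seed = seed)
}

## first-principles one-term PERMANOVA pseudo-F (Gower centering written
## out directly), independent of the package implementation
brute_permanova_F <- function(d, x) {
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  X <- cbind(1, x)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_model <- sum(H * G)
  ss_res <- sum(diag(G)) - ss_model
  (ss_model / 1) / (ss_res / (n - 2))
}
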