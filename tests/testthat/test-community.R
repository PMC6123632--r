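test_that("jaccard distances match hand counts and conventions", {
  m <- matrix(0L, 4, 3, dimnames = list(letters[1:4], c("s1", "s2", "s3")))
  m[c("a", "b", "c"), "s1"] <- 1L
  m[c("b", "c", "d"), "s2"] <- 1L
  J <- jaccard_matrix(m)
  expect_equal(J["s1", "s2"], 0.5)        # 1 - 2/4
  expect_equal(J["s1", "s1"], 0)
  expect_equal(J["s1", "s3"], 1)          # s3 empty vs non-empty: disjoint
  expect_equal(J["s3", "s3"], 0)
  expect_true(isSymmetric(unname(J)))

  ident <- matrix(1L, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_equal(max(jaccard_matrix(ident)), 0)
})

test_that("jaccard equals the set-algebra oracle on all small matrices", {
  for (mat in enumerate_incidence(4, 3)) {
    expect_equal(suppressMessages(jaccard_matrix(mat)),
                 brute_jaccard(mat), ignore_attr = TRUE)
  }
})

test_that("jaccard obeys the triangle inequality on random matrices", {
  set.seed(3)
  for (rep in 1:20) {
    m <- matrix(rbinom(40, 1, 0.5), 8, 5,
                dimnames = list(paste0("u", 1:8), paste0("s", 1:5)))
    J <- suppressMessages(jaccard_matrix(m))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(J[i, j], J[i, k] + J[k, j] + 1e-12)
  }
})

null_jaccard <- function(seed, n_sites = 8, n_units = 15) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_units * n_sites, 1, 0.4), n_units, n_sites,
                dimnames = list(paste0("u", seq_len(n_units)),
                                sprintf("site%02d", seq_len(n_sites))))
    if (all(colSums(m) > 0)) return(jaccard_matrix(m))
  }
}

test_that("permanova agrees with vegan::adonis2 on F, R2 and exact p", {
  skip_if_not_installed("vegan")
  J <- null_jaccard(9)
  cov <- simulate_covariates(8, seed = 2)
  # identical permutations handed to both implementations: p matches exactly
  set.seed(33)
  perms <- t(replicate(99, sample.int(8)))
  mine <- permanova(J, cov, c("depth", "mean_grain_size"),
                    permutations = perms)
  ad <- vegan::adonis2(stats::as.dist(J) ~ depth + mean_grain_size,
                       data = cov, permutations = perms, by = "terms")
  expect_equal(mine$pseudo_F[1:2], ad$F[1:2])
  expect_equal(mine$R2[1:3], ad$R2[1:3])
  expect_equal(mine$p[1:2], ad$`Pr(>F)`[1:2])
  expect_equal(sum(mine$R2[1:3]), 1)
})

test_that("4-site toy p equals full enumeration of all 24 permutations", {
  J <- null_jaccard(4, n_sites = 4, n_units = 10)
  cov <- data.frame(site = rownames(J), depth = c(0.2, 1.4, 6.1, 9.5))
  all_perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  all_perms <- all_perms[apply(all_perms, 1, function(r)
    length(unique(r)) == 4), ]
  fit <- permanova(J, cov, "depth", permutations = all_perms)
  # exhaustive oracle: first-principles F for every permutation
  F_all <- apply(all_perms, 1, function(ord)
    brute_permanova_F(J[ord, ord], cov$depth))
  F_obs <- brute_permanova_F(J, cov$depth)
  expect_equal(fit$pseudo_F[1], F_obs)
  expect_equal(fit$p[1], (1 + sum(F_all >= F_obs - 1e-12)) / (1 + 24))
})

test_that("permanova validates inputs and is deterministic", {
  J <- null_jaccard(5)
  cov <- simulate_covariates(8, seed = 2)
  cov$flat <- 1
  expect_error(permanova(J, cov, "flat"), "constant covariate: flat")
  expect_error(permanova(J, cov, "nope"), "unknown term")
  a <- permanova(J, cov, "depth", n_perm = 99, seed = 4)
  b <- permanova(J, cov, "depth", n_perm = 99, seed = 4)
  expect_identical(a, b)
})

test_that("permanova p is invariant to site relabeling", {
  J <- null_jaccard(6)
  cov <- simulate_covariates(8, seed = 7)
  fit1 <- permanova(J, cov, "depth", n_perm = 199, seed = 11)
  # relabel sites consistently in distances and covariates
  relab <- setNames(sprintf("st%02d", 8:1), rownames(J))
  J2 <- J
  rownames(J2) <- colnames(J2) <- relab[rownames(J)]
  cov2 <- cov
  cov2$site <- relab[cov$site]
  fit2 <- permanova(J2, cov2, "depth", n_perm = 199, seed = 11)
  expect_equal(fit1$pseudo_F, fit2$pseudo_F)
  expect_equal(fit1$p, fit2$p)
})

two_method_fixture <- function(seed = 1) {
  set.seed(seed)
  sites <- sprintf("site%02d", 1:6)
  mk <- function(tag, n, ph) {
    counts <- matrix(rbinom(n * 6, 2, 0.5), n, 6,
                     dimnames = list(paste0(tag, seq_len(n)), sites))
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    unit_set("sv", setNames(as.list(rownames(counts)), rownames(counts)),
             counts,
             phylum = setNames(rep_len(ph, nrow(counts)),
                               rownames(counts)))
  }
  list(a = mk("a", 12, c("Annelida", "Nematoda")),
       b = mk("b", 12, c("Annelida", "Nematoda")))
}

test_that("identical unit sets give zero contrasts with p 1", {
  fx <- two_method_fixture()
  cmp <- compare_methods(list(m1 = fx$a, m2 = fx$a), n_perm = 99, seed = 1)
  expect_true(all(cmp$contrasts$delta == 0))
  expect_true(all(cmp$contrasts$p == 1))
  expect_false(any(cmp$contrasts$flag))
})

test_that("swapping method labels negates contrasts exactly", {
  fx <- two_method_fixture(3)
  c1 <- compare_methods(list(x = fx$a, y = fx$b), n_perm = 199, seed = 5)
  c2 <- compare_methods(list(x = fx$b, y = fx$a), n_perm = 199, seed = 5)
  expect_equal(c1$contrasts$delta, -c2$contrasts$delta)
})

test_that("compare_methods validates site sets and emits reports", {
  fx <- two_method_fixture(4)
  bad <- fx$b
  colnames(bad$site_counts)[1] <- "elsewhere"
  expect_error(compare_methods(list(a = fx$a, b = bad)), "different site")

  cov <- simulate_covariates(6, seed = 9)
  cmp <- compare_methods(list(m1 = fx$a, m2 = fx$b), covariates = cov,
                         terms = "depth", n_perm = 99, seed = 2)
  expect_s3_class(cmp$permanova$m1, "permanova")
  expect_named(cmp$jaccard, c("m1", "m2"))
  d <- withr::local_tempdir()
  write_comparison(cmp, d)
  expect_true(file.exists(file.path(d, "report.tsv")))
  expect_true(file.exists(file.path(d, "report.json")))
  expect_true(file.exists(file.path(d, "jaccard_m1.tsv")))
  back <- read.delim(file.path(d, "report.tsv"))
  expect_equal(nrow(back), nrow(cmp$contrasts))
})
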