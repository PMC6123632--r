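test_that("Yule simulator produces ultrametric trees of the right shape", {
  t1 <- simulate_yule_tree(1, 1, seed = 1)
  expect_equal(ape::Ntip(t1), 1)
  expect_equal(attr(t1, "height"), 0)

  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(attr(t2, "ultrametric"))

  t10 <- simulate_yule_tree(10, 2, seed = 5)
  expect_equal(ape::Ntip(t10), 10)
  expect_equal(t10$Nnode, 9)  # internal nodes = n - 1
  expect_true(attr(t10, "ultrametric"))

  expect_error(simulate_yule_tree(5, birth_rate = 0), "birth_rate")
  # bit-reproducible
  expect_identical(ape::write.tree(simulate_yule_tree(8, 1, seed = 9)),
                   ape::write.tree(simulate_yule_tree(8, 1, seed = 9)))
})

test_that("mean Yule root height matches the analytic expectation", {
  lambda <- 1
  hts <- vapply(1:500, function(s)
    attr(simulate_yule_tree(10, lambda, seed = s), "height"), 0)
  expected <- sum(1 / (lambda * (2:10)))
  expect_lt(abs(mean(hts) - expected) / expected, 0.1)
})

test_that("coalescent grafting keeps ultrametricity and separation", {
  st <- simulate_yule_tree(6, 1, seed = 3)

  g1 <- graft_coalescent_tips(st, 1, 0.01, seed = 1)
  expect_equal(ape::Ntip(g1), 6)
  expect_equal(sort(g1$tip.label), sort(paste0(st$tip.label, "_tip1")))

  g <- graft_coalescent_tips(st, 4, 0.01 * attr(st, "height"), seed = 2)
  expect_equal(ape::Ntip(g), 24)
  expect_true(attr(g, "ultrametric"))

  # all within-species MRCAs younger than all species-tree nodes
  dep_s <- ape::node.depth.edgelength(st)
  sp_node_ages <- max(dep_s[1:6]) - dep_s[-(1:6)]
  for (sp in st$tip.label) {
    tips <- grep(paste0("^", sp, "_tip"), g$tip.label, value = TRUE)
    mrca <- ape::getMRCA(g, tips)
    mrca_age <- attr(g, "height") - ape::node.depth.edgelength(g)[mrca]
    term_len <- st$edge.length[match(match(sp, st$tip.label), st$edge[, 2])]
    expect_lt(mrca_age, term_len)
  }

  expect_error(
    graft_coalescent_tips(st, 8, 100 * attr(st, "height"), seed = 1,
                          max_retries = 3),
    "retries")
})

test_that("sequence evolution follows the Jukes-Cantor expectation", {
  tr <- read_newick("(A:0.5,B:0.5);")
  rg <- list(region_spec("R", 200, 0, "ACGTACGT", "TTGGCCAA"))
  s <- evolve_sequences(tr, rg, seed = 1)
  expect_identical(s$seq[1], s$seq[2])  # rate 0: identical tips
  expect_true(startsWith(s$seq[1], "ACGTACGT"))
  expect_true(endsWith(s$seq[1], revcomp("TTGGCCAA")))

  # two tips at patristic distance 1, rate 0.3: expected per-site identity
  r <- 0.3; d <- 1
  p_match <- 1 / 4 + 3 / 4 * exp(-4 * r * d / 3)
  rg2 <- list(region_spec("R", 200, r, "ACGTACGT", "TTGGCCAA"))
  obs <- vapply(1:200, function(s) {
    sq <- evolve_sequences(tr, rg2, seed = s)
    a <- strsplit(substr(sq$seq[1], 9, 208), "")[[1]]
    b <- strsplit(substr(sq$seq[2], 9, 208), "")[[1]]
    mean(a == b)
  }, 0)
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_match), 3 * se)

  # primers identical across tips even at high rate
  expect_true(all(startsWith(
    evolve_sequences(simulate_yule_tree(5, 1, 2), rg2, seed = 3)$seq,
    "ACGTACGT")))
})

test_that("survey with perfect detection reproduces the true incidence", {
  mc <- simulate_metacommunity(
    n_species = 8, within_species_n = 2, n_sites = 5,
    detection = detection_model(1, read_depth_mean = 3, error_rate = 0),
    seed = 4)
  sv <- mc$survey
  for (me in c("specimen", "metabarcoding")) {
    rr <- sv$reads[sv$reads$method == me, ]
    obs <- table(factor(rr$species, rownames(sv$incidence_true)),
                 factor(rr$site, colnames(sv$incidence_true)))
    expect_equal(unname((obs > 0) * 1L), unname(sv$incidence_true))
  }
  # error-free reads are copies of a tip amplicon of their species
  i <- 25
  sp <- sv$reads$species[i]
  expect_true(sv$reads$seq[i] %in%
                mc$sequences$seq[mc$sequences$species == sp])
})

test_that("zeroed detection silences a phylum in that method only", {
  det <- detection_model(1, read_depth_mean = 3, error_rate = 0)
  det$prob["Gastrotricha", "metabarcoding"] <- 0
  mc <- simulate_metacommunity(n_species = 14, within_species_n = 1,
                               n_sites = 4, detection = det, seed = 6)
  rr <- mc$survey$reads
  expect_equal(sum(rr$method == "metabarcoding" &
                     rr$phylum == "Gastrotricha"), 0)
  expect_gt(sum(rr$method == "specimen" & rr$phylum == "Gastrotricha"), 0)
})

test_that("synthetic truth round trips through JSON and explains reads", {
  mc <- simulate_metacommunity(n_species = 6, within_species_n = 1,
                               n_sites = 4, seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(mc$survey$truth, f)
  back <- read_truth(f)
  expect_identical(back$incidence_true, mc$survey$incidence_true)
  expect_equal(back$species, mc$survey$truth$species)
  reads <- mc$survey$reads
  expect_identical(unname(unlist(back$read_map[reads$id])), reads$species)
})

test_that("generators are bit-reproducible given config and seed", {
  a <- simulate_metacommunity(n_species = 6, n_sites = 4, seed = 42)
  b <- simulate_metacommunity(n_species = 6, n_sites = 4, seed = 42)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$survey$reads, b$survey$reads)
  expect_identical(a$covariates, b$covariates)
})
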