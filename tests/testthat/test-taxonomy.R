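test_that("hit filtering applies span, window and top-k rules", {
  h <- hit_table(rep("q", 3), c("A;F;S1", "A;F;S2", "A;F;S3"),
                 c(98.0, 97.6, 97.4), c(150, 150, 150))
  expect_equal(filter_hits(h)$pct_identity, c(98.0, 97.6))

  # top hit with span 100 is excluded; the next becomes top
  h2 <- hit_table(rep("q", 2), c("A;F;S1", "A;F;S2"),
                  c(99, 95), c(100, 150))
  expect_equal(filter_hits(h2)$pct_identity, 95)

  # span exactly at the limit fails the strict > rule
  h3 <- hit_table("q", "A;F;S", 99, 120)
  expect_equal(nrow(filter_hits(h3)), 0)

  # six hits within the window: keep the first five
  h6 <- hit_table(rep("q", 6), rep("A;F;S", 6),
                  c(98, 98, 98, 97.9, 97.8, 97.7), rep(150, 6))
  expect_equal(nrow(filter_hits(h6)), 5)

  expect_equal(nrow(filter_hits(h6[0, ])), 0)
})

test_that("consensus taxonomy takes the agreed prefix under the ceiling", {
  mk <- function(lineages, ids) {
    filter_hits(hit_table(rep("q1", length(lineages)), lineages, ids,
                          rep(150, length(lineages))))
  }
  # all five hits agree at species, best > 97
  a <- consensus_taxonomy(mk(rep("Annelida;Nerillidae;Nerilla sp.", 5),
                             c(98.2, 98.1, 98.1, 98.0, 97.9)))
  expect_equal(a$rank, "species")
  expect_equal(a$label, "Nerilla sp.")
  expect_equal(a$basis, "consensus")

  # family ceiling but families disagree: phylum-level assignment
  b <- consensus_taxonomy(mk(c("Annelida;Nerillidae;Nerilla sp.",
                               "Annelida;Saccocirridae;Saccocirrus sp."),
                             c(95.0, 94.8)))
  expect_equal(b$rank, "phylum")
  expect_equal(b$label, "Annelida")

  # best hit below all thresholds: unassigned
  c_ <- consensus_taxonomy(mk("Annelida;Nerillidae;Nerilla sp.", 89.9))
  expect_equal(c_$rank, "unassigned")
  expect_equal(c_$label, "")

  # phylum disagreement: unassigned even though identity is high
  d <- consensus_taxonomy(mk(c("Annelida;F;S", "Nematoda;F;S"),
                             c(98, 97.9)))
  expect_equal(d$rank, "unassigned")

  # species ceiling with agreement only at family
  e <- consensus_taxonomy(mk(c("Annelida;Nerillidae;Nerilla sp.",
                               "Annelida;Nerillidae;Mesonerilla sp."),
                             c(98, 97.8)))
  expect_equal(e$rank, "family")
  expect_equal(e$label, "Nerillidae")
})

test_that("raising rank thresholds never deepens an assignment", {
  rank_depth <- c(unassigned = 0, phylum = 1, family = 2, species = 3)
  for (s in 1:200) {
    h <- filter_hits(random_hits(sample(1:6, 1), seed = s))
    base <- consensus_taxonomy(h, thresholds = c(97, 93, 90))
    up <- consensus_taxonomy(h, thresholds = c(98.5, 95, 92))
    expect_lte(rank_depth[[up$rank]], rank_depth[[base$rank]])
  }
})

test_that("widening the top window never deepens the consensus rank", {
  rank_depth <- c(unassigned = 0, phylum = 1, family = 2, species = 3)
  for (s in 201:400) {
    h <- random_hits(sample(2:6, 1), seed = s)
    narrow <- consensus_taxonomy(filter_hits(h, top_window = 0.5))
    wide <- consensus_taxonomy(filter_hits(h, top_window = 5))
    expect_lte(rank_depth[[wide$rank]], rank_depth[[narrow$rank]])
  }
})

rescue_fixture <- function() {
  # the smallest supported clade around q holds six assigned Annelida tips
  # (the two clades nested below it carry no support of their own)
  tr <- read_newick(
    "(((a:1,(b:0.5,q:0.5):0.5):1,((c:1,d:1):0.5,(e:1,f:1):0.5)0.99:0.5)0.99:1,out:3);")
  asg <- data.frame(
    query = c("a", "b", "c", "d", "e", "f", "q", "out"),
    rank = c(rep("species", 6), "unassigned", "species"),
    label = c(letters[1:6], "", "x"),
    phylum = c(rep("Annelida", 6), NA, "Nematoda"),
    basis = "consensus", stringsAsFactors = FALSE)
  list(tree = tr, asg = asg)
}

test_that("clade rescue assigns the phylum of a supported pure clade", {
  fx <- rescue_fixture()
  out <- clade_rescue(fx$tree, fx$asg, min_clade = 5, support_min = 0.95)
  q <- out[out$query == "q", ]
  expect_equal(q$rank, "phylum")
  expect_equal(q$label, "Annelida")
  expect_equal(q$basis, "clade_rescue")
  # previously assigned rows never change
  expect_identical(out[out$query != "q", ], fx$asg[fx$asg$query != "q", ])
})

test_that("clade rescue fails on small or impure clades, missing support", {
  fx <- rescue_fixture()
  # demand seven other tips: the supported clade only has six
  out <- clade_rescue(fx$tree, fx$asg, min_clade = 7, support_min = 0.95)
  expect_equal(out[out$query == "q", "rank"], "unassigned")

  # drop support below the cutoff everywhere: no supported clade at all
  out2 <- clade_rescue(fx$tree, fx$asg, min_clade = 5, support_min = 0.999)
  expect_equal(out2[out2$query == "q", "rank"], "unassigned")

  # make one clade member a different phylum: purity fails
  asg3 <- fx$asg
  asg3$phylum[asg3$query == "c"] <- "Nematoda"
  out3 <- clade_rescue(fx$tree, asg3, min_clade = 5, support_min = 0.95)
  expect_equal(out3[out3$query == "q", "rank"], "unassigned")

  # an unassigned member inside the clade also blocks rescue
  asg4 <- fx$asg
  asg4$rank[asg4$query == "d"] <- "unassigned"
  asg4$phylum[asg4$query == "d"] <- NA
  out4 <- clade_rescue(fx$tree, asg4, min_clade = 5, support_min = 0.95)
  expect_equal(out4[out4$query == "q", "rank"], "unassigned")

  expect_error(clade_rescue(fx$tree, rbind(fx$asg, data.frame(
    query = "ghost", rank = "unassigned", label = "", phylum = NA,
    basis = "consensus")), 5, 0.95), "absent")
})

test_that("clade rescue is invariant to tip order", {
  fx <- rescue_fixture()
  out1 <- clade_rescue(fx$tree, fx$asg, 5, 0.95)
  rot <- ape::rotate(fx$tree, ape::getMRCA(fx$tree, c("a", "q")))
  rot <- read_newick(ape::write.tree(rot))
  out2 <- clade_rescue(rot, fx$asg, 5, 0.95)
  expect_equal(out1[order(out1$query), ], out2[order(out2$query), ])
})

test_that("naive search returns ranked hits and recovers species", {
  a <- base_100mer()
  refs <- sequence_table(c("ref1", "ref2", "ref3"),
                         c(a, mutate_at(a, 1:10), mutate_at(a, 30:60)),
                         phylum = "Annelida",
                         species = c("S1", "S2", "S3"))
  hits <- naive_search(sequence_table("q", a), refs)
  expect_equal(hits$species[1], "S1")
  expect_equal(hits$pct_identity[1], 100)
  expect_equal(nrow(hits), 3)  # k larger than the reference count

  expect_error(naive_search(sequence_table("q", a), refs[0, ]), "empty")

  # classifier pipeline: error-free queries against a complete reference
  # of three well-separated species recover every species label
  set.seed(52)
  b <- random_seq(150)
  refs2 <- sequence_table(
    c("rA", "rB", "rC"),
    c(b, mutate_at(b, seq(2, 150, 10)), mutate_at(b, seq(5, 150, 10))),
    phylum = "Annelida", species = c("spA", "spB", "spC"))
  queries <- refs2
  queries$id <- paste0("q_", refs2$id)
  asg <- classify_hits(naive_search(queries, refs2, k = 5))
  expect_true(all(asg$rank == "species"))
  expect_equal(asg$label, refs2$species)
})
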