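v9 <- function() default_regions()$V9

test_that("primer pairs are located with exact coordinates", {
  rg <- v9()
  seq1 <- paste0("NNN", rg$fwd_primer, strrep("ACGT", 25),
                 revcomp(rg$rev_primer), "NNN")
  h <- locate_primer_pair(seq1, rg$fwd_primer, rg$rev_primer)
  expect_true(h$found)
  expect_equal(h$strand, "+")
  expect_equal(h$end - h$start, 100)
  expect_equal(h$start, 3 + nchar(rg$fwd_primer))
  expect_equal(substr(seq1, h$start + 1, h$end), strrep("ACGT", 25))
  expect_equal(h$fwd_mismatches + h$rev_mismatches, 0)

  # primer absent: a not-found result, not an error
  miss <- locate_primer_pair(strrep("ACGT", 50), rg$fwd_primer,
                             rg$rev_primer)
  expect_false(miss$found)
})

test_that("minus-strand hits map back to forward coordinates", {
  rg <- v9()
  region <- strrep("ACGT", 25)
  seq1 <- paste0("NNN", rg$fwd_primer, region, revcomp(rg$rev_primer), "NNN")
  h1 <- locate_primer_pair(seq1, rg$fwd_primer, rg$rev_primer)
  h2 <- locate_primer_pair(revcomp(seq1), rg$fwd_primer, rg$rev_primer)
  expect_true(h2$found)
  expect_equal(h2$strand, "-")
  L <- nchar(seq1)
  expect_equal(h2$start, L - h1$end)
  expect_equal(h2$end, L - h1$start)
  expect_equal(revcomp(substr(revcomp(seq1), h2$start + 1, h2$end)), region)
})

test_that("mismatches and IUPAC degeneracies are tolerated up to the cap", {
  fwd <- "ACGTACGTAC"
  rev <- "GGTTGGTTGG"
  region <- strrep("CTGA", 20)
  base <- paste0(fwd, region, revcomp(rev))
  # two substitutions in the forward primer site still match
  mutated <- paste0("ACCTACGTTC", region, revcomp(rev))
  h <- locate_primer_pair(mutated, fwd, rev, max_mismatch = 2)
  expect_true(h$found)
  expect_equal(h$fwd_mismatches, 2)
  h3 <- locate_primer_pair(paste0("AGCTAGGTTC", region, revcomp(rev)),
                           fwd, rev, max_mismatch = 2)
  expect_false(h3$found)  # three mismatches exceed the cap

  # degenerate primer code N matches any base at that position
  hN <- locate_primer_pair(base, "ACGTNCGTAC", rev, max_mismatch = 0)
  expect_true(hN$found)
  expect_equal(hN$fwd_mismatches, 0)
})

test_that("region extraction drops sequences missing a region", {
  rgs <- default_regions()
  mc <- simulate_metacommunity(n_species = 5, within_species_n = 1,
                               n_sites = 3, seed = 8)
  ext <- extract_regions(mc$sequences, rgs)
  expect_equal(nrow(ext$V1V2), nrow(mc$sequences))
  expect_equal(nrow(ext$V9), nrow(mc$sequences))
  expect_true(all(nchar(ext$V9$seq) == rgs$V9$length))

  # break the V9 forward primer in one sequence: omitted from V9 only
  seqs <- mc$sequences
  seqs$seq[2] <- sub(rgs$V9$fwd_primer, strrep("A", 16), seqs$seq[2],
                     fixed = TRUE)
  ext2 <- suppressMessages(extract_regions(seqs, rgs))
  expect_equal(nrow(ext2$V9), nrow(seqs) - 1)
  expect_equal(nrow(ext2$V1V2), nrow(seqs))
})

test_that("re-extraction from a primer-retaining fragment is idempotent", {
  rg <- v9()
  mc <- simulate_metacommunity(n_species = 4, within_species_n = 1,
                               n_sites = 3, seed = 9)
  s <- mc$sequences[1, ]
  h <- locate_primer_pair(s$seq, rg$fwd_primer, rg$rev_primer)
  frag <- substr(s$seq, h$start - nchar(rg$fwd_primer) + 1,
                 h$end + nchar(rg$rev_primer))
  s2 <- s
  s2$seq <- frag
  e1 <- extract_regions(s, list(rg))$V9$seq
  e2 <- extract_regions(s2, list(rg))$V9$seq
  expect_identical(e1, e2)
})

test_that("identity profile means pairwise identities per group", {
  a <- base_100mer()
  tab <- sequence_table(c("x", "y"), c(a, a), phylum = "Annelida")
  prof <- region_identity_profile(list(R = tab))
  expect_equal(prof$mean_identity, 1)

  # scattered disjoint substitutions on a random background give exact
  # pairwise identities 0.9, 0.8, 0.7, which average to 0.8
  set.seed(99)
  s1 <- random_seq(100)
  s2 <- mutate_at(s1, seq(1, 91, 10))
  s3 <- mutate_at(s1, sort(c(seq(3, 93, 10), seq(6, 96, 10))))
  expect_equal(percent_identity(s1, s2), 0.9)
  expect_equal(percent_identity(s1, s3), 0.8)
  expect_equal(percent_identity(s2, s3), 0.7)
  tab3 <- sequence_table(c("s1", "s2", "s3"), c(s1, s2, s3),
                         phylum = "Annelida")
  prof3 <- region_identity_profile(list(R = tab3))
  expect_equal(prof3$mean_identity, 0.8)
  expect_equal(prof3$n, 3)

  # singleton cells report n = 1 with an undefined mean
  lone <- sequence_table("z", a, phylum = "Nematoda")
  prof1 <- region_identity_profile(list(R = lone))
  expect_true(is.na(prof1$mean_identity))

  # profile is invariant to input order
  profr <- region_identity_profile(list(R = tab3[c(3, 1, 2), ]))
  expect_equal(profr$mean_identity, prof3$mean_identity)
})

test_that("faster V9 divergence lowers V9 identity in every phylum", {
  mc <- simulate_metacommunity(n_species = 21, within_species_n = 1,
                               n_sites = 3, seed = 14)
  ext <- extract_regions(mc$sequences, mc$regions)
  prof <- region_identity_profile(ext)
  wide <- reshape(prof[, c("group", "region", "mean_identity")],
                  direction = "wide", idvar = "group", timevar = "region")
  ok <- wide$mean_identity.V9 < wide$mean_identity.V1V2
  expect_true(all(ok))
})
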