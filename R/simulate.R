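## Synthetic-community generator. The generative structure mirrors the
## assumptions behind the survey pipeline: a Yule (pure-birth) species tree
## with Kingman-coalescent within-species tip clusters (the generative
## counterpart of GMYC delimitation), Jukes-Cantor sequence evolution over
## primer-flanked variable regions with unequal rates, and a multi-site
## occupancy survey observed through phylum-by-method detection
## probabilities with read-level substitution errors.

.default_phyla <- c("Annelida", "Gastrotricha", "Mollusca", "Nematoda",
                    "Nemertea", "Platyhelminthes", "Xenacoelomorpha")

fmt_bl <- function(x) sprintf("%.12g", x)

#' Specify a marker variable region
#'
#' @param name region name, e.g. \code{"V1V2"} or \code{"V9"}.
#' @param length region length in bp (fixed across taxa in simulation).
#' @param rate substitution rate per site per unit tree time (primers
#'   themselves are conserved, rate 0).
#' @param fwd_primer,rev_primer primer sequences (IUPAC codes allowed for
#'   matching; simulated primers are literal).
#' @return a list of class \code{"region_spec"}.
#' @export
region_spec <- function(name, length, rate, fwd_primer, rev_primer) {
  stopifnot(nzchar(name), length > 0, rate >= 0,
            nzchar(fwd_primer), nzchar(rev_primer))
  structure(list(name = name, length = as.integer(length), rate = rate,
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer)),
            class = "region_spec")
}

#' Default V1-V2 and V9 region specifications
#'
#' Primer sequences are the published 18S sets: EukF/SR7 for the V1-V2
#' single-specimen amplicon and Illumina_Euk_1391f/EukBr for the V9
#' metabarcoding amplicon. The V9 default rate is three times the V1-V2
#' rate, reproducing the faster divergence of V9 relative to V1-V2.
#'
#' @param rate_v1v2,rate_v9 substitution rates per site per unit tree time.
#' @param len_v1v2,len_v9 region lengths in bp.
#' @return a named list of two \code{region_spec}s.
#' @export
default_regions <- function(rate_v1v2 = 0.1, rate_v9 = 0.3,
                            len_v1v2 = 340, len_v9 = 130) {
  list(
    V1V2 = region_spec("V1V2", len_v1v2, rate_v1v2,
                       fwd_primer = "AACCTGGTTGATCCTGCCAGT",   # EukF
                       rev_primer = "GTTCAACTACGAGCTTTTTAA"),  # SR7
    V9 = region_spec("V9", len_v9, rate_v9,
                     fwd_primer = "GTACACACCGCCCGTC",          # Illumina_Euk_1391f
                     rev_primer = "TGATCCTTCTGCAGGTTCACCTAC")  # EukBr
  )
}

#' Simulate an ultrametric Yule (pure-birth) species tree
#'
#' While k lineages exist the waiting time to the next speciation is
#' exponential with rate \code{birth_rate * k}; the process is observed
#' from the root split (2 lineages) until the interval following the n-th
#' lineage, so the expected root age is \eqn{\sum_{k=2}^{n} 1/(\lambda k)}.
#'
#' @param n_species number of species tips (>= 1).
#' @param birth_rate speciation rate \eqn{\lambda > 0}.
#' @param seed integer seed; the generator is bit-reproducible.
#' @return an ultrametric \code{phylo} with tips \code{sp1..spn}.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (birth_rate <= 0) mb_stop("birth_rate must be > 0")
  if (n_species < 1) mb_stop("n_species must be >= 1")
  set.seed(as.integer(seed))
  if (n_species == 1)
    return(annotate_ultrametric(ape::read.tree(text = "(sp1:0);")))
  iv <- rexp(n_species - 1, rate = birth_rate * (2:n_species))
  height <- sum(iv)
  split_ages <- if (n_species > 2) height - cumsum(iv)[1:(n_species - 2)]
                else numeric(0)
  # node 1 is the root; active lineages are (parent-id) slots awaiting
  # either a further split or tip closure at age 0
  age <- height
  parent <- NA_integer_
  active <- c(1L, 1L)
  for (a in split_ages) {
    i <- sample.int(length(active), 1L)
    p <- active[i]
    age <- c(age, a)
    parent <- c(parent, p)
    nid <- length(age)
    active <- c(active[-i], nid, nid)
  }
  tip_parent <- active
  tip_name <- paste0("sp", seq_along(tip_parent))
  build <- function(nid) {
    kids <- which(parent == nid)
    tips <- which(tip_parent == nid)
    parts <- c(
      vapply(kids, function(k)
        paste0(build(k), ":", fmt_bl(age[nid] - age[k])), ""),
      vapply(tips, function(k)
        paste0(tip_name[k], ":", fmt_bl(age[nid])), "")
    )
    paste0("(", paste(parts, collapse = ","), ")")
  }
  tree <- ape::read.tree(text = paste0(build(1L), ";"))
  annotate_ultrametric(tree)
}

## one Kingman coalescent subtree newick for m tips, returning the string
## and its height; rate while j lineages is choose(j,2)/theta
rcoal_newick <- function(m, theta, tip_names) {
  heights <- rep(0, m)
  subs <- tip_names
  a <- 0
  while (length(subs) > 1L) {
    j <- length(subs)
    a <- a + rexp(1L, rate = j * (j - 1) / 2 / theta)
    pick <- sample.int(j, 2L)
    merged <- paste0("(", subs[pick[1]], ":", fmt_bl(a - heights[pick[1]]),
                     ",", subs[pick[2]], ":", fmt_bl(a - heights[pick[2]]), ")")
    subs <- c(subs[-pick], merged)
    heights <- c(heights[-pick], a)
  }
  list(newick = subs, height = a)
}

#' Graft within-species coalescent tip clusters onto a species tree
#'
#' Each species tip is replaced by a Kingman coalescent subtree of
#' \code{within_species_n} tips whose height is sampled conditional on
#' being shorter than the species' terminal branch (bounded rejection
#' sampling), so the grafted tree stays ultrametric and every
#' within-species MRCA is younger than its species' stem origin.
#'
#' @param species_tree an ultrametric \code{phylo} (tips become species).
#' @param within_species_n tips per species (>= 1). With 1 tip the topology
#'   is unchanged and tips are merely renamed.
#' @param theta coalescent time scale (> 0); the expected subtree height is
#'   \code{2 * theta * (1 - 1/n)}.
#' @param seed integer seed.
#' @param max_retries rejection-sampling bound per species.
#' @return an ultrametric \code{phylo} with tips \code{<species>_tip<j>}.
#' @export
graft_coalescent_tips <- function(species_tree, within_species_n, theta,
                                  seed = 1L, max_retries = 100L) {
  if (theta <= 0) mb_stop("theta must be > 0")
  if (within_species_n < 1) mb_stop("within_species_n must be >= 1")
  set.seed(as.integer(seed))
  labs <- species_tree$tip.label
  if (within_species_n == 1L) {
    out <- species_tree
    out$tip.label <- paste0(labs, "_tip1")
    return(annotate_ultrametric(out))
  }
  text <- ape::write.tree(species_tree)
  term_len <- setNames(
    species_tree$edge.length[match(seq_along(labs), species_tree$edge[, 2])],
    labs)
  for (lab in labs) {
    b <- term_len[[lab]]
    sub <- NULL
    for (try in seq_len(max_retries)) {
      cand <- rcoal_newick(within_species_n, theta,
                           paste0(lab, "_tip", seq_len(within_species_n)))
      if (cand$height < b) { sub <- cand; break }
    }
    if (is.null(sub))
      mb_stop("coalescent height exceeded terminal branch of ", lab,
              " after ", max_retries, " retries; lower theta")
    text <- sub(paste0("([(,])", lab, ":[0-9.eE+-]+"),
                paste0("\\1", sub$newick, ":", fmt_bl(b - sub$height)),
                text)
  }
  annotate_ultrametric(ape::read.tree(text = text))
}

.bases <- c("A", "C", "G", "T")

#' Evolve primer-flanked sequences along a tree under Jukes-Cantor
#'
#' The emitted amplicon for every tip is the concatenation, over regions,
#' of the forward primer, the variable region, and the reverse complement
#' of the reverse primer (the form the region actually takes on the
#' forward strand of an amplicon). Primer positions evolve at rate 0; each
#' variable region evolves at its own rate, so for two tips at patristic
#' distance d the expected per-site identity in a region of rate r is the
#' Jukes-Cantor closed form \eqn{1/4 + (3/4) \exp(-4 r d / 3)}.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param regions list of \code{\link{region_spec}}s (at least one).
#' @param seed integer seed.
#' @return a sequence table (one row per tip, in tip order); tips named
#'   \code{<species>_tip<j>} get their species filled in.
#' @export
evolve_sequences <- function(tree, regions, seed = 1L) {
  if (!length(regions)) mb_stop("at least one region is required")
  if (is.null(tree$edge.length)) mb_stop("tree has no branch lengths")
  set.seed(as.integer(seed))
  segs <- lapply(regions, function(rg) {
    fwd <- strsplit(rg$fwd_primer, "")[[1]]
    rev <- strsplit(revcomp(rg$rev_primer), "")[[1]]
    list(chars = c(fwd, rep(NA, rg$length), rev),
         rates = c(rep(0, length(fwd)), rep(rg$rate, rg$length),
                   rep(0, length(rev))))
  })
  chars <- unlist(lapply(segs, `[[`, "chars"))
  rates <- unlist(lapply(segs, `[[`, "rates"))
  L <- length(chars)
  root_seq <- match(chars, .bases)
  free <- which(is.na(root_seq))
  root_seq[free] <- sample.int(4L, length(free), replace = TRUE)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nrow = nnode, ncol = L)
  root <- ntip + 1L
  seqs[root, ] <- root_seq
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    s <- seqs[par, ]
    p <- 0.75 * (1 - exp(-4 * rates * elens[e] / 3))
    hit <- which(runif(L) < p)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[child, ] <- s
  }
  ids <- tree$tip.label
  species <- ifelse(grepl("_tip[0-9]+$", ids), sub("_tip[0-9]+$", "", ids),
                    NA_character_)
  sequence_table(
    ids,
    vapply(seq_len(ntip), function(i)
      paste(.bases[seqs[i, ]], collapse = ""), ""),
    species = species)
}

#' Reverse-complement a nucleotide string (IUPAC-aware)
#'
#' @param x a single nucleotide string.
#' @return the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Phylum-by-method detection model
#'
#' Detection probability applies per species-by-site occurrence; a detected
#' occurrence yields a zero-truncated Poisson number of reads (so detection
#' probability 1 with error rate 0 reproduces the true incidence exactly),
#' and each read carries i.i.d. substitution errors.
#'
#' @param prob either a single probability or a phyla-by-methods matrix of
#'   detection probabilities in [0, 1] (rownames phyla, colnames methods).
#' @param methods method names, used when \code{prob} is scalar.
#' @param phyla phylum names, used when \code{prob} is scalar.
#' @param read_depth_mean mean reads per detected occurrence (> 0).
#' @param error_rate per-base substitution probability in [0, 0.1].
#' @return a list of class \code{"detection_model"}.
#' @export
detection_model <- function(prob = 0.95,
                            methods = c("specimen", "metabarcoding"),
                            phyla = .default_phyla,
                            read_depth_mean = 20, error_rate = 0.002) {
  if (!is.matrix(prob)) {
    prob <- matrix(prob, nrow = length(phyla), ncol = length(methods),
                   dimnames = list(phyla, methods))
  }
  if (any(prob < 0 | prob > 1)) mb_stop("detection probabilities must be in [0,1]")
  if (read_depth_mean <= 0) mb_stop("read_depth_mean must be > 0")
  if (error_rate < 0 || error_rate > 0.1)
    mb_stop("error_rate must be in [0, 0.1]")
  structure(list(prob = prob, read_depth_mean = read_depth_mean,
                 error_rate = error_rate),
            class = "detection_model")
}

#' Default biased detection model
#'
#' Baseline detection 0.95 everywhere, depressed to 0.3 for Gastrotricha
#' and Nemertea under metabarcoding. These values are illustrative (real
#' per-phylum detection probabilities are unknown); they reproduce the
#' qualitative structure of a metabarcoding deficit for specific phyla.
#'
#' @param baseline detection probability for all other cells.
#' @param deficits named vector of depressed metabarcoding probabilities.
#' @param ... passed to \code{\link{detection_model}}.
#' @return a \code{detection_model}.
#' @export
default_detection <- function(baseline = 0.95,
                              deficits = c(Gastrotricha = 0.3, Nemertea = 0.3),
                              ...) {
  dm <- detection_model(prob = baseline, ...)
  for (ph in intersect(names(deficits), rownames(dm$prob)))
    dm$prob[ph, "metabarcoding"] <- deficits[[ph]]
  dm
}

ztpois <- function(n, lambda) {
  # zero-truncated Poisson by inversion on the conditional CDF
  u <- runif(n)
  qpois(exp(-lambda) + u * (1 - exp(-lambda)), lambda)
}

add_read_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  s <- match(strsplit(seq, "")[[1]], .bases)
  hit <- which(runif(length(s)) < error_rate & !is.na(s))
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
  }
  paste(.bases[s], collapse = "")
}

#' Simulate a multi-site survey observed through method-specific detection
#'
#' True incidence is Bernoulli(\code{occupancy_prob}) per species-by-site,
#' resampled so every species occupies at least one site. For each method,
#' every true occurrence is detected with the (phylum, method) probability;
#' detected occurrences emit a zero-truncated Poisson number of reads,
#' each copied from one of the species' tip sequences with i.i.d.
#' substitution errors.
#'
#' @param truth_tree the generating tree (stored in the truth object).
#' @param sequences sequence table of tip amplicons with \code{species} and
#'   \code{phylum} filled.
#' @param n_sites number of sites (>= 2).
#' @param occupancy_prob per species-by-site occupancy probability.
#' @param detection a \code{\link{detection_model}}.
#' @param seed integer seed.
#' @return a list of class \code{"mb_survey"}: \code{incidence_true}
#'   (species x sites), \code{reads} (a sequence table with a
#'   \code{method} column), and \code{truth} (species/phylum map, the
#'   read-to-species map, parameters and the generating tree as newick).
#' @export
simulate_survey <- function(truth_tree, sequences, n_sites, occupancy_prob,
                            detection, seed = 1L) {
  if (n_sites < 2) mb_stop("n_sites must be >= 2")
  stopifnot(inherits(detection, "detection_model"))
  set.seed(as.integer(seed))
  seqs <- sequences[!is.na(sequences$species), , drop = FALSE]
  species <- unique(seqs$species)
  phylum_of <- vapply(species, function(sp) {
    ph <- unique(seqs$phylum[seqs$species == sp])
    ph <- ph[!is.na(ph)]
    if (length(ph)) ph[[1]] else "Unknown"
  }, "")
  missing_ph <- setdiff(unique(phylum_of), rownames(detection$prob))
  if (length(missing_ph))
    mb_stop("no detection probabilities for phylum: ",
            paste(missing_ph, collapse = ", "))
  sites <- sprintf("site%02d", seq_len(n_sites))
  inc <- matrix(0L, length(species), n_sites,
                dimnames = list(species, sites))
  for (i in seq_along(species)) {
    repeat {
      row <- rbinom(n_sites, 1L, occupancy_prob)
      if (any(row == 1L)) break
    }
    inc[i, ] <- row
  }
  methods <- colnames(detection$prob)
  tip_of <- split(seq_len(nrow(seqs)), seqs$species)
  reads <- vector("list", 0L)
  for (method in methods) {
    for (i in seq_along(species)) {
      sp <- species[i]
      p_det <- detection$prob[phylum_of[[i]], method]
      for (j in which(inc[i, ] == 1L)) {
        if (rbinom(1L, 1L, p_det) == 0L) next
        n_reads <- ztpois(1L, detection$read_depth_mean)
        tpl_rows <- tip_of[[sp]]
        for (k in seq_len(n_reads)) {
          tpl <- seqs$seq[sample(tpl_rows, 1L)]
          reads[[length(reads) + 1L]] <- data.frame(
            id = sprintf("%s_%s_%s_r%d", method, sites[j], sp, k),
            seq = add_read_errors(tpl, detection$error_rate),
            phylum = phylum_of[[i]], species = sp, site = sites[j],
            abundance = 1L, method = method, stringsAsFactors = FALSE)
        }
      }
    }
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    cbind(sequence_table(character(), character()),
          method = character())
  rownames(reads) <- NULL
  truth <- list(
    species = species,
    phylum = as.list(phylum_of),
    incidence_true = inc,
    read_map = setNames(as.list(reads$species), reads$id),
    params = list(n_sites = n_sites, occupancy_prob = occupancy_prob,
                  detection = detection$prob,
                  read_depth_mean = detection$read_depth_mean,
                  error_rate = detection$error_rate, seed = as.integer(seed)),
    tree = ape::write.tree(truth_tree))
  structure(list(incidence_true = inc, reads = reads, truth = truth),
            class = "mb_survey")
}

#' Serialize or restore a synthetic truth object as JSON
#'
#' @param truth the \code{truth} component of an \code{mb_survey}.
#' @param path JSON file path.
#' @return \code{read_truth} returns the truth list with the incidence
#'   matrix restored.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$incidence_true <- list(species = rownames(truth$incidence_true),
                             sites = colnames(truth$incidence_true),
                             cells = unname(as.data.frame(t(truth$incidence_true))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  inc <- t(as.matrix(as.data.frame(raw$incidence_true$cells)))
  dimnames(inc) <- list(raw$incidence_true$species, raw$incidence_true$sites)
  storage.mode(inc) <- "integer"
  rownames(inc) <- raw$incidence_true$species
  raw$incidence_true <- inc
  raw$read_map <- as.list(raw$read_map)
  raw
}

#' Simulate site covariates for a survey
#'
#' Sites fall into three depth habitats (littoral 0-0.5 m, sublittoral
#' 1-4 m, offshore 6-16 m) in roughly the 9:6:4 proportion of the original
#' 19-site design; salinity is 38 for most sites with occasional brackish
#' outliers; grain-size statistics are drawn from ranges typical of
#' heterogeneous sands.
#'
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return a covariate data.frame (see \code{\link{read_covariates}}).
#' @export
simulate_covariates <- function(n_sites, seed = 1L) {
  set.seed(as.integer(seed))
  habitat <- sample(c("littoral", "sublittoral", "offshore"), n_sites,
                    replace = TRUE, prob = c(9, 6, 4) / 19)
  depth <- ifelse(habitat == "littoral", runif(n_sites, 0, 0.5),
                  ifelse(habitat == "sublittoral", runif(n_sites, 1, 4),
                         runif(n_sites, 6, 16)))
  data.frame(
    site = sprintf("site%02d", seq_len(n_sites)),
    depth = round(depth, 2),
    salinity = sample(c(38, 36, 31), n_sites, replace = TRUE,
                      prob = c(16, 2, 1) / 19),
    mean_grain_size = round(exp(rnorm(n_sites, log(250), 0.6)), 1),
    sorting = round(runif(n_sites, 0.5, 2.5), 3),
    skewness = round(rnorm(n_sites, 0, 0.5), 3),
    kurtosis = round(rnorm(n_sites, 1, 0.3), 3),
    stringsAsFactors = FALSE)
}

#' Simulate a full synthetic metacommunity
#'
#' Chains the generators: Yule species tree, coalescent tip clusters,
#' Jukes-Cantor amplicon evolution over the default V1-V2/V9 regions,
#' phylum assignment in contiguous blocks of the tree's tip order, and a
#' multi-site survey observed through a phylum-by-method detection model.
#'
#' @param n_species number of species.
#' @param birth_rate Yule speciation rate.
#' @param within_species_n tips (individuals) sequenced per species.
#' @param theta_frac coalescent scale as a fraction of species-tree height.
#' @param phyla phylum names; species are assigned in contiguous blocks of
#'   the tree's ladderized tip order so phyla are (mostly) clades.
#' @param regions list of \code{region_spec}s.
#' @param n_sites,occupancy_prob survey design.
#' @param detection a \code{detection_model}, or \code{NULL} for
#'   \code{\link{default_detection}}.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return a list of class \code{"mb_metacommunity"} with components
#'   \code{species_tree}, \code{tree}, \code{sequences}, \code{survey},
#'   \code{covariates}, \code{regions}, \code{params}.
#' @export
simulate_metacommunity <- function(n_species = 35, birth_rate = 1,
                                   within_species_n = 3, theta_frac = 0.01,
                                   phyla = .default_phyla,
                                   regions = default_regions(),
                                   n_sites = 19, occupancy_prob = 0.35,
                                   detection = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  species_tree <- simulate_yule_tree(n_species, birth_rate, stage_seeds[1])
  theta <- theta_frac * attr(species_tree, "height")
  tree <- graft_coalescent_tips(species_tree, within_species_n, theta,
                                stage_seeds[2])
  seqs <- evolve_sequences(tree, regions, stage_seeds[3])
  # contiguous blocks of the cladewise tip order approximate phylum clades
  sp_order <- unique(sub("_tip[0-9]+$", "", tree$tip.label))
  block <- ceiling(seq_along(sp_order) / (length(sp_order) / length(phyla)))
  block <- pmin(block, length(phyla))
  phylum_of <- setNames(phyla[block], sp_order)
  seqs$phylum <- unname(phylum_of[seqs$species])
  if (is.null(detection)) detection <- default_detection(phyla = phyla)
  survey <- simulate_survey(tree, seqs, n_sites, occupancy_prob, detection,
                            stage_seeds[4])
  covariates <- simulate_covariates(n_sites, stage_seeds[4])
  structure(list(species_tree = species_tree, tree = tree, sequences = seqs,
                 survey = survey, covariates = covariates, regions = regions,
                 params = list(n_species = n_species, birth_rate = birth_rate,
                               within_species_n = within_species_n,
                               theta_frac = theta_frac, n_sites = n_sites,
                               occupancy_prob = occupancy_prob,
                               seed = as.integer(seed))),
            class = "mb_metacommunity")
}
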