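#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults are the values used throughout the meiofauna survey workflow:
#' 99\% identity for greedy OTU clustering, rank ceilings of >97/>93/>90\%
#' identity for species/family/phylum assignment, a 0.5-point top-hit window
#' over at most five hits with alignment span >120 bp, clade rescue requiring
#' at least five other same-phylum tips in a supported clade, and 999
#' permutations for randomization tests.
#'
#' @param cluster_identity greedy-clustering identity threshold, in (0.5, 1].
#' @param rank_thresholds named numeric, percent-identity ceilings (strict
#'   \code{>}) for ranks \code{species}, \code{family}, \code{phylum}.
#' @param top_window width (percent identity points) of the window below the
#'   top hit within which hits are retained.
#' @param min_span minimum alignment span in bp (strict \code{>}).
#' @param top_k maximum number of hits considered per query.
#' @param min_clade minimum number of \emph{other} assigned tips required in
#'   a supported clade for phylum rescue.
#' @param support_min minimum node support for a clade to count as supported.
#' @param min_abundance denoising: unique sequences below this abundance are
#'   merged into an error parent or dropped.
#' @param max_err_links denoising: maximum substitution distance to an error
#'   parent.
#' @param n_perm number of permutations for randomization tests.
#' @param ultrametric_tol relative tip-depth tolerance (fraction of tree
#'   height) when flagging trees as non-ultrametric.
#' @param seed integer random seed; always explicit.
#' @return a validated list of class \code{"mb_config"}.
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' cfg$cluster_identity
#' @export
pipeline_config <- function(cluster_identity = 0.99,
                            rank_thresholds = c(species = 97, family = 93,
                                                phylum = 90),
                            top_window = 0.5,
                            min_span = 120,
                            top_k = 5,
                            min_clade = 5,
                            support_min = 0.95,
                            min_abundance = 2,
                            max_err_links = 1,
                            n_perm = 999,
                            ultrametric_tol = 1e-6,
                            seed = 1L) {
  cfg <- list(cluster_identity = cluster_identity,
              rank_thresholds = rank_thresholds,
              top_window = top_window, min_span = min_span, top_k = top_k,
              min_clade = min_clade, support_min = support_min,
              min_abundance = min_abundance, max_err_links = max_err_links,
              n_perm = n_perm, ultrametric_tol = ultrametric_tol,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "mb_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!isTRUE(ok)) mb_stop("invalid config: ", what)
  chk(cfg$cluster_identity > 0.5 && cfg$cluster_identity <= 1,
      "cluster_identity must be in (0.5, 1]")
  chk(all(c("species", "family", "phylum") %in% names(cfg$rank_thresholds)),
      "rank_thresholds needs species, family, phylum")
  rt <- cfg$rank_thresholds
  chk(all(rt >= 0 & rt <= 100) && rt["species"] >= rt["family"] &&
        rt["family"] >= rt["phylum"],
      "rank_thresholds must be in [0,100] and ordered species >= family >= phylum")
  chk(cfg$top_window >= 0, "top_window must be >= 0")
  chk(cfg$min_span >= 0, "min_span must be >= 0")
  chk(cfg$top_k >= 1, "top_k must be >= 1")
  chk(cfg$min_clade >= 1, "min_clade must be >= 1")
  chk(cfg$support_min >= 0 && cfg$support_min <= 1,
      "support_min must be in [0,1]")
  chk(cfg$min_abundance >= 1, "min_abundance must be >= 1")
  chk(cfg$max_err_links >= 0, "max_err_links must be >= 0")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$ultrametric_tol > 0, "ultrametric_tol must be > 0")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected so typos do not silently fall back
#' to defaults. Missing keys take their defaults from
#' \code{\link{pipeline_config}}.
#'
#' @param path file path.
#' @param cfg an \code{mb_config} list (for writing).
#' @return \code{read_config} returns an \code{mb_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) mb_stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- formals(pipeline_config)
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    mb_stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$rank_thresholds))
    raw$rank_thresholds <- unlist(raw$rank_thresholds)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mb_config"))
  out <- unclass(cfg)
  out$rank_thresholds <- as.list(out$rank_thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mb_config <- function(x, ...) {
  cat("metabias pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                paste(if (!is.null(names(v)) && any(nzchar(names(v))))
                        paste0(names(v), "=", v) else v, collapse = " ")))
  }
  invisible(x)
}
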