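# Seeded generator of cluster-structured, mosaic synthetic phage genomes
# with an embedded marker gene and a truth table.

#' Configuration for the synthetic phage panel generator
#'
#' The generator emulates a labelled phage collection: each cluster has an
#' independent random ancestor (real clusters share little nucleotide
#' similarity; set `shared_root = TRUE` for a connected phylogeny), each
#' subcluster is a copy of its cluster ancestor diverged at
#' `within_cluster_divergence`, and each member a copy of its subcluster
#' ancestor diverged at `within_subcluster_divergence`. A marker gene of
#' `tmp_length` bases is embedded at a fixed locus and reported in the truth
#' table. Substitutions are uniform across the three alternative bases
#' (Jukes-Cantor-like); this is adequate for identity-level behaviour but is
#' not a biological sequence model.
#'
#' @param n_clusters,subclusters_per_cluster,members_per_subcluster panel
#'   shape (defaults 5 x 2 x 2).
#' @param genome_length,tmp_length sequence lengths in bp (defaults 20000 and
#'   3000, the typical size of a tape measure protein gene).
#' @param tmp_start fixed 1-based start of the embedded marker gene.
#' @param within_subcluster_divergence per-member substitution rate from the
#'   subcluster ancestor (default 0.05, i.e. members within a subcluster end
#'   up at roughly 90% pairwise identity).
#' @param within_cluster_divergence per-subcluster substitution rate from the
#'   cluster ancestor (default 0.20).
#' @param shared_root logical; derive cluster ancestors from one root.
#' @param shared_root_divergence substitution rate root -> cluster ancestor
#'   when `shared_root = TRUE`.
#' @param indel_rate per-site indel event rate (default 0; substitution-only
#'   panels keep the marker trivially alignable).
#' @param mosaic_swap_rate probability per genome of one horizontal-exchange
#'   segment swap (default 0; see [mosaic_swap()]).
#' @param seed integer RNG seed; the whole panel is reproducible from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_clusters = 5, subclusters_per_cluster = 2,
                         members_per_subcluster = 2,
                         genome_length = 20000, tmp_length = 3000,
                         tmp_start = 2001,
                         within_subcluster_divergence = 0.05,
                         within_cluster_divergence = 0.20,
                         shared_root = FALSE, shared_root_divergence = 0.40,
                         indel_rate = 0, mosaic_swap_rate = 0, seed = 1) {
  if (within_subcluster_divergence > within_cluster_divergence)
    stop("within_subcluster_divergence must be <= within_cluster_divergence")
  rates <- c(within_subcluster_divergence, within_cluster_divergence,
             shared_root_divergence, indel_rate, mosaic_swap_rate)
  if (any(rates < 0) || any(rates[1:4] >= 1))
    stop("divergence/indel rates must lie in [0, 1)")
  if (genome_length <= 0 || tmp_length <= 0 || tmp_length >= genome_length)
    stop("need 0 < tmp_length < genome_length")
  if (tmp_start < 1 || tmp_start + tmp_length - 1 > genome_length)
    stop("marker gene interval outside genome bounds")
  structure(as.list(environment()), class = "synth_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run expr under a locally seeded RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mutate a sequence by substitutions and indels
#'
#' Each site is substituted to a uniformly chosen different base with
#' probability `sub_rate`; indel events occur at per-site rate `indel_rate`
#' with geometric lengths (mean 3) and equal insertion/deletion odds.
#'
#' @param s nucleotide [seq_record] or string.
#' @param sub_rate,indel_rate rates in `[0, 1)`.
#' @param seed optional integer; when given, the result is a deterministic
#'   function of `(s, rates, seed)` and the caller's RNG stream is untouched.
#' @return [seq_record] (same id) or string, matching the input type.
#' @export
diverge <- function(s, sub_rate, indel_rate = 0, seed = NULL) {
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)")
  str <- .as_residues(s)
  out <- .with_seed(seed, {
    ch <- strsplit(str, "")[[1]]
    n <- length(ch)
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3)
      col <- match(ch[hit], c("A", "C", "G", "T"))
      pick <- alt[cbind(sample.int(3, length(hit), replace = TRUE), col)]
      ch[hit] <- pick
    }
    if (indel_rate > 0) {
      k <- rbinom(1, n, indel_rate)
      if (k > 0) {
        pos <- sort(sample.int(n, k), decreasing = TRUE)
        lens <- rgeom(k, 1 / 3) + 1
        ins <- runif(k) < 0.5
        for (e in seq_len(k)) {
          if (ins[e]) {
            ch <- append(ch, sample(c("A","C","G","T"), lens[e],
                                    replace = TRUE), after = pos[e])
          } else {
            drop <- pos[e]:min(pos[e] + lens[e] - 1, length(ch))
            ch <- ch[-drop]
          }
        }
      }
    }
    paste(ch, collapse = "")
  })
  if (inherits(s, "seq_record")) seq_record(s$id, out, s$alphabet) else out
}

#' Generate a labelled synthetic phage panel
#'
#' @param config [synth_config()].
#' @return List with `genomes` (list of [seq_record]), `tmp_genes` (the
#'   embedded marker genes, same ids), and `truth` (`data.frame`: `id`,
#'   `cluster`, `subcluster`, `tmp_start`, `tmp_end`; mosaic donor segments,
#'   if any, in `attr(truth, "donors")`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    cl_names <- LETTERS[seq_len(config$n_clusters)]
    root <- if (config$shared_root) .random_dna(config$genome_length) else NULL
    genomes <- list()
    truth <- list()
    for (ci in seq_along(cl_names)) {
      anc <- if (is.null(root)) .random_dna(config$genome_length)
             else diverge(root, config$shared_root_divergence)
      for (si in seq_len(config$subclusters_per_cluster)) {
        subanc <- diverge(anc, config$within_cluster_divergence,
                          config$indel_rate)
        sub_name <- paste0(cl_names[ci], si)
        for (mi in seq_len(config$members_per_subcluster)) {
          id <- sprintf("phage_%s_%d", sub_name, mi)
          g <- diverge(subanc, config$within_subcluster_divergence,
                       config$indel_rate)
          genomes[[id]] <- seq_record(id, g)
          truth[[id]] <- data.frame(
            id = id, cluster = cl_names[ci], subcluster = sub_name,
            tmp_start = config$tmp_start,
            tmp_end = config$tmp_start + config$tmp_length - 1,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    attr(truth, "donors") <- data.frame(
      id = character(0), donor_id = character(0), start = integer(0),
      end = integer(0), stringsAsFactors = FALSE)
    if (config$mosaic_swap_rate > 0) {
      sw <- mosaic_swap(genomes, truth, config$mosaic_swap_rate)
      genomes <- sw$genomes
      truth <- sw$truth
    }
    tmp_genes <- lapply(genomes, function(g)
      seq_record(g$id, substr(g$residues, config$tmp_start,
                              config$tmp_start + config$tmp_length - 1)))
    list(genomes = genomes, tmp_genes = tmp_genes, truth = truth)
  })
}

#' Horizontal-exchange segment swaps between clusters
#'
#' With probability `rate` per genome, a random segment (5-15% of genome
#' length by default) is replaced by the segment at the same coordinates in
#' a random genome from a different cluster, emulating the genetic mosaicism
#' of phage genomes. The embedded marker gene interval is protected from
#' swaps by default, mirroring its hypothesised evolutionary stability.
#' Donor segments are recorded in `attr(truth, "donors")`.
#'
#' @param genomes named list of [seq_record].
#' @param truth truth table with `tmp_start`/`tmp_end` columns.
#' @param rate per-genome swap probability.
#' @param seed optional local RNG seed.
#' @param protect_tmp logical; keep swaps out of the marker interval.
#' @param segment_frac numeric `(min, max)` segment size as genome fraction.
#' @return List `genomes`, `truth` (truth gains donor records).
#' @export
mosaic_swap <- function(genomes, truth, rate, seed = NULL, protect_tmp = TRUE,
                        segment_frac = c(0.05, 0.15)) {
  if (length(unique(truth$cluster)) < 2) stop("need >= 2 clusters")
  .with_seed(seed, {
    src <- genomes # swaps are simultaneous: donors are the input sequences
    donors <- attr(truth, "donors")
    if (is.null(donors))
      donors <- data.frame(id = character(0), donor_id = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
    for (id in names(genomes)) {
      if (runif(1) >= rate) next
      me <- truth[truth$id == id, ]
      others <- truth$id[truth$cluster != me$cluster]
      donor_id <- if (length(others) == 1) others else sample(others, 1)
      glen <- nchar(genomes[[id]]$residues)
      dlen <- nchar(src[[donor_id]]$residues)
      seg <- round(glen * runif(1, segment_frac[1], segment_frac[2]))
      # candidate start positions keeping the segment inside both genomes
      # and, when protected, outside the marker interval
      max_start <- min(glen, dlen) - seg + 1
      if (max_start < 1) next
      cand <- seq_len(max_start)
      if (protect_tmp) {
        bad <- cand <= me$tmp_end & (cand + seg - 1) >= me$tmp_start
        cand <- cand[!bad]
      }
      if (!length(cand)) next
      start <- if (length(cand) == 1) cand else sample(cand, 1)
      end <- start + seg - 1
      s <- genomes[[id]]$residues
      substr(s, start, end) <- substr(src[[donor_id]]$residues, start, end)
      genomes[[id]] <- seq_record(id, s)
      donors <- rbind(donors, data.frame(
        id = id, donor_id = donor_id, start = start, end = end,
        stringsAsFactors = FALSE))
    }
    attr(truth, "donors") <- donors
    list(genomes = genomes, truth = truth)
  })
}
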