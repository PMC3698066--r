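# Word-match dotplots, global affine-gap alignment, progressive MSA and
# alignment identity statistics.

#' Alignment scoring parameters
#'
#' Defaults follow the marker-gene alignment protocol this package targets:
#' free end gaps, a 65% similarity cost matrix (match 5.0 / mismatch -4.0),
#' gap open penalty 12 and gap extension penalty 3. A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param match,mismatch residue pair scores (match > 0 > mismatch).
#' @param gap_open,gap_extend affine gap penalties (`gap_open >= gap_extend
#'   >= 0`), entered as positive costs.
#' @param free_end_gaps logical; leading/trailing gaps are free.
#' @return List of class `scoring_params`.
#' @export
scoring_params <- function(match = 5, mismatch = -4, gap_open = 12,
                           gap_extend = 3, free_end_gaps = TRUE) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, free_end_gaps = free_end_gaps),
            class = "scoring_params")
}

#' Dotplot parameters
#'
#' @param word_length exact-match word length; when `NULL` it is resolved per
#'   alphabet at comparison time (10 for nucleotide, 3 for amino acid).
#' @param both_strands logical; also match against the reverse complement of
#'   the second sequence (nucleotide only).
#' @return List of class `dotplot_params`.
#' @export
dotplot_params <- function(word_length = NULL, both_strands = FALSE) {
  if (!is.null(word_length) && word_length < 1) stop("word_length must be >= 1")
  structure(list(word_length = word_length, both_strands = both_strands),
            class = "dotplot_params")
}

.resolve_word <- function(params, alphabet) {
  if (!is.null(params$word_length)) return(as.integer(params$word_length))
  if (identical(alphabet, "amino_acid")) 3L else 10L
}

# all overlapping words of length w, 1-based start positions
seq_words <- function(s, w) {
  s <- .as_residues(s)
  n <- nchar(s)
  if (w > n) stop("word length exceeds sequence length")
  substring(s, 1:(n - w + 1), w:n)
}

.longest_run <- function(posA, posB) {
  if (!length(posA)) return(0L)
  d <- posB - posA
  best <- 0L
  for (dd in unique(d)) {
    p <- sort(posA[d == dd])
    runs <- rle(c(TRUE, diff(p) == 1L))
    # consecutive positions on one diagonal
    lens <- runs$lengths[runs$values]
    if (length(p) == 1L) lens <- 1L
    # rle on the diff-based indicator: reconstruct run lengths of consecutive hits
    r <- 1L; mx <- 1L
    if (length(p) > 1L) {
      for (k in 2:length(p)) {
        r <- if (p[k] - p[k - 1L] == 1L) r + 1L else 1L
        if (r > mx) mx <- r
      }
    }
    if (mx > best) best <- mx
  }
  best
}

#' Word-match dotplot between two sequences
#'
#' Every exact word match between the two sequences is reported as a hit at
#' its pair of (1-based) start positions; runs of hits along a diagonal are
#' the dotplot's visual signature of homology. `coverageA` is the fraction of
#' the first sequence's words that occur anywhere in the second sequence and
#' is the similarity measure used by [classify_gene()].
#'
#' @param a,b [seq_record] objects (or plain strings) on the same alphabet.
#' @param params [dotplot_params()].
#' @return Object of class `dotplot_result`: `hits` (data.frame `posA`,
#'   `posB`, `strand`), `coverageA`, `coverageB`, `longest_diagonal_run`,
#'   `word_length` and the two ids/lengths.
#' @export
dotplot <- function(a, b, params = dotplot_params()) {
  alph_a <- if (inherits(a, "seq_record")) a$alphabet else "nucleotide"
  alph_b <- if (inherits(b, "seq_record")) b$alphabet else "nucleotide"
  if (!identical(alph_a, alph_b)) stop("alphabet mismatch between sequences")
  sa <- .as_residues(a); sb <- .as_residues(b)
  w <- .resolve_word(params, alph_a)
  if (w > min(nchar(sa), nchar(sb)))
    stop("word_length (", w, ") exceeds shortest sequence length")
  wa <- seq_words(sa, w)
  wb <- seq_words(sb, w)
  posB_by_word <- split(seq_along(wb), wb)
  idx <- posB_by_word[wa]
  nhit <- lengths(idx)
  hits <- data.frame(
    posA = rep.int(seq_along(wa), nhit),
    posB = unlist(idx, use.names = FALSE),
    strand = rep("+", sum(nhit)),
    stringsAsFactors = FALSE)
  covA_fwd <- mean(nhit > 0L)
  covB_words <- wb %in% wa
  if (params$both_strands && alph_a == "nucleotide") {
    wrc <- seq_words(revcomp(sb), w)
    pos_rc <- split(seq_along(wrc), wrc)
    idx2 <- pos_rc[wa]
    n2 <- lengths(idx2)
    if (sum(n2)) {
      # map positions on the reverse strand back to plus-strand coordinates
      posB_plus <- nchar(sb) - w + 2L - unlist(idx2, use.names = FALSE)
      hits <- rbind(hits, data.frame(
        posA = rep.int(seq_along(wa), n2),
        posB = posB_plus, strand = "-", stringsAsFactors = FALSE))
    }
    covA <- mean(nhit > 0L | n2 > 0L)
    covB_words <- covB_words | wb %in% wrc
  } else {
    covA <- covA_fwd
  }
  fwd <- hits$strand == "+"
  structure(list(
    hits = hits,
    coverageA = covA,
    coverageB = mean(covB_words),
    longest_diagonal_run = .longest_run(hits$posA[fwd], hits$posB[fwd]),
    word_length = w,
    id_a = if (inherits(a, "seq_record")) a$id else "A",
    id_b = if (inherits(b, "seq_record")) b$id else "B",
    len_a = nchar(sa), len_b = nchar(sb)),
    class = "dotplot_result")
}

#' @export
print.dotplot_result <- function(x, ...) {
  cat(sprintf(
    "<dotplot> %s (%d) vs %s (%d), w=%d: %d hits, coverageA=%.3f, longest run=%d\n",
    x$id_a, x$len_a, x$id_b, x$len_b, x$word_length, nrow(x$hits),
    x$coverageA, x$longest_diagonal_run))
  invisible(x)
}

#' @export
plot.dotplot_result <- function(x, ...) {
  plot(NA, xlim = c(1, x$len_a), ylim = c(1, x$len_b),
       xlab = x$id_a, ylab = x$id_b, ...)
  fwd <- x$hits$strand == "+"
  if (any(fwd)) graphics::points(x$hits$posA[fwd], x$hits$posB[fwd],
                                 pch = ".", col = "black")
  if (any(!fwd)) graphics::points(x$hits$posA[!fwd], x$hits$posB[!fwd],
                                  pch = ".", col = "red")
  invisible(x)
}

#' Export dotplot hits as TSV
#'
#' @param x `dotplot_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dotplot_tsv <- function(x, path) {
  write.table(x$hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.degap <- function(s) gsub("-", "", s, fixed = TRUE)

# identity between two gapped rows; denominator = columns where at least one
# row has a residue, optionally excluding terminal overhangs (columns before
# the first / after the last position where both rows have residues)
pairwise_identity <- function(ra, rb, exclude_overhangs = TRUE) {
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  both <- ca != "-" & cb != "-"
  any_res <- ca != "-" | cb != "-"
  keep <- any_res
  if (exclude_overhangs && any(both)) {
    rng <- range(which(both))
    keep <- keep & seq_along(ca) >= rng[1] & seq_along(ca) <= rng[2]
  }
  denom <- sum(keep)
  if (denom == 0) return(0)
  100 * sum(ca == cb & both & keep) / denom
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global alignment under the affine gap model, with end gaps free by
#' default. Percent identity counts identical residue columns over columns
#' where at least one sequence has a residue; under free end gaps the
#' unaligned terminal overhangs are excluded from the denominator (set
#' `exclude_overhangs = FALSE` to keep them).
#'
#' @param a,b [seq_record] or plain strings on one alphabet.
#' @param params [scoring_params()].
#' @param exclude_overhangs logical; defaults to `params$free_end_gaps`.
#' @return Object of class `alignment_result`: `aligned_a`, `aligned_b`,
#'   `score`, `pct_identity`.
#' @export
global_align <- function(a, b, params = scoring_params(),
                         exclude_overhangs = params$free_end_gaps) {
  sa <- .as_residues(a); sb <- .as_residues(b)
  res <- gotoh_align_cpp(sa, sb, params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         params$free_end_gaps)
  pid <- if (nchar(sa) == 0 || nchar(sb) == 0) 0 else
    pairwise_identity(res$aligned_a, res$aligned_b, exclude_overhangs)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, pct_identity = pid),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score=%g, identity=%.2f%%, %d columns\n",
              x$score, x$pct_identity, nchar(x$aligned_a)))
  invisible(x)
}

# column frequency profile of a set of aligned rows over a fixed alphabet;
# gaps are excluded (profile columns hold residue frequencies only)
.profile_freq <- function(rows, letters_) {
  L <- nchar(rows[1])
  mat <- matrix(0, nrow = length(letters_), ncol = L,
                dimnames = list(letters_, NULL))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    ok <- ch %in% letters_
    if (any(ok)) {
      tab <- table(factor(ch[ok], levels = letters_), which(ok))
      mat[, as.integer(colnames(tab))] <-
        mat[, as.integer(colnames(tab))] + unclass(tab)
    }
  }
  # normalise by number of rows so that gap mass simply drops out
  mat / length(rows)
}

.merge_profiles <- function(rows_a, rows_b, params, letters_) {
  fa <- .profile_freq(rows_a, letters_)
  fb <- .profile_freq(rows_b, letters_)
  M <- matrix(params$mismatch, length(letters_), length(letters_))
  diag(M) <- params$match
  S <- t(fa) %*% M %*% fb
  path <- gotoh_profile_cpp(S, params$gap_open, params$gap_extend,
                            params$free_end_gaps)
  ops <- path$ops
  ia <- ops != 2L  # consume a column of A unless it's a left (gap in A) move
  ib <- ops != 1L
  expand <- function(rows, consume) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      out <- rep("-", length(consume))
      out[consume] <- ch
      paste(out, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  out <- c(expand(rows_a, ia), expand(rows_b, ib))
  names(out) <- c(names(rows_a), names(rows_b))
  out
}

#' Progressive multiple sequence alignment
#'
#' Small-scale progressive aligner: pairwise identities from [global_align()]
#' give a distance matrix, a neighbor-joining guide tree orders the merges,
#' and groups are merged by profile-profile affine-gap alignment under the
#' same scoring parameters. This approximates the classic ClustalW procedure
#' rather than cloning it.
#'
#' @param seqs list of [seq_record] (>= 1, one alphabet).
#' @param params [scoring_params()].
#' @return Character vector of equal-length gapped rows, named by record id,
#'   in input order. Every row degaps to its input sequence.
#' @export
msa <- function(seqs, params = scoring_params()) {
  if (length(seqs) == 0) stop("no sequences")
  alph <- unique(vapply(seqs, function(r)
    if (inherits(r, "seq_record")) r$alphabet else "nucleotide", ""))
  if (length(alph) > 1) stop("mixed alphabets in MSA input")
  ids <- vapply(seqs, function(r)
    if (inherits(r, "seq_record")) r$id else NA_character_, "")
  if (anyNA(ids)) ids <- paste0("seq", seq_along(seqs))
  strs <- vapply(seqs, .as_residues, "")
  names(strs) <- ids
  if (length(strs) == 1L) return(strs)
  letters_ <- if (alph == "nucleotide") c("A", "C", "G", "T") else
    setdiff(AA_CHARS, "*")
  if (length(strs) == 2L) {
    al <- global_align(strs[1], strs[2], params)
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- ids
    return(.drop_gap_columns(out))
  }
  n <- length(strs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pid <- global_align(strs[i], strs[j], params)$pct_identity
    D[i, j] <- D[j, i] <- 1 - pid / 100
  }
  guide <- ape::nj(as.dist(D))
  guide <- ape::root(guide, outgroup = guide$tip.label[1], resolve.root = TRUE)
  # postorder merge of aligned groups
  groups <- as.list(ids)
  aligned <- as.list(strs)
  names(aligned) <- ids
  edge <- guide$edge
  ntips <- length(guide$tip.label)
  node_rows <- vector("list", ntips + guide$Nnode)
  for (i in seq_len(ntips)) node_rows[[i]] <- setNames(strs[guide$tip.label[i]],
                                                      guide$tip.label[i])
  ord <- ape::reorder.phylo(guide, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    if (is.null(node_rows[[parent]])) {
      node_rows[[parent]] <- node_rows[[child]]
    } else {
      node_rows[[parent]] <- .merge_profiles(node_rows[[parent]],
                                             node_rows[[child]], params,
                                             letters_)
    }
    node_rows[child] <- list(NULL)
  }
  root <- ntips + 1L
  out <- node_rows[[root]]
  out <- .drop_gap_columns(out)
  out[ids]
}

.drop_gap_columns <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(mat != "-") > 0
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(rows)
  out
}

#' Write an alignment as FASTA
#'
#' @param rows named character vector of equal-length gapped rows.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(rows, path) {
  write_fasta(mapply(function(id, s) list(id = id, residues = s),
                     names(rows), rows, SIMPLIFY = FALSE), path)
}

#' Alignment identity statistics
#'
#' Two summaries of a multiple alignment: the percentage of columns that are
#' gap-free and carry one identical residue in every row (percent identical
#' sites), and the mean over all row pairs of pairwise percent identity
#' (columns where at least one of the pair has a residue; terminal overhangs
#' excluded by default).
#'
#' @param msa_rows character vector of equal-length gapped rows (>= 2).
#' @param exclude_overhangs passed to the pairwise identity rule.
#' @return Named numeric: `pct_identical_sites`, `pct_mean_pairwise_identity`.
#' @export
identity_stats <- function(msa_rows, exclude_overhangs = TRUE) {
  if (length(msa_rows) < 2) stop("need >= 2 rows")
  if (length(unique(nchar(msa_rows))) != 1) stop("ragged MSA rows")
  mat <- do.call(rbind, strsplit(msa_rows, ""))
  ident <- apply(mat, 2, function(col) all(col != "-") &&
                   length(unique(col)) == 1L)
  pct_ident <- 100 * sum(ident) / ncol(mat)
  prs <- combn(length(msa_rows), 2)
  pid <- apply(prs, 2, function(p)
    pairwise_identity(msa_rows[p[1]], msa_rows[p[2]], exclude_overhangs))
  c(pct_identical_sites = pct_ident, pct_mean_pairwise_identity = mean(pid))
}
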