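# Conserved-window scanning on marker-gene alignments, degenerate primer
# pair design, in-silico PCR and cross-reactivity screening.

# per-column summary of an MSA: gap flag, minimal IUPAC consensus code,
# degenerate flag
.msa_columns <- function(msa_rows) {
  if (length(unique(nchar(msa_rows))) != 1) stop("ragged MSA rows")
  mat <- do.call(rbind, strsplit(toupper(msa_rows), ""))
  L <- ncol(mat)
  gap <- logical(L); code <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    if (any(col == "-")) { gap[j] <- TRUE; code[j] <- "-"; next }
    code[j] <- iupac_code(unique(col))
  }
  list(gap = gap, code = code, degenerate = !gap & !code %in% c("A", "C", "G", "T"))
}

#' Scan an alignment for conserved primer-design windows
#'
#' Finds every gap-free alignment window of an allowed length whose
#' column-wise consensus (the smallest IUPAC code covering the bases observed
#' in each column) has at most `max_degenerate` degenerate columns — the
#' regions where a fixed-length degenerate primer can sit. Windows are
#' reported longest-first; overlaps are allowed.
#'
#' @param msa_rows character vector of equal-length gapped rows (>= 2).
#' @param min_len,max_len window length bounds (defaults 16 and 22 bp).
#' @param max_degenerate maximum degenerate columns per window (default 3).
#' @return `data.frame` with columns `msa_column_start`, `length`,
#'   `consensus`, `degenerate_positions`, `gap_free`.
#' @export
find_conserved_windows <- function(msa_rows, min_len = 16, max_len = 22,
                                   max_degenerate = 3) {
  if (length(msa_rows) < 2) stop("need >= 2 rows")
  cols <- .msa_columns(msa_rows)
  L <- length(cols$gap)
  cum_gap <- cumsum(cols$gap)
  cum_deg <- cumsum(cols$degenerate)
  out <- list()
  for (len in seq(min(max_len, L), min_len)) {
    starts <- seq_len(L - len + 1)
    ng <- cum_gap[starts + len - 1] - c(0, cum_gap)[starts]
    nd <- cum_deg[starts + len - 1] - c(0, cum_deg)[starts]
    ok <- ng == 0 & nd <= max_degenerate
    if (any(ok)) {
      st <- starts[ok]
      out[[length(out) + 1]] <- data.frame(
        msa_column_start = st,
        length = len,
        consensus = vapply(st, function(s)
          paste(cols$code[s:(s + len - 1)], collapse = ""), ""),
        degenerate_positions = nd[ok],
        gap_free = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(msa_column_start = integer(0), length = integer(0),
                      consensus = character(0),
                      degenerate_positions = integer(0),
                      gap_free = logical(0)))
  do.call(rbind, out)
}

# map MSA column positions to ungapped residue positions, per row
.residue_pos <- function(row) cumsum(strsplit(row, "")[[1]] != "-")

#' Design degenerate primer pairs from conserved windows
#'
#' Pairs an upstream window (forward primer = its consensus) with a
#' downstream window (reverse primer = reverse complement of its consensus)
#' such that the predicted product length — inclusive of both primer
#' footprints — falls within `product_range` on every row of the alignment.
#' Pairs are ranked by total degenerate positions, then by product length.
#'
#' @param windows output of [find_conserved_windows()].
#' @param msa_rows the alignment the windows came from (named rows).
#' @param product_range numeric `(min, max)` product length (default 150-900).
#' @param degeneracy_cap maximum combined degeneracy of the pair (product of
#'   per-base set sizes over both primers; default 64).
#' @param group label attached to the designed pairs.
#' @param max_pairs stop after this many acceptable pairs (default 100).
#' @return `data.frame` of class `primer_pairs`: `group`, `forward`,
#'   `reverse`, `fwd_msa_start`, `rev_msa_end`, `degenerate_positions`,
#'   `product_length` (per-row median) and a list column `products` of
#'   per-template predicted lengths.
#' @export
design_primer_pairs <- function(windows, msa_rows,
                                product_range = c(150, 900),
                                degeneracy_cap = 64, group = "",
                                max_pairs = 100) {
  empty <- data.frame(group = character(0), forward = character(0),
                      reverse = character(0), fwd_msa_start = integer(0),
                      rev_msa_end = integer(0),
                      degenerate_positions = integer(0),
                      product_length = numeric(0))
  empty$products <- list()
  class(empty) <- c("primer_pairs", class(empty))
  if (nrow(windows) < 2) return(empty)
  if (is.null(names(msa_rows)))
    names(msa_rows) <- paste0("row", seq_along(msa_rows))
  rpos <- lapply(msa_rows, .residue_pos)
  w <- windows[order(windows$degenerate_positions, windows$msa_column_start,
                     -windows$length), , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(w))) {
    if (length(res) >= max_pairs) break
    fs <- w$msa_column_start[i]
    for (j in seq_len(nrow(w))) {
      if (length(res) >= max_pairs) break
      rs <- w$msa_column_start[j]
      re <- rs + w$length[j] - 1
      if (rs < fs + w$length[i]) next  # reverse window must lie downstream
      lens <- vapply(names(msa_rows), function(id)
        rpos[[id]][re] - c(0, rpos[[id]])[fs] , 0)
      if (any(lens < product_range[1]) || any(lens > product_range[2])) next
      fwd <- w$consensus[i]
      rev_ <- revcomp(w$consensus[j])
      if (iupac_degeneracy(fwd) * iupac_degeneracy(rev_) > degeneracy_cap) next
      res[[length(res) + 1]] <- data.frame(
        group = group, forward = fwd, reverse = rev_,
        fwd_msa_start = fs, rev_msa_end = re,
        degenerate_positions = w$degenerate_positions[i] +
          w$degenerate_positions[j],
        product_length = stats::median(lens),
        products = I(list(lens)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$degenerate_positions, out$product_length), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("primer_pairs", class(out))
  out
}

# start positions (1-based) where pattern matches template IUPAC-wise with
# at most max_mismatch mismatching positions
iupac_scan <- function(template, pattern, max_mismatch = 0,
                       match_template_n = FALSE) {
  tn <- nchar(template); pn <- nchar(pattern)
  if (pn > tn) return(integer(0))
  tch <- strsplit(toupper(template), "")[[1]]
  pch <- strsplit(toupper(pattern), "")[[1]]
  npos <- tn - pn + 1
  mism <- integer(npos)
  for (l in seq_len(pn)) {
    ok <- iupac_match(tch[l:(l + npos - 1)], pch[l],
                      match_template_n = match_template_n)
    mism <- mism + !ok
  }
  which(mism <= max_mismatch)
}

#' In-silico PCR
#'
#' Predicts the amplicons a degenerate primer pair would produce from a
#' nucleotide template. The forward primer is matched IUPAC-wise on the plus
#' strand and the reverse primer as its reverse complement downstream; the
#' symmetric orientation (product read off the minus strand) is also
#' searched, so results are strand-symmetric. Coordinates are 1-based
#' inclusive and amplicons include both primer footprints. Degenerate
#' template bases match no primer base unless `match_template_n = TRUE`.
#'
#' @param template nucleotide [seq_record] (or string).
#' @param pair one-row `primer_pairs` entry, or a list/row with `forward` and
#'   `reverse` IUPAC strings.
#' @param max_mismatch non-IUPAC mismatches tolerated per primer (default 0).
#' @param max_product longest product reported (default 5000).
#' @param match_template_n relax the template-N rule.
#' @return `data.frame` with columns `template_id`, `start`, `end`, `length`,
#'   `orientation` (`"+"` when the forward primer sits on the plus strand).
#' @export
insilico_pcr <- function(template, pair, max_mismatch = 0, max_product = 5000,
                         match_template_n = FALSE) {
  s <- .as_residues(template)
  id <- if (inherits(template, "seq_record")) template$id else "template"
  fwd <- toupper(pair$forward); rev_ <- toupper(pair$reverse)
  one_orientation <- function(p5, p3, orient) {
    # p5 binds plus strand as given; p3 binds as revcomp downstream
    f_starts <- iupac_scan(s, p5, max_mismatch, match_template_n)
    r_starts <- iupac_scan(s, revcomp(p3), max_mismatch, match_template_n)
    if (!length(f_starts) || !length(r_starts)) return(NULL)
    res <- list()
    for (fs in f_starts) {
      ends <- r_starts + nchar(p3) - 1
      ok <- ends - fs + 1 >= nchar(p5) + nchar(p3) &
        ends - fs + 1 <= max_product
      for (e in ends[ok]) {
        res[[length(res) + 1]] <- data.frame(
          template_id = id, start = fs, end = e, length = e - fs + 1,
          orientation = orient, stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  out <- rbind(one_orientation(fwd, rev_, "+"),
               one_orientation(rev_, fwd, "-"))
  if (is.null(out))
    out <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  # the two orientations describe the same duplex; drop duplicated intervals
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reactivity screen of primer pairs against a panel
#'
#' Runs [insilico_pcr()] for every (pair, template) combination. A pair is
#' subcluster-specific when it amplifies only the templates of its own group
#' (a diagonal-only matrix when rows are grouped).
#'
#' @param panel [reference_panel()] of nucleotide templates.
#' @param pairs `primer_pairs` data.frame (one row per pair; `group` labels
#'   the intended target).
#' @param ... passed to [insilico_pcr()].
#' @return Integer matrix, rows = primer pairs (named by group), columns =
#'   template ids, entries = amplicon counts.
#' @export
cross_reactivity <- function(panel, pairs, ...) {
  ids <- names(panel$records)
  m <- matrix(0L, nrow = nrow(pairs), ncol = length(ids),
              dimnames = list(pairs$group, ids))
  if (nrow(pairs) == 0 || length(ids) == 0) return(m)
  for (i in seq_len(nrow(pairs))) {
    for (id in ids) {
      m[i, id] <- nrow(insilico_pcr(panel$records[[id]], pairs[i, ], ...))
    }
  }
  m
}

#' Write primer pairs as TSV
#'
#' Columns mirror a bench-ready primer table: group, forward, reverse,
#' product length.
#'
#' @param pairs `primer_pairs` data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_primer_tsv <- function(pairs, path) {
  df <- pairs[, c("group", "forward", "reverse", "product_length")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
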