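# Sequence records, alphabets, IUPAC degeneracy, FASTA and label-table I/O.

# IUPAC degenerate nucleotide codes -> the set of concrete bases each covers
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

NUC_CHARS <- names(IUPAC_SETS)
AA_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

# minimal IUPAC code covering a set of concrete bases (keyed by sorted set)
.iupac_lookup <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases character vector of concrete bases (subset of A, C, G, T).
#' @return Single IUPAC letter whose degeneracy set is exactly the input set.
#' @examples
#' iupac_code(c("C", "T")) # "Y"
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- .iupac_lookup[key]
  if (is.na(code)) stop("not a set of concrete nucleotides: ",
                        paste(bases, collapse = ","))
  unname(code)
}

#' Degeneracy of an IUPAC string
#'
#' Product of per-position set sizes (a primer with one Y and one R has
#' degeneracy 4).
#'
#' @param s IUPAC nucleotide string.
#' @return Integer degeneracy.
#' @export
iupac_degeneracy <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(ch, NUC_CHARS)
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ","))
  prod(vapply(IUPAC_SETS[ch], length, 0L))
}

# template char x pattern char match table; template must be concrete ACGT
.iupac_match_table <- local({
  tm <- matrix(FALSE, nrow = length(NUC_CHARS), ncol = length(NUC_CHARS),
               dimnames = list(NUC_CHARS, NUC_CHARS))
  for (p in NUC_CHARS) tm[IUPAC_SETS[[p]], p] <- TRUE
  tm[setdiff(NUC_CHARS, c("A", "C", "G", "T")), ] <- FALSE
  tm
})

#' IUPAC-aware base matching
#'
#' Tests whether a concrete template base is covered by a (possibly
#' degenerate) pattern base, as a primer would anneal. A degenerate template
#' base (including N) matches nothing by default, which is the conservative
#' convention for in-silico PCR; set `match_template_n = TRUE` to let a
#' template N match any pattern base.
#'
#' @param template_base character vector of template bases.
#' @param pattern_base character vector of pattern (primer) bases, recycled.
#' @param match_template_n logical; relax the template-N rule.
#' @return Logical vector.
#' @examples
#' iupac_match("C", "Y") # TRUE
#' iupac_match("A", "Y") # FALSE
#' @export
iupac_match <- function(template_base, pattern_base, match_template_n = FALSE) {
  tb <- toupper(template_base)
  pb <- toupper(pattern_base)
  bad <- setdiff(c(tb, pb), NUC_CHARS)
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ","))
  out <- .iupac_match_table[cbind(tb, pb)]
  if (match_template_n) out <- out | tb == "N"
  out
}

#' Construct a sequence record
#'
#' A `seq_record` is a named sequence with a declared alphabet. Nucleotide
#' residues are restricted to A/C/G/T unless `degenerate = TRUE`, which
#' additionally admits the IUPAC ambiguity codes; amino-acid residues are the
#' 20 standard letters plus X and `*`. Lowercase input is uppercased and U is
#' normalised to T.
#'
#' @param id non-empty record identifier.
#' @param residues sequence string.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param degenerate logical; permit IUPAC ambiguity codes (nucleotide only).
#' @return Object of class `seq_record` with fields `id`, `alphabet`,
#'   `residues`, `degenerate`.
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "amino_acid"),
                       degenerate = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  residues <- toupper(residues)
  if (alphabet == "nucleotide") {
    residues <- gsub("U", "T", residues, fixed = TRUE)
    allowed <- if (degenerate) NUC_CHARS else c("A", "C", "G", "T")
  } else {
    allowed <- AA_CHARS
  }
  ch <- unique(strsplit(residues, "")[[1]])
  bad <- setdiff(ch, allowed)
  if (length(bad))
    stop("invalid ", alphabet, " character(s) in '", id, "': ",
         paste(bad, collapse = ","))
  structure(list(id = id, alphabet = alphabet, residues = residues,
                 degenerate = degenerate),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head_ <- substr(x$residues, 1, 60)
  cat(sprintf("<seq_record> %s [%s, %d %s]\n  %s%s\n", x$id, x$alphabet, n,
              if (x$alphabet == "nucleotide") "nt" else "aa",
              head_, if (n > 60) "..." else ""))
  invisible(x)
}

.as_residues <- function(x) {
  if (inherits(x, "seq_record")) x$residues else as.character(x)
}

#' Read a FASTA file
#'
#' Residues are uppercased, line wraps and blank lines removed, record order
#' preserved. Malformed input (sequence data before the first header, an
#' empty header, illegal residue characters) is reported with the offending
#' line number; duplicate record ids are an error.
#'
#' @param path FASTA file path.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param degenerate logical; permit IUPAC ambiguity codes.
#' @return Named list of [seq_record] objects (possibly empty).
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino_acid"),
                       degenerate = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  cur_chunks <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(cur_chunks, collapse = ""))
    }
  }
  for (k in seq_along(lines)) {
    if (!keep[k]) next
    ln <- trimws(lines[k])
    if (startsWith(ln, ">")) {
      id <- trimws(sub("^>", "", ln))
      id <- sub("\\s.*$", "", id) # first whitespace-delimited token
      if (!nzchar(id)) stop("malformed FASTA header at line ", k, " of ", path)
      flush()
      cur <- id
      cur_chunks <- character(0)
    } else {
      if (is.null(cur))
        stop("sequence data before first header at line ", k, " of ", path)
      cur_chunks <- c(cur_chunks, ln)
    }
  }
  flush()
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    recs[[i]] <- tryCatch(
      seq_record(ids[i], seqs[i], alphabet, degenerate = degenerate),
      error = function(e) stop("record '", ids[i], "' in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  names(recs) <- ids
  recs
}

#' Write records to FASTA
#'
#' @param records list of [seq_record] (or named character vector).
#' @param path output file path.
#' @param width line-wrap width (default 70 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    nm <- names(records)
    records <- mapply(function(id, s) list(id = id, residues = s),
                      nm, records, SIMPLIFY = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    s <- r$residues
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", r$id),
                 substring(s, starts, pmin(starts + width - 1, nchar(s)))), con)
  }
  invisible(path)
}

#' Read a cluster/subcluster label table
#'
#' Tab-separated with header `id<TAB>cluster<TAB>subcluster`; the subcluster
#' column may be absent or empty (cluster-only assignments, singletons). By
#' convention a subcluster name starts with its cluster name (A1 is in
#' cluster A); violations are a warning, not an error.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `id`, `cluster`, `subcluster`.
#' @export
read_label_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("id", "cluster") %in% names(df)))
    stop("label table needs 'id' and 'cluster' columns: ", path)
  if (!"subcluster" %in% names(df)) df$subcluster <- ""
  df <- df[, c("id", "cluster", "subcluster")]
  df$subcluster[is.na(df$subcluster)] <- ""
  label_table(df$id, df$cluster, df$subcluster)
}

#' Construct a label table
#'
#' @param id,cluster,subcluster character vectors (subcluster may be empty
#'   strings).
#' @return `data.frame` with one row per sequence id.
#' @export
label_table <- function(id, cluster, subcluster = "") {
  df <- data.frame(id = as.character(id), cluster = as.character(cluster),
                   subcluster = as.character(subcluster),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate id(s) in label table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ","))
  has_sub <- nzchar(df$subcluster)
  off <- has_sub & !startsWith(df$subcluster, df$cluster)
  if (any(off))
    warning("subcluster name(s) not prefixed by cluster: ",
            paste(df$id[off], collapse = ","))
  df
}

#' Write a label table as TSV
#'
#' @param labels label table `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_label_table <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement (IUPAC-aware)
#'
#' @param s nucleotide string (IUPAC codes allowed) or a nucleotide
#'   [seq_record].
#' @return Reverse-complemented string.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' revcomp("RY")   # "RY"
#' @export
revcomp <- function(s) {
  s <- toupper(.as_residues(s))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), NUC_CHARS)
  if (length(bad)) stop("non-nucleotide character(s): ", paste(bad, collapse = ","))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stops rendered as `*`; a trailing partial codon is
#' dropped. Degenerate codons are translated when the ambiguity is silent
#' (e.g. GCN -> A) and are an error otherwise.
#'
#' @param s nucleotide string or [seq_record].
#' @param frame reading frame offset, 0, 1 or 2.
#' @return Amino-acid string.
#' @examples
#' translate_seq("ATGAAA") # "MK"
#' @export
translate_seq <- function(s, frame = 0) {
  s <- toupper(.as_residues(s))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (nchar(s) < 3 + frame) stop("sequence too short for frame ", frame)
  s <- substr(s, frame + 1, nchar(s))
  s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
  aa <- tryCatch(
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "error.if.X")),
    error = function(e) stop("translation error: ", conditionMessage(e),
                             call. = FALSE))
  aa
}
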