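# Single-gene cluster/subcluster prediction against a labelled reference
# panel, and recovery-accuracy statistics.

#' Labelled reference panel
#'
#' Marker-gene sequences carrying cluster/subcluster assignments; the ground
#' truth the classifier compares against.
#'
#' @param records list of [seq_record].
#' @param labels label table (see [label_table()]) covering every record id.
#' @return Object of class `reference_panel`.
#' @export
reference_panel <- function(records, labels) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids in panel")
  missing <- setdiff(ids, labels$id)
  if (length(missing))
    stop("unlabelled panel record(s): ", paste(missing, collapse = ","))
  labels <- labels[match(ids, labels$id), , drop = FALSE]
  if (length(unique(labels$cluster)) < 1) stop("panel needs >= 1 cluster")
  names(records) <- ids
  structure(list(records = records, labels = labels),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d sequences, %d clusters, %d subclusters\n",
              length(x$records), length(unique(x$labels$cluster)),
              length(unique(x$labels$subcluster[nzchar(x$labels$subcluster)]))))
  invisible(x)
}

#' Classify a single marker gene against a reference panel
#'
#' The query is compared to every panel sequence by word-match dotplot; its
#' similarity to a reference is the fraction of query words found anywhere in
#' that reference (`coverageA`). The call is the cluster/subcluster of the
#' best-covered reference, or unassigned when the best similarity falls below
#' `threshold` (singleton behaviour). Coverage ties are broken by global
#' alignment percent identity, then lexicographically by reference id.
#'
#' @param query [seq_record].
#' @param panel [reference_panel()] on the same alphabet.
#' @param dp [dotplot_params()].
#' @param threshold unassigned threshold on word coverage (default 0.25).
#' @param loo logical; leave-one-out — drop the panel record whose id equals
#'   the query id before classifying.
#' @param align_params [scoring_params()] used only for tie-breaking.
#' @return One-row `data.frame` (class `cluster_call`): `query_id`, `status`,
#'   `cluster`, `subcluster`, `best_hit_id`, `similarity`,
#'   `runner_up_margin`.
#' @export
classify_gene <- function(query, panel, dp = dotplot_params(),
                          threshold = 0.25, loo = FALSE,
                          align_params = scoring_params()) {
  if (!inherits(panel, "reference_panel")) stop("panel must be a reference_panel")
  recs <- panel$records
  labs <- panel$labels
  if (loo) {
    keep <- names(recs) != query$id
    recs <- recs[keep]
    labs <- labs[keep, , drop = FALSE]
  }
  if (length(recs) == 0) stop("empty reference panel")
  sims <- vapply(recs, function(r) dotplot(query, r, dp)$coverageA, 0)
  best_sim <- max(sims)
  cand <- which(sims >= best_sim - 1e-12)
  if (length(cand) > 1) {
    pid <- vapply(cand, function(i)
      global_align(query, recs[[i]], align_params)$pct_identity, 0)
    cand <- cand[pid >= max(pid) - 1e-9]
    cand <- cand[order(names(recs)[cand])]
  }
  best <- cand[1]
  runner <- if (length(sims) > 1) max(sims[-best]) else 0
  assigned <- best_sim >= threshold
  out <- data.frame(
    query_id = query$id,
    status = if (assigned) "assigned" else "unassigned",
    cluster = if (assigned) labs$cluster[best] else "",
    subcluster = if (assigned) labs$subcluster[best] else "",
    best_hit_id = names(recs)[best],
    similarity = best_sim,
    runner_up_margin = best_sim - runner,
    stringsAsFactors = FALSE)
  class(out) <- c("cluster_call", class(out))
  out
}

#' Classify many queries
#'
#' @param queries list of [seq_record].
#' @param panel [reference_panel()].
#' @param ... passed to [classify_gene()] (notably `threshold`, `dp`, `loo`).
#' @return `data.frame` of calls, one row per query.
#' @export
classify_panel <- function(queries, panel, ...) {
  do.call(rbind, lapply(queries, classify_gene, panel = panel, ...))
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` at level
#' `1 - alpha`, computed on the unrounded proportion and returned in
#' percentage points.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @return Named numeric: `proportion_pct`, `halfwidth_pct`.
#' @examples
#' proportion_ci(241, 247) # 97.6 +/- 1.92
#' @export
proportion_ci <- function(successes, n, alpha = 0.05) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  p <- successes / n
  z <- qnorm(1 - alpha / 2)
  c(proportion_pct = 100 * p,
    halfwidth_pct = 100 * z * sqrt(p * (1 - p) / n))
}

#' Score classifier calls against known labels
#'
#' Counts exact cluster- and subcluster-level matches; unassigned calls count
#' as incorrect. A call is subcluster-correct when both its cluster and its
#' subcluster match the truth row (so subcluster-correct implies
#' cluster-correct). The confidence half-width is the Wald interval on the
#' subcluster-recovery proportion at `alpha = 0.05`.
#'
#' @param calls `data.frame` of calls from [classify_gene()]/[classify_panel()].
#' @param truth label table with a row for every `query_id`.
#' @return Object of class `recovery_report` with fields `n`,
#'   `cluster_correct`, `subcluster_correct`, `cluster_accuracy_pct`,
#'   `subcluster_accuracy_pct`, `ci_halfwidth_pct`, `misassigned_ids`.
#' @export
evaluate_recovery <- function(calls, truth) {
  if (anyDuplicated(calls$query_id))
    stop("duplicate query ids in calls")
  m <- match(calls$query_id, truth$id)
  if (anyNA(m))
    stop("call id(s) missing from truth: ",
         paste(calls$query_id[is.na(m)], collapse = ","))
  tr <- truth[m, , drop = FALSE]
  assigned <- calls$status == "assigned"
  cl_ok <- assigned & calls$cluster == tr$cluster
  sub_ok <- cl_ok & calls$subcluster == tr$subcluster
  n <- nrow(calls)
  ci <- proportion_ci(sum(sub_ok), n)
  structure(list(
    n = n,
    cluster_correct = sum(cl_ok),
    subcluster_correct = sum(sub_ok),
    cluster_accuracy_pct = 100 * sum(cl_ok) / n,
    subcluster_accuracy_pct = 100 * sum(sub_ok) / n,
    ci_halfwidth_pct = unname(ci["halfwidth_pct"]),
    misassigned_ids = calls$query_id[!sub_ok]),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    paste0("<recovery_report> n=%d\n  cluster:    %d/%d = %.1f%%\n",
           "  subcluster: %d/%d = %.1f%% (+/- %.2f at 95%%)\n"),
    x$n, x$cluster_correct, x$n, x$cluster_accuracy_pct,
    x$subcluster_correct, x$n, x$subcluster_accuracy_pct,
    x$ci_halfwidth_pct))
  if (length(x$misassigned_ids))
    cat("  misassigned:", paste(x$misassigned_ids, collapse = ", "), "\n")
  invisible(x)
}
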