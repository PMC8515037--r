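# Weight-based re-ranking of pathway-enrichment results.

#' Re-rank enrichment results by pathway weight coefficient
#'
#' The traditional ordering (`rank_before`) sorts pathways by ascending
#' enrichment p-value; the weighted ordering (`rank_after`) sorts by
#' descending pathway N score, where N is the sum of the T scores of the
#' pathway's member targets (see [pathway_scores()]). Ties in N are broken
#' by ascending enrichment p, then pathway id, making the order a
#' deterministic total order. Pathways whose members all lack a T score get
#' N = 0 and sink to the bottom rather than being dropped.
#'
#' @param enrichment Data frame with columns `pathway_id`, `pathway_name`,
#'   `enrichment_p`, and members as a `target_symbols` semicolon-joined
#'   column (or a `members` list column). Pathway ids must be unique.
#' @param tscores A `target_scores` table (see [target_scores()]), or any
#'   data frame with `target_symbol` and `t_score` columns.
#' @return The enrichment table with `n_score`, `rank_before`, `rank_after`
#'   filled, sorted by `rank_after`; class `reranked_enrichment`.
#' @export
rerank_enrichment <- function(enrichment, tscores) {
  if (!is.data.frame(enrichment) || nrow(enrichment) == 0L) {
    stop("enrichment table must be a non-empty data frame")
  }
  needed <- c("pathway_id", "enrichment_p")
  if (!all(needed %in% names(enrichment))) {
    stop("enrichment table must have columns 'pathway_id' and 'enrichment_p'")
  }
  p <- as.numeric(enrichment$enrichment_p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("enrichment_p must lie in [0, 1]")
  }
  nscores <- pathway_scores(tscores, enrichment)  # validates ids, members
  out <- as.data.frame(enrichment)
  out$enrichment_p <- p
  out$n_score <- nscores$n_score[match(out$pathway_id, nscores$pathway_id)]
  ord_before <- order(out$enrichment_p, out$pathway_id)
  out$rank_before[ord_before] <- seq_len(nrow(out))
  ord_after <- order(-out$n_score, out$enrichment_p, out$pathway_id)
  out$rank_after[ord_after] <- seq_len(nrow(out))
  out <- out[order(out$rank_after), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reranked_enrichment", "data.frame")
  out
}

#' Summarize how re-ranking changed an enrichment ordering
#'
#' Compares the p-value ordering against the weight ordering: the two top-k
#' lists and their overlap, per-pathway rank shifts, and Kendall's tau
#' between the full orderings (1 for identical orders, -1 for an exact
#' reversal).
#'
#' @param reranked Output of [rerank_enrichment()].
#' @param k Size of the head-to-head top lists; must not exceed the table.
#' @return A list of class `rank_shift_report`: `k`, `top_before`,
#'   `top_after` (pathway ids in rank order), `overlap` (their common ids),
#'   `overlap_size`, `shifts` (per-pathway `rank_before`, `rank_after`,
#'   `delta` = before - after, positive = promoted), and `kendall_tau`.
#' @export
rank_shift_report <- function(reranked, k = 5L) {
  needed <- c("pathway_id", "rank_before", "rank_after")
  if (!is.data.frame(reranked) || !all(needed %in% names(reranked))) {
    stop("reranked must carry pathway_id, rank_before and rank_after")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(reranked)) {
    stop("k must lie between 1 and the number of pathways (", nrow(reranked), ")")
  }
  top_before <- reranked$pathway_id[order(reranked$rank_before)][seq_len(k)]
  top_after <- reranked$pathway_id[order(reranked$rank_after)][seq_len(k)]
  shifts <- data.frame(
    pathway_id = reranked$pathway_id,
    rank_before = reranked$rank_before,
    rank_after = reranked$rank_after,
    delta = reranked$rank_before - reranked$rank_after,
    stringsAsFactors = FALSE
  )
  tau <- if (nrow(reranked) < 2L) {
    1
  } else {
    stats::cor(reranked$rank_before, reranked$rank_after, method = "kendall")
  }
  out <- list(
    k = k,
    top_before = top_before,
    top_after = top_after,
    overlap = intersect(top_before, top_after),
    overlap_size = length(intersect(top_before, top_after)),
    shifts = shifts,
    kendall_tau = as.numeric(tau)
  )
  class(out) <- "rank_shift_report"
  out
}

#' @export
print.rank_shift_report <- function(x, ...) {
  cat(sprintf("Rank shift report (top %d): overlap %d/%d, Kendall tau %.3f\n",
              x$k, x$overlap_size, x$k, x$kendall_tau))
  cat("  by enrichment p: ", paste(x$top_before, collapse = ", "), "\n")
  cat("  by weight N:     ", paste(x$top_after, collapse = ", "), "\n")
  invisible(x)
}

#' Read an enrichment table from CSV
#'
#' @param path CSV with header
#'   `pathway_id,pathway_name,enrichment_p,target_symbols` where
#'   `target_symbols` joins member genes with semicolons.
#' @return A data frame suitable for [rerank_enrichment()].
#' @export
read_enrichment_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pathway_id", "pathway_name", "enrichment_p", "target_symbols")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("enrichment file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw
}
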