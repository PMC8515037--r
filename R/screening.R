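# Differential-expression screening and multi-set target intersection.

#' Screen a differential-expression table by fold change and p-value
#'
#' Labels each gene `up` when `log_fc > lfc_threshold` and
#' `p_value < p_threshold`, `down` when `log_fc < -lfc_threshold` and
#' `p_value < p_threshold`, otherwise `not_significant`. Both inequalities
#' are strict: a gene exactly at the fold-change or p-value boundary is not
#' significant. The logFC column is treated as supplied (no re-derivation of
#' fold changes), and the p-value column is whatever the caller provides
#' (unadjusted by default; pass an adjusted column if preferred).
#'
#' @param stats Data frame with columns `gene_symbol`, `log_fc`, `p_value`.
#'   Gene symbols are uppercased and must be unique.
#' @param lfc_threshold Positive fold-change cutoff (default 1.2).
#' @param p_threshold Significance cutoff in (0, 1) (default 0.05).
#' @return A list of class `deg_screen`: `table` (the input plus a
#'   `regulation` factor) and `counts` (named vector over
#'   up/down/not_significant).
#' @examples
#' de <- data.frame(gene_symbol = c("A", "B", "C"),
#'                  log_fc = c(2, -3, 0.1), p_value = c(0.01, 0.001, 0.5))
#' classify_degs(de)$counts
#' @export
classify_degs <- function(stats, lfc_threshold = 1.2, p_threshold = 0.05) {
  if (!is.data.frame(stats) ||
      !all(c("gene_symbol", "log_fc", "p_value") %in% names(stats))) {
    stop("stats must have columns 'gene_symbol', 'log_fc', 'p_value'")
  }
  if (!is.finite(lfc_threshold) || lfc_threshold <= 0) {
    stop("lfc_threshold must be positive")
  }
  if (!is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  tab <- data.frame(
    gene_symbol = toupper(trimws(as.character(stats$gene_symbol))),
    log_fc = as.numeric(stats$log_fc),
    p_value = as.numeric(stats$p_value),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tab$gene_symbol)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(tab$gene_symbol[duplicated(tab$gene_symbol)]),
               collapse = ", "))
  }
  if (anyNA(tab$log_fc) || !all(is.finite(tab$log_fc))) {
    stop("log_fc must be finite")
  }
  if (anyNA(tab$p_value) || any(tab$p_value < 0) || any(tab$p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  sig <- tab$p_value < p_threshold
  reg <- rep("not_significant", nrow(tab))
  reg[sig & tab$log_fc > lfc_threshold] <- "up"
  reg[sig & tab$log_fc < -lfc_threshold] <- "down"
  tab$regulation <- factor(reg, levels = c("up", "down", "not_significant"))
  counts <- table(tab$regulation)
  out <- list(table = tab,
              counts = stats::setNames(as.integer(counts), names(counts)),
              lfc_threshold = lfc_threshold, p_threshold = p_threshold)
  class(out) <- "deg_screen"
  out
}

#' @export
print.deg_screen <- function(x, ...) {
  cat(sprintf(
    "DEG screen (|logFC| > %g, p < %g): %d up, %d down, %d not significant\n",
    x$lfc_threshold, x$p_threshold,
    x$counts[["up"]], x$counts[["down"]], x$counts[["not_significant"]]))
  invisible(x)
}

normalize_symbols <- function(symbols) {
  symbols <- toupper(trimws(as.character(symbols)))
  unique(symbols[nzchar(symbols)])
}

#' Venn intersection of 2-4 target sets
#'
#' Computes the core intersection and every Venn region (symbols belonging
#' to exactly a given combination of sets). Symbols are uppercased and
#' deduplicated before any set operation. Region counts always sum to the
#' size of the union.
#'
#' @param sets A named list of 2 to 4 character vectors of gene symbols.
#' @return A list of class `venn_regions`: `labels`, `core` (symbols in all
#'   sets), `regions` (named list keyed like `"A&B"`), `region_counts`, and
#'   `union_size`.
#' @examples
#' intersect_sets(list(drug = c("IL6", "JAK3"), disease = c("IL6", "TNF")))
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    stop("need between 2 and 4 sets to intersect")
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, normalize_symbols)
  names(sets) <- labels
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  k <- length(sets)
  regions <- list()
  # every non-empty subset of the k sets defines an exclusive region
  for (mask in seq_len(2L^k - 1L)) {
    in_sets <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
    key <- paste(labels[in_sets], collapse = "&")
    if (length(universe)) {
      hit <- apply(membership, 1L, function(row) all(row == in_sets))
      regions[[key]] <- universe[hit]
    } else {
      regions[[key]] <- character(0)
    }
  }
  core <- Reduce(intersect, sets)
  out <- list(
    labels = labels,
    sets = sets,
    core = sort(core),
    regions = regions,
    region_counts = vapply(regions, length, integer(1)),
    union_size = length(universe)
  )
  class(out) <- "venn_regions"
  out
}

#' @export
print.venn_regions <- function(x, ...) {
  cat(sprintf("Venn intersection of %d sets (%s): union %d, core %d\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$union_size, length(x$core)))
  nonzero <- x$region_counts[x$region_counts > 0]
  if (length(nonzero)) {
    for (key in names(nonzero)) {
      cat(sprintf("  %-30s %d\n", key, nonzero[[key]]))
    }
  }
  invisible(x)
}

#' Read a target set from a plain-text file
#'
#' @param path Text file with one gene symbol per line; blank lines ignored.
#' @param label Optional label; defaults to the file name sans extension.
#' @return A list with `label` and the normalized `symbols`.
#' @export
read_target_set <- function(path, label = NULL) {
  symbols <- normalize_symbols(readLines(path, warn = FALSE))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  list(label = label, symbols = symbols)
}
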