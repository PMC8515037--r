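# The dose-effect weight coefficient cascade: absorption fraction from
# log P, component score Z, target score T, pathway score N.

#' Transdermal absorption fraction from log P
#'
#' For a percutaneously applied compound with octanol-water partition
#' coefficient P (log P = n, base 10), the fraction partitioning into the
#' oil phase, Coil / (Coil + Cwater) = 10^n / (10^n + 1), is taken as its
#' transdermal absorption fraction. The function is strictly increasing,
#' bounded in (0, 1), with f(0) = 1/2 and f(n) + f(-n) = 1.
#'
#' @param log_p Numeric vector of base-10 octanol-water partition
#'   coefficients; must be finite.
#' @return Numeric vector of absorption fractions in (0, 1).
#' @examples
#' absorption_fraction(0)    # 0.5
#' absorption_fraction(1)    # 10/11
#' @export
absorption_fraction <- function(log_p) {
  if (length(log_p) == 0L) return(numeric(0))
  if (anyNA(log_p) || !all(is.finite(log_p))) {
    stop("log_p must be finite (no NA/NaN/Inf)")
  }
  # 10^n / (10^n + 1) = logistic(n * ln 10); plogis is stable for large |n|
  stats::plogis(as.numeric(log_p) * log(10))
}

#' Component weight coefficients (Z scores)
#'
#' Each component's score is its transdermal absorption fraction times its
#' relative content: Z = 10^n/(10^n + 1) * w, with n the component's log P
#' and w its content (percent of total peak area by default). Z is linear in
#' content, so rescaling all contents by a common factor rescales every
#' downstream T and N score by the same factor without changing any ranking.
#'
#' @param components A `component_table` (see [read_component_table()]) with
#'   finite `log_p` for every scored row.
#' @param normalize If `TRUE`, divide contents by their total before scoring
#'   so that weights sum to 1. Changes only the scale of Z/T/N, never any
#'   ranking.
#' @param on_missing_logp `"error"` (default) stops naming the offending
#'   components; `"skip"` drops them with a warning.
#' @return Data frame of class `component_scores` with columns
#'   `component_name`, `absorption_fraction`, `z_score`, sorted by
#'   descending `z_score` (ties by name).
#' @export
component_scores <- function(components, normalize = FALSE,
                             on_missing_logp = c("error", "skip")) {
  components <- validate_component_table(components)
  on_missing_logp <- match.arg(on_missing_logp)
  if (anyDuplicated(components$name)) {
    stop("duplicate component name(s): ",
         paste(unique(components$name[duplicated(components$name)]),
               collapse = ", "),
         " (content weight would be ambiguous)")
  }
  missing <- is.na(components$log_p) | !is.finite(components$log_p)
  if (any(missing)) {
    offenders <- paste(components$name[missing], collapse = ", ")
    if (on_missing_logp == "error") {
      stop("missing log_p for component(s): ", offenders)
    }
    warning("skipping component(s) without log_p: ", offenders)
    components <- components[!missing, , drop = FALSE]
  }
  w <- components$content_pct
  if (normalize && nrow(components) && sum(w) > 0) w <- w / sum(w)
  frac <- absorption_fraction(components$log_p)
  out <- data.frame(
    component_name = components$name,
    absorption_fraction = frac,
    z_score = frac * w,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$z_score, out$component_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("component_scores", "data.frame")
  out
}

# normalize component -> target edge lists: trim, uppercase targets,
# drop duplicate pairs
normalize_edges <- function(edges) {
  if (!is.data.frame(edges) ||
      !all(c("component_name", "target_symbol") %in% names(edges))) {
    stop("edges must have columns 'component_name' and 'target_symbol'")
  }
  out <- data.frame(
    component_name = trimws(as.character(edges$component_name)),
    target_symbol = toupper(trimws(as.character(edges$target_symbol))),
    stringsAsFactors = FALSE
  )
  out[!duplicated(out), , drop = FALSE]
}

#' Target weight coefficients (T scores)
#'
#' A target's score is the sum of the Z scores of the distinct components
#' that act on it: T = sum of incident Z. Duplicate edges are collapsed
#' before summation; targets are uppercased. Output covers exactly the
#' targets appearing in the edge list.
#'
#' @param scores A `component_scores` table from [component_scores()].
#' @param edges Data frame with columns `component_name`, `target_symbol`;
#'   every component named must exist in `scores`.
#' @return Data frame of class `target_scores` with columns `target_symbol`,
#'   `t_score`, sorted by descending `t_score` (ties by symbol).
#' @export
target_scores <- function(scores, edges) {
  if (!is.data.frame(scores) ||
      !all(c("component_name", "z_score") %in% names(scores))) {
    stop("scores must have columns 'component_name' and 'z_score'")
  }
  edges <- normalize_edges(edges)
  unknown <- setdiff(edges$component_name, scores$component_name)
  if (length(unknown)) {
    stop("edge list references unknown component(s): ",
         paste(unknown, collapse = ", "))
  }
  z <- scores$z_score[match(edges$component_name, scores$component_name)]
  agg <- tapply(z, edges$target_symbol, sum)
  out <- data.frame(
    target_symbol = names(agg),
    t_score = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$t_score, out$target_symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_scores", "data.frame")
  out
}

# pathway table: pathway_id, pathway_name (optional), and members either as
# a list column `members` or a `target_symbols` semicolon-joined string
pathway_members <- function(pathways) {
  if (!is.data.frame(pathways) || !"pathway_id" %in% names(pathways)) {
    stop("pathway table must have a 'pathway_id' column")
  }
  if (nrow(pathways) == 0L) stop("pathway table is empty")
  if (anyDuplicated(pathways$pathway_id)) {
    stop("duplicate pathway id(s): ",
         paste(unique(pathways$pathway_id[duplicated(pathways$pathway_id)]),
               collapse = ", "))
  }
  members <- if ("members" %in% names(pathways)) {
    pathways$members
  } else if ("target_symbols" %in% names(pathways)) {
    strsplit(as.character(pathways$target_symbols), ";", fixed = TRUE)
  } else {
    stop("pathway table needs a 'members' list column or a ",
         "'target_symbols' semicolon-joined column")
  }
  members <- lapply(members, function(m) unique(toupper(trimws(m[nzchar(trimws(m))]))))
  if (any(lengths(members) == 0L)) {
    stop("pathway member lists must be non-empty")
  }
  names(members) <- pathways$pathway_id
  members
}

#' Pathway weight coefficients (N scores)
#'
#' A pathway's score is the sum of the T scores of its member targets:
#' N = T_1 + T_2 + ... . Members absent from the target score table
#' contribute 0 (pathway annotations are broader than a drug's target set);
#' a target belonging to several pathways contributes to each.
#'
#' @param tscores A `target_scores` table from [target_scores()].
#' @param pathways Data frame with columns `pathway_id`, optional
#'   `pathway_name`, and members as either a `members` list column or a
#'   semicolon-joined `target_symbols` character column.
#' @return Data frame of class `pathway_scores` with columns `pathway_id`,
#'   `pathway_name`, `n_score`, `n_members`, `n_members_scored`, sorted by
#'   descending `n_score` (ties by id).
#' @export
pathway_scores <- function(tscores, pathways) {
  if (!is.data.frame(tscores) ||
      !all(c("target_symbol", "t_score") %in% names(tscores))) {
    stop("tscores must have columns 'target_symbol' and 't_score'")
  }
  members <- pathway_members(pathways)
  tvals <- stats::setNames(tscores$t_score,
                           toupper(trimws(tscores$target_symbol)))
  n_score <- vapply(members, function(m) {
    sum(tvals[intersect(m, names(tvals))])
  }, numeric(1))
  out <- data.frame(
    pathway_id = names(members),
    pathway_name = if ("pathway_name" %in% names(pathways)) {
      as.character(pathways$pathway_name)
    } else {
      names(members)
    },
    n_score = as.numeric(n_score),
    n_members = lengths(members),
    n_members_scored = vapply(members, function(m) {
      length(intersect(m, names(tvals)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_score, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Run the full Z/T/N weight-coefficient cascade
#'
#' Convenience composition of [component_scores()], [target_scores()] and
#' [pathway_scores()]. Deterministic: each table is sorted by descending
#' score with ties broken by name/id ascending.
#'
#' @inheritParams component_scores
#' @param edges Component -> target edge list (see [target_scores()]).
#' @param pathways Optional pathway annotation table (see
#'   [pathway_scores()]); when `NULL` the pathway table is omitted.
#' @return A list of class `score_table` with elements `z`, `t` and (when
#'   pathways are supplied) `n`.
#' @examples
#' comps <- data.frame(name = c("a", "b"), cas = "", content_pct = c(10, 5),
#'                     retention_index = c(900, 1000), log_p = c(0, 1))
#' edges <- data.frame(component_name = c("a", "b", "b"),
#'                     target_symbol = c("TP1", "TP1", "TP2"))
#' score_all(validate_component_table(comps), edges)
#' @export
score_all <- function(components, edges, pathways = NULL, normalize = FALSE,
                      on_missing_logp = c("error", "skip")) {
  z <- component_scores(components, normalize = normalize,
                        on_missing_logp = on_missing_logp)
  t <- if (nrow(as.data.frame(edges)) == 0L) {
    out <- data.frame(target_symbol = character(0), t_score = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("target_scores", "data.frame")
    out
  } else {
    target_scores(z, edges)
  }
  res <- list(z = z, t = t)
  if (!is.null(pathways)) res$n <- pathway_scores(t, pathways)
  class(res) <- "score_table"
  res
}

#' @export
print.score_table <- function(x, n = 5L, ...) {
  cat("Dose-effect weight coefficient cascade\n")
  cat(sprintf("  Z: %d components (max %.4g)\n", nrow(x$z),
              if (nrow(x$z)) x$z$z_score[1L] else NA))
  cat(sprintf("  T: %d targets (max %.4g)\n", nrow(x$t),
              if (nrow(x$t)) x$t$t_score[1L] else NA))
  if (!is.null(x$n)) {
    cat(sprintf("  N: %d pathways (max %.4g)\n", nrow(x$n),
                if (nrow(x$n)) x$n$n_score[1L] else NA))
  }
  top <- utils::head(x$z, n)
  if (nrow(top)) {
    cat(sprintf("Top components by Z:\n"))
    print.data.frame(top, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' @export
summary.score_table <- function(object, ...) {
  out <- list(
    n_components = nrow(object$z),
    n_targets = nrow(object$t),
    n_pathways = if (is.null(object$n)) NA_integer_ else nrow(object$n),
    total_z = sum(object$z$z_score),
    total_t = sum(object$t$t_score)
  )
  class(out) <- "summary.score_table"
  out
}

#' @export
print.summary.score_table <- function(x, ...) {
  cat(sprintf(
    "score_table: %d components (sum Z = %.4g), %d targets (sum T = %.4g)",
    x$n_components, x$total_z, x$n_targets, x$total_t))
  if (!is.na(x$n_pathways)) cat(sprintf(", %d pathways", x$n_pathways))
  cat("\n")
  invisible(x)
}

#' Plot a weight-coefficient table
#'
#' Horizontal bar chart of the top scores in a cascade table.
#'
#' @param x A `score_table`.
#' @param which One of `"z"`, `"t"`, `"n"`.
#' @param top Number of bars to show.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.score_table <- function(x, which = c("z", "t", "n"), top = 10L, ...) {
  which <- match.arg(which)
  tab <- x[[which]]
  if (is.null(tab) || !nrow(tab)) stop("no ", which, " scores to plot")
  score_col <- c(z = "z_score", t = "t_score", n = "n_score")[[which]]
  name_col <- c(z = "component_name", t = "target_symbol",
                n = "pathway_name")[[which]]
  tab <- utils::head(tab, top)
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(rev(tab[[score_col]]), names.arg = rev(tab[[name_col]]),
                    horiz = TRUE, las = 1,
                    xlab = sprintf("%s score", toupper(which)), ...)
  invisible(x)
}
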