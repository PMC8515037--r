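# Positive-control-normalized docking composites: S = Z * A / B.

#' Composite docking score
#'
#' Normalizes a component's raw docking score A at a target by the score B
#' of the positive-control drug docked at the same target, and weights by
#' the component's Z score: S = Z * A / B. When the component docks exactly
#' as well as the control (A = B), S equals Z. S is linear in Z and in A;
#' its sign follows the sign of A (docking schemes where lower or negative
#' is better pass through unchanged — higher-is-better, as in LibDock-style
#' scores, is a documented convention, not enforced).
#'
#' @param z_score Non-negative component weight coefficient(s).
#' @param raw_score Raw docking score(s) A.
#' @param positive_control_score Positive-control score(s) B; strictly
#'   positive.
#' @return Numeric vector of composite scores S.
#' @examples
#' composite_score(2, 50, 50)    # 2: docks exactly like the control
#' composite_score(1.5, 80, 100) # 1.2
#' @export
composite_score <- function(z_score, raw_score, positive_control_score) {
  z <- as.numeric(z_score)
  a <- as.numeric(raw_score)
  b <- as.numeric(positive_control_score)
  if (anyNA(b) || any(!is.finite(b)) || any(b <= 0)) {
    stop("positive_control_score must be strictly positive (the A/B ratio ",
         "is undefined otherwise)")
  }
  if (anyNA(z) || any(!is.finite(z)) || any(z < 0)) {
    stop("z_score must be finite and non-negative")
  }
  if (anyNA(a) || any(!is.finite(a))) stop("raw_score must be finite")
  z * a / b
}

#' Assemble the component-by-target composite score matrix
#'
#' Every docking row (component, target, A) is combined with the target's
#' positive-control score B and the component's weight Z into
#' S = Z * A / B. Pairs never docked stay `NA` in the matrix — a missing
#' experiment is reported as absent, never imputed as zero, because a zero
#' would silently demote the component. Per-target rankings (the heatmap
#' ordering) sort by descending S with ties broken by component name.
#'
#' @param dockings Data frame with columns `component_name`,
#'   `target_symbol`, `raw_score`.
#' @param controls Data frame with columns `target_symbol`,
#'   `positive_control_score` (one row per docked target).
#' @param zscores A `component_scores` table, or any data frame with
#'   `component_name` and `z_score` columns.
#' @return A list of class `docking_matrix`: `matrix` (components x
#'   targets, `NA` for absent pairs) and `long` (one row per docked pair
#'   with `composite` and `rank_within_target`).
#' @export
score_matrix <- function(dockings, controls, zscores) {
  if (!is.data.frame(dockings) ||
      !all(c("component_name", "target_symbol", "raw_score") %in%
           names(dockings))) {
    stop("dockings must have columns 'component_name', 'target_symbol', 'raw_score'")
  }
  if (!is.data.frame(controls) ||
      !all(c("target_symbol", "positive_control_score") %in% names(controls))) {
    stop("controls must have columns 'target_symbol', 'positive_control_score'")
  }
  if (!is.data.frame(zscores) ||
      !all(c("component_name", "z_score") %in% names(zscores))) {
    stop("zscores must have columns 'component_name' and 'z_score'")
  }
  dk <- data.frame(
    component_name = trimws(as.character(dockings$component_name)),
    target_symbol = toupper(trimws(as.character(dockings$target_symbol))),
    raw_score = as.numeric(dockings$raw_score),
    stringsAsFactors = FALSE
  )
  ctrl_sym <- toupper(trimws(as.character(controls$target_symbol)))
  no_b <- unique(dk$target_symbol[!dk$target_symbol %in% ctrl_sym])
  no_z <- unique(
    dk$component_name[!dk$component_name %in% zscores$component_name])
  if (length(no_b) || length(no_z)) {
    msg <- c(
      if (length(no_b)) paste0("targets without a positive-control score: ",
                               paste(no_b, collapse = ", ")),
      if (length(no_z)) paste0("components without a Z score: ",
                               paste(no_z, collapse = ", ")))
    stop("docking table fails referential integrity; ",
         paste(msg, collapse = "; "))
  }
  if (anyDuplicated(paste(dk$component_name, dk$target_symbol, sep = "\r"))) {
    stop("duplicate docking row(s) for the same component-target pair")
  }
  b <- as.numeric(controls$positive_control_score)[
    match(dk$target_symbol, ctrl_sym)]
  z <- as.numeric(zscores$z_score)[
    match(dk$component_name, zscores$component_name)]
  dk$composite <- composite_score(z, dk$raw_score, b)

  comps <- sort(unique(dk$component_name))
  tgts <- sort(unique(dk$target_symbol))
  mat <- matrix(NA_real_, nrow = length(comps), ncol = length(tgts),
                dimnames = list(comps, tgts))
  mat[cbind(match(dk$component_name, comps), match(dk$target_symbol, tgts))] <-
    dk$composite

  dk <- dk[order(dk$target_symbol, -dk$composite, dk$component_name), ,
           drop = FALSE]
  dk$rank_within_target <- stats::ave(
    seq_len(nrow(dk)), dk$target_symbol, FUN = seq_along)
  rownames(dk) <- NULL
  out <- list(matrix = mat, long = dk)
  class(out) <- "docking_matrix"
  out
}

#' @export
print.docking_matrix <- function(x, ...) {
  cat(sprintf("Composite docking matrix: %d components x %d targets (%d pairs)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$long)))
  top <- x$long[x$long$rank_within_target == 1L, , drop = FALSE]
  if (nrow(top)) {
    cat("Top component per target:\n")
    print.data.frame(
      top[, c("target_symbol", "component_name", "composite")],
      row.names = FALSE, digits = 5)
  }
  invisible(x)
}
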