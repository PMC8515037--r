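# Seeded generators for every pipeline input, plus the packaged
# identification-table fixture. Each generator is a pure function of its
# config: a fixed per-generator offset added to the config seed gives
# independent, reproducible substreams, and the caller's RNG state is
# restored afterwards.

SEED_OFFSETS <- c(ladder = 11L, components = 23L, edges = 37L,
                  pathways = 41L, de = 53L, docking = 67L)

with_substream <- function(seed, offset, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

#' Configuration for the synthetic input generators
#'
#' Defaults mirror the study conditions of a transdermal essential-oil
#' network-pharmacology analysis: 20 identified components, 29 key targets,
#' 16 enriched pathways, a 2000-gene expression table with 28% of genes
#' carrying a planted |logFC| 2.0 effect (about 560 differential genes at
#' zero noise), and component log P values around 4.5 (typical
#' sesquiterpene lipophilicity).
#'
#' @param seed Integer seed; every generator derives its own substream from
#'   it, so the same config reproduces every table bit-identically.
#' @param n_components,n_targets,n_pathways Sizes of the component, target
#'   and pathway universes.
#' @param edge_probability Independent inclusion probability of each
#'   component-target edge.
#' @param n_genes Number of genes in the differential-expression table.
#' @param frac_de Fraction of genes receiving a planted effect.
#' @param effect_size Magnitude of the planted |logFC|.
#' @param noise_sd Standard deviation of Gaussian logFC noise (applied to
#'   planted and null genes alike).
#' @param logp_mean,logp_sd Mean and sd of the component log P
#'   distribution (normal truncated to \[-2, 8\]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_components = 20L, n_targets = 29L,
                       n_pathways = 16L, edge_probability = 0.15,
                       n_genes = 2000L, frac_de = 0.28, effect_size = 2.0,
                       noise_sd = 0.5, logp_mean = 4.5, logp_sd = 1.0) {
  cfg <- list(seed = as.integer(seed), n_components = as.integer(n_components),
              n_targets = as.integer(n_targets),
              n_pathways = as.integer(n_pathways),
              edge_probability = as.numeric(edge_probability),
              n_genes = as.integer(n_genes), frac_de = as.numeric(frac_de),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              logp_mean = as.numeric(logp_mean),
              logp_sd = as.numeric(logp_sd))
  counts <- c("n_components", "n_targets", "n_pathways", "n_genes")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) stop(nm, " must be a positive count")
  }
  for (nm in c("edge_probability", "frac_de")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]")
    }
  }
  if (is.na(cfg$noise_sd) || cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.na(cfg$effect_size) || cfg$effect_size < 0) {
    stop("effect_size must be >= 0")
  }
  if (is.na(cfg$logp_sd) || cfg$logp_sd <= 0) stop("logp_sd must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate an n-alkane ladder (C8-C40)
#'
#' Retention times follow an affine trend in carbon number (about 1.75 min
#' per carbon from 4 min at C8, matching a routine temperature-programmed
#' run) plus uniform jitter small enough to keep the ladder strictly
#' increasing.
#'
#' @param config A [sim_config()].
#' @return An [alkane_ladder()] with 33 entries.
#' @export
make_alkane_ladder <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, SEED_OFFSETS[["ladder"]], {
    carbon <- 8:40
    rt <- 4 + 1.75 * (carbon - 8) + stats::runif(length(carbon), -0.5, 0.5)
    alkane_ladder(carbon, rt)
  })
}

# normal truncated to [lo, hi] by rejection; bounds are several sd out for
# any realistic config, so this terminates quickly
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic component identification table
#'
#' Relative contents are a symmetric Dirichlet draw scaled to sum to 95%
#' (real chromatograms leave a few percent unidentified); log P values are
#' normal with `logp_mean`/`logp_sd`, truncated to \[-2, 8\]. Names are
#' unique; CAS strings are synthetic placeholders.
#'
#' @param config A [sim_config()].
#' @return A `component_table` with `n_components` rows.
#' @export
make_component_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_components
  with_substream(config$seed, SEED_OFFSETS[["components"]], {
    raw <- stats::rgamma(n, shape = 1)
    content <- 95 * raw / sum(raw)
    logp <- rtruncnorm(n, config$logp_mean, config$logp_sd, -2, 8)
    ri <- sort(stats::runif(n, 900, 2100))
    validate_component_table(data.frame(
      name = sprintf("component_%02d", seq_len(n)),
      cas = sprintf("0000-SYN-%02d", seq_len(n)),
      content_pct = content,
      retention_index = ri,
      log_p = logp,
      stringsAsFactors = FALSE
    ))
  })
}

#' Generate a component-target edge list
#'
#' Each of the `n_components * n_targets` pairs is included independently
#' with `edge_probability`.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `component_name`, `target_symbol`.
#' @export
make_bipartite_edges <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comps <- sprintf("component_%02d", seq_len(config$n_components))
  tgts <- sprintf("TGT%02d", seq_len(config$n_targets))
  with_substream(config$seed, SEED_OFFSETS[["edges"]], {
    grid <- expand.grid(component_name = comps, target_symbol = tgts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < config$edge_probability
    out <- grid[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a pathway annotation table
#'
#' Each pathway is a random non-empty subset of the target universe
#' (between 1 and min(10, n_targets) members).
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `pathway_id`, `pathway_name`,
#'   `target_symbols` (semicolon-joined members).
#' @export
make_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tgts <- sprintf("TGT%02d", seq_len(config$n_targets))
  with_substream(config$seed, SEED_OFFSETS[["pathways"]], {
    sizes <- sample.int(min(10L, config$n_targets), config$n_pathways,
                        replace = TRUE)
    members <- lapply(sizes, function(m) sort(sample(tgts, m)))
    data.frame(
      pathway_id = sprintf("PWY%03d", seq_len(config$n_pathways)),
      pathway_name = sprintf("synthetic pathway %d",
                             seq_len(config$n_pathways)),
      target_symbols = vapply(members, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a differential-expression table with known truth
#'
#' A `frac_de` share of genes receive a planted logFC of +/-`effect_size`
#' (sign balanced at random) plus `noise_sd` Gaussian noise, and the fixed
#' small p-value 1e-6; the remaining genes receive pure-noise logFC and
#' Uniform(0, 1) p-values. The returned truth labels let recovery by
#' [classify_degs()] be checked exactly at zero noise, and against the
#' closed-form normal exceedance probability when noise is present.
#'
#' @param config A [sim_config()].
#' @return A list: `stats` (columns `gene_symbol`, `log_fc`, `p_value`) and
#'   `truth` (columns `gene_symbol`, `label` in up/down/not_significant).
#' @export
make_de_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_substream(config$seed, SEED_OFFSETS[["de"]], {
    genes <- sprintf("G%05d", seq_len(n))
    n_de <- round(config$frac_de * n)
    de_idx <- if (n_de > 0L) sample.int(n, n_de) else integer(0)
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc <- stats::rnorm(n, 0, config$noise_sd)
    lfc[de_idx] <- lfc[de_idx] + sign * config$effect_size
    p <- stats::runif(n)
    p[de_idx] <- 1e-6
    label <- rep("not_significant", n)
    label[de_idx] <- ifelse(sign > 0, "up", "down")
    list(
      stats = data.frame(gene_symbol = genes, log_fc = lfc, p_value = p,
                         stringsAsFactors = FALSE),
      truth = data.frame(gene_symbol = genes, label = label,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate docking and positive-control score tables
#'
#' Positive-control scores B are Uniform(80, 120) per target (LibDock-scale
#' magnitudes); each component's raw score A at a target is B times a
#' log-normal ratio with median 1, so A/B ratios are positive and centred
#' at unity. All component-target pairs are docked.
#'
#' @param config A [sim_config()].
#' @return A list: `dockings` (columns `component_name`, `target_symbol`,
#'   `raw_score`) and `controls` (columns `target_symbol`,
#'   `positive_control_score`).
#' @export
make_docking_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comps <- sprintf("component_%02d", seq_len(config$n_components))
  tgts <- sprintf("TGT%02d", seq_len(config$n_targets))
  with_substream(config$seed, SEED_OFFSETS[["docking"]], {
    b <- stats::runif(length(tgts), 80, 120)
    grid <- expand.grid(component_name = comps, target_symbol = tgts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ratio <- stats::rlnorm(nrow(grid), meanlog = 0, sdlog = 0.15)
    grid$raw_score <- b[match(grid$target_symbol, tgts)] * ratio
    list(
      dockings = grid,
      controls = data.frame(target_symbol = tgts,
                            positive_control_score = b,
                            stringsAsFactors = FALSE)
    )
  })
}

#' Packaged GC-MS identification table of German chamomile volatile oil
#'
#' The 20 identified components with their relative contents (percent of
#' total peak area) and Kovats retention indices, as packaged in
#' `inst/extdata/table1_components.csv`. No partition coefficients are
#' published for these components; `log_p` is therefore empty. A companion
#' lookup of illustrative, synthetic log P values is packaged as
#' `demo_logp_synthetic.csv` and can be merged with [merge_logp()] for
#' demonstrations.
#'
#' @return A `component_table` with 20 rows.
#' @examples
#' tab <- table1_fixture()
#' tab$name[which.max(tab$content_pct)]
#' @export
table1_fixture <- function() {
  read_component_table(
    system.file("extdata", "table1_components.csv", package = "oilnet",
                mustWork = TRUE))
}
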