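# Independent brute-force oracles and random-instance builders used across
# the suite. Each oracle deliberately avoids the code path it checks.

# nested-loop Z/T/N cascade: components is a data.frame(name, content_pct,
# log_p); edges data.frame(component_name, target_symbol); pathways a named
# list of member character vectors
oracle_cascade <- function(components, edges, pathways = NULL) {
  z <- numeric(nrow(components))
  names(z) <- components$name
  for (i in seq_len(nrow(components))) {
    n <- components$log_p[i]
    z[i] <- (10^n / (10^n + 1)) * components$content_pct[i]
  }
  pairs <- unique(paste(edges$component_name, toupper(edges$target_symbol),
                        sep = "\r"))
  tgt <- list()
  for (p in pairs) {
    bits <- strsplit(p, "\r", fixed = TRUE)[[1L]]
    tgt[[bits[2L]]] <- c(tgt[[bits[2L]]], z[[bits[1L]]])
  }
  t_scores <- vapply(tgt, sum, numeric(1))
  n_scores <- NULL
  if (!is.null(pathways)) {
    n_scores <- vapply(pathways, function(members) {
      total <- 0
      for (m in toupper(members)) {
        if (m %in% names(t_scores)) total <- total + t_scores[[m]]
      }
      total
    }, numeric(1))
  }
  list(z = z, t = t_scores, n = n_scores)
}

# O(K^2) concordant/discordant pair counting (no ties expected)
oracle_kendall_tau <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  concordant <- discordant <- 0L
  for (i in seq_len(length(a) - 1L)) {
    for (j in (i + 1L):length(a)) {
      s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
      if (s > 0) concordant <- concordant + 1L
      if (s < 0) discordant <- discordant + 1L
    }
  }
  (concordant - discordant) / choose(length(a), 2)
}

# per-symbol membership enumeration over all 2^k - 1 Venn regions
oracle_venn <- function(sets) {
  sets <- lapply(sets, function(s) unique(toupper(trimws(s))))
  labels <- names(sets)
  universe <- unique(unlist(sets))
  counts <- integer(0)
  k <- length(sets)
  for (mask in seq_len(2L^k - 1L)) {
    in_sets <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
    key <- paste(labels[in_sets], collapse = "&")
    hits <- 0L
    for (sym in universe) {
      member <- vapply(sets, function(s) sym %in% s, logical(1))
      if (all(member == in_sets)) hits <- hits + 1L
    }
    counts[[key]] <- hits
  }
  counts
}

# degree by direct adjacency counting over deduplicated edges
oracle_degrees <- function(edges) {
  pairs <- unique(paste(edges$component_name, toupper(edges$target_symbol),
                        sep = "\r"))
  deg <- integer(0)
  for (p in pairs) {
    bits <- strsplit(p, "\r", fixed = TRUE)[[1L]]
    for (v in bits) {
      if (!v %in% names(deg)) deg[v] <- 0L
      deg[v] <- deg[v] + 1L
    }
  }
  deg
}

random_component_table <- function(n) {
  validate_component_table(data.frame(
    name = sprintf("cmp%02d", seq_len(n)),
    cas = "0-0-0",
    content_pct = round(runif(n, 0, 20), 3),
    retention_index = sort(runif(n, 900, 2100)),
    log_p = round(runif(n, -2, 8), 2),
    stringsAsFactors = FALSE
  ))
}

random_edges <- function(components, n_targets, p = 0.4) {
  tgts <- sprintf("TG%02d", seq_len(n_targets))
  grid <- expand.grid(component_name = components$name, target_symbol = tgts,
                      stringsAsFactors = FALSE)
  grid[runif(nrow(grid)) < p, , drop = FALSE]
}

random_pathway_list <- function(n_pathways, n_targets) {
  tgts <- sprintf("TG%02d", seq_len(n_targets))
  out <- lapply(seq_len(n_pathways), function(i) {
    sample(tgts, sample.int(n_targets, 1L))
  })
  names(out) <- sprintf("pwy%02d", seq_len(n_pathways))
  out
}

pathway_list_to_table <- function(pathways) {
  data.frame(
    pathway_id = names(pathways),
    pathway_name = names(pathways),
    target_symbols = vapply(pathways, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

random_ladder <- function() {
  k <- sample(3:12, 1L)
  start <- sample(8:(40 - k), 1L)
  carbon <- seq(start, start + k)
  alkane_ladder(carbon, cumsum(runif(length(carbon), 0.5, 3)) + 2)
}
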