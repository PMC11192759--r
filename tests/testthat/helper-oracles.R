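# Independent brute-force oracles used to freeze expected values.

# all shortest directed paths by exhaustive simple-path enumeration;
# returns the lexicographically smallest node sequence among the shortest
oracle_shortest_path <- function(net, source, sink) {
  g <- as_igraph(net)
  paths <- igraph::all_simple_paths(g, from = source, to = sink, mode = "out")
  if (source == sink) return(source)
  if (length(paths) == 0) return(character(0))
  seqs <- lapply(paths, function(p) igraph::V(g)$name[p])
  lens <- vapply(seqs, length, 1L)
  seqs <- seqs[lens == min(lens)]
  keys <- vapply(seqs, paste, "", collapse = "\r")
  seqs[[order(keys)[1]]]
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n+m, n) rank assignments (requires no ties)
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  n <- length(x)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# optimal 1-D k-means by exhaustive search over contiguous partitions of the
# sorted values (the optimal 1-D partition is always contiguous)
oracle_kmeans_1d <- function(x, k = 3) {
  xs <- sort(x)
  n <- length(xs)
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL
  best_ss <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    ss <- 0
    groups <- list()
    for (g in seq_len(k)) {
      seg <- xs[(bounds[g] + 1):bounds[g + 1]]
      ss <- ss + sum((seg - mean(seg))^2)
      groups[[g]] <- seg
    }
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- groups
    }
  }
  list(groups = best, wss = best_ss,
       centers = vapply(best, mean, numeric(1)))
}

# AUC by counting concordant positive-negative pairs (ties count half)
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# closed-form 4PL viability on log10 dose
oracle_4pl <- function(doses, ic50, slope = 2, lower = 0, upper = 1,
                       zero_floor = 0.1) {
  ld <- log10(pmax(doses, zero_floor))
  lower + (upper - lower) / (1 + exp(slope * (ld - log10(ic50))))
}

# random valid signaling network for property tests
random_network <- function(seed, n_nodes = 8, p_edge = 0.25) {
  set.seed(seed)
  ids <- paste0("N", seq_len(n_nodes))
  nodes <- tibble::tibble(
    id = ids,
    base_activity = round(runif(n_nodes, 0.05, 0.95), 3),
    base_concentration = round(runif(n_nodes, 0.3, 3), 3),
    readout = c("cell_cycle", "apoptosis", rep("none", n_nodes - 2))
  )
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, ]
  edges <- if (nrow(pairs) > 0) {
    tibble::tibble(source = pairs$source, target = pairs$target,
                   sign = sample(c(-1, 1), nrow(pairs), replace = TRUE),
                   weight = round(runif(nrow(pairs), 0.5, 5), 3))
  } else NULL
  signaling_network(nodes, edges)
}
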