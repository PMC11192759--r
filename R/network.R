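#' Construct a signaling network
#'
#' A signaling network is the substrate every simulation runs on: a signed,
#' weighted, directed graph whose nodes are proteins (or logical entities such
#' as "DNA repair") carrying two per-node state variables, an activity in
#' \[0, 1\] that evolves during simulation and a positive concentration that
#' scales the node's influence on its targets.
#'
#' @param nodes A data frame with one row per node. Required column: `id`.
#'   Optional columns (defaults in parentheses): `label` (= id),
#'   `base_activity` (0.5), `base_concentration` (1), `activity_min` (0),
#'   `activity_max` (1), `role` ("neutral"; one of oncogene, tumor_suppressor,
#'   neutral), `module` (NA), `readout` ("none"; one of none, cell_cycle,
#'   apoptosis).
#' @param edges A data frame with one row per directed edge. Required columns:
#'   `source`, `target`. Optional: `sign` (+1 activating / -1 inhibiting,
#'   default +1), `weight` (positive, default 1).
#' @param validate If `TRUE` (default), abort on invariant violations.
#'
#' @return An object of class `signaling_network`: a list with tibbles
#'   `nodes` and `edges`.
#' @export
#' @examples
#' net <- signaling_network(
#'   nodes = data.frame(id = c("A", "B"), base_activity = c(0.9, 0.1)),
#'   edges = data.frame(source = "A", target = "B", sign = 1, weight = 2)
#' )
#' net
signaling_network <- function(nodes, edges = NULL, validate = TRUE) {
  nodes <- as_tibble(nodes)
  assert_that("id" %in% names(nodes), "`nodes` must have an `id` column")
  nodes$id <- as.character(nodes$id)

  defaults <- list(
    label = nodes$id, base_activity = 0.5, base_concentration = 1,
    activity_min = 0, activity_max = 1, role = "neutral",
    module = NA_character_, readout = "none"
  )
  for (col in names(defaults)) {
    if (!col %in% names(nodes)) nodes[[col]] <- defaults[[col]]
  }
  nodes <- nodes[, c("id", "label", "base_activity", "base_concentration",
                     "activity_min", "activity_max", "role", "module", "readout")]

  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- tibble(source = character(), target = character(),
                    sign = numeric(), weight = numeric())
  } else {
    edges <- as_tibble(edges)
    assert_that(all(c("source", "target") %in% names(edges)),
                "`edges` must have `source` and `target` columns")
    if (!"sign" %in% names(edges)) edges$sign <- 1
    if (!"weight" %in% names(edges)) edges$weight <- 1
    edges <- edges[, c("source", "target", "sign", "weight")]
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
  }

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "signaling_network")
  if (validate) {
    report <- validate_network(net, require_readouts = FALSE)
    if (nrow(report) > 0) {
      rlang::abort(c("invalid signaling network",
                     stats::setNames(report$message, rep("x", nrow(report)))))
    }
  }
  net
}

#' @export
print.signaling_network <- function(x, ...) {
  ro <- table(factor(x$nodes$readout, levels = c("cell_cycle", "apoptosis")))
  cat(sprintf("<signaling_network> %d nodes, %d edges (%d cell-cycle, %d apoptosis readouts)\n",
              nrow(x$nodes), nrow(x$edges), ro[["cell_cycle"]], ro[["apoptosis"]]))
  invisible(x)
}

#' Validate a signaling network
#'
#' Checks every structural invariant and returns a report instead of raising:
#' unique node ids, activity bounds ordered and containing the base activity,
#' positive concentrations and edge weights, valid role/readout levels, readout
#' nodes having neutral role, edges referring to existing nodes, and the
#' presence of at least one cell-cycle and one apoptosis readout node (both are
#' required to compute a cell-fate verdict).
#'
#' @param net A `signaling_network`.
#' @param require_readouts If `TRUE` (default) the absence of a readout class
#'   is reported as a violation; set `FALSE` when validating partial networks
#'   not meant for simulation.
#' @return A tibble with columns `element` (node/edge/network), `id` and
#'   `message`; zero rows iff the network is valid.
#' @export
validate_network <- function(net, require_readouts = TRUE) {
  n <- net$nodes
  e <- net$edges
  bad <- list()
  note <- function(element, id, message) {
    bad[[length(bad) + 1]] <<- tibble(element = element, id = id, message = message)
  }

  dup <- unique(n$id[duplicated(n$id)])
  for (d in dup) note("node", d, sprintf("duplicated node id '%s'", d))

  chk <- function(idx, msg_fmt) {
    for (i in which(idx)) note("node", n$id[i], sprintf(msg_fmt, n$id[i]))
  }
  chk(!is.finite(n$base_activity) | n$base_activity < 0 | n$base_activity > 1,
      "node '%s': base_activity outside [0, 1]")
  chk(!is.finite(n$base_concentration) | n$base_concentration <= 0,
      "node '%s': base_concentration must be > 0")
  chk(n$activity_min > n$activity_max,
      "node '%s': activity_min exceeds activity_max")
  chk(n$activity_min < 0 | n$activity_max > 1,
      "node '%s': activity bounds outside [0, 1]")
  chk(n$base_activity < n$activity_min | n$base_activity > n$activity_max,
      "node '%s': base_activity outside [activity_min, activity_max]")
  chk(!n$role %in% c("oncogene", "tumor_suppressor", "neutral"),
      "node '%s': unknown role")
  chk(!n$readout %in% c("none", "cell_cycle", "apoptosis"),
      "node '%s': unknown readout class")
  chk(n$readout != "none" & n$role != "neutral",
      "node '%s': readout nodes must have neutral role")

  if (nrow(e) > 0) {
    for (i in which(!e$source %in% n$id)) {
      note("edge", paste0(e$source[i], "->", e$target[i]),
           sprintf("edge source '%s' is not a network node", e$source[i]))
    }
    for (i in which(!e$target %in% n$id)) {
      note("edge", paste0(e$source[i], "->", e$target[i]),
           sprintf("edge target '%s' is not a network node", e$target[i]))
    }
    for (i in which(!e$sign %in% c(-1, 1))) {
      note("edge", paste0(e$source[i], "->", e$target[i]),
           "edge sign must be +1 (activating) or -1 (inhibiting)")
    }
    for (i in which(!is.finite(e$weight) | e$weight <= 0)) {
      note("edge", paste0(e$source[i], "->", e$target[i]),
           "edge weight must be a positive real")
    }
    for (i in which(e$source == e$target)) {
      note("edge", e$source[i], sprintf("self-loop on node '%s'", e$source[i]))
    }
  }

  if (require_readouts) {
    if (!any(n$readout == "cell_cycle")) {
      note("network", NA_character_, "no cell_cycle readout node")
    }
    if (!any(n$readout == "apoptosis")) {
      note("network", NA_character_, "no apoptosis readout node")
    }
  }

  if (length(bad) == 0) {
    tibble(element = character(), id = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Convert a signaling network to an igraph object
#'
#' Node and edge attributes are carried over; edge `sign` and `weight` become
#' igraph edge attributes.
#'
#' @param net A `signaling_network`.
#' @return An igraph directed graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges[, c("source", "target", "sign", "weight")],
    directed = TRUE,
    vertices = net$nodes
  )
}

GRAPH_JSON_FORMAT <- "cellavatar-graph"
GRAPH_JSON_VERSION <- 1L

#' Read a signaling network from disk
#'
#' The canonical on-disk format is a versioned graph-json document (see
#' [write_network()]); SIF and GraphML are import conveniences. SIF carries no
#' numeric attributes: weights default to 1 and node parameters to their
#' constructor defaults, with interaction words `inhibits`/`inhibit`/`-1`
#' mapped to inhibiting edges and everything else to activating.
#'
#' @param path File to read.
#' @param format One of `"graph-json"`, `"sif"`, `"graphml"`; defaults from
#'   the file extension.
#' @return A validated `signaling_network`.
#' @export
read_network <- function(path, format = c("auto", "graph-json", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "graph-json", sif = "sif", graphml = "graphml",
                     rlang::abort(sprintf("cannot infer network format from '%s'", path)))
  }
  assert_that(file.exists(path), sprintf("network file '%s' does not exist", path))

  if (format == "graph-json") {
    doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) {
                      rlang::abort(sprintf("failed to parse graph-json '%s': %s",
                                           path, conditionMessage(e)))
                    })
    if (!identical(doc$format, GRAPH_JSON_FORMAT)) {
      rlang::abort(sprintf("'%s' is not a %s document", path, GRAPH_JSON_FORMAT))
    }
    nodes <- as_tibble(doc$nodes)
    edges <- if (length(doc$edges)) as_tibble(doc$edges) else NULL
    return(signaling_network(nodes, edges))
  }

  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    badline <- which(vapply(parts, length, 1L) < 3)
    if (length(badline)) {
      rlang::abort(sprintf("SIF parse error at line %d of '%s': expected 3 tab-separated fields",
                           badline[1], path))
    }
    src <- vapply(parts, `[[`, "", 1)
    rel <- vapply(parts, `[[`, "", 2)
    tgt <- vapply(parts, `[[`, "", 3)
    sign <- ifelse(tolower(rel) %in% c("inhibits", "inhibit", "-1"), -1, 1)
    ids <- unique(c(src, tgt))
    return(signaling_network(tibble(id = ids),
                             tibble(source = src, target = tgt,
                                    sign = sign, weight = 1)))
  }

  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  nodes$id <- NULL  # GraphML XML node ids; vertex names are authoritative
  names(nodes)[names(nodes) == "name"] <- "id"
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edges)) names(edges)[1:2] <- c("source", "target")
  signaling_network(nodes, if (nrow(edges)) edges else NULL)
}

#' Write a signaling network to disk
#'
#' @param net A `signaling_network`.
#' @param path Output file.
#' @param format One of `"graph-json"` (canonical; round-trips bit-exactly
#'   through [read_network()]), `"sif"` (drops numeric attributes), or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "graph-json", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "graph-json", sif = "sif", graphml = "graphml",
                     "graph-json")
  }
  if (format == "graph-json") {
    doc <- list(format = GRAPH_JSON_FORMAT, version = GRAPH_JSON_VERSION,
                nodes = net$nodes, edges = net$edges)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (format == "sif") {
    rel <- ifelse(net$edges$sign < 0, "inhibits", "activates")
    writeLines(paste(net$edges$source, rel, net$edges$target, sep = "\t"), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Trace the shortest signal path between two nodes
#'
#' Follows directed edges from a source (typically a drug target) to a sink
#' (typically an effector readout), returning a shortest path by edge count.
#' Ties are broken by the lexicographically smallest node-id sequence. The
#' cumulative sign (product of edge signs along the path) says whether the net
#' effect of the source on the sink is activating (+1) or inhibiting (-1).
#'
#' @param net A `signaling_network`.
#' @param source,sink Node ids.
#' @return A tibble with columns `node` and `sign_to_next` (sign of the edge
#'   leaving that node; `NA` for the sink), with attribute `cumulative_sign`.
#'   Zero rows if the sink is unreachable.
#' @export
trace_signal_path <- function(net, source, sink) {
  for (id in c(source, sink)) {
    assert_that(id %in% net$nodes$id, sprintf("unknown node id '%s'", id))
  }
  g <- as_igraph(net)
  # weights = NA: shortest means fewest edges, not smallest weight sum
  paths <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = sink, mode = "out",
                               weights = NA)$vpaths
  )
  if (length(paths) == 0) {
    out <- tibble(node = character(), sign_to_next = numeric())
    attr(out, "cumulative_sign") <- NA_real_
    return(out)
  }
  seqs <- lapply(paths, function(p) igraph::V(g)$name[p])
  # lexicographic tie-break on the node-id sequence
  keys <- vapply(seqs, paste, "", collapse = "\r")
  best <- seqs[[order(keys)[1]]]

  signs <- rep(NA_real_, length(best))
  if (length(best) > 1) {
    for (i in seq_len(length(best) - 1)) {
      hit <- net$edges$source == best[i] & net$edges$target == best[i + 1]
      signs[i] <- net$edges$sign[which(hit)[1]]
    }
  }
  out <- tibble(node = best, sign_to_next = signs)
  attr(out, "cumulative_sign") <- if (length(best) > 1) prod(signs, na.rm = TRUE) else 1
  out
}
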