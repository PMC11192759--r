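#' Compute expression fold-changes against a healthy-tissue baseline
#'
#' Fold-change for a gene is `(cell + eps) / (mean(baseline) + eps)` where the
#' baseline mean is taken over the healthy tissue samples and `eps` is a
#' pseudocount guarding against zero baselines. Only genes present in both
#' tables are used.
#'
#' @param cell_expression Data frame with columns `gene_id`, `value`
#'   (non-negative expression of one cell line).
#' @param baseline_expression Data frame with columns `gene_id`, `value`; one
#'   row per gene per baseline sample (e.g. per tissue).
#' @param eps Pseudocount added to both numerator and denominator (default 1).
#' @return A tibble with columns `gene_id`, `fold_change` (strictly positive).
#' @export
compute_fold_change <- function(cell_expression, baseline_expression, eps = 1) {
  cell <- as_tibble(cell_expression)
  base <- as_tibble(baseline_expression)
  assert_that(all(c("gene_id", "value") %in% names(cell)) &&
                all(c("gene_id", "value") %in% names(base)),
              "expression tables need `gene_id` and `value` columns")
  base_mean <- base |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(baseline = mean(.data$value), .groups = "drop")
  joined <- dplyr::inner_join(cell, base_mean, by = "gene_id")
  if (nrow(joined) == 0) {
    rlang::abort("no genes shared between cell and baseline expression tables")
  }
  joined |>
    dplyr::transmute(.data$gene_id,
                     fold_change = (.data$value + eps) / (.data$baseline + eps))
}

#' Map a mutation to its functional effect on a node
#'
#' Pathogenic mutations in tumor suppressors are taken as loss-of-function.
#' Pathogenic mutations in oncogenes are taken as gain-of-function unless the
#' consequence is clearly truncating (frameshift or stop gain), which is
#' loss-of-function. Non-pathogenic mutations, and pathogenic mutations in
#' role-neutral nodes, have no effect.
#'
#' @param consequence Character vector: one of `missense`, `frameshift`,
#'   `stop_gain`, `splice`, `inframe`, `other`.
#' @param pathogenic Logical vector.
#' @param role Character vector: `oncogene`, `tumor_suppressor` or `neutral`.
#' @return Character vector: `gain_of_function`, `loss_of_function` or `none`.
#' @export
#' @examples
#' map_variant_effect("missense", TRUE, "oncogene")     # gain_of_function
#' map_variant_effect("stop_gain", TRUE, "oncogene")    # loss_of_function
#' map_variant_effect("missense", FALSE, "tumor_suppressor")  # none
map_variant_effect <- function(consequence, pathogenic, role) {
  truncating <- consequence %in% c("frameshift", "stop_gain")
  dplyr::case_when(
    !pathogenic ~ "none",
    role == "tumor_suppressor" ~ "loss_of_function",
    role == "oncogene" & truncating ~ "loss_of_function",
    role == "oncogene" ~ "gain_of_function",
    .default = "none"
  )
}

#' Build a cell-line avatar from a network plus omics tables
#'
#' Conditions the generic network into a cell-line-specific instance:
#' effective concentration is `base_concentration * fold_change` (genes absent
#' from the expression table keep fold-change 1), and pathogenic mutations cap
#' the activity range — loss-of-function pins `activity_max` (and the base
#' activity) to 0, gain-of-function pins `activity_min` (and the base
#' activity) to 1 — so the node is held there for the whole simulation.
#'
#' @param net A `signaling_network`.
#' @param expression Data frame with columns `gene_id`, `fold_change`
#'   (strictly positive), or `NULL` for no expression conditioning.
#' @param mutations Data frame with columns `gene_id`, `consequence`,
#'   `pathogenic`, or `NULL`. Records whose `gene_id` is not a network node are
#'   skipped with a message.
#' @param cell_line Identifier stored on the avatar.
#' @param indication Optional tissue label.
#' @return A `cell_avatar`: a `signaling_network` whose nodes table carries a
#'   `concentration` column and mutated activity bounds, with `cell_line` and
#'   `indication` attributes.
#' @export
build_avatar <- function(net, expression = NULL, mutations = NULL,
                         cell_line = "cell", indication = NA_character_) {
  nodes <- net$nodes
  fc <- rep(1, nrow(nodes))
  if (!is.null(expression) && nrow(as_tibble(expression)) > 0) {
    expression <- as_tibble(expression)
    assert_that(all(c("gene_id", "fold_change") %in% names(expression)),
                "expression table needs `gene_id` and `fold_change` columns")
    assert_that(all(expression$fold_change > 0),
                "fold-changes must be strictly positive")
    idx <- match(nodes$id, expression$gene_id)
    fc[!is.na(idx)] <- expression$fold_change[idx[!is.na(idx)]]
  }
  nodes$concentration <- nodes$base_concentration * fc

  if (!is.null(mutations) && nrow(as_tibble(mutations)) > 0) {
    mutations <- as_tibble(mutations)
    assert_that(all(c("gene_id", "consequence", "pathogenic") %in% names(mutations)),
                "mutation table needs `gene_id`, `consequence`, `pathogenic` columns")
    unmapped <- setdiff(unique(mutations$gene_id), nodes$id)
    if (length(unmapped) > 0) {
      rlang::inform(sprintf("skipping %d mutation record(s) on unmapped gene(s): %s",
                            sum(mutations$gene_id %in% unmapped),
                            paste(unmapped, collapse = ", ")))
      mutations <- mutations[!mutations$gene_id %in% unmapped, ]
    }
    if (nrow(mutations) > 0) {
      mutations$effect <- map_variant_effect(
        mutations$consequence, mutations$pathogenic,
        nodes$role[match(mutations$gene_id, nodes$id)]
      )
      eff <- mutations |>
        dplyr::filter(.data$effect != "none") |>
        dplyr::distinct(.data$gene_id, .data$effect)
      conflict <- eff |>
        dplyr::count(.data$gene_id) |>
        dplyr::filter(.data$n > 1)
      if (nrow(conflict) > 0) {
        rlang::abort(sprintf(
          "conflicting gain- and loss-of-function effects on node(s): %s",
          paste(conflict$gene_id, collapse = ", ")))
      }
      lof <- nodes$id %in% eff$gene_id[eff$effect == "loss_of_function"]
      gof <- nodes$id %in% eff$gene_id[eff$effect == "gain_of_function"]
      nodes$activity_max[lof] <- 0
      nodes$base_activity[lof] <- 0
      nodes$activity_min[gof] <- 1
      nodes$base_activity[gof] <- 1
    }
  }

  avatar <- structure(list(nodes = nodes, edges = net$edges),
                      class = c("cell_avatar", "signaling_network"))
  attr(avatar, "cell_line") <- cell_line
  attr(avatar, "indication") <- indication
  bad <- avatar$nodes$activity_min > avatar$nodes$activity_max
  if (any(bad)) {
    rlang::abort(sprintf("avatar activity bounds inverted on node(s): %s",
                         paste(avatar$nodes$id[bad], collapse = ", ")))
  }
  avatar
}

#' @export
print.cell_avatar <- function(x, ...) {
  capped <- sum(x$nodes$activity_max == 0 | x$nodes$activity_min == 1)
  cat(sprintf("<cell_avatar> '%s': %d nodes, %d edges, %d mutation-capped node(s)\n",
              attr(x, "cell_line"), nrow(x$nodes), nrow(x$edges), capped))
  invisible(x)
}

#' Read cell-line expression / mutation tables
#'
#' Expression TSV columns: `cell_line`, `gene_id`, `fold_change`. Mutation TSV
#' columns: `cell_line`, `gene_id`, `consequence`, `pathogenic`. An optional
#' alias map TSV (`alias`, `gene_id`) renames incoming gene ids to network
#' node ids before use.
#'
#' @param path TSV file.
#' @param alias_map Optional data frame or TSV path with columns `alias`,
#'   `gene_id`.
#' @return A tibble.
#' @export
read_expression_table <- function(path, alias_map = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  apply_alias(tab, alias_map)
}

#' @rdname read_expression_table
#' @export
read_mutation_table <- function(path, alias_map = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (is.character(tab$pathogenic)) {
    tab$pathogenic <- toupper(tab$pathogenic) %in% c("TRUE", "T", "1", "YES")
  }
  apply_alias(tab, alias_map)
}

apply_alias <- function(tab, alias_map) {
  if (is.null(alias_map)) return(tab)
  if (is.character(alias_map)) {
    alias_map <- readr::read_tsv(alias_map, show_col_types = FALSE)
  }
  idx <- match(tab$gene_id, alias_map$alias)
  tab$gene_id[!is.na(idx)] <- alias_map$gene_id[idx[!is.na(idx)]]
  tab
}
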