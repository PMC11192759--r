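#' Filter raw compound bioactivity records
#'
#' Keeps records that are informative about human target binding: organism
#' "Homo sapiens", confidence score strictly greater than 5, binding assay
#' type, affinity at or below 10000 nM (weaker binders are considered
#' ineffective) and relation `=` (uncapped `>` values are unreliable).
#' Duplicate drug-target pairs are collapsed to the minimum (strongest)
#' affinity.
#'
#' @param records Data frame with columns `drug`, `target`, `affinity_nM`,
#'   `relation`, `assay_type`, `confidence`, `organism`.
#' @param max_affinity_nM Upper affinity cutoff (default 10000).
#' @param min_confidence Records must exceed this confidence (default 5).
#' @return A tibble with columns `drug`, `target`, `affinity_nM`, one row per
#'   surviving drug-target pair. Empty output is allowed (a message is
#'   emitted).
#' @export
filter_bioactivity <- function(records, max_affinity_nM = 10000,
                               min_confidence = 5) {
  records <- as_tibble(records)
  need <- c("drug", "target", "affinity_nM", "relation", "assay_type",
            "confidence", "organism")
  assert_that(all(need %in% names(records)),
              paste("bioactivity table needs columns:", paste(need, collapse = ", ")))
  assert_that(all(records$affinity_nM > 0), "affinities must be positive")
  out <- records |>
    dplyr::filter(.data$organism == "Homo sapiens",
                  .data$confidence > min_confidence,
                  .data$assay_type == "binding",
                  .data$affinity_nM <= max_affinity_nM,
                  .data$relation == "=") |>
    dplyr::group_by(.data$drug, .data$target) |>
    dplyr::summarise(affinity_nM = min(.data$affinity_nM), .groups = "drop") |>
    dplyr::arrange(.data$drug, .data$target)
  if (nrow(out) == 0) rlang::inform("no bioactivity records survived filtering")
  out
}

#' Fractional target inhibition at a given dose
#'
#' One-site occupancy model: `inhibition = dose^h / (dose^h + affinity^h)`
#' with Hill coefficient `h` (default 1). Strictly increasing in dose,
#' exactly 0.5 at `dose == affinity`, and approaching 1 asymptotically. The
#' engine applies it as an activity ceiling on the target node:
#' `activity_max := min(activity_max, 1 - inhibition)`; several drugs hitting
#' one target combine by taking the lowest resulting cap.
#'
#' @param dose_nM Non-negative dose(s) in nM.
#' @param affinity_nM Positive affinity(ies) in nM.
#' @param hill Hill coefficient (default 1).
#' @return Inhibition fraction(s) in \[0, 1).
#' @export
target_inhibition <- function(dose_nM, affinity_nM, hill = 1) {
  assert_that(all(dose_nM >= 0), "dose must be non-negative")
  assert_that(all(affinity_nM > 0), "affinity must be positive")
  dose_nM^hill / (dose_nM^hill + affinity_nM^hill)
}

#' Activity caps induced by a treatment
#'
#' Converts a set of (target profile, dose) treatments into per-node activity
#' ceilings. Targets absent from the node set are ignored.
#'
#' @param treatments A data frame with columns `target`, `affinity_nM`,
#'   `dose_nM` (one row per drug-target record under its drug's dose).
#' @param node_ids Character vector of network node ids.
#' @param hill Hill coefficient passed to [target_inhibition()].
#' @return Named numeric vector over `node_ids` of ceilings in \[0, 1\]
#'   (1 where untargeted).
#' @export
treatment_caps <- function(treatments, node_ids, hill = 1) {
  caps <- stats::setNames(rep(1, length(node_ids)), node_ids)
  if (is.null(treatments) || nrow(as_tibble(treatments)) == 0) return(caps)
  treatments <- as_tibble(treatments)
  hit <- treatments$target %in% node_ids
  treatments <- treatments[hit, ]
  if (nrow(treatments) == 0) return(caps)
  per_target <- treatments |>
    dplyr::mutate(cap = 1 - target_inhibition(.data$dose_nM, .data$affinity_nM, hill)) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(cap = min(.data$cap), .groups = "drop")
  caps[per_target$target] <- pmin(caps[per_target$target], per_target$cap)
  caps
}

#' Build a drug target profile from filtered bioactivity records
#'
#' @param records Filtered bioactivity tibble (see [filter_bioactivity()]).
#' @param drug Drug identifier to extract.
#' @return A tibble with columns `drug`, `target`, `affinity_nM`.
#' @export
target_profile <- function(records, drug) {
  out <- as_tibble(records) |> dplyr::filter(.data$drug == !!drug)
  assert_that(nrow(out) > 0, sprintf("no targets for drug '%s' after filtering", drug))
  out[, c("drug", "target", "affinity_nM")]
}

#' Classify a drug into a mechanism-of-action group
#'
#' The MoA group is the pathway of the drug's primary target, defined as the
#' target with the numerically lowest affinity (the strongest binder); ties
#' break on the lexicographically smallest target id. A primary target missing
#' from the pathway map classifies as "other" with a warning.
#'
#' @param profile A target profile tibble (`target`, `affinity_nM`).
#' @param pathway_map Data frame with columns `target`, `pathway`.
#' @return A single MoA group string.
#' @export
classify_moa <- function(profile, pathway_map) {
  profile <- as_tibble(profile)
  assert_that(nrow(profile) > 0, "empty target profile")
  ord <- order(profile$affinity_nM, profile$target)
  primary <- profile$target[ord[1]]
  pathway_map <- as_tibble(pathway_map)
  hit <- match(primary, pathway_map$target)
  if (is.na(hit)) {
    rlang::warn(sprintf("primary target '%s' absent from pathway map; MoA 'other'",
                        primary))
    return("other")
  }
  pathway_map$pathway[hit]
}

#' Read a ChEMBL-style bioactivity TSV
#'
#' Expected columns mirror a ChEMBL export: `drug`, `target`,
#' `standard_value` (nM), `standard_relation`, `assay_type`,
#' `confidence_score`, `organism`. They are renamed to the internal schema.
#'
#' @param path TSV file.
#' @return A tibble in the [filter_bioactivity()] input schema.
#' @export
read_bioactivity_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ren <- c(affinity_nM = "standard_value", relation = "standard_relation",
           confidence = "confidence_score")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(tab)) names(tab)[names(tab) == ren[[new]]] <- new
  }
  tab
}
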