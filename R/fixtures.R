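#' Specification of a synthetic fixture bundle
#'
#' Describes a small self-contained world — network, cell lines, drugs —
#' with known ground truth, standing in for a curated signaling network and
#' public omics/bioactivity archives. Generation is a pure function of the
#' spec: the same spec always yields byte-identical tables.
#'
#' The generated network has `n_pathways` parallel survival pathways (entry
#' receptor -> transducer kinase) converging on a cell-cycle readout, wired
#' as a logical OR (`survival_logic = "OR"`: any single pathway sustains the
#' cell, so only blocking all of them kills — the substrate for combination
#' synergy) or AND (`survival_logic = "AND"`: every pathway is required, so
#' single-agent blockade kills — the substrate for monotherapy lethality).
#' An apoptosis readout is inhibited by the cell-cycle node, so collapse of
#' proliferative signaling also activates apoptosis. Disconnected decoy
#' nodes are included as negative controls for the biomarker screen.
#'
#' @param seed Master seed (default 1).
#' @param n_pathways Number of parallel survival pathways (default 3).
#' @param survival_logic `"OR"` or `"AND"`.
#' @param n_cell_lines Number of viable cell lines (default 3).
#' @param include_native_dead Also generate a cell line whose planted
#'   mutations knock out every pathway, making it natively dead
#'   (default TRUE).
#' @param fc_sd Standard deviation of log fold-changes in the expression
#'   panel (median fold-change is 1; default 0.15).
#' @param noise_sd Simulation noise the fixture is designed for
#'   (default 0.05).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_pathways = 3L, survival_logic = c("OR", "AND"),
                         n_cell_lines = 3L, include_native_dead = TRUE,
                         fc_sd = 0.15, noise_sd = 0.05) {
  survival_logic <- match.arg(survival_logic)
  assert_that(n_pathways >= 1, "need at least one pathway")
  assert_that(n_cell_lines >= 1, "need at least one cell line")
  structure(list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
                 survival_logic = survival_logic,
                 n_cell_lines = as.integer(n_cell_lines),
                 include_native_dead = include_native_dead,
                 fc_sd = fc_sd, noise_sd = noise_sd),
            class = "fixture_spec")
}

#' Generate the fixture signaling network
#'
#' See [fixture_spec()] for the topology. Edge weights and biases are chosen
#' so that with all pathways intact the cell-cycle readout settles around
#' 0.9 (alive) and with the pathways blocked it collapses below 0.1 with
#' apoptosis activated (dead); the margins are wide enough that the default
#' initialization noise never flips the verdict.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `network` (a `signaling_network`) and `metadata`
#'   (node/edge counts, pathway membership, decoy ids).
#' @export
make_toy_network <- function(spec = fixture_spec()) {
  np <- spec$n_pathways
  rtk <- paste0("RTK", seq_len(np))
  kin <- paste0("K", seq_len(np))

  # OR gate: basal logit(0.05); AND gate: basal logit(0.002)
  cc_base <- if (spec$survival_logic == "OR") 0.05 else 0.002

  nodes <- dplyr::bind_rows(
    tibble(id = rtk, base_activity = 0.9, role = "oncogene",
           module = paste0("P", seq_len(np)), readout = "none"),
    tibble(id = kin, base_activity = 0.05, role = "neutral",
           module = paste0("P", seq_len(np)), readout = "none"),
    tibble(id = "CELLCYCLE", base_activity = cc_base, role = "neutral",
           module = "effector", readout = "cell_cycle"),
    tibble(id = "APOPT", base_activity = 0.7, role = "neutral",
           module = "effector", readout = "apoptosis"),
    tibble(id = c("DECOY1", "DECOY2"), base_activity = 0.5, role = "neutral",
           module = "decoy", readout = "none")
  )
  edges <- dplyr::bind_rows(
    tibble(source = rtk, target = kin, sign = 1, weight = 12),
    tibble(source = kin, target = "CELLCYCLE", sign = 1, weight = 10),
    tibble(source = "CELLCYCLE", target = "APOPT", sign = -1, weight = 10)
  )
  network <- signaling_network(nodes, edges)
  list(network = network,
       metadata = list(n_nodes = nrow(nodes), n_edges = nrow(edges),
                       pathways = stats::setNames(as.list(kin), rtk),
                       decoys = c("DECOY1", "DECOY2"),
                       survival_logic = spec$survival_logic))
}

#' Generate the expression and mutation panel
#'
#' Expression fold-changes are log-normal with median 1 (sd `fc_sd` on the
#' log scale). Planted mutations give the panel its ground truth: under OR
#' logic the first cell line carries a pathogenic stop-gain in the last
#' pathway's receptor (loss of function), which removes the redundant rescue
#' route and makes the first-two-pathway drug pair synergistic in that line
#' only. A benign missense is planted as a no-effect control, and the
#' optional native-dead line carries stop-gains in every receptor.
#'
#' @param spec A [fixture_spec()].
#' @param toy Output of [make_toy_network()] (regenerated if missing).
#' @return List with tibbles `expression` (`cell_line`, `gene_id`,
#'   `fold_change`) and `mutations` (`cell_line`, `gene_id`, `consequence`,
#'   `pathogenic`).
#' @export
make_avatar_panel <- function(spec = fixture_spec(), toy = make_toy_network(spec)) {
  ids <- toy$network$nodes$id
  cls <- paste0("CL", seq_len(spec$n_cell_lines))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  expression <- purrr::map_dfr(cls, function(cl) {
    tibble(cell_line = cl, gene_id = ids,
           fold_change = exp(stats::rnorm(length(ids), 0, spec$fc_sd)))
  })

  np <- spec$n_pathways
  muts <- list()
  if (spec$survival_logic == "OR" && np >= 3 && spec$n_cell_lines >= 1) {
    # CL1 loses the redundant rescue pathway -> dual-pathway synergy planted
    muts[[1]] <- tibble(cell_line = "CL1", gene_id = paste0("RTK", np),
                        consequence = "stop_gain", pathogenic = TRUE)
  }
  if (spec$n_cell_lines >= 3) {
    muts[[length(muts) + 1]] <- tibble(cell_line = "CL3", gene_id = "RTK1",
                                       consequence = "missense",
                                       pathogenic = FALSE)
  }
  if (spec$include_native_dead) {
    expression <- dplyr::bind_rows(expression,
      tibble(cell_line = "CL_DEAD", gene_id = ids, fold_change = 1))
    muts[[length(muts) + 1]] <- tibble(cell_line = "CL_DEAD",
                                       gene_id = paste0("RTK", seq_len(np)),
                                       consequence = "frameshift",
                                       pathogenic = TRUE)
  }
  mutations <- if (length(muts)) dplyr::bind_rows(muts) else {
    tibble(cell_line = character(), gene_id = character(),
           consequence = character(), pathogenic = logical())
  }
  list(expression = expression, mutations = mutations)
}

#' Generate the drug bioactivity panel
#'
#' Drugs DRUG_A / DRUG_B / DRUG_D target the receptors of pathways 1, 2 and
#' (when present) 3 at 100 nM; DRUG_C targets pathway 1's kinase (a
#' same-pathway partner for DRUG_A); DRUG_M is a multi-target drug with tied
#' 10 nM affinities for the MoA tie-break. The panel also plants one record
#' per bioactivity filter so that filtering removes exactly the planted
#' violations: confidence 5, relation '>', affinity 12000 nM, non-human
#' organism, functional assay, plus a 200 nM duplicate of DRUG_A-RTK1 that
#' must collapse onto the 100 nM record.
#'
#' @param spec A [fixture_spec()].
#' @return List with `bioactivity` (raw records tibble), `pathway_map`
#'   (`target`, `pathway`), `ddr_drugs`, `nonddr_drugs`, and
#'   `planted_bad` (row count of records that filtering must remove).
#' @export
make_drug_panel <- function(spec = fixture_spec()) {
  np <- spec$n_pathways
  ok <- function(drug, target, aff) {
    tibble(drug = drug, target = target, affinity_nM = aff, relation = "=",
           assay_type = "binding", confidence = 8L, organism = "Homo sapiens")
  }
  good <- dplyr::bind_rows(
    ok("DRUG_A", "RTK1", 100),
    ok("DRUG_A", "RTK1", 200),           # duplicate, collapses to 100
    if (np >= 2) ok("DRUG_B", "RTK2", 100),
    ok("DRUG_C", "K1", 100),
    if (np >= 3) ok("DRUG_D", paste0("RTK", np), 100),
    if (np >= 2) ok("DRUG_M", "RTK1", 10),
    if (np >= 2) ok("DRUG_M", "RTK2", 10)
  )
  bad <- dplyr::bind_rows(
    ok("DRUG_A", "RTK1", 50) |> dplyr::mutate(confidence = 5L),
    ok("DRUG_B", "RTK2", 50) |> dplyr::mutate(relation = ">"),
    ok("DRUG_C", "K1", 12000),
    ok("DRUG_A", "RTK1", 50) |> dplyr::mutate(organism = "Mus musculus"),
    ok("DRUG_B", "RTK2", 50) |> dplyr::mutate(assay_type = "functional")
  )
  moa <- c("DDR", "TK/RTK", "PIK3/AKT/MTOR", "ERK", "NFKB", "JAK/STAT",
           "EM/TM", "CSNK")
  pathway_map <- dplyr::bind_rows(purrr::map_dfr(seq_len(np), function(k) {
    tibble(target = c(paste0("RTK", k), paste0("K", k)),
           pathway = moa[(k - 1) %% length(moa) + 1])
  }))
  list(bioactivity = dplyr::bind_rows(good, bad),
       pathway_map = pathway_map,
       ddr_drugs = c("DRUG_A", "DRUG_C"),
       nonddr_drugs = intersect(c("DRUG_B", "DRUG_D", "DRUG_M"),
                                unique(good$drug)),
       planted_bad = nrow(bad))
}

#' Generate a complete fixture bundle in memory
#'
#' Network, avatar panel, drug panel, perturbation list and ground-truth
#' annotations, all derived deterministically from the spec. The ground
#' truth names which (cell line, drug pair) combinations are synergistic by
#' construction and which planted perturbations are combination-specific
#' biomarkers with which sign; the decoy nodes must never be flagged.
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_bundle` list: `spec`, `network`, `expression`,
#'   `mutations`, `bioactivity`, `pathway_map`, `perturbations`,
#'   `ground_truth`.
#' @export
make_fixture_bundle <- function(spec = fixture_spec()) {
  toy <- make_toy_network(spec)
  panel <- make_avatar_panel(spec, toy)
  drugs <- make_drug_panel(spec)
  np <- spec$n_pathways

  perturbations <- list(
    perturbation("DECOY1", "lof"),
    perturbation("DECOY2", "overexpress")
  )
  biomarkers <- tibble(cell_line = character(), node = character(),
                       kind = character(), expected_sign = numeric(),
                       scope = character())
  syn <- tibble(cell_line = character(), drugA = character(),
                drugB = character(), synergistic = logical())

  if (spec$survival_logic == "OR" && np >= 3) {
    perturbations <- c(perturbations, list(
      perturbation(paste0("RTK", np), "lof"),
      perturbation(paste0("K", np), "gof")
    ))
    biomarkers <- dplyr::bind_rows(
      tibble(cell_line = "CL2", node = paste0("RTK", np), kind = "lof",
             expected_sign = 1, scope = "combination_specific"),
      tibble(cell_line = "CL1", node = paste0("K", np), kind = "gof",
             expected_sign = -1, scope = "combination_specific")
    )
    syn <- dplyr::bind_rows(
      tibble(cell_line = "CL1", drugA = "DRUG_A", drugB = "DRUG_B",
             synergistic = TRUE),
      tibble(cell_line = "CL2", drugA = "DRUG_A", drugB = "DRUG_B",
             synergistic = FALSE),
      tibble(cell_line = "CL1", drugA = "DRUG_A", drugB = "DRUG_C",
             synergistic = FALSE)
    )
  }
  if (spec$survival_logic == "OR" && np == 2) {
    syn <- tibble(cell_line = "CL1", drugA = "DRUG_A", drugB = "DRUG_B",
                  synergistic = TRUE)
  }

  structure(list(
    spec = spec, network = toy$network, network_metadata = toy$metadata,
    expression = panel$expression, mutations = panel$mutations,
    bioactivity = drugs$bioactivity, pathway_map = drugs$pathway_map,
    ddr_drugs = drugs$ddr_drugs, nonddr_drugs = drugs$nonddr_drugs,
    planted_bad = drugs$planted_bad,
    perturbations = perturbations,
    ground_truth = list(synergy = syn, biomarkers = biomarkers,
                        native_dead = if (spec$include_native_dead) "CL_DEAD" else character(0))
  ), class = "fixture_bundle")
}

#' Build the avatar for one fixture cell line
#'
#' @param bundle A `fixture_bundle`.
#' @param cell_line Cell-line id present in the bundle's expression table.
#' @return A `cell_avatar`.
#' @export
fixture_avatar <- function(bundle, cell_line) {
  expr <- bundle$expression |>
    dplyr::filter(.data$cell_line == !!cell_line) |>
    dplyr::select("gene_id", "fold_change")
  assert_that(nrow(expr) > 0, sprintf("unknown fixture cell line '%s'", cell_line))
  muts <- bundle$mutations |>
    dplyr::filter(.data$cell_line == !!cell_line) |>
    dplyr::select("gene_id", "consequence", "pathogenic")
  build_avatar(bundle$network, expr, muts, cell_line = cell_line)
}

#' Write a fixture bundle to a directory
#'
#' Writes `network.json` (graph-json), `expression.tsv`, `mutations.tsv`,
#' `bioactivity.tsv`, `pathways.tsv`, `perturbations.tsv` and
#' `ground_truth.json`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bundle$network, file.path(dir, "network.json"))
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(bundle$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(bundle$bioactivity, file.path(dir, "bioactivity.tsv"))
  readr::write_tsv(bundle$pathway_map, file.path(dir, "pathways.tsv"))
  readr::write_tsv(
    tibble(node = vapply(bundle$perturbations, `[[`, "", "node"),
           kind = vapply(bundle$perturbations, `[[`, "", "code")),
    file.path(dir, "perturbations.tsv")
  )
  jsonlite::write_json(
    list(spec = unclass(bundle$spec),
         ddr_drugs = bundle$ddr_drugs, nonddr_drugs = bundle$nonddr_drugs,
         planted_bad = bundle$planted_bad,
         network_metadata = bundle$network_metadata,
         ground_truth = bundle$ground_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
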