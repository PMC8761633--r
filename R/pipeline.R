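#' Run the full feature-to-statistics analysis on in-memory tables
#'
#' Folds every annotated hairpin once, derives the domain free-energy
#' features and motif profiles, converts lanes to control-normalized
#' cleavage efficiencies, and produces the correlation report, the
#' motif-count strata, and (when families are annotated) the
#' conserved-vs-unique comparison. Deterministic given its inputs.
#'
#' @param records Hairpin record tibble (see [read_hairpins()]).
#' @param lanes Lane intensity tibble (see [cleavage_efficiencies()]), or
#'   `NULL`.
#' @param expression Expression tibble with `id`/`mirna_id` and `total`
#'   (see [read_expression_table()]), or `NULL`.
#' @param model An [energy_model()].
#' @param mghg_table Optional mGHG score table.
#' @param windows Motif windows ([motif_windows()]).
#' @param aggregate Replicate aggregation rule for lanes.
#' @return List with `features`, `motifs`, `efficiencies`, `report`,
#'   `strata` (list per response), and `conserved` (or `NULL`).
#' @export
analyze_cohort <- function(records, lanes = NULL, expression = NULL,
                           model = energy_model(), mghg_table = NULL,
                           windows = motif_windows(),
                           aggregate = "mean") {
  ann <- records[!is.na(records$mir5p_start) | !is.na(records$mir3p_start), ]
  folds <- setNames(
    purrr::map(ann$sequence, fold_mfe, model = model),
    ann$id
  )
  features <- hairpin_features(ann, model, folds = folds)
  motifs <- motif_profiles(ann, model, mghg_table = mghg_table,
                           windows = windows, folds = folds)
  feature_tab <- dplyr::left_join(
    features, motifs[c("id", "motif_count", "mghg_score")], by = "id")

  efficiencies <- if (!is.null(lanes)) {
    cleavage_efficiencies(lanes, aggregate = aggregate)
  }
  report <- correlation_report(feature_tab, efficiencies, expression)

  strata <- list()
  if (!is.null(efficiencies)) {
    for (enz in unique(efficiencies$enzyme)) {
      d <- efficiencies[efficiencies$enzyme == enz & !efficiencies$is_control, ]
      strata[[paste0(tolower(enz), "_efficiency")]] <- stratify_by_motif_count(
        motifs, dplyr::rename(d, id = "substrate_id"),
        value = "relative_efficiency")
    }
  }
  if (!is.null(expression)) {
    idc <- if ("id" %in% names(expression)) "id" else "mirna_id"
    strata[["expression"]] <- stratify_by_motif_count(
      motifs,
      tibble::tibble(id = expression[[idc]], total = expression$total),
      value = "total")
  }

  conserved <- NULL
  if (!is.null(efficiencies) && any(!is.na(records$family))) {
    d <- efficiencies[tolower(efficiencies$enzyme) == "drosha" &
                        !efficiencies$is_control, ]
    if (nrow(d) >= 4) {
      conserved <- conserved_vs_unique(
        records, tibble::tibble(id = d$substrate_id,
                                value = d$relative_efficiency))
    }
  }

  list(features = feature_tab, motifs = motifs,
       efficiencies = efficiencies, report = report, strata = strata,
       conserved = conserved)
}

#' Run the pipeline from files and write a report bundle
#'
#' File-level orchestration over [analyze_cohort()]: reads the hairpin
#' FASTA + annotation, optional lane and expression TSVs and mGHG table,
#' runs every stage, and writes `features.tsv`, `motifs.tsv`,
#' `efficiencies.tsv`, `correlation_report.tsv`, `strata_*.tsv`,
#' `conserved_vs_unique.tsv` plus the fully-resolved configuration
#' (`run_config.yaml`) into `out_dir`. Rerunning the same configuration
#' reproduces the bundle byte for byte.
#'
#' @param fasta,annotation Hairpin cohort paths (see [read_hairpins()]).
#' @param lanes_tsv,expression_tsv,mghg_table_tsv Optional input paths.
#' @param out_dir Output directory, created if needed.
#' @param model An [energy_model()].
#' @param windows Motif windows.
#' @param combine Tissue combination rule for expression (`"sum"`/`"mean"`).
#' @param aggregate Replicate aggregation rule for lanes.
#' @param human_number_filter Apply the human name-number < 1000 filter.
#' @return Invisibly, the [analyze_cohort()] result list.
#' @export
run_full <- function(fasta, annotation, lanes_tsv = NULL,
                     expression_tsv = NULL, mghg_table_tsv = NULL,
                     out_dir = ".", model = energy_model(),
                     windows = motif_windows(), combine = "sum",
                     aggregate = "mean", human_number_filter = TRUE) {
  for (p in c(fasta, annotation, lanes_tsv, expression_tsv, mghg_table_tsv)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  records <- read_hairpins(fasta, annotation)
  if (human_number_filter) records <- filter_human_mirna_number(records)
  lanes <- if (!is.null(lanes_tsv)) {
    readr::read_tsv(lanes_tsv, col_types = readr::cols(), progress = FALSE)
  }
  expression <- if (!is.null(expression_tsv)) {
    read_expression_table(expression_tsv, combine = combine)
  }
  mghg_table <- if (!is.null(mghg_table_tsv)) read_mghg_table(mghg_table_tsv)

  res <- analyze_cohort(records, lanes, expression, model = model,
                        mghg_table = mghg_table, windows = windows,
                        aggregate = aggregate)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(out_dir, name))
  }
  w(res$features, "features.tsv")
  w(res$motifs, "motifs.tsv")
  w(res$efficiencies, "efficiencies.tsv")
  w(res$report, "correlation_report.tsv")
  for (nm in names(res$strata)) {
    w(res$strata[[nm]], paste0("strata_", nm, ".tsv"))
  }
  w(res$conserved, "conserved_vs_unique.tsv")
  cfg <- list(fasta = fasta, annotation = annotation,
              lanes_tsv = lanes_tsv, expression_tsv = expression_tsv,
              mghg_table_tsv = mghg_table_tsv, combine = combine,
              aggregate = aggregate, human_number_filter = human_number_filter,
              windows = windows,
              package_version = as.character(utils::packageVersion("mirhairpin")))
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
  invisible(res)
}

#' Write a cohort to disk in the pipeline's input dialects
#'
#' Emits the FASTA + annotation TSV, lane TSV, expression TSV and the
#' ground-truth TSV of a simulated cohort, so a simulated dataset can be
#' pushed through [run_full()] exactly like real data.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "hairpins.fa"),
    annotation = file.path(dir, "arms.tsv"),
    lanes = file.path(dir, "lanes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_hairpins(cohort$records, paths$fasta, paths$annotation)
  readr::write_tsv(cohort$lanes, paths$lanes)
  readr::write_tsv(cohort$expression, paths$expression)
  readr::write_tsv(cohort$truth, paths$truth)
  invisible(paths)
}
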