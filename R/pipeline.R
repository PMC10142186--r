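# End-to-end orchestration: read -> clean -> aggregate/filter -> diversity ->
# MCC/prune -> summarize -> multi-restart regression -> report.

#' Configure a pipeline run
#'
#' @param venom Path to the venom composition CSV/TSV.
#' @param diet Path to the diet record CSV/TSV.
#' @param trees Path to a Newick/Nexus file (one tree or a posterior sample;
#'   with more than one tree the MCC tree is selected first).
#' @param max_total_percent,min_total_percent Venom cleaning thresholds.
#' @param min_diet_items Minimum pooled prey records per species.
#' @param indices Diversity indices to analyse ("shannon", "simpson").
#' @param levels Diet taxonomic levels to analyse ("family", "order").
#' @param n_runs Restarts of each regression (the 100-restart protocol).
#' @param n_starts Randomized starts within each run.
#' @param seed Pipeline seed; all child streams derive from it.
#' @param outdir Output directory, or NULL to keep results in memory only.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(venom, diet, trees,
                            max_total_percent = 110, min_total_percent = 90,
                            min_diet_items = 5,
                            indices = c("shannon", "simpson"),
                            levels = c("family", "order"),
                            n_runs = 100, n_starts = 1,
                            seed = 1, outdir = NULL) {
  indices <- match.arg(indices, c("shannon", "simpson"), several.ok = TRUE)
  levels <- match.arg(levels, c("family", "order"), several.ok = TRUE)
  stopifnot(max_total_percent > 0, min_total_percent >= 0,
            min_diet_items >= 0, n_runs >= 1)
  structure(
    list(venom = venom, diet = diet, trees = trees,
         max_total_percent = max_total_percent,
         min_total_percent = min_total_percent,
         min_diet_items = min_diet_items,
         indices = indices, levels = levels,
         n_runs = n_runs, n_starts = n_starts,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and (optionally) writes all
#' artifacts: `diversity.tsv` (per-record indices), `cleaning.json`
#' (consolidated removal log), `mcc.nwk` (selected tree), and `report.tsv`
#' (one row per index/level analysis). When both proteome and transcriptome
#' records survive cleaning, Welch t-tests comparing the two methods on venom
#' diversity (and on family richness) are included.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `summaries` (per analysis),
#'   `report` (data.frame), `diversity` (per-record table), `cleaning`
#'   (consolidated report list), `mcc` (tree and score or NULL),
#'   `welch` (method-comparison tests or NULL).
#' @export
run_pipeline <- function(config) {
  profiles <- read_venom_profiles(config$venom)
  cleaned <- clean_venom_profiles(profiles,
                                  max_total_percent = config$max_total_percent,
                                  min_total_percent = config$min_total_percent)
  diet_rows <- read_diet_records(config$diet)
  diet_clean <- list()
  tables <- list(family = list(), order = list())
  for (lev in c("family", "order")) {
    agg <- aggregate_diet(diet_rows, level = lev)
    filt <- filter_diet(agg, min_items = config$min_diet_items)
    tables[[lev]] <- filt$tables
    diet_clean[[lev]] <- filt$report
  }

  trees <- read_trees(config$trees)
  mcc <- if (length(trees) > 1L) mcc_tree(trees)
         else list(tree = trees[[1]], score = 0, index = 1L)

  div <- diversity_table(cleaned$profiles, tables$family, tables$order)

  summaries <- list()
  for (lev in config$levels) {
    for (idx in config$indices) {
      dcol <- paste0("diet_", idx, "_", lev)
      vcol <- paste0("venom_", idx)
      rows <- div[!is.na(div[[dcol]]), c("species", dcol, vcol)]
      names(rows) <- c("species", "x", "y")
      common <- intersect(unique(rows$species), mcc$tree$tip.label)
      if (length(common) < 3)
        stop("fewer than 3 species shared between data and tree at level ",
             lev, ": ", paste(common, collapse = ", "))
      rows <- rows[rows$species %in% common, , drop = FALSE]
      tr <- prune_to_taxa(mcc$tree, common)
      C <- bm_covariance(tr)
      summ <- summarize_replicates(rows)
      summaries[[paste(idx, lev, sep = "_")]] <-
        multistart_analysis(summ, C, index = idx, diet_level = lev,
                            n_runs = config$n_runs, seed = config$seed,
                            n_starts = config$n_starts)
    }
  }

  report <- build_report(summaries)

  welch <- NULL
  meth <- div$method
  if (length(unique(meth)) == 2L && all(table(meth) >= 2)) {
    welch <- list(
      shannon = welch_t_test(div$venom_shannon[meth == "proteome"],
                             div$venom_shannon[meth == "transcriptome"]),
      simpson = welch_t_test(div$venom_simpson[meth == "proteome"],
                             div$venom_simpson[meth == "transcriptome"]))
  }

  cleaning <- list(
    venom = list(n_input = cleaned$report$n_input,
                 n_removed = cleaned$report$n_removed_abundance,
                 removed = cleaned$report$removed_ids),
    diet = lapply(diet_clean, function(r)
      list(n_input = r$n_input, n_removed = r$n_removed_diet,
           removed = r$removed_ids)),
    venom_species_without_diet = attr(div, "dropped_species"))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(div, file.path(config$outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cleaning, file.path(config$outdir, "cleaning.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ape::write.tree(mcc$tree, file.path(config$outdir, "mcc.nwk"))
    build_report(summaries, file.path(config$outdir, "report.tsv"))
  }

  structure(list(summaries = summaries, report = report, diversity = div,
                 cleaning = cleaning, mcc = mcc, welch = welch,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  nrec <- nrow(x$diversity)
  nsp <- length(unique(x$diversity$species))
  cat(sprintf("<pipeline_result> %d records across %d species\n", nrec, nsp))
  print(x$report)
  invisible(x)
}
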