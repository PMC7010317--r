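#' Write a deterministic report bundle
#'
#' Writes the per-cell feature table, group frequency table, and p-value
#' matrices as CSV files plus a JSON run manifest (seed, configuration
#' echo, realized cutoffs, package version) under deterministic file
#' names. Rerunning with the same inputs yields byte-identical CSVs.
#'
#' @param features per-cell records (after filters; the `excluded`
#'   attribute, when present, is written alongside).
#' @param blebbing a [blebbing_table()] or NULL.
#' @param fisher output of [fisher_pairwise_fdr()] or NULL.
#' @param fa_tests output of [fa_group_test()] or NULL.
#' @param dir output directory (created if needed).
#' @param manifest named list merged into the manifest (e.g. seed,
#'   realized `fa_upper_cutoff`).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(features, blebbing = NULL, fisher = NULL,
                         fa_tests = NULL, dir = "blebmorph-report",
                         manifest = list()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  }
  files <- character(0)
  wcsv <- function(x, name) {
    path <- file.path(dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wcsv(features, "cell_features.csv")
  excl <- attr(features, "excluded")
  if (!is.null(excl) && nrow(excl)) wcsv(excl, "cell_features_excluded.csv")
  if (!is.null(blebbing)) wcsv(blebbing, "blebbing_frequencies.csv")
  if (!is.null(fisher)) {
    wcsv(fisher$results, "fisher_pairwise.csv")
    wcsv(as.data.frame(fisher$p_adjusted_matrix), "fisher_p_adjusted_matrix.csv")
  }
  if (!is.null(fa_tests)) {
    if (!is.null(fa_tests$anova)) wcsv(fa_tests$anova, "fa_anova.csv")
    wcsv(fa_tests$tukey, "fa_tukey.csv")
    wcsv(fa_tests$rank, "fa_rank_mw.csv")
  }
  man <- c(list(package = "blebmorph",
                version = as.character(utils::packageVersion("blebmorph")),
                n_cells = nrow(features)),
           manifest)
  if (!is.null(attr(features, "fa_upper_cutoff")))
    man$fa_upper_cutoff <- attr(features, "fa_upper_cutoff")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, path)
  invisible(files)
}
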