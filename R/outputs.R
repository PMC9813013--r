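# Tabular outputs: every figure and table of a run exported as delimited
# text, plus a run-metadata file for reproducibility.

#' Write analysis outputs to a directory
#'
#' Writes comma-delimited tables with headers: the per-scenario cohort traces,
#' the base-case summary (life-years, QALYs, total cost, incremental results
#' and ICERs per perspective, in million VND and USD), and, when supplied,
#' the tornado table, the PSA iteration list, the cost-effectiveness plane
#' points and the acceptability curve. A `run_metadata.yaml` records the
#' seed, package version and a hash of the serialised configuration, so a
#' rerun with the same configuration and seed is byte-identical in all
#' numeric tables.
#'
#' @param cea a `cea_result` from [run_cea()].
#' @param out_dir output directory (created if absent).
#' @param dsa optional `tornado_table` from [run_dsa()].
#' @param psa optional `psa_result` from [run_psa()].
#' @param ceac_table optional data frame from [ceac()].
#' @param seed seed recorded in the metadata.
#' @return Invisible character vector of the files written.
#' @export
write_outputs <- function(cea, out_dir, dsa = NULL, psa = NULL,
                          ceac_table = NULL, seed = NULL) {
  stopifnot(inherits(cea, "cea_result"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", out_dir))
  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  summary <- merge(cea$summary, cea$incremental, by = "perspective")
  put(summary, "cea_summary.csv")
  for (sc in names(cea$traces)) {
    occ <- cea$traces[[sc]]$occupancy
    put(data.frame(cycle = as.integer(rownames(occ)), occ,
                   check.names = FALSE),
        sprintf("trace_%s.csv", sc))
  }
  if (!is.null(dsa)) {
    tt <- as.data.frame(dsa)
    tt$base_icer <- attr(dsa, "base_icer")
    put(tt, "tornado.csv")
  }
  if (!is.null(psa)) {
    put(psa$iterations, "psa_iterations.csv")
    put(ce_plane_export(psa), "ce_plane.csv")
    if (is.null(ceac_table)) ceac_table <- ceac(psa)
  }
  if (!is.null(ceac_table)) put(ceac_table, "ceac.csv")
  cfg <- tempfile(fileext = ".yaml")
  save_config(cea$params, cfg)
  meta <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("cbecea")),
    config_hash = unname(tools::md5sum(cfg)))
  unlink(cfg)
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(files, meta_path))
}
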