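#' End-to-end distributed run on a synthetic cohort
#'
#' Generates a synthetic horizontally partitioned cohort, runs the full
#' file-based exchange protocol, and verifies the result against the
#' pooled individual-level reference fit. With `mode = "cooperative"`
#' (the default) the center and every partner run in this process, all
#' exchanges still passing through files; with `mode = "processes"` each
#' partner runs as a separate R process polling the shared directory,
#' exercising real concurrent scheduling.
#'
#' @param family `"linear"`, `"logistic"`, or `"cox"`.
#' @param n_sites Number of data partners.
#' @param seed Master seed for the cohort.
#' @param workdir Protocol directory (temporary by default).
#' @param mode `"cooperative"` or `"processes"`.
#' @param n_per_site Per-site sample sizes (smaller default than the
#'   full test cohort, for quick runs).
#' @param timeout Per-round collection timeout in seconds.
#' @param keep_workdir Keep protocol files after the run.
#' @return List with `fit` (the distributed `"dra_fit"`), `pooled` (the
#'   reference fit), `comparison` ([dra_compare()] report), `timings`
#'   ([summarize_timings()] of the transfer log), and `workdir`.
#' @export
dra_simulate <- function(family = c("linear", "logistic", "cox"),
                         n_sites = 3L, seed = 1L, workdir = NULL,
                         mode = c("cooperative", "processes"),
                         n_per_site = c(180L, 260L, 120L),
                         timeout = 120, keep_workdir = FALSE) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  cohort <- generate_cohort(cohort_config(
    n_sites = n_sites, n_per_site = n_per_site, seed = seed))
  spec <- cohort$specs[[family]]
  if (is.null(workdir)) workdir <- tempfile("dranet_sim_")

  if (mode == "cooperative") {
    fit <- dra_fit(cohort$sites, spec, engine = "files",
                   workdir = workdir, keep_workdir = TRUE)
  } else {
    data_dir <- file.path(workdir, "sitedata")
    write_cohort(cohort, data_dir)
    site_ids <- names(cohort$sites)
    protocol_dirs(workdir, site_ids)
    for (s in site_ids)
      spawn_partner_process(workdir, s,
                            file.path(data_dir, paste0(s, ".csv")), spec)
    fit <- dra_run_center(workdir, site_ids, spec, timeout = timeout)
  }
  if (!keep_workdir) on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  pooled <- dra_pooled_fit(cohort$sites, spec)
  comparison <- dra_compare(fit, pooled)
  timings <- if (!is.null(fit$transfer_log) && nrow(fit$transfer_log))
    summarize_timings(fit$transfer_log)
  list(fit = fit, pooled = pooled, comparison = comparison,
       timings = timings, workdir = workdir)
}

# Launch one data-partner node as a detached Rscript process. Returns the
# child PID. The child inherits this session's library paths so the
# installed package resolves.
spawn_partner_process <- function(workdir, site_id, data_csv, spec) {
  spec_file <- file.path(workdir, paste0("spec_", site_id, ".json"))
  writeLines(as.character(spec_to_json(spec)), spec_file)
  code <- sprintf(
    paste0(".libPaths(strsplit(Sys.getenv('DRANET_LIBS'), ',')[[1]]); ",
           "library(dranet); ",
           "spec <- dranet:::spec_from_json(readLines('%s')); ",
           "dra_run_partner('%s', '%s', '%s', spec, timeout = 60)"),
    spec_file, workdir, site_id, data_csv)
  script <- file.path(workdir, paste0("partner_", site_id, ".R"))
  writeLines(code, script)
  rscript <- file.path(R.home("bin"), "Rscript")
  system2(rscript, shQuote(script),
          stdout = file.path(workdir, paste0("partner_", site_id, ".out")),
          stderr = file.path(workdir, paste0("partner_", site_id, ".err")),
          env = paste0("DRANET_LIBS=", paste(.libPaths(), collapse = ",")),
          wait = FALSE)
  invisible(NULL)
}
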