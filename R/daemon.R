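#' Settings for a daemon run
#'
#' @param config_path Path to the XML configuration file.
#' @param spool_root Spool directory to crawl; must exist.
#' @param local_hostname Host name used for job partitioning (default: this
#'   machine's unqualified name).
#' @param pool_size Maximum concurrent jobs (default: all logical CPUs).
#' @param min_age_seconds Candidate age gate, see [crawl_spool()].
#' @param loop_interval_seconds Sleep between loop iterations (default 30 s,
#'   so an empty spool does not hot-spin).
#' @param mode `"once"`, `"loop"` or `"dry-run"` (plan but execute nothing).
#' @param log_path Central log file (default `conversion.log` under the
#'   spool root).
#' @param retry_errors If `TRUE`, ignore the error ledger for this run so
#'   previously failed inputs get one more attempt.
#' @return A `run_settings` object.
#' @export
run_settings <- function(config_path, spool_root,
                         local_hostname = spoolflow::local_hostname(),
                         pool_size = max(1L, parallel::detectCores()),
                         min_age_seconds = 300, loop_interval_seconds = 30,
                         mode = c("once", "loop", "dry-run"),
                         log_path = file.path(spool_root, "conversion.log"),
                         retry_errors = FALSE) {
  mode <- match.arg(mode)
  stopifnot(loop_interval_seconds >= 0, min_age_seconds >= 0, pool_size >= 1)
  if (!dir.exists(spool_root)) stop("spool root not found: ", spool_root)
  structure(list(config_path = config_path, spool_root = spool_root,
                 local_hostname = local_hostname, pool_size = pool_size,
                 min_age_seconds = min_age_seconds,
                 loop_interval_seconds = loop_interval_seconds, mode = mode,
                 log_path = log_path, retry_errors = retry_errors),
            class = "run_settings")
}

#' Run one parse -> crawl -> plan -> execute iteration
#'
#' @param settings A [run_settings()] object.
#' @param config Optional already-parsed `spool_config`; when `NULL` the
#'   configuration file is (re-)parsed, which is what makes configuration
#'   edits effective on the next iteration without a restart.
#' @return An `iteration_report`: candidate count, the plan, the job
#'   results and success/failure tallies.  In dry-run mode nothing is
#'   executed and the report carries the plan only.
#' @export
run_once <- function(settings, config = NULL) {
  if (is.null(config)) config <- parse_config(settings$config_path)
  ledger <- if (isTRUE(settings$retry_errors)) empty_ledger()
  else load_ledger(settings$log_path)
  cands <- crawl_spool(settings$spool_root, config, settings$min_age_seconds)
  plan <- plan_iteration(cands, config, settings$local_hostname, ledger)
  results <- if (settings$mode == "dry-run") list()
  else execute_plan(plan, settings$pool_size, settings$log_path)
  status <- vapply(results, function(r) r$status, character(1))
  structure(list(n_candidates = length(cands), plan = plan, results = results,
                 n_success = sum(status == "success"),
                 n_failure = sum(status == "failure"), when = Sys.time()),
            class = "iteration_report")
}

#' Run the daemon loop
#'
#' Repeats [run_once()] with a sleep in between, re-parsing the
#' configuration every iteration (hot reload).  A transient configuration
#' parse failure is logged as a warning and the previous good configuration
#' is kept, trading strictness for availability.  An interrupt stops the
#' loop cleanly after the current iteration's jobs have finished; all state
#' lives in the tree and the central log, so a killed daemon loses nothing.
#'
#' @param settings A [run_settings()] object.
#' @param max_iterations Stop after this many iterations (default `Inf`,
#'   i.e. run until interrupted); useful for tests and drills.
#' @param on_iteration Optional callback `function(i, report)` invoked after
#'   each iteration.
#' @return The last `iteration_report`, invisibly.
#' @export
run_loop <- function(settings, max_iterations = Inf, on_iteration = NULL) {
  last_good <- NULL; report <- NULL; i <- 0L
  repeat {
    config <- tryCatch(parse_config(settings$config_path), error = function(e) {
      warning("configuration parse failed, keeping previous configuration: ",
              conditionMessage(e), call. = FALSE)
      last_good
    })
    interrupted <- FALSE
    if (!is.null(config)) {
      last_good <- config
      tryCatch(report <- run_once(settings, config = config),
               interrupt = function(c) interrupted <<- TRUE)
    }
    i <- i + 1L
    if (!is.null(on_iteration)) on_iteration(i, report)
    if (interrupted || i >= max_iterations) return(invisible(report))
    if (settings$loop_interval_seconds > 0) Sys.sleep(settings$loop_interval_seconds)
  }
}

#' Summarize the central log
#'
#' @param log_path Central log file; may be absent.
#' @return A `log_status`: per-converter success/failure counts, the number
#'   of unparsable lines, and the most recent failure records.  Read-only.
#' @export
log_status <- function(log_path) {
  pl <- parse_log(log_path)
  rec <- pl$records
  per <- data.frame(converter_id = character(), successes = integer(),
                    failures = integer(), stringsAsFactors = FALSE)
  recent <- NULL
  if (NROW(rec)) {
    agg <- stats::aggregate(cbind(successes = rec$status == "success",
                                  failures = rec$status == "failure"),
                            by = list(converter_id = rec$converter_id), FUN = sum)
    per <- agg[order(agg$converter_id), , drop = FALSE]
    recent <- utils::tail(rec[rec$status == "failure", , drop = FALSE], 5L)
  }
  structure(list(per_converter = per, unparsable = pl$unparsable,
                 recent_failures = recent), class = "log_status")
}
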