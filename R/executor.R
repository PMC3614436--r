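#' This machine's unqualified, lower-cased hostname
#' @export
local_hostname <- function() tolower(sub("\\..*$", "", Sys.info()[["nodename"]]))

same_host <- function(a, b) identical(tolower(sub("\\..*$", "", a)),
                                      tolower(sub("\\..*$", "", b)))

# shell-style split of an option string: whitespace separates tokens,
# double-quoted groups stay one token.  No other shell interpretation.
tokenize_options <- function(s) {
  toks <- character(); buf <- ""; inq <- FALSE; started <- FALSE
  for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
    if (ch == '"') { inq <- !inq; started <- TRUE }
    else if (!inq && grepl("^[ \t]$", ch)) {
      if (started) { toks <- c(toks, buf); buf <- ""; started <- FALSE }
    } else { buf <- paste0(buf, ch); started <- TRUE }
  }
  if (inq) stop("unbalanced quotes in converter options: ", s)
  if (started) toks <- c(toks, buf)
  toks
}

build_command_tokens <- function(converter, input, output)
  c(converter$converter_cmd, tokenize_options(converter$converter_options),
    input, output)

#' Assemble the command for a job
#'
#' @param job A `conversion_job` from [plan_iteration()].
#' @return Character vector of command tokens: executable, tokenized
#'   options, input path, output path.  Tokens are passed to the process
#'   without further shell interpretation.
#' @export
build_command <- function(job)
  build_command_tokens(job$converter, job$input_path, job$output_path)

#' Execute a plan on a bounded worker pool
#'
#' Runs at most `pool_size` jobs concurrently and returns only after every
#' job has finished (the iteration barrier: the next crawl starts from a
#' settled tree).  Each job writes to a temporary name
#' (`<output>.inprogress`) that is renamed to the real output only on
#' success and deleted otherwise, so the output-exists idempotency check can
#' never see a partial file.  One log record per job is appended to the
#' central log after the barrier; the final tree state is independent of
#' `pool_size`.
#'
#' @param plan An `iteration_plan`.
#' @param pool_size Maximum concurrent jobs (default: all logical CPUs).
#' @param log_path Central log file, appended to (tab-separated, one record
#'   per line: timestamp, host, converter id, input, output, status, return
#'   code, duration in seconds).
#' @return List of `job_result` objects (fields `job`, `status`,
#'   `return_code`, `started_at`, `finished_at`, `host`).
#' @export
execute_plan <- function(plan, pool_size = max(1L, parallel::detectCores()), log_path) {
  stopifnot(pool_size >= 1)
  con <- tryCatch(suppressWarnings(file(log_path, "a")),
                  error = function(e) stop("central log not writable: ", log_path))
  close(con)
  run_job <- function(job) {
    tmp <- paste0(job$output_path, ".inprogress")
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    dir.create(dirname(job$output_path), recursive = TRUE, showWarnings = FALSE)
    tokens <- build_command_tokens(job$converter, job$input_path, tmp)
    t0 <- Sys.time()
    rc <- tryCatch(suppressWarnings(
      system2(tokens[1], shQuote(tokens[-1]), stdout = FALSE, stderr = FALSE)),
      error = function(e) 127L)
    ok <- identical(as.integer(rc), 0L) && file.exists(tmp) && file.rename(tmp, job$output_path)
    structure(list(job = job, status = if (ok) "success" else "failure",
                   return_code = as.integer(rc), started_at = t0,
                   finished_at = Sys.time(), host = local_hostname()),
              class = "job_result")
  }
  results <- if (pool_size > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(plan$jobs, run_job, mc.cores = pool_size)
  else lapply(plan$jobs, run_job)
  for (res in results) append_log_record(log_path, res)
  results
}

log_fields <- c("timestamp", "host", "converter_id", "input_path",
                "output_path", "status", "return_code", "duration_seconds")

append_log_record <- function(log_path, res) {
  esc <- function(x) gsub("[\t\r\n]+", " ", as.character(x))
  dur <- sprintf("%.3f", as.numeric(difftime(res$finished_at, res$started_at, units = "secs")))
  line <- paste(esc(c(format(res$finished_at, "%Y-%m-%dT%H:%M:%S"), res$host,
                      res$job$converter$converter_id, res$job$input_path,
                      res$job$output_path, res$status, res$return_code, dur)),
                collapse = "\t")
  cat(line, file = log_path, sep = "\n", append = TRUE)
}

parse_log <- function(log_path) {
  if (is.null(log_path) || !file.exists(log_path))
    return(list(records = NULL, unparsable = 0L))
  parts <- strsplit(readLines(log_path, warn = FALSE), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) > 0]
  ok <- lengths(parts) == length(log_fields) &
    vapply(parts, function(p) length(p) >= 6 && p[6] %in% c("success", "failure"), logical(1))
  if (any(!ok)) warning(sum(!ok), " malformed log line(s) skipped", call. = FALSE)
  rec <- if (any(ok)) as.data.frame(do.call(rbind, parts[ok]), stringsAsFactors = FALSE) else NULL
  if (!is.null(rec)) names(rec) <- log_fields
  list(records = rec, unparsable = sum(!ok))
}

ledger_key <- function(input_path, converter_id)
  paste(input_path, converter_id, sep = "\t")

#' An empty error ledger
#' @export
empty_ledger <- function() structure(list(entries = character()), class = "error_ledger")

#' Reconstruct the error ledger from the central log
#'
#' The ledger is the set of (input, converter) pairs whose latest record is
#' a failure; such pairs are excluded from later iterations so a corrupt
#' input cannot cause an endless loop of processing attempts.  A later
#' success for the same pair clears earlier failures.  The log is the single
#' source of truth: there is no separate state file, and an operator clears
#' an error by editing the log or running one iteration with
#' `retry_errors = TRUE`.
#'
#' @param log_path Central log file; an absent file yields an empty ledger.
#' @return An `error_ledger`.
#' @export
load_ledger <- function(log_path) {
  rec <- parse_log(log_path)$records
  entries <- character()
  for (i in seq_len(NROW(rec))) {
    key <- ledger_key(rec$input_path[i], rec$converter_id[i])
    entries <- if (rec$status[i] == "failure") union(entries, key)
    else setdiff(entries, key)
  }
  structure(list(entries = entries), class = "error_ledger")
}
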