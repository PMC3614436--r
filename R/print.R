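#' @export
print.spool_config <- function(x, ...) {
  cat(sprintf("<spool_config> %d converter(s), %d rule(s)\n",
              length(x$converters), length(x$rules)))
  for (cv in x$converters)
    cat(sprintf("  converter %-6s %s -> %s/%s  [%s] %s\n", cv$converter_id,
                cv$from_file_ext, cv$converter_dir, cv$to_file_ext,
                cv$hostname, cv$converter_cmd))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    on <- Filter(Negate(is.null),
                 list(project = r$project, area = r$area, instrument = r$instrument,
                      user = r$user,
                      from = if (!is.null(r$date_begin)) format(r$date_begin),
                      to = if (!is.null(r$date_end)) format(r$date_end),
                      pattern = r$pattern))
    cat(sprintf("  rule %d -> converter %s  %s\n", i, r$converter_id,
                if (length(on)) paste(names(on), unlist(on), sep = "=", collapse = " ")
                else "(match all)"))
  }
  invisible(x)
}

#' @export
print.iteration_plan <- function(x, ...) {
  cat(sprintf(
    "<iteration_plan> %d job(s); skipped: %d existing, %d errored, %d foreign-host\n",
    length(x$jobs), x$skipped_existing, x$skipped_errored, x$skipped_foreign_host))
  for (j in x$jobs)
    cat(sprintf("  [rule %d, converter %s] %s -> %s\n", j$rule_index,
                j$converter$converter_id, j$input_path, j$output_path))
  invisible(x)
}

#' @export
print.iteration_report <- function(x, ...) {
  cat(sprintf("<iteration_report> %s: %d candidate(s), %d job(s) planned, %d ok, %d failed\n",
              format(x$when, "%Y-%m-%d %H:%M:%S"), x$n_candidates,
              length(x$plan$jobs), x$n_success, x$n_failure))
  cat(sprintf("  skipped: %d existing, %d errored, %d foreign-host\n",
              x$plan$skipped_existing, x$plan$skipped_errored,
              x$plan$skipped_foreign_host))
  invisible(x)
}

#' @export
print.log_status <- function(x, ...) {
  cat("<log_status>\n")
  if (nrow(x$per_converter)) print(x$per_converter, row.names = FALSE)
  else cat("  (no records)\n")
  if (x$unparsable) cat(sprintf("  unparsable lines: %d\n", x$unparsable))
  if (NROW(x$recent_failures))
    cat(sprintf("  recent failure: converter %s on %s\n",
                x$recent_failures$converter_id, x$recent_failures$input_path),
        sep = "")
  invisible(x)
}

#' @export
print.error_ledger <- function(x, ...) {
  cat(sprintf("<error_ledger> %d excluded (input, converter) pair(s)\n",
              length(x$entries)))
  invisible(x)
}
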