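#' Test one candidate against one pass rule
#'
#' A candidate passes when its name carries the converter's input extension
#' and every present rule field matches: exact equality for project, area,
#' instrument and user; inclusive bounds for the acquisition date; and an
#' unanchored regular-expression search over the relative path for
#' `pattern`.  All present filters are conjunctive; a rule with no optional
#' fields passes every candidate with the right extension.
#'
#' @param candidate A `candidate_file` from [crawl_spool()].
#' @param rule A [filter_rule()].
#' @param converter The [converter_spec()] the rule references.
#' @return `TRUE` or `FALSE`.
#' @export
candidate_matches_rule <- function(candidate, rule, converter) {
  stopifnot(identical(rule$converter_id, converter$converter_id))
  if (!endsWith(basename(candidate$relative_path), converter$from_file_ext))
    return(FALSE)
  md <- candidate$metadata
  eq <- function(want, have) is.null(want) || (!is.null(have) && identical(have, want))
  if (!eq(rule$project, md$project) || !eq(rule$area, md$area) ||
      !eq(rule$instrument, md$instrument) || !eq(rule$user, md$user))
    return(FALSE)
  if (!is.null(rule$date_begin) || !is.null(rule$date_end)) {
    d <- md$acquired_date
    if (is.null(d)) return(FALSE)
    if (!is.null(rule$date_begin) && d < rule$date_begin) return(FALSE)
    if (!is.null(rule$date_end) && d > rule$date_end) return(FALSE)
  }
  is.null(rule$pattern) || grepl(rule$pattern, candidate$relative_path, perl = TRUE)
}

#' Derive the output path for an input and a converter
#'
#' Outputs live in `dirname(input)/converter_dir/` and rename the input by
#' swapping exactly the input extension for the output extension.  Nothing
#' is created on disk.
#'
#' @param input_path Input file path (its name must end with the
#'   converter's `from_file_ext`).
#' @param converter A [converter_spec()].
#' @return The derived output path.
#' @export
derive_output_path <- function(input_path, converter) {
  name <- basename(input_path)
  ext <- converter$from_file_ext
  if (!endsWith(name, ext))
    stop("input does not carry extension '", ext, "': ", input_path)
  stem <- substr(name, 1L, nchar(name) - nchar(ext))
  out <- paste0(stem, converter$to_file_ext)
  if (nzchar(converter$converter_dir))
    file.path(dirname(input_path), converter$converter_dir, out)
  else file.path(dirname(input_path), out)
}

#' Plan one iteration's jobs
#'
#' Every (candidate, rule) match fires -- a file may legitimately be
#' converted by several converters, so standard instrument-wide rules and
#' project-specific rules accumulate rather than shadow each other.
#' Duplicate (input, converter) matches collapse to one job keeping the
#' lowest rule index.  Each surviving pair is then skipped, in this
#' precedence, when it has a recorded failure in the error ledger
#' (`skipped_errored`), when its output already exists on disk
#' (`skipped_existing` -- the idempotency rule), or when the converter is
#' bound to a different host (`skipped_foreign_host`).  Planning touches
#' nothing on disk.
#'
#' @param candidates List of `candidate_file`s crawled against `config`.
#' @param config A `spool_config`.
#' @param local_hostname This machine's name; compared case-insensitively on
#'   the unqualified host name.
#' @param ledger An `error_ledger` (see [load_ledger()]).
#' @return An `iteration_plan` with fields `jobs`, `skipped_existing`,
#'   `skipped_errored` and `skipped_foreign_host`.
#' @export
plan_iteration <- function(candidates, config, local_hostname = spoolflow::local_hostname(),
                           ledger = empty_ledger()) {
  ids <- converter_ids(config)
  jobs <- list(); seen <- character()
  n_exist <- n_err <- n_host <- 0L
  for (cand in candidates) for (i in seq_along(config$rules)) {
    rule <- config$rules[[i]]
    conv <- config$converters[[match(rule$converter_id, ids)]]
    if (!candidate_matches_rule(cand, rule, conv)) next
    key <- ledger_key(cand$absolute_path, conv$converter_id)
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- derive_output_path(cand$absolute_path, conv)
    if (key %in% ledger$entries) n_err <- n_err + 1L
    else if (file.exists(out)) n_exist <- n_exist + 1L
    else if (!same_host(conv$hostname, local_hostname)) n_host <- n_host + 1L
    else jobs[[length(jobs) + 1L]] <-
        structure(list(input_path = cand$absolute_path, converter = conv,
                       output_path = out, rule_index = i,
                       command_preview = build_command_tokens(conv, cand$absolute_path, out)),
                  class = "conversion_job")
  }
  structure(list(jobs = jobs, skipped_existing = n_exist,
                 skipped_errored = n_err, skipped_foreign_host = n_host),
            class = "iteration_plan")
}
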