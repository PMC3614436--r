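#' Define a converter program binding
#'
#' A converter binds one external executable (or wrapper script) that turns
#' an input file of one extension into an output file of another, together
#' with the host it is licensed/installed on and the sub-directory its
#' outputs are written to (next to the input file).
#'
#' @param converter_id Opaque identifier, unique within a configuration;
#'   filter rules reference converters by this id.
#' @param converter_dir Name of the output directory (a single path
#'   component, created under the input file's directory).
#' @param converter_cmd Path to the converter executable or wrapper script.
#' @param converter_options Option string passed verbatim (after shell-style
#'   tokenization honouring double quotes) to the command, before the input
#'   and output paths.
#' @param from_file_ext Input filename suffix, including the leading dot.
#' @param to_file_ext Output filename suffix, including the leading dot.
#' @param hostname DNS hostname of the machine the converter runs on; jobs
#'   for converters bound to other hosts are skipped locally, which is how
#'   work is partitioned across servers without locking.
#' @return An object of class `converter_spec`.
#' @seealso [filter_rule()], [spool_config()]
#' @export
converter_spec <- function(converter_id, converter_dir, converter_cmd,
                           converter_options = "", from_file_ext, to_file_ext,
                           hostname = local_hostname()) {
  structure(list(converter_id = as.character(converter_id),
                 converter_dir = as.character(converter_dir),
                 converter_cmd = as.character(converter_cmd),
                 converter_options = as.character(converter_options),
                 from_file_ext = as.character(from_file_ext),
                 to_file_ext = as.character(to_file_ext),
                 hostname = as.character(hostname)),
            class = "converter_spec")
}

#' Define a pass rule over candidate path metadata
#'
#' Files are blocked by default; a rule passes a candidate to its converter
#' when every *present* field matches (all filters are conjunctive).  A rule
#' with no optional fields matches every candidate carrying the converter's
#' input extension.
#'
#' @param converter_id Id of the converter this rule triggers.
#' @param project,area,instrument,user Optional exact-match filters against
#'   the corresponding path components.
#' @param date_begin,date_end Optional inclusive acquisition-date bounds;
#'   accepts `Date`, `"YYYYMMDD"` or `"YYYY-MM-DD"`.
#' @param pattern Optional regular expression searched (unanchored) in the
#'   candidate's relative path.
#' @return An object of class `filter_rule`.
#' @export
filter_rule <- function(converter_id, project = NULL, area = NULL,
                        instrument = NULL, user = NULL, date_begin = NULL,
                        date_end = NULL, pattern = NULL) {
  as_d <- function(x) {
    if (is.null(x) || (is.character(x) && !nzchar(x))) return(NULL)
    if (inherits(x, "Date")) x else as.Date(x, tryFormats = c("%Y%m%d", "%Y-%m-%d"))
  }
  chr <- function(x) if (is.null(x) || (is.character(x) && !nzchar(x))) NULL else as.character(x)
  structure(list(converter_id = as.character(converter_id),
                 project = chr(project), area = chr(area),
                 instrument = chr(instrument), user = chr(user),
                 date_begin = as_d(date_begin), date_end = as_d(date_end),
                 pattern = chr(pattern)),
            class = "filter_rule")
}

#' Assemble a configuration from converters and rules
#'
#' @param converters List of [converter_spec()] objects.
#' @param rules List of [filter_rule()] objects.
#' @param source_fingerprint MD5 of the file the config was parsed from
#'   (`NA` for configs built in code).
#' @return An object of class `spool_config`.  No validation is performed
#'   here; use [validate_config()] to obtain diagnostics.
#' @export
spool_config <- function(converters = list(), rules = list(),
                         source_fingerprint = NA_character_) {
  structure(list(converters = converters, rules = rules,
                 source_fingerprint = source_fingerprint),
            class = "spool_config")
}

converter_ids <- function(config)
  vapply(config$converters, function(x) x$converter_id, character(1))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an XML configuration file
#'
#' The file holds two parts under one root element: a `<converterList>` of
#' `<converter>` elements (attributes `converterID`, `converterDir`,
#' `converterCmd`, `converterOptions`, `fromFileExt`, `toFileExt`,
#' `hostname`) and a `<rulesList>` of `<rule>` elements (attributes
#' `converterID`, `project`, `omics`, `instrument`, `user`, `beginDate`,
#' `endDate`, `keyword`; dates as `YYYYMMDD`).  Absent and empty-string rule
#' attributes are both wildcards.  Unknown attributes are ignored with a
#' warning so configurations can evolve without breaking older daemons.
#'
#' @param path Path to the XML file.
#' @return A `spool_config` with `source_fingerprint` set from the file
#'   bytes.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  doc <- xml2::read_xml(path)
  known_cv <- c("converterID", "converterDir", "converterCmd", "converterOptions",
                "fromFileExt", "toFileExt", "hostname")
  known_rl <- c("converterID", "project", "omics", "instrument", "user",
                "beginDate", "endDate", "keyword")
  att <- function(nd, nm) { v <- xml2::xml_attr(nd, nm); if (is.na(v)) NULL else v }
  warn_unknown <- function(nd, known, what) {
    extra <- setdiff(names(xml2::xml_attrs(nd)), known)
    if (length(extra))
      warning(sprintf("ignoring unknown %s attribute(s): %s", what,
                      paste(extra, collapse = ", ")), call. = FALSE)
  }
  cvs <- lapply(xml2::xml_find_all(doc, "./converterList/converter"), function(nd) {
    warn_unknown(nd, known_cv, "converter")
    converter_spec(converter_id = att(nd, "converterID") %||% "",
                   converter_dir = att(nd, "converterDir") %||% "",
                   converter_cmd = att(nd, "converterCmd") %||% "",
                   converter_options = att(nd, "converterOptions") %||% "",
                   from_file_ext = att(nd, "fromFileExt") %||% "",
                   to_file_ext = att(nd, "toFileExt") %||% "",
                   hostname = att(nd, "hostname") %||% "")
  })
  rls <- lapply(xml2::xml_find_all(doc, "./rulesList/rule"), function(nd) {
    warn_unknown(nd, known_rl, "rule")
    filter_rule(converter_id = att(nd, "converterID") %||% "",
                project = att(nd, "project"), area = att(nd, "omics"),
                instrument = att(nd, "instrument"), user = att(nd, "user"),
                date_begin = att(nd, "beginDate"), date_end = att(nd, "endDate"),
                pattern = att(nd, "keyword"))
  })
  ids <- vapply(cvs, function(x) x$converter_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate converter_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dangling <- setdiff(vapply(rls, function(x) x$converter_id, character(1)), ids)
  if (length(dangling))
    stop("rule(s) reference missing converter_id: ", paste(dangling, collapse = ", "))
  spool_config(cvs, rls, source_fingerprint = unname(tools::md5sum(path)))
}

#' Check a configuration against its invariants
#'
#' @param config A `spool_config`.
#' @return Character vector of diagnostics, empty when the configuration is
#'   valid.  Never raises and never mutates `config`.
#' @export
validate_config <- function(config) {
  d <- character()
  ids <- converter_ids(config)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    d <- c(d, sprintf("duplicate converter_id: %s", paste(dup, collapse = ", ")))
  for (cv in config$converters) {
    who <- sprintf("converter '%s'", cv$converter_id)
    if (!nzchar(cv$converter_id)) d <- c(d, "converter with empty converter_id")
    for (f in c("from_file_ext", "to_file_ext"))
      if (!startsWith(cv[[f]], "."))
        d <- c(d, sprintf("%s: %s must begin with '.'", who, f))
    if (grepl("[/\\\\]", cv$converter_dir))
      d <- c(d, sprintf("%s: converter_dir must be a single path component", who))
    if (!nzchar(cv$converter_dir) && identical(cv$from_file_ext, cv$to_file_ext))
      d <- c(d, sprintf("%s: output path would equal input path", who))
  }
  for (i in seq_along(config$rules)) {
    r <- config$rules[[i]]
    who <- sprintf("rule %d (converter '%s')", i, r$converter_id)
    if (!r$converter_id %in% ids)
      d <- c(d, sprintf("%s: references unknown converter_id '%s'", who, r$converter_id))
    if (!is.null(r$date_begin) && !is.null(r$date_end) && r$date_begin > r$date_end)
      d <- c(d, sprintf("%s: date_begin after date_end", who))
    if (!is.null(r$pattern) &&
        !tryCatch({ grepl(r$pattern, "", perl = TRUE); TRUE },
                  error = function(e) FALSE, warning = function(w) FALSE))
      d <- c(d, sprintf("%s: invalid regular expression '%s'", who, r$pattern))
  }
  d
}

#' Write a configuration back to XML
#'
#' The emitted file re-parses to a field-equal configuration (order
#' preserved; the fingerprint naturally reflects the new bytes).  The write
#' is atomic: content goes to a temporary sibling file that is renamed into
#' place, so a failed write leaves no partial file.
#'
#' @param config A valid `spool_config` (see [validate_config()]).
#' @param path Destination path.
#' @export
write_config <- function(config, path) {
  diag <- validate_config(config)
  if (length(diag)) stop("refusing to write invalid configuration:\n  ",
                         paste(diag, collapse = "\n  "))
  doc <- xml2::xml_new_root("spoolConfiguration")
  cl <- xml2::xml_add_child(doc, "converterList")
  for (cv in config$converters)
    xml2::xml_add_child(cl, "converter", converterID = cv$converter_id,
                        converterDir = cv$converter_dir, converterCmd = cv$converter_cmd,
                        converterOptions = cv$converter_options,
                        fromFileExt = cv$from_file_ext, toFileExt = cv$to_file_ext,
                        hostname = cv$hostname)
  rl <- xml2::xml_add_child(doc, "rulesList")
  for (r in config$rules) {
    at <- list(converterID = r$converter_id, project = r$project, omics = r$area,
               instrument = r$instrument, user = r$user,
               beginDate = if (!is.null(r$date_begin)) format(r$date_begin, "%Y%m%d"),
               endDate = if (!is.null(r$date_end)) format(r$date_end, "%Y%m%d"),
               keyword = r$pattern)
    do.call(xml2::xml_add_child, c(list(rl, "rule"), Filter(Negate(is.null), at)))
  }
  tmp <- tempfile("config", tmpdir = dirname(path), fileext = ".xml")
  xml2::write_xml(doc, tmp)
  if (!file.rename(tmp, path)) { unlink(tmp); stop("cannot write configuration to ", path) }
  invisible(path)
}

#' Append a rule to a configuration
#'
#' @param config A `spool_config`.
#' @param rule A [filter_rule()] whose `converter_id` exists in `config`.
#' @return A new configuration with the rule appended; `config` itself is
#'   unchanged.
#' @export
add_rule <- function(config, rule) {
  if (!rule$converter_id %in% converter_ids(config))
    stop("rule references unknown converter_id: ", rule$converter_id)
  config$rules <- c(config$rules, list(rule))
  config
}
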