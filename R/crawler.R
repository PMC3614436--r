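#' Extract path metadata per the facility naming convention
#'
#' Spool paths follow `project/area/instrument/user_date/filename`: a unique
#' project identifier, the scientific area (the -omics technology), the
#' instrument that produced the file, then a leaf directory combining the
#' measuring user and the acquisition date (`<user>_<YYYYMMDD>`, split on the
#' *last* underscore so instrument-style user names survive), and finally the
#' file name, whose extension-stripped tokens (split on `_`) become keywords.
#' Deeper paths (e.g. outputs inside a converter directory) reuse the first
#' four components.  Degenerate input never raises; it yields
#' `conforming = FALSE` with whatever fields parsed.
#'
#' @param relative_path Path relative to the spool root, `/`-separated.
#' @return An object of class `path_metadata` with fields `project`, `area`,
#'   `instrument`, `user`, `acquired_date`, `keywords` and `conforming`.
#' @export
extract_path_metadata <- function(relative_path) {
  parts <- strsplit(as.character(relative_path)[1], "/", fixed = TRUE)[[1]]
  parts <- parts[!is.na(parts) & nzchar(parts)]
  md <- list(project = NULL, area = NULL, instrument = NULL, user = NULL,
             acquired_date = NULL, keywords = character(), conforming = FALSE)
  n <- length(parts)
  if (n == 0) return(structure(md, class = "path_metadata"))
  stem <- sub("\\.[^.]*$", "", parts[n])
  kw <- strsplit(stem, "_", fixed = TRUE)[[1]]
  md$keywords <- kw[nzchar(kw)]
  if (n >= 5) {
    md$project <- parts[1]; md$area <- parts[2]; md$instrument <- parts[3]
    sep <- regexpr("_[^_]*$", parts[4])
    if (sep > 1) {
      md$user <- substr(parts[4], 1, sep - 1)
      ds <- substring(parts[4], sep + 1)
      if (grepl("^[0-9]{8}$", ds)) {
        d <- as.Date(ds, "%Y%m%d")
        if (!is.na(d)) md$acquired_date <- d
      }
    }
    md$conforming <- !is.null(md$user) && !is.null(md$acquired_date)
  }
  structure(md, class = "path_metadata")
}

#' Crawl the spool for conversion candidates
#'
#' Walks the tree under `root` and returns every entry -- file *or*
#' directory, since some vendors store a raw acquisition as a folder --
#' whose name ends with any `from_file_ext` declared in `config`, and whose
#' modification age is at least `min_age_seconds` (so half-copied files
#' still being pushed from an instrument PC are left alone).  Converter
#' outputs that carry a declared input extension are candidates like any
#' other entry; that is what makes multi-level workflows possible.
#'
#' @param root Spool root directory.
#' @param config A `spool_config`; only its converters' input extensions
#'   matter here.
#' @param min_age_seconds Minimum age since last modification (default 300).
#' @return List of `candidate_file` objects (fields `absolute_path`,
#'   `relative_path`, `metadata`, `modified_age_seconds`), ordered by
#'   relative path for determinism.
#' @export
crawl_spool <- function(root, config, min_age_seconds = 300) {
  if (!dir.exists(root)) stop("spool root not found: ", root)
  stopifnot(min_age_seconds >= 0)
  exts <- unique(vapply(config$converters, function(x) x$from_file_ext, character(1)))
  rel <- gsub("\\\\", "/", list.files(root, recursive = TRUE, include.dirs = TRUE))
  keep <- rep(FALSE, length(rel))
  for (e in exts[nzchar(exts)]) keep <- keep | endsWith(basename(rel), e)
  rel <- sort(rel[keep], method = "radix")
  abs <- file.path(root, rel)
  age <- as.numeric(difftime(Sys.time(), file.mtime(abs), units = "secs"))
  ok <- !is.na(age) & age >= min_age_seconds
  rel <- rel[ok]; abs <- abs[ok]; age <- age[ok]
  lapply(seq_along(rel), function(i)
    structure(list(absolute_path = abs[i], relative_path = rel[i],
                   metadata = extract_path_metadata(rel[i]),
                   modified_age_seconds = age[i]),
              class = "candidate_file"))
}
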