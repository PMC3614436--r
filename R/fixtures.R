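#' Describe a synthetic spool tree
#'
#' The generator emulates a project-centric facility layout: every project
#' has a unique identifier, under which the hierarchy runs scientific area
#' (the -omics technology), instrument, then a `<user>_<YYYYMMDD>` leaf
#' directory holding the acquisitions of one user on one day, with keyword
#' tokens in the file names.  A fraction of raw entries are generated as
#' *directories* (some vendors store an acquisition as a folder), and a
#' fraction of non-conforming noise entries (loose files at the root,
#' shallow scratch directories) exercises the default-block behaviour.
#'
#' @param n_projects Number of projects (ids `p1001`, `p1002`, ...).
#' @param areas Scientific-area names.
#' @param instruments_per_area Instruments generated per area.
#' @param users User names measuring in every leaf.
#' @param files_per_leaf Acquisitions per user/date leaf.
#' @param date_range Length-2 `Date` (or parseable) acquisition-date range.
#' @param extensions Named numeric vector of extension sampling weights.
#' @param noise_fraction Non-conforming entries as a share of conforming
#'   ones, in `[0, 1]`.
#' @param dir_candidate_fraction Share of `.raw` entries emitted as
#'   directories rather than files.
#' @param seed RNG seed; identical (spec, seed) yields an identical tree.
#' @return A `spool_spec` object.
#' @export
spool_spec <- function(n_projects = 2, areas = c("Proteomics", "Metabolomics"),
                       instruments_per_area = 2, users = c("ruth", "silvio"),
                       files_per_leaf = 5,
                       date_range = as.Date(c("2011-01-01", "2011-12-31")),
                       extensions = c(".raw" = 0.7, ".wiff" = 0.3),
                       noise_fraction = 0.2, dir_candidate_fraction = 0.25,
                       seed = 1L) {
  stopifnot(n_projects >= 0, instruments_per_area >= 0, files_per_leaf >= 0,
            noise_fraction >= 0, noise_fraction <= 1,
            dir_candidate_fraction >= 0, dir_candidate_fraction <= 1,
            length(extensions) >= 1, !is.null(names(extensions)))
  structure(list(n_projects = n_projects, areas = areas,
                 instruments_per_area = instruments_per_area, users = users,
                 files_per_leaf = files_per_leaf,
                 date_range = as.Date(date_range),
                 extensions = extensions, noise_fraction = noise_fraction,
                 dir_candidate_fraction = dir_candidate_fraction,
                 seed = as.integer(seed)),
            class = "spool_spec")
}

n_conforming <- function(spec)
  spec$n_projects * length(spec$areas) * spec$instruments_per_area *
    length(spec$users) * spec$files_per_leaf

n_noise <- function(spec) round(spec$noise_fraction * n_conforming(spec))

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic spool tree
#'
#' Creates the tree described by `spec` under `dest` (which must be empty
#' or absent; existing content is never overwritten).  File contents are
#' small random bytes -- the daemon filters on paths only, never on
#' content.  Modification times are back-dated one hour so fresh fixtures
#' pass the default crawl age gate.
#'
#' @param spec A [spool_spec()].
#' @param dest Destination directory.
#' @param manifest_path Optional path for a plain-text manifest, one
#'   relative path per line.
#' @return Character vector of created candidate-relevant relative paths
#'   (conforming entries plus noise entries; the filler file inside a
#'   directory-style raw entry is not listed), sorted.
#' @export
generate_spool_tree <- function(spec, dest, manifest_path = NULL) {
  if (dir.exists(dest) && length(list.files(dest, all.files = TRUE, no.. = TRUE)))
    stop("destination is not empty, refusing to overwrite: ", dest)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  methods <- c("ETD", "CID", "HCD", "QC")
  inst_base <- c("VELOS", "QTOF", "TOF", "ORBI")
  manifest <- with_seed(spec$seed, {
    rel <- character()
    for (p in seq_len(spec$n_projects)) for (a in seq_along(spec$areas))
      for (ins in seq_len(spec$instruments_per_area)) for (u in spec$users) {
        day <- spec$date_range[1] +
          sample.int(as.integer(spec$date_range[2] - spec$date_range[1]) + 1L, 1L) - 1L
        leaf <- file.path(sprintf("p%d", 1000L + p), spec$areas[a],
                          sprintf("%s_%d", inst_base[(a - 1L) %% length(inst_base) + 1L], ins),
                          sprintf("%s_%s", u, format(day, "%Y%m%d")))
        for (k in seq_len(spec$files_per_leaf)) {
          ext <- sample(names(spec$extensions), 1L, prob = spec$extensions)
          name <- sprintf("sample%d_%s%s", k, sample(methods, 1L), ext)
          rel <- c(rel, file.path(leaf, name))
        }
      }
    as_dir <- endsWith(rel, ".raw") &
      stats::runif(length(rel)) < spec$dir_candidate_fraction
    noise <- character()
    for (i in seq_len(n_noise(spec)))
      noise <- c(noise, if (i %% 2)
        sprintf("loose_%d%s", i, sample(names(spec$extensions), 1L, prob = spec$extensions))
        else sprintf("scratch/notes_%d.tmp", i))
    for (i in seq_along(rel)) {
      abs <- file.path(dest, rel[i])
      if (as_dir[i]) {
        dir.create(abs, recursive = TRUE)
        writeBin(as.raw(sample.int(256L, 64L, replace = TRUE) - 1L),
                 file.path(abs, "_FUNC001.DAT"))
      } else {
        dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
        writeBin(as.raw(sample.int(256L, 64L, replace = TRUE) - 1L), abs)
      }
    }
    for (nz in noise) {
      abs <- file.path(dest, nz)
      dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
      writeBin(as.raw(sample.int(256L, 32L, replace = TRUE) - 1L), abs)
    }
    sort(c(rel, noise), method = "radix")
  })
  past <- Sys.time() - 3600
  for (f in rev(list.files(dest, recursive = TRUE, include.dirs = TRUE, full.names = TRUE)))
    Sys.setFileTime(f, past)
  if (!is.null(manifest_path)) writeLines(manifest, manifest_path)
  invisible(manifest)
}

mock_kinds <- c("copy", "fail", "slow", "partial")

#' Emit a mock converter executable
#'
#' Mock converters honour the real wrapper contract -- the input and output
#' paths arrive as the final two arguments, exit status 0 signals success,
#' and the artifact must end up at the passed output path.  They are
#' emitted as small shell scripts (batch files on Windows) so a test
#' iteration over many files stays fast.
#'
#' Kinds: `copy` copies input to output and exits 0; `fail` writes nothing
#' and exits 1; `slow` sleeps `sleep_seconds` then copies; `partial` writes
#' the output file and *then* exits 1, which is how the temp-then-rename
#' output protocol gets exercised.
#'
#' @param kind One of `"copy"`, `"fail"`, `"slow"`, `"partial"`.
#' @param dest Path for the script, or an existing directory to create
#'   `mock-<kind>` in.
#' @param sleep_seconds Delay used by the `slow` kind.
#' @param counter_path Optional file; every invocation appends one line to
#'   it before acting, letting tests count executions.
#' @return Path to the executable script.
#' @export
make_mock_converter <- function(kind, dest, sleep_seconds = 0.5,
                                counter_path = NULL) {
  kind <- match.arg(kind, mock_kinds)
  windows <- .Platform$OS.type == "windows"
  if (dir.exists(dest))
    dest <- file.path(dest, paste0("mock-", kind, if (windows) ".bat" else ".sh"))
  count <- if (!is.null(counter_path))
    sprintf('printf \'%%s\\n\' "$1" >> %s', shQuote(counter_path)) else ""
  body <- switch(kind,
    copy = 'cp -R "$1" "$2"',
    fail = "exit 1",
    slow = sprintf('sleep %s\ncp -R "$1" "$2"', format(sleep_seconds)),
    partial = 'printf partial > "$2"\nexit 1')
  if (windows) {
    body <- switch(kind,
      copy = "copy /Y %1 %2 >nul",
      fail = "exit /b 1",
      slow = sprintf("timeout /t %d >nul\ncopy /Y %%1 %%2 >nul", ceiling(sleep_seconds)),
      partial = "echo partial > %2\nexit /b 1")
    writeLines(c("@echo off", body), dest)
  } else {
    writeLines(c("#!/bin/sh", count, body), dest)
    Sys.chmod(dest, "0755")
  }
  dest
}
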