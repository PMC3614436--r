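# Independent brute-force oracle for the planner, written with different
# string mechanics than the implementation (substr-based suffix test,
# sub()-based output derivation, regexpr for pattern search).

naive_suffix <- function(name, ext) {
  n <- nchar(name); e <- nchar(ext)
  n >= e && substr(name, n - e + 1L, n) == ext
}

naive_matches <- function(cand, rule, conv) {
  if (!naive_suffix(basename(cand$relative_path), conv$from_file_ext)) return(FALSE)
  md <- cand$metadata
  for (f in c("project", "area", "instrument", "user"))
    if (!is.null(rule[[f]]) && (is.null(md[[f]]) || md[[f]] != rule[[f]])) return(FALSE)
  if (!is.null(rule$date_begin) || !is.null(rule$date_end)) {
    if (is.null(md$acquired_date)) return(FALSE)
    if (!is.null(rule$date_begin) && md$acquired_date < rule$date_begin) return(FALSE)
    if (!is.null(rule$date_end) && md$acquired_date > rule$date_end) return(FALSE)
  }
  is.null(rule$pattern) ||
    regexpr(rule$pattern, cand$relative_path, perl = TRUE) > 0
}

naive_output <- function(input, conv) {
  base <- sub(paste0(gsub("([.\\\\])", "\\\\\\1", conv$from_file_ext), "$"), "",
              basename(input))
  file.path(dirname(input), conv$converter_dir, paste0(base, conv$to_file_ext))
}

# returns per-category sets of "input\tconverter_id" keys
naive_plan_keys <- function(candidates, config, hostname, ledger_keys = character()) {
  ids <- vapply(config$converters, function(x) x$converter_id, character(1))
  out <- list(jobs = character(), errored = character(),
              existing = character(), foreign = character())
  short <- function(h) tolower(sub("\\..*$", "", h))
  for (cand in candidates) {
    cids <- character()
    for (r in config$rules) {
      conv <- config$converters[[which(ids == r$converter_id)[1]]]
      if (naive_matches(cand, r, conv)) cids <- c(cids, conv$converter_id)
    }
    for (cid in unique(cids)) {
      conv <- config$converters[[which(ids == cid)[1]]]
      key <- paste(cand$absolute_path, cid, sep = "\t")
      if (key %in% ledger_keys) out$errored <- c(out$errored, key)
      else if (file.exists(naive_output(cand$absolute_path, conv)))
        out$existing <- c(out$existing, key)
      else if (short(conv$hostname) != short(hostname))
        out$foreign <- c(out$foreign, key)
      else out$jobs <- c(out$jobs, key)
    }
  }
  lapply(out, sort)
}

# --- randomized instance generators (used by property and acceptance tests)

rand_spool_spec <- function() {
  spool_spec(n_projects = sample(1:2, 1),
             areas = sample(c("Proteomics", "Metabolomics"), sample(1:2, 1)),
             instruments_per_area = 1,
             users = sample(c("ruth", "silvio", "jdoe"), sample(1:2, 1)),
             files_per_leaf = sample(1:3, 1),
             extensions = c(".raw" = 0.6, ".wiff" = 0.4),
             noise_fraction = sample(c(0, 0.3), 1),
             dir_candidate_fraction = 0.2,
             seed = sample.int(1e6, 1))
}

rand_rule <- function(cid) {
  maybe <- function(x, p = 0.3) if (stats::runif(1) < p) x else NULL
  dates <- sort(as.Date("2011-01-01") + sample.int(364, 2))
  filter_rule(cid,
              project = maybe(sample(c("p1001", "p1002", "p9999"), 1)),
              area = maybe(sample(c("Proteomics", "Metabolomics"), 1)),
              instrument = maybe(sample(c("VELOS_1", "QTOF_1", "TOF_1"), 1)),
              user = maybe(sample(c("ruth", "silvio", "jdoe"), 1)),
              date_begin = maybe(dates[1], 0.2), date_end = maybe(dates[2], 0.2),
              pattern = maybe(sample(c("ETD", "CID", "sample[12]", "QC"), 1)))
}

rand_config <- function(hosts = local_hostname()) {
  n_conv <- sample(1:3, 1)
  convs <- lapply(seq_len(n_conv), function(i)
    converter_spec(paste0("c", i), paste0("out", i), "/bin/true",
                   sample(c("", "-x -y", '--filter "pp true 2-"'), 1),
                   sample(c(".raw", ".wiff", ".mgf"), 1), ".o",
                   hostname = sample(hosts, 1)))
  rules <- lapply(seq_len(sample(0:4, 1)), function(i)
    rand_rule(paste0("c", sample.int(n_conv, 1))))
  spool_config(convs, rules)
}

# one randomized planner instance checked against the oracle; returns the
# number of disagreements (0 when implementation and oracle agree)
check_plan_against_oracle <- function(env = parent.frame()) {
  root <- new_root(env = env)
  generate_spool_tree(rand_spool_spec(), root)
  config <- rand_config(hosts = c(local_hostname(), "elsewhere"))
  cands <- crawl_spool(root, config, min_age_seconds = 0)
  ids <- vapply(config$converters, function(x) x$converter_id, character(1))
  # plant pre-existing outputs and ledger entries for random matched pairs
  ledger <- empty_ledger()
  for (cand in cands) for (cid in unique(ids)) {
    conv <- config$converters[[which(ids == cid)[1]]]
    if (!naive_suffix(basename(cand$relative_path), conv$from_file_ext)) next
    r <- stats::runif(1)
    out <- naive_output(cand$absolute_path, conv)
    if (r < 0.15) {
      dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
      writeLines("prior", out)
    } else if (r < 0.25) {
      ledger$entries <- c(ledger$entries, paste(cand$absolute_path, cid, sep = "\t"))
    }
  }
  plan <- plan_iteration(cands, config, local_hostname(), ledger)
  want <- naive_plan_keys(cands, config, local_hostname(), ledger$entries)
  sum(!identical(job_keys(plan), want$jobs),
      plan$skipped_errored != length(want$errored),
      plan$skipped_existing != length(want$existing),
      plan$skipped_foreign_host != length(want$foreign))
}
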