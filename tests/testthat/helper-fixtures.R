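# Shared fixture builders.  Everything is generated in code at test time;
# nothing is read from disk fixtures.

new_root <- function(env = parent.frame()) {
  root <- tempfile("spool")
  dir.create(root)
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  root
}

# a config wired to freshly generated mock converters; one converter per
# (from, to, dir) triple, all bound to the local host unless told otherwise
mock_config <- function(kinds = "copy", froms = ".raw", tos = ".mgf",
                        dirs = "mgf", ids = NULL, hosts = NULL,
                        rules = "wildcard", env = parent.frame(), ...) {
  n <- max(lengths(list(kinds, froms, tos, dirs)))
  kinds <- rep_len(kinds, n); froms <- rep_len(froms, n)
  tos <- rep_len(tos, n); dirs <- rep_len(dirs, n)
  ids <- ids %||% as.character(seq(28, length.out = n))
  hosts <- rep_len(hosts %||% local_hostname(), n)
  bin <- tempfile("mocks"); dir.create(bin)
  withr::defer(unlink(bin, recursive = TRUE), envir = env)
  convs <- lapply(seq_len(n), function(i)
    converter_spec(ids[i], dirs[i],
                   make_mock_converter(kinds[i], tempfile(tmpdir = bin, fileext = ".sh"), ...),
                   "", froms[i], tos[i], hostname = hosts[i]))
  rl <- if (identical(rules, "wildcard")) lapply(ids, filter_rule) else rules
  spool_config(convs, rl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_config <- function(config, env = parent.frame()) {
  path <- tempfile("config", fileext = ".xml")
  withr::defer(unlink(path), envir = env)
  write_config(config, path)
  path
}

test_settings <- function(config, root, env = parent.frame(), pool_size = 2, ...) {
  run_settings(config_path = if (is.character(config)) config
               else write_tmp_config(config, env = env),
               spool_root = root, min_age_seconds = 0,
               loop_interval_seconds = 0, pool_size = pool_size, ...)
}

# plant loose candidate files (age-backdated) without the full generator
plant <- function(root, rel_paths, as_dir = FALSE) {
  for (p in rel_paths) {
    abs <- file.path(root, p)
    if (as_dir) dir.create(abs, recursive = TRUE)
    else {
      dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
      writeLines("x", abs)
    }
    Sys.setFileTime(abs, Sys.time() - 3600)
  }
  invisible(file.path(root, rel_paths))
}

job_keys <- function(plan)
  sort(vapply(plan$jobs, function(j)
    paste(j$input_path, j$converter$converter_id, sep = "\t"), character(1)))

# stable snapshot of a tree for state-equality assertions (paths + sizes)
tree_state <- function(root) {
  f <- sort(list.files(root, recursive = TRUE, include.dirs = TRUE))
  data.frame(path = f, size = file.size(file.path(root, f)))
}
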