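---
title: "How spoolflow schedules conversions: rules, idempotency and the error ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How spoolflow schedules conversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spoolflow)
```

## The processing model

`spoolflow` treats file conversion the way a stateful packet filter treats
packets: candidate files on a shared spool are compared against an ordered
rule set, the default action is *block*, and a matching rule *passes* the
file to a configured converter. One iteration of the daemon is a pure
pipeline with a single side-effecting stage at the end:

1. `parse_config()` — read converters and rules from one XML file;
2. `crawl_spool()` — enumerate candidates by input extension;
3. `plan_iteration()` — pure planning: match, collapse, skip;
4. `execute_plan()` — run the surviving jobs on a worker pool and append
   one record per job to the central log.

The key assumption behind this design is that *all* coordination state can
live in exactly two places: the file tree itself (an output exists, or it
does not) and the append-only log. There are no databases, lock files,
or checkpoint files. A daemon killed at any point loses nothing: the next
iteration re-derives everything. The cost of this choice is that each
iteration re-crawls the spool; the facility practice of clearing the spool
periodically keeps that walk cheap, and an age-gated crawl is far more
portable than OS file-notification services, which differ between the
platforms converters are locked to.

### Path metadata

Candidates are classified entirely by *where they are*, never by content,
because vendor formats are opaque binaries. The fixed convention is

```
project / area / instrument / user_date / filename
```

with `user_date = <user>_<YYYYMMDD>`. The component is split on its *last*
underscore so users like `van_der_berg` parse correctly, while the
instrument keeps its underscores by virtue of being its own component.
The extension-stripped filename splits on `_` into keyword tokens (e.g.
the fragmentation method, `ETD` vs `CID`) which rules reach through
regular expressions. Paths deeper than five components — converter outputs
inside an output directory — reuse the first four components, so
project-scoped rules still apply to second-stage inputs.
`extract_path_metadata()` never throws: malformed paths simply come back
`conforming = FALSE` with whatever parsed, and then fail any rule that
filters on a missing field (while still matching pure wildcard rules,
which is deliberate: an extension-only rule should sweep everything).

### Matching semantics

All present rule fields are conjunctive; all matching rules fire. The
alternative — first-match-wins, as in actual packet filters — was rejected
because facilities run instrument-wide standard rules *and* per-project
custom rules over the same files, and both are meant to act.
Duplicate (input, converter) matches from overlapping rules collapse to a
single job keeping the lowest rule index, so overlap never causes double
execution; the output-existence check would catch it anyway, but collapsing
keeps the plan's counters meaningful. Patterns use unanchored Perl-style
regular-expression search over the relative path: substring semantics are
what keyword filtering implies.

### Skip precedence

A matched pair is skipped for exactly one reason, tested in the order

1. **error ledger** — a recorded failure with no later success;
2. **output exists** — the idempotency rule;
3. **foreign host** — the converter is bound to another machine.

The order is the cheapest-and-most-conservative-first resolution of an
otherwise arbitrary choice; it also means the counters in an
`iteration_plan` are well defined, which the tests rely on.

### Why re-conversion is a new converter

Converter programs get upgraded, and facilities then want old data
re-converted. Since the only skip predicate is output existence, the model
for "convert again with version 2" is a *new* converter entry with a
different `converter_dir`: old outputs stay, new outputs land next to them.
No timestamp or version comparison exists, on purpose.

## Execution

`execute_plan()` bounds concurrency with a fork-based pool (`parallel`);
on Windows, or with `pool_size = 1`, it degrades to serial execution with
an identical contract: the final tree state is independent of the pool
size, and the call returns only after every job finished (the iteration
barrier — the next crawl must see a settled tree).

Two details make the existence check a safe idempotency predicate:

- **Temp-then-rename.** Each job is handed `<output>.inprogress` as its
  output argument; only on exit status 0 *and* the temporary actually
  existing is it renamed to the real output. On any failure the temporary
  is deleted. A tool that writes output and then crashes therefore leaves
  nothing behind (the `partial` mock converter exercises exactly this).
- **Post-barrier logging.** The parent process appends all log records
  after the pool joins, one tab-separated line per job, with separator
  characters scrubbed from fields — records can never interleave within a
  host. Cross-host append atomicity on a network share is *not* guaranteed
  and is a known limitation; in practice each host mostly logs its own
  partition of the work.

Command assembly tokenizes the converter's option string shell-style
(whitespace-separated, double-quoted groups kept whole, unbalanced quotes
are a configuration error) and appends input and output paths; tokens are
passed to the process without any further shell interpretation, so spaces
in spool paths are safe.

The error ledger is replayed from the log on every iteration: a pair is
excluded iff its most recent record is a failure. Clearing an error is an
operator action — fix the input, then either truncate the log or run one
iteration with `retry_errors = TRUE`, which ignores the ledger once.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `min_age_seconds` | 300 s | Instruments push files to the spool over the network; a five-minute age gate avoids converting half-copied files without needing transfer-completion signals. |
| `pool_size` | all logical CPUs | Converters are CPU-bound (peak picking, deconvolution); full utilization is the point of automation. |
| `loop_interval_seconds` | 30 s | The loop could re-iterate immediately; a short sleep stops an empty spool from hot-spinning while keeping worst-case latency well under any acquisition time. |
| hostname matching | case-insensitive, unqualified | DNS names are case-insensitive, and FQDN vs short name must not split one machine into two. |
| date format | `YYYYMMDD` | Sortable, unambiguous, identical to the directory-name usage. |

## The synthetic spool generator

`generate_spool_tree()` emulates the facility layout the daemon is built
for: project identifiers (`p1001`, ...), areas as -omics technologies,
instruments per area, `<user>_<date>` leaves, keyword-bearing file names,
a weighted extension mix, a fraction of directory-shaped raw entries
(Waters-style acquisitions are folders), and a fraction of non-conforming
noise (loose root-level files, scratch directories). Defaults are 2
projects × 2 areas × 2 instruments × 2 users × 5 files = 80 conforming
entries plus 20 % noise — enough variety to exercise every filter
dimension while keeping a full daemon iteration in the low seconds, which
is also the problem size the test-suite and the acceptance checks run at
(the planner/oracle comparison uses 100 smaller randomized trees).
Identical `(spec, seed)` reproduces an identical manifest, and generation
restores the caller's RNG stream.

What the generator does **not** emulate: real vendor file contents (bytes
are random; the daemon never reads them), file-arrival races and partial
network copies (the age gate is tested directly instead), SMB permission
semantics, and truly concurrent multi-host execution against one share —
host partitioning is tested by planning the same tree from several
simulated hostnames, which verifies disjointness and coverage but not
shared-filesystem contention. Passing tests therefore demonstrate the
scheduling semantics, not network-filesystem robustness.

Mock converters are emitted as small POSIX shell scripts (batch files on
Windows) honouring the real wrapper contract — `<input> <output>` as final
arguments, exit 0 on success, artifact at the output path. Script startup
is effectively free, which keeps multi-hundred-job test iterations fast;
the same contract is what real wrapper scripts around `msconvert` and
similar tools implement, so the mocks differ from production wrappers only
in what they do between argv and exit.

## Degenerate inputs and edge policies

- Empty configuration: valid; every iteration plans zero jobs.
- Absent optional rule attribute and empty string are both wildcards
  (tolerant of hand-edited XML).
- Unknown XML attributes warn and are ignored — configurations must be
  extensible on the fly without breaking older daemons.
- A transient configuration parse failure inside the loop keeps the
  previous good configuration (availability over strictness); a broken
  config at first start is a hard error.
- `from_file_ext == to_file_ext` is allowed when `converter_dir` is
  non-empty (the directory keeps output ≠ input); it is a validation error
  otherwise.
- Candidates may be directories; suffix matching applies to the entry
  name regardless of kind, and the copy semantics of converters decide
  what to do with folder inputs.

## Known limitations

- One crawl per iteration scales linearly with spool size; very large
  spools rely on periodic archiving, or on splitting the spool root.
- The central log's multi-host append atomicity is per-host only.
- Rule vocabulary is fixed to the five metadata dimensions plus regex;
  content-based filtering is out of scope by design.
- The path convention is a single pluggable point
  (`extract_path_metadata()`); facilities with different layouts adapt
  that one function.
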