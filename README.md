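# spoolflow

Rule-based conversion orchestration for instrument spool directories.

## The problem

Core facilities that run many mass spectrometers accumulate a steady stream
of vendor-proprietary raw files (Thermo `.raw`, Sciex `.wiff`, Waters `.raw`
folders, ...) on a shared spool, and every downstream analysis needs them
converted into open formats — mgf peak lists, mzXML/mzML, netCDF — with
options that differ by project, instrument, fragmentation method and user.
The converters are external, single-platform, often licensed executables;
doing this by hand through GUIs does not scale past a handful of files per
day.

`spoolflow` automates the whole task with packet-filter semantics: files are
**blocked by default**, and declarative **pass rules** forward matching
files to configured converters. Each daemon iteration is

1. **parse** the XML configuration (converters + rules),
2. **crawl** the spool for candidate files by input extension,
3. **match** each candidate's path metadata against every rule, and
4. **execute** the planned conversions on a bounded pool of workers.

A candidate's metadata comes from the facility path convention
`project/area/instrument/user_date/filename`, e.g.

```
p1000/Proteomics/VELOS_1/jdoe_20110503/sample1_ETD.raw
```

Rules filter on project, area, instrument, user, an inclusive acquisition
date window, and free regular expressions over the relative path; all
present fields must match (conjunction), and every matching rule fires, so
instrument-wide standard rules and project-specific custom rules coexist on
the same files.

The design is deliberately stateless and crash-only:

- **Idempotency** — a job is only planned when its output file does not
  already exist, so re-running on an unchanged tree is a no-op.
- **Error exclusion** — results go to a central tab-separated log; inputs
  whose conversion failed are excluded from later iterations (no endless
  retry loops on corrupt files). The ledger of failed pairs is *derived*
  from the log; there is no other state.
- **Multi-host partitioning** — each converter names the host it runs on;
  every participating server runs the same loop against the same
  configuration and simply skips foreign-host jobs.
- **Multi-level workflows** — converter outputs are ordinary candidates, so
  a `.raw → .mgf` rule and a `.mgf → .txt` rule chain automatically,
  converging in one iteration per stage.
- **Hot reload** — the configuration is re-parsed every iteration, so new
  rules, converters or hosts take effect without a restart.
- Outputs are written to a temporary name and renamed only on success, so
  the existence check never mistakes a partial file for a finished one.

## Worked example

Everything below is generated; no instrument data is needed. The bundled
fixture generator builds a facility-style spool (80 conforming files across
2 projects × 2 areas × 2 instruments × 2 users, plus 20 % non-conforming
noise), and mock converters stand in for real vendor tools.

```r
library(spoolflow)

spool <- file.path(tempdir(), "spool")
manifest <- generate_spool_tree(spool_spec(seed = 1), spool)
length(manifest)
#> [1] 96
head(manifest, 3)
#> [1] "loose_1.raw"   "loose_11.raw"  "loose_13.wiff"

conv <- make_mock_converter("copy", tempdir())   # stands in for msconvert etc.
cfg <- spool_config(
  converters = list(
    converter_spec("28", "mgf_hscore", conv, "", ".raw",  ".mgf"),
    converter_spec("31", "mgf",        conv, "", ".wiff", ".mgf")),
  rules = list(
    filter_rule("28"),                    # every .raw, facility-wide
    filter_rule("31", pattern = "ETD")))  # only ETD runs of the .wiff files
config_path <- file.path(tempdir(), "config.xml")
write_config(cfg, config_path)

settings <- run_settings(config_path, spool, min_age_seconds = 0, pool_size = 2)
run_once(settings)
#> <iteration_report> 2026-09-20 02:48:30: 88 candidate(s), 58 job(s) planned, 58 ok, 0 failed
#>   skipped: 0 existing, 0 errored, 0 foreign-host
run_once(settings)
#> <iteration_report> 2026-09-20 02:48:30: 88 candidate(s), 0 job(s) planned, 0 ok, 0 failed
#>   skipped: 58 existing, 0 errored, 0 foreign-host
log_status(settings$log_path)
#> <log_status>
#>  converter_id successes failures
#>            28        54        0
#>            31         4        0
```

88 of the 96 created entries carry a declared input extension and are
candidates; 54 `.raw` files match the wildcard rule and 4 of the `.wiff`
files contain `ETD` in their path, so 58 jobs run. The second iteration
plans nothing — all 58 outputs exist — which is the fixed point the daemon
loop rests at until new files arrive.

On a real deployment you would point `converter_cmd` at a wrapper script
for the actual tool (the wrapper must place its final artifact at the
output path it is handed and exit non-zero on failure) and run the loop:

```sh
exec/spoolflow run --config config.xml --root /srv/spool --loop --interval 30
exec/spoolflow validate --config config.xml
exec/spoolflow add-rule --config config.xml --converter-id 28 --project p1000
exec/spoolflow status   --log /srv/spool/conversion.log
```

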