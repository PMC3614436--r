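conv_a <- converter_spec("28", "mgf_hscore", "/opt/wrap.sh", "", ".raw", ".mgf", "srv-a")

cand_for <- function(rel, root = "/spool")
  structure(list(absolute_path = file.path(root, rel), relative_path = rel,
                 metadata = extract_path_metadata(rel), modified_age_seconds = 3600),
            class = "candidate_file")

test_that("rule fields are conjunctive filters with wildcard defaults", {
  cand <- cand_for("p1000/Proteomics/VELOS_1/jdoe_20110503/sample1_ETD.raw")
  expect_true(candidate_matches_rule(cand, filter_rule("28"), conv_a))
  expect_true(candidate_matches_rule(
    cand, filter_rule("28", project = "p1000", area = "Proteomics",
                      instrument = "VELOS_1", user = "jdoe",
                      date_begin = "20110503", date_end = "20110503"), conv_a))
  expect_false(candidate_matches_rule(cand, filter_rule("28", project = "p2000"), conv_a))
  expect_false(candidate_matches_rule(cand, filter_rule("28", user = "ruth"), conv_a))
  expect_false(candidate_matches_rule(
    cand, filter_rule("28", date_begin = "20110504"), conv_a))
  expect_false(candidate_matches_rule(
    cand, filter_rule("28", date_end = "20110502"), conv_a))
  # wrong extension blocks regardless of other fields
  expect_false(candidate_matches_rule(
    cand_for("p1000/Proteomics/VELOS_1/jdoe_20110503/sample1.wiff"),
    filter_rule("28"), conv_a))
  # non-conforming candidates fail any metadata filter but pass pure wildcards
  loose <- cand_for("loose.raw")
  expect_true(candidate_matches_rule(loose, filter_rule("28"), conv_a))
  expect_false(candidate_matches_rule(loose, filter_rule("28", project = "p1000"), conv_a))
  expect_false(candidate_matches_rule(loose, filter_rule("28", date_begin = "20110101"), conv_a))
})

test_that("patterns are regular-expression searches over the relative path", {
  etd <- cand_for("p1000/Proteomics/VELOS_1/jdoe_20110503/sample1_ETD.raw")
  cid <- cand_for("p1000/Proteomics/VELOS_1/jdoe_20110503/sample1_CID.raw")
  rule <- filter_rule("28", pattern = ".*ETD.*")
  expect_true(candidate_matches_rule(etd, rule, conv_a))
  expect_false(candidate_matches_rule(cid, rule, conv_a))
  # unanchored search, cross-checked against an independent regexpr scan
  for (pat in c("ETD", "sample[0-9]", "^p1000/", "VELOS_1/jdoe")) {
    for (cand in list(etd, cid)) {
      expect_identical(
        candidate_matches_rule(cand, filter_rule("28", pattern = pat), conv_a),
        regexpr(pat, cand$relative_path, perl = TRUE) > 0)
    }
  }
})

test_that("output paths land in the converter directory with swapped extension", {
  expect_identical(
    derive_output_path("/s/p1/Proteomics/V_1/jdoe_20110503/sample1.raw", conv_a),
    "/s/p1/Proteomics/V_1/jdoe_20110503/mgf_hscore/sample1.mgf")
  # exactly the declared suffix is removed, the rest of the name survives
  expect_identical(basename(derive_output_path("/s/a.b.raw", conv_a)), "a.b.mgf")
  same_ext <- converter_spec("9", "v2", "c", "", ".mgf", ".mgf", "h")
  out <- derive_output_path("/s/leaf/x.mgf", same_ext)
  expect_identical(out, "/s/leaf/v2/x.mgf")
  expect_false(identical(out, "/s/leaf/x.mgf"))
  expect_error(derive_output_path("/s/leaf/x.raw", same_ext), "extension")
})

test_that("planning emits all matching (file, converter) pairs once", {
  root <- new_root()
  plant(root, "p1/Proteomics/V_1/ruth_20110101/s1_ETD.raw")
  me <- local_hostname()
  cfg <- spool_config(
    list(converter_spec("28", "mgf", "c", "", ".raw", ".mgf", me),
         converter_spec("29", "mzxml", "c", "", ".raw", ".mzXML", me)),
    list(filter_rule("28"), filter_rule("29", pattern = "ETD"),
         filter_rule("28", project = "p1")))  # duplicate match for 28
  cands <- crawl_spool(root, cfg, 0)
  plan <- plan_iteration(cands, cfg, me)
  expect_length(plan$jobs, 2)
  expect_setequal(vapply(plan$jobs, function(j) j$converter$converter_id, character(1)),
                  c("28", "29"))
  # collapsed duplicate keeps the lowest rule index
  j28 <- plan$jobs[[which(vapply(plan$jobs, function(j) j$converter$converter_id,
                                 character(1)) == "28")]]
  expect_identical(j28$rule_index, 1L)
  expect_identical(j28$command_preview, build_command(j28))
})

test_that("skip causes follow the ledger > existing > host precedence", {
  root <- new_root()
  abs <- plant(root, "p1/Proteomics/V_1/ruth_20110101/s1.raw")
  me <- local_hostname()
  mk <- function(host) spool_config(
    list(converter_spec("28", "mgf", "c", "", ".raw", ".mgf", host)),
    list(filter_rule("28")))
  cands <- crawl_spool(root, mk(me), 0)

  p <- plan_iteration(cands, mk("other-host"), me)
  expect_length(p$jobs, 0)
  expect_identical(p$skipped_foreign_host, 1L)

  plant(root, "p1/Proteomics/V_1/ruth_20110101/mgf/s1.mgf")
  p <- plan_iteration(cands, mk(me), me)
  expect_identical(p$skipped_existing, 1L)
  # hostname comparison is case-insensitive and drops the domain part
  p2 <- plan_iteration(cands, mk(toupper(paste0(me, ".example.org"))), me)
  expect_identical(p2$skipped_existing, 1L)

  ledger <- empty_ledger()
  ledger$entries <- paste(abs, "28", sep = "\t")
  p <- plan_iteration(cands, mk(me), me, ledger)
  expect_identical(p$skipped_errored, 1L)
  expect_identical(p$skipped_existing, 0L)
})

test_that("planner agrees with the brute-force oracle on random instances", {
  withr::local_seed(101)
  for (i in 1:15) expect_identical(check_plan_against_oracle(), 0L)
})

test_that("per-host plans partition the all-hosts plan", {
  withr::local_seed(55)
  root <- new_root()
  generate_spool_tree(spool_spec(seed = 5), root)
  hosts <- c("srv-a", "srv-b")
  cfg <- spool_config(
    list(converter_spec("1", "o1", "c", "", ".raw", ".o", "srv-a"),
         converter_spec("2", "o2", "c", "", ".wiff", ".o", "srv-b"),
         converter_spec("3", "o3", "c", "", ".raw", ".x", "srv-b")),
    list(filter_rule("1"), filter_rule("2"), filter_rule("3", pattern = "ETD")))
  cands <- crawl_spool(root, cfg, 0)
  per_host <- lapply(hosts, function(h) job_keys(plan_iteration(cands, cfg, h)))
  expect_length(intersect(per_host[[1]], per_host[[2]]), 0)
  all_cfg <- cfg
  for (i in seq_along(all_cfg$converters)) all_cfg$converters[[i]]$hostname <- "one"
  expect_setequal(unlist(per_host), job_keys(plan_iteration(cands, all_cfg, "one")))
})
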