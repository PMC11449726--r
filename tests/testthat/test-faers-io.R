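# Parsing, deduplication, target-drug matching, dataset assembly and
# time-to-onset exclusion rules.

test_that("deduplication keeps the right version in both branches", {
  # same case, same receipt date: higher PRIMARYID survives
  demo <- toy_demo(caseid = c(1, 1), primaryid = c(10, 11),
                   fda_dt = c("20200101", "20200101"))
  expect_equal(deduplicate_cases(demo)$primaryid, "11")
  # same case, different receipt dates: latest date survives even with a
  # lower PRIMARYID
  demo <- toy_demo(caseid = c(1, 1), primaryid = c(10, 9),
                   fda_dt = c("20200101", "20200401"))
  expect_equal(deduplicate_cases(demo)$primaryid, "9")
  # deleted cases vanish entirely
  demo <- toy_demo(caseid = 2, primaryid = 20, fda_dt = "20200101")
  expect_equal(nrow(deduplicate_cases(demo, deleted_caseids = "2")), 0)
  expect_equal(nrow(deduplicate_cases(demo[0, ])), 0)
})

test_that("deduplication is idempotent and order-independent", {
  demo <- toy_demo(caseid = c(1, 1, 2, 2, 2, 3),
                   primaryid = c(10, 11, 20, 21, 19, 30),
                   fda_dt = c("20200101", "20200101", "20200301",
                              "20200301", "20200501", "20190101"))
  base <- deduplicate_cases(demo)
  expect_equal(sort(base$primaryid), c("11", "19", "30"))
  expect_equal(deduplicate_cases(base), base)
  withr::with_seed(1, {
    for (i in 1:10) {
      perm <- demo[sample(nrow(demo)), ]
      got <- deduplicate_cases(perm)
      expect_setequal(got$primaryid, base$primaryid)
    }
  })
})

test_that("target-drug matching is normalised and dictionary-driven", {
  syn <- esl_synonyms()
  expect_true(match_target_drug("APTIOM", syn))
  expect_true(match_target_drug("  aptiom ", syn))
  expect_true(match_target_drug("Eslicarbazepine  Acetate", syn))
  expect_false(match_target_drug("CARBAMAZEPINE", syn))
  expect_error(match_target_drug("APTIOM", character(0)), "empty")
})

test_that("age units convert to years and implausible ages are dropped", {
  demo <- toy_demo(caseid = 1:6, primaryid = 1:6, fda_dt = "20200101",
                   age = c(24, 45, 3, 730.5, 2, 150),
                   age_cod = c("MON", "YR", "DEC", "DY", "WK", "YR"))
  ds <- assemble_dataset(toy_raw(
    demo = demo, drug = toy_drug(1:6, "APTIOM"),
    reac = toy_reac(1:6, "SEIZURE")))
  expect_equal(ds$reports$age_years,
               c(2, 45, 30, 2, 2 / 52.18, NA_real_), tolerance = 1e-12)
})

test_that("assembly flags PS-only target reports and collapses events", {
  demo <- toy_demo(caseid = 1:3, primaryid = 1:3, fda_dt = "20200101")
  drug <- dplyr::bind_rows(
    toy_drug(1, "APTIOM", role_cod = "PS"),
    toy_drug(2, "APTIOM", role_cod = "SS"),      # suspect but not primary
    toy_drug(2, "CARBAMAZEPINE", role_cod = "PS", drug_seq = 2),
    toy_drug(3, "LAMOTRIGINE", role_cod = "PS"))
  reac <- toy_reac(c(1, 1, 1, 2, 3), c("SEIZURE", "SEIZURE", "Rash ",
                                       "SEIZURE", "DIZZINESS"))
  ds <- assemble_dataset(toy_raw(demo = demo, drug = drug, reac = reac))
  expect_equal(ds$reports$target, c(TRUE, FALSE, FALSE))
  # duplicate (report, PT) rows collapse; PT is normalised
  expect_equal(ds$counts$n_event_records, 4)
  expect_setequal(ds$events$pt[ds$events$primaryid == "1"],
                  c("SEIZURE", "RASH"))
  # orphan events (unknown primaryid) are dropped and counted
  reac2 <- dplyr::bind_rows(reac, toy_reac(99, "FALL"))
  ds2 <- assemble_dataset(toy_raw(demo = demo, drug = drug, reac = reac2))
  expect_equal(ds2$counts$orphan_events_dropped, 1)
  expect_equal(ds2$counts$n_event_records, 4)
})

test_that("read_quarter refuses files with missing mandatory columns", {
  dir <- withr::local_tempdir()
  tab <- generate_tables(small_config(n_cases = 10))
  write_fixture(tab, dir)
  demo_path <- list.files(dir, pattern = "^DEMO", full.names = TRUE)
  lines <- readLines(demo_path)
  writeLines(gsub("primaryid", "pid", lines), demo_path)
  expect_error(read_quarter(dir), "primaryid")
})

test_that("assembled counts agree with the generator's bookkeeping", {
  cfg <- small_config(seed = 7, n_cases = 600, duplicate_rate = 0.3,
                      deleted_rate = 0.05)
  tab <- generate_tables(cfg)
  ds <- assemble_dataset(tab)
  gt <- tab$ground_truth
  expect_equal(ds$counts$n_reports, gt$n_surviving)
  expect_equal(ds$counts$n_target_reports, gt$n_surviving_target)
  # the surviving version of every case is the one ground truth predicts
  expect_setequal(ds$reports$primaryid, gt$surviving$primaryid)
  # event-record total equals the target-stratum contingency margin
  cells <- pt_contingency(ds)
  expect_equal(sum(cells$a), ds$counts$n_target_event_records)
  expect_true(all(cells$a + cells$b == ds$counts$n_target_event_records))
  expect_true(all(cells$c + cells$d ==
                    ds$counts$n_event_records -
                      ds$counts$n_target_event_records))
})

test_that("time-to-onset follows the day-difference and exclusion rules", {
  res <- tto_days(c("20240104", "202401", "20240110", "20240101", "",
                    "20241301"),
                  c("20240131", "20240131", "20240101", "20240101",
                    "20240131", "20240215"))
  expect_equal(res$days[1], 27)
  expect_equal(res$reason,
               c("ok", "partial_date", "nonpositive", "nonpositive",
                 "missing_date", "invalid_date"))
  expect_true(all(is.na(res$days[-1])))
})

test_that("extract_tto uses the earliest PS start date of the target drug", {
  demo <- toy_demo(caseid = 1, primaryid = 1, fda_dt = "20200301",
                   event_dt = "20200210")
  drug <- toy_drug(1, "APTIOM")
  ther <- tibble::tibble(primaryid = "1", caseid = "1",
                         dsg_drug_seq = c(1L, 1L),
                         start_dt = c("20200201", "20200115"))
  ds <- assemble_dataset(toy_raw(demo = demo, drug = drug,
                                 reac = toy_reac(1, "SEIZURE"), ther = ther))
  tto <- extract_tto(ds)
  expect_equal(tto$days, 26)  # from 20200115, the earlier start
  expect_equal(tto$reason, "ok")
})
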