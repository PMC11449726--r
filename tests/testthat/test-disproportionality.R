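# The four estimators, their signal flags, contingency construction and the
# grouped (SOC/SMQ) aggregation.

test_that("estimators agree with a hand-transcribed arithmetic oracle", {
  a <- 10; b <- 90; c <- 100; d <- 9900
  o <- oracle_metrics(a, b, c, d)
  expect_equal(ror_stats(a, b, c, d)$ror, 11)
  expect_equal(prr_stats(a, b, c, d)$prr, 10)
  expect_equal(ebgm_stats(a, b, c, d)$ebgm, 10 * 10100 / (100 * 110))
  expect_equal(ebgm_stats(a, b, c, d, "as_printed")$ebgm,
               10 * 10100 / (110 * 9990))
  bc <- bcpnn_stats(a, b, c, d)
  expect_equal(bc$ic, o$ic, tolerance = 1e-12)
  expect_equal(bc$e_ic, o$e_ic, tolerance = 1e-12)
  expect_equal(bc$v_ic, o$v_ic, tolerance = 1e-12)
  expect_equal(bc$ic_minus_2sd, o$ic_minus_2sd, tolerance = 1e-12)
})

test_that("independence tables give ROR = PRR = EBGM = 1 and IC = 0 exactly", {
  for (cells in list(c(10, 10, 10, 10), c(5, 45, 50, 450),
                     c(100, 900, 1000, 9000))) {
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    expect_identical(ror_stats(a, b, c, d)$ror, 1)
    expect_identical(prr_stats(a, b, c, d)$prr, 1)
    expect_identical(ebgm_stats(a, b, c, d)$ebgm, 1)
    expect_identical(bcpnn_stats(a, b, c, d)$ic, 0)
  }
  # the CI is symmetric about 1 on the log scale
  ci <- ror_stats(10, 10, 10, 10)
  expect_equal(log(ci$ror_lo), -log(ci$ror_hi))
  # posterior IC expectation shrinks toward 0 at scale
  big <- bcpnn_stats(1000, 249000, 3000, 747000)
  expect_lt(abs(big$e_ic), 0.01)
})

test_that("point estimates are scale invariant; intervals narrow", {
  a <- 12; b <- 80; c <- 55; d <- 4000
  base_r <- ror_stats(a, b, c, d)
  base_p <- prr_stats(a, b, c, d)
  base_e <- ebgm_stats(a, b, c, d)
  for (k in c(2, 10)) {
    r <- ror_stats(k * a, k * b, k * c, k * d)
    p <- prr_stats(k * a, k * b, k * c, k * d)
    e <- ebgm_stats(k * a, k * b, k * c, k * d)
    expect_equal(r$ror, base_r$ror, tolerance = 1e-12)
    expect_equal(p$prr, base_p$prr, tolerance = 1e-12)
    expect_equal(e$ebgm, base_e$ebgm, tolerance = 1e-12)
    expect_lt(r$ror_hi - r$ror_lo, base_r$ror_hi - base_r$ror_lo)
  }
})

test_that("zero cells flag estimates as undefined without corrections", {
  expect_true(is.na(ror_stats(0, 10, 10, 10)$ror))
  expect_true(is.na(prr_stats(5, 5, 0, 10)$prr))
  # a = 0: observed IC undefined, posterior moments finite (priors dominate)
  bc <- bcpnn_stats(0, 10, 10, 100)
  expect_true(is.na(bc$ic))
  expect_true(is.finite(bc$e_ic))
  expect_true(is.finite(bc$v_ic))
})

test_that("signal flags follow the four algorithm standards", {
  # a = 2 with a huge ROR still fails the support condition a >= 3
  m <- signal_metrics(tibble::tibble(pt = "X", a = 2, b = 10, c = 2,
                                     d = 10000))
  expect_false(m$ror_pos)
  expect_false(m$combined_pos)
  # independence: every flag off
  m0 <- signal_metrics(tibble::tibble(pt = "X", a = 10, b = 10, c = 10,
                                      d = 10))
  expect_false(any(m0$ror_pos, m0$prr_pos, m0$bcpnn_pos, m0$mgps_pos,
                   m0$combined_pos))
  # a strong association fires all four, and the combined call is their
  # conjunction
  ms <- signal_metrics(tibble::tibble(pt = "X", a = 40, b = 460, c = 60,
                                      d = 9440))
  expect_true(all(ms$ror_pos, ms$prr_pos, ms$bcpnn_pos, ms$mgps_pos))
  expect_equal(ms$combined_pos,
               ms$ror_pos & ms$prr_pos & ms$bcpnn_pos & ms$mgps_pos)
  # Bonferroni: p_adj = min(1, m * p_raw) with m = PTs observed (a >= 1)
  tbl <- tibble::tibble(pt = c("X", "Y", "Z"), a = c(5, 3, 0),
                        b = c(95, 97, 100), c = c(50, 80, 40),
                        d = c(4950, 4920, 4960))
  mm <- signal_metrics(tbl)
  expect_equal(attr(mm, "m_tests"), 2)
  expect_equal(mm$p_adj, pmin(1, 2 * mm$p_raw))
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  withr::with_seed(5, {
    for (i in 1:40) {
      cells <- as.vector(stats::rmultinom(1, sample(10:60, 1), rep(0.25, 4)))
      p_pkg <- pvkit:::.fisher_p(cells[1], cells[2], cells[3], cells[4])
      p_or <- oracle_fisher_p(cells[1], cells[2], cells[3], cells[4])
      expect_equal(p_pkg, p_or, tolerance = 1e-9)
    }
  })
})

test_that("contingency cells match a brute-force recount of the raw rows", {
  cfg <- small_config(seed = 7, n_cases = 500)
  tab <- generate_tables(cfg)
  ds <- assemble_dataset(tab)
  cells <- pt_contingency(ds)
  # recount independently from the raw generated rows
  surv <- tab$ground_truth$surviving
  reac <- dplyr::distinct(tab$reac[tab$reac$primaryid %in% surv$primaryid, ],
                          primaryid, pt)
  target_flag <- tab$ground_truth$target_flag
  reac$target <- target_flag$is_target[
    match(substr(reac$primaryid, 1, 7), target_flag$caseid)]
  tot_t <- sum(reac$target)
  tot_o <- sum(!reac$target)
  for (pt in c("HYPONATRAEMIA", "SEIZURE", "DRUG INEFFECTIVE")) {
    a <- sum(reac$target & reac$pt == pt)
    c_ <- sum(!reac$target & reac$pt == pt)
    row <- cells[cells$pt == pt, ]
    expect_equal(row$a, a)
    expect_equal(row$c, c_)
    expect_equal(row$b, tot_t - a)
    expect_equal(row$d, tot_o - c_)
  }
  # margins are constant across PTs (conservation)
  expect_equal(unique(cells$a + cells$b), tot_t)
  expect_equal(unique(cells$c + cells$d), tot_o)
  # a PT absent everywhere still yields a valid all-zero-a table
  absent <- pt_contingency(ds, pts = "NO SUCH TERM")
  expect_equal(absent$a, 0L)
  expect_equal(absent$c, 0L)
})

test_that("two PTs on one target report each count that report once", {
  demo <- toy_demo(caseid = 1:2, primaryid = 1:2, fda_dt = "20200101")
  drug <- dplyr::bind_rows(toy_drug(1, "APTIOM"),
                           toy_drug(2, "CARBAMAZEPINE"))
  reac <- toy_reac(c(1, 1, 2), c("SEIZURE", "RASH", "SEIZURE"))
  ds <- assemble_dataset(toy_raw(demo = demo, drug = drug, reac = reac))
  cells <- pt_contingency(ds)
  expect_equal(cells$a[cells$pt == "SEIZURE"], 1L)
  expect_equal(cells$a[cells$pt == "RASH"], 1L)
  # single-PT toy case from first principles: one target report with only X,
  # one comparator report without X
  ds2 <- assemble_dataset(toy_raw(
    demo = toy_demo(caseid = 3:4, primaryid = 3:4, fda_dt = "20200101"),
    drug = dplyr::bind_rows(toy_drug(3, "APTIOM"),
                            toy_drug(4, "CARBAMAZEPINE")),
    reac = toy_reac(3:4, c("X", "Y"))))
  cx <- pt_contingency(ds2, pts = "X")
  expect_equal(unlist(cx[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 0L, 0L, 1L))
})

test_that("volcano coordinates are the plain monotone transforms", {
  m <- tibble::tibble(pt = c("A", "B", "C"), ror = c(1, 8, NA),
                      p_adj = c(1, 0.01, 0.5),
                      combined_pos = c(FALSE, TRUE, FALSE))
  v <- volcano_table(m)
  expect_equal(v$pt, c("A", "B"))  # undefined ROR drops out
  expect_equal(v$log2_ror, c(0, 3))
  expect_equal(v$neg_log10_p_adj, c(0, 2))
})

test_that("group aggregation recounts distinct report-group pairs", {
  maps <- load_term_maps()
  demo <- toy_demo(caseid = 1:4, primaryid = 1:4, fda_dt = "20200101")
  drug <- dplyr::bind_rows(toy_drug(1, "APTIOM"), toy_drug(2, "APTIOM"),
                           toy_drug(3, "CARBAMAZEPINE"),
                           toy_drug(4, "CARBAMAZEPINE"))
  # report 1 has two nervous-system PTs -> one (report, SOC) pair
  reac <- toy_reac(c(1, 1, 1, 2, 3, 4),
                   c("SEIZURE", "DIZZINESS", "MYSTERY TERM",
                     "HYPONATRAEMIA", "SEIZURE", "NAUSEA"))
  ds <- assemble_dataset(toy_raw(demo = demo, drug = drug, reac = reac))
  soc <- aggregate_by_group(ds, maps, "soc")
  expect_equal(soc$a[soc$group == "Nervous system disorders"], 1L)
  expect_equal(soc$a[soc$group == "Metabolism and nutrition disorders"], 1L)
  # unmapped PTs are reported, not silently dropped
  expect_true("UNMAPPED" %in% soc$group)
  # SMQ grouping: restricted to the positive set, narrow scope only,
  # PTs in two narrow SMQs contribute to both
  pos <- c("DERMATITIS EXFOLIATIVE", "STEVENS-JOHNSON SYNDROME")
  demo2 <- toy_demo(caseid = 5:8, primaryid = 5:8, fda_dt = "20200101")
  drug2 <- dplyr::bind_rows(toy_drug(5, "APTIOM"), toy_drug(6, "APTIOM"),
                            toy_drug(7, "CARBAMAZEPINE"),
                            toy_drug(8, "CARBAMAZEPINE"))
  reac2 <- toy_reac(c(5, 6, 7, 8),
                    c("DERMATITIS EXFOLIATIVE", "STEVENS-JOHNSON SYNDROME",
                      "RASH", "NAUSEA"))
  ds2 <- assemble_dataset(toy_raw(demo = demo2, drug = drug2, reac = reac2))
  smq <- aggregate_by_group(ds2, maps, "smq", positive_pts = pos)
  expect_setequal(smq$group,
                  c("Hypersensitivity", "Severe cutaneous adverse reactions"))
  expect_equal(smq$n_member_pts, c(2L, 2L))
  expect_equal(smq$a, c(2L, 2L))
})
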