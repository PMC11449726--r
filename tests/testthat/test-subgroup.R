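# Sex-stratified reporting odds ratios, age-group assignment, and the
# per-PT logistic models.

# A target-only toy dataset with controllable sex/age/PT structure.
subgroup_dataset <- function(sex, age, has_pt, pt = "SEIZURE") {
  n <- length(sex)
  demo <- toy_demo(caseid = seq_len(n), primaryid = seq_len(n),
                   fda_dt = "20200101", sex = sex, age = age)
  drug <- toy_drug(seq_len(n), "APTIOM")
  reac <- dplyr::bind_rows(
    toy_reac(which(has_pt), pt),
    toy_reac(seq_len(n), "DRUG INEFFECTIVE"))  # every report needs >= 1 PT
  assemble_dataset(toy_raw(demo = demo, drug = drug, reac = reac))
}

test_that("sex_ror matches the cross-product on report-level cells", {
  # 200 males (20 with the PT), 200 females (10 with it)
  sex <- rep(c("M", "F"), each = 200)
  has <- c(rep(c(TRUE, FALSE), c(20, 180)), rep(c(TRUE, FALSE), c(10, 190)))
  ds <- subgroup_dataset(sex, age = 40, has_pt = has)
  out <- sex_ror(ds, "SEIZURE")
  expect_equal(unlist(out[, c("a", "b", "c", "d")], use.names = FALSE),
               c(20, 180, 10, 190))
  expect_equal(out$ror, (20 * 190) / (180 * 10))
  o <- oracle_metrics(20, 180, 10, 190)
  expect_equal(out$ror_lo, o$ror_lo, tolerance = 1e-12)
  expect_equal(out$ror_hi, o$ror_hi, tolerance = 1e-12)
})

test_that("sex_ror is antisymmetric under stratum swap and null at equality", {
  sex <- rep(c("M", "F"), each = 100)
  has <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 30, 70))
  ds <- subgroup_dataset(sex, age = 40, has_pt = has)
  out <- sex_ror(ds, "SEIZURE")
  expect_equal(out$ror, 1)
  expect_false(out$sex_differential)
  # swapping the strata labels inverts the estimate and swaps the CI bounds
  sex2 <- rep(c("F", "M"), each = 100)
  has2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 60, 15, 85))
  ds_a <- subgroup_dataset(rep(c("M", "F"), each = 100), age = 40,
                           has_pt = has2)
  ds_b <- subgroup_dataset(sex2, age = 40, has_pt = has2)
  ra <- sex_ror(ds_a, "SEIZURE")
  rb <- sex_ror(ds_b, "SEIZURE")
  expect_equal(ra$ror, 1 / rb$ror, tolerance = 1e-12)
  expect_equal(ra$ror_lo, 1 / rb$ror_hi, tolerance = 1e-12)
  expect_equal(ra$ror_hi, 1 / rb$ror_lo, tolerance = 1e-12)
})

test_that("zero cells make the sex contrast inestimable", {
  sex <- rep(c("M", "F"), each = 50)
  has <- c(rep(TRUE, 5), rep(FALSE, 95))  # no female events
  ds <- subgroup_dataset(sex, age = 40, has_pt = has)
  out <- sex_ror(ds, "SEIZURE")
  expect_false(out$estimable)
  expect_true(is.na(out$ror))
})

test_that("unknown sex is excluded from the sex-stratified table", {
  sex <- c(rep("M", 50), rep("F", 50), rep("UNK", 40))
  has <- rep(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
             c(10, 40, 5, 45, 20, 20))
  ds <- subgroup_dataset(sex, age = 40, has_pt = has)
  out <- sex_ror(ds, "SEIZURE")
  expect_equal(out$a + out$b, 50)
  expect_equal(out$c + out$d, 50)
})

test_that("age groups split at 18 and 65 with unknowns kept apart", {
  expect_equal(assign_age_group(c(17.9, 18, 64.9, 65, 90, NA)),
               c("children", "adult", "adult", "elderly", "elderly",
                 "unknown"))
})

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  withr::with_seed(31, {
    age <- c(runif(150, 2, 17), runif(300, 20, 60), runif(150, 66, 88))
    has <- runif(600) < ifelse(age < 18, 0.25, ifelse(age < 65, 0.10, 0.18))
    sex <- sample(c("M", "F"), 600, replace = TRUE)
  })
  ds <- subgroup_dataset(sex, age = round(age, 1), has_pt = has)
  out <- logistic_or(ds, "SEIZURE", adjust = TRUE)
  grp <- assign_age_group(round(age, 1))
  for (g in c("children", "elderly")) {
    a <- sum(has & grp == g); b <- sum(!has & grp == g)
    c_ <- sum(has & grp == "adult"); d <- sum(!has & grp == "adult")
    row <- out[out$contrast == paste0(g, "_vs_adult"), ]
    expect_true(row$estimable)
    expect_equal(row$crude_or, (a * d) / (b * c_), tolerance = 1e-6)
  }
})

test_that("adjusted and crude ORs coincide when sex is independent of both", {
  # sex balanced and unrelated to outcome or age: adjustment changes nothing
  withr::with_seed(77, {
    n <- 4000
    age <- c(runif(n / 4, 2, 17), runif(n / 2, 20, 60), runif(n / 4, 66, 88))
    sex <- rep(c("M", "F"), n / 2)
    has <- runif(n) < ifelse(age < 18, 0.3, 0.1)
  })
  ds <- subgroup_dataset(sex, age = round(age, 1), has_pt = has)
  out <- logistic_or(ds, "SEIZURE", adjust = TRUE)
  row <- out[out$contrast == "children_vs_adult", ]
  expect_equal(row$adj_or, row$crude_or, tolerance = 0.02)
})

test_that("contrasts with an empty arm are flagged inestimable", {
  withr::with_seed(9, {
    age <- c(runif(50, 2, 17), runif(200, 20, 60), runif(50, 66, 88))
    grp <- assign_age_group(age)
    has <- runif(300) < 0.15
    has[grp == "elderly"] <- FALSE  # PT absent in the elderly arm
    sex <- sample(c("M", "F"), 300, replace = TRUE)
  })
  ds <- subgroup_dataset(sex, age = round(age, 1), has_pt = has)
  out <- logistic_or(ds, "SEIZURE")
  eld <- out[out$contrast == "elderly_vs_adult", ]
  expect_false(eld$estimable)
  expect_true(is.na(eld$crude_or))
  expect_equal(eld$reason, "zero_events_in_arm")
  # the other contrast is unaffected
  expect_true(out$estimable[out$contrast == "children_vs_adult"])
})

test_that("reports with unknown age or sex are excluded from the models", {
  sex <- c(rep("M", 100), rep("F", 100), rep("UNK", 50))
  age <- c(rep(10, 50), rep(40, 100), rep(70, 50), rep(NA, 50))
  has <- rep(c(TRUE, FALSE), 125)
  ds <- subgroup_dataset(sex, age = age, has_pt = has)
  out <- logistic_or(ds, "SEIZURE")
  known <- !is.na(age) & sex %in% c("M", "F")
  grp <- assign_age_group(age)
  expect_equal(out$n_events_adult[1], sum(has & known & grp == "adult"))
})
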