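test_that("Gower dissimilarity matches hand computations", {
  a <- data.frame(age = 60, sex = "F", fall = 0)
  b <- data.frame(age = 70, sex = "M", fall = 0)
  d <- gower_distance(a, b, c("age", "sex", "fall"),
                      ranges = list(age = 50, sex = NA, fall = NA))
  expect_equal(d, (10 / 50 + 1 + 0) / 3)   # = 0.4
  expect_equal(gower_distance(a, a, c("age", "sex", "fall"),
                              ranges = list(age = 50, sex = NA, fall = NA)),
               0)
  # categorical mismatch in every variable
  x <- data.frame(sex = "F", dep = "ED")
  y <- data.frame(sex = "M", dep = "inpatient")
  expect_equal(gower_distance(x, y, c("sex", "dep")), 1)
  # missing components are skipped and the mean renormalized
  a2 <- data.frame(age = 60, sex = NA, fall = 0)
  expect_equal(gower_distance(a2, b, c("age", "sex", "fall"),
                              ranges = list(age = 50, sex = NA, fall = NA)),
               (10 / 50 + 0) / 2)
  # all components missing: maximally unlike
  a3 <- data.frame(age = NA, sex = NA)
  expect_equal(gower_distance(a3, b, c("age", "sex"),
                              ranges = list(age = 50, sex = NA)), 1)
  expect_error(gower_distance(a, b, character()), "non-empty")
})

test_that("Gower agrees with cluster::daisy on complete mixed data", {
  skip_if_not_installed("cluster")
  set.seed(31)
  n <- 15
  d <- data.frame(age = runif(n, 40, 90),
                  bmi = runif(n, 18, 40),
                  sex = factor(sample(c("F", "M"), n, TRUE)),
                  fall = factor(sample(0:1, n, TRUE)))
  vars <- names(d)
  ranges <- list(age = diff(range(d$age)), bmi = diff(range(d$bmi)),
                 sex = NA, fall = NA)
  D_daisy <- as.matrix(cluster::daisy(d, metric = "gower"))
  for (i in 1:4) for (j in 5:9) {
    ours <- gower_distance(d[i, ], d[j, ], vars, ranges)
    expect_equal(ours, D_daisy[i, j], tolerance = 1e-10)
  }
})

test_that("an exact covariate duplicate is always the selected control", {
  d <- data.frame(
    image_id = c("c1", "k1", "k2"),
    fracture = c(1, 0, 0),
    age = c(70, 70, 30),
    sex = c("F", "F", "M"),
    bmi = c(25, 25, 40),
    fall = c(1, 1, 0), pain = c(0, 0, 1),
    stringsAsFactors = FALSE)
  m <- match_controls(d, level = "pt", seed = 1)
  expect_equal(m$pairs$control_id, "k1")
  expect_equal(m$pairs$dissimilarity, 0)
})

test_that("matched cohorts are 1:1 with 50% prevalence, sampled without replacement", {
  co <- simulate_cohort(small_sim(seed = 19))
  imp <- impute(filter_infeasible(co))$table
  for (lv in c("random", "demographics", "pt")) {
    m <- match_controls(imp, level = lv, seed = 3)
    expect_equal(nrow(m$pairs), sum(imp$fracture == 1 &
                                      imp$partition == "test"))
    expect_false(any(duplicated(m$pairs$control_id)))
    expect_equal(mean(m$records$fracture), 0.5)
    expect_true(all(m$records$partition == "test"))
    expect_true(all(imp$fracture[match(m$pairs$case_id,
                                       imp$image_id)] == 1))
    expect_true(all(imp$fracture[match(m$pairs$control_id,
                                       imp$image_id)] == 0))
  }
})

test_that("greedy assignment matches exhaustive enumeration on a toy pool", {
  # two cases share a nearest control: first in processing order takes it,
  # the second gets its runner-up; verified against brute-force greedy
  # enumeration over both processing orders
  d <- data.frame(
    image_id = c("caseA", "caseB", "k1", "k2", "k3"),
    fracture = c(1, 1, 0, 0, 0),
    age = c(50, 52, 51, 60, 80),
    sex = "F", bmi = 25, fall = 0, pain = 0,
    stringsAsFactors = FALSE)
  vars <- match_variables("pt")
  ranges <- list(age = 30, sex = NA, bmi = NA, fall = NA, pain = NA)
  cases <- d[d$fracture == 1, ]; ctrls <- d[d$fracture == 0, ]
  D <- outer(1:2, 1:3, Vectorize(function(i, j)
    gower_distance(cases[i, ], ctrls[j, ], vars, ranges)))
  greedy_oracle <- function(order) {
    used <- rep(FALSE, 3); out <- character(2)
    for (i in order) {
      dd <- D[i, ]; dd[used] <- Inf
      j <- which(dd == min(dd))
      j <- j[order(ctrls$image_id[j])][1]
      used[j] <- TRUE
      out[i] <- ctrls$image_id[j]
    }
    out
  }
  for (s in 1:6) {
    m <- match_controls(d, level = "pt", seed = s)
    ord <- withr::with_seed(s %% 2147483647, sample(2))
    want <- greedy_oracle(ord)
    got <- m$pairs$control_id[match(c("caseA", "caseB"), m$pairs$case_id)]
    expect_equal(got, want)
  }
  # both orders resolve the contested control to the first case processed
  expect_setequal(greedy_oracle(1:2), c("k1", "k2"))
  expect_setequal(greedy_oracle(2:1), c("k1", "k2"))
})

test_that("ties break on the smallest control image_id", {
  d <- data.frame(
    image_id = c("case", "z9", "a1"),
    fracture = c(1, 0, 0),
    age = c(70, 70, 70), sex = "F", bmi = 25, fall = 0, pain = 0,
    stringsAsFactors = FALSE)
  m <- match_controls(d, level = "pt", seed = 5)
  expect_equal(m$pairs$control_id, "a1")
  expect_error(match_controls(d[d$fracture == 0, ], level = "pt"),
               "no fracture cases")
})

test_that("matching improves covariate balance over random sampling", {
  res <- collapse_run(1)
  expect_lte(res$balance[["pt_hp"]], res$balance[["random"]])
})

test_that("cohort summary matches hand arithmetic", {
  d <- data.frame(image_id = 1:4, patient_id = c("p1", "p1", "p2", "p3"),
                  fracture = c(1, 0, 0, 1),
                  age = c(80, 60, 70, 90), sex = c("F", "F", "M", "F"),
                  bmi = c(20, 30, 25, NA), fall = c(1, 0, 0, 1),
                  pain = c(0, 1, 1, 0),
                  scanner_model = c("A", "A", "B", "C"),
                  stringsAsFactors = FALSE)
  s <- cohort_summary(list(toy = d))
  expect_equal(s["n_radiographs", "toy"], 4)
  expect_equal(s["n_patients", "toy"], 3)
  expect_equal(s["n_scanners", "toy"], 3)
  expect_equal(s["age_mean", "toy"], 75)
  expect_equal(s["age_sd", "toy"], round(sd(c(80, 60, 70, 90)), 2))
  expect_equal(s["female_pct", "toy"], 75)
  expect_equal(s["fracture_pct", "toy"], 50)
  expect_equal(s["bmi_mean", "toy"], 25)
  # one fracture + one control: 50%
  s2 <- cohort_summary(list(pair = d[1:2, ]))
  expect_equal(s2["fracture_pct", "pair"], 50)
})
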