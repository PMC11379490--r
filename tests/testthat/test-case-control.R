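test_that("case selection follows the outcome hierarchy", {
  tab <- make_participants(4, qrisk2 = 10, event = 1,
                           event_type = c("mi_acs;stroke",
                                          "stroke,cvd_death",
                                          "pci_cabg", "stroke"))
  cases <- select_cases(tab)
  expect_equal(cases$event_type,
               c("mi_acs", "cvd_death", "pci_cabg", "stroke"))
  tab$event_type[1] <- "angina"
  expect_error(select_cases(tab), "unknown event label")
})

test_that("planted label mix is returned exactly", {
  mix <- c(cvd_death = 11, mi_acs = 113, pci_cabg = 25, stroke = 46)
  labels <- rep(names(mix), mix)
  tab <- make_participants(300, qrisk2 = 10)
  tab$event[seq_along(labels)] <- 1
  tab$event_type[seq_along(labels)] <- sample(labels)
  cases <- select_cases(tab)
  expect_equal(attr(cases, "label_counts"), mix)
  expect_equal(nrow(cases), 195)
})

test_that("an event-free table yields an empty case set with a warning", {
  tab <- make_participants(10, qrisk2 = 8)
  expect_warning(cases <- select_cases(tab), "empty case set")
  expect_equal(nrow(cases), 0)
})

test_that("null-covariate propensity scores concentrate at the case fraction", {
  set.seed(111)
  n <- 4000
  tab <- make_participants(n, qrisk2 = runif(n, 2, 25))
  tab$age <- runif(n, 40, 74)
  tab$bmi <- rnorm(n, 28, 4)
  tab$sex <- sample(c("male", "female"), n, replace = TRUE)
  tab$smoking <- sample(c("current", "ex", "never"), n, replace = TRUE)
  tab$ethnicity <- sample(c("white", "non-white"), n, replace = TRUE)
  tab$event <- rbinom(n, 1, 0.1)  # independent of all covariates
  ps <- fit_propensity(tab)
  expect_lt(abs(mean(ps) - mean(tab$event)), 0.01)
  expect_lt(sd(ps), 0.05)

  # duplicated covariate rows must receive identical scores
  tab2 <- tab
  tab2[2, setdiff(names(tab2), c("id", "event"))] <-
    tab2[1, setdiff(names(tab2), c("id", "event"))]
  ps2 <- fit_propensity(tab2)
  expect_equal(ps2[1], ps2[2], tolerance = 1e-10)
})

test_that("a planted age effect drives the propensity monotonically", {
  set.seed(112)
  n <- 3000
  tab <- make_participants(n, qrisk2 = runif(n, 2, 25))
  tab$age <- runif(n, 40, 74)
  tab$bmi <- rnorm(n, 28, 4)
  tab$event <- rbinom(n, 1, plogis(-4 + 0.08 * (tab$age - 57)))
  ps <- fit_propensity(tab)
  expect_gt(cor(ps, tab$age), 0.8)
})

test_that("missing covariates are rejected up front", {
  tab <- make_participants(10, qrisk2 = 10)
  tab$bmi[3] <- NA
  expect_error(fit_propensity(tab), "complete")
  tab$bmi <- NULL
  expect_error(fit_propensity(tab), "missing covariate")
})

test_that("SMD matches closed forms and the direct formula", {
  g <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(smd(rep(1:2, 50), g), 0)
  x <- c(rnorm(50, 0, 1), rnorm(50, 1, 1))
  set.seed(113)
  x <- c(rnorm(500, 0, 1), rnorm(500, 1, 1))
  g <- rep(c(TRUE, FALSE), each = 500)
  direct <- abs(mean(x[1:500]) - mean(x[501:1000])) /
    sqrt((var(x[1:500]) + var(x[501:1000])) / 2)
  expect_equal(smd(x, g), direct, tolerance = 1e-12)

  # exact closed form: means 0 and 1, both SD exactly 1
  a <- c(-1, 0, 1); b <- c(0, 1, 2)
  expect_equal(smd(c(a, b), rep(c(TRUE, FALSE), each = 3)), 1.0)

  # categorical: per-level binary SMD aggregated as the maximum
  v <- c(rep("x", 30), rep("y", 70), rep("x", 50), rep("y", 50))
  g2 <- rep(c(TRUE, FALSE), each = 100)
  p1 <- 0.3; p2 <- 0.5
  expect_equal(smd(v, g2),
               abs(p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2))

  expect_warning(s <- smd(c(0, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE)),
                 "infinite")
  expect_true(is.infinite(s))
  expect_error(smd(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("greedy matching reproduces the hand solution on a line", {
  # each case has two dedicated neighbours; solution is order-invariant
  cases <- make_participants(3, qrisk2 = 10)
  cases$id <- c("c1", "c2", "c3")
  pool <- make_participants(6, qrisk2 = 10)
  pool$id <- paste0("p", 1:6)
  ps_cases <- c(0.20, 0.50, 0.80)
  ps_pool <- c(0.21, 0.19, 0.51, 0.49, 0.81, 0.79)
  des <- match_controls(cases, pool, ps_cases, ps_pool, ratio = 2,
                        caliper = 1, seed = 42)
  got <- split(des$matches$control_id, des$matches$case_id)
  expect_setequal(got$c1, c("p1", "p2"))
  expect_setequal(got$c2, c("p3", "p4"))
  expect_setequal(got$c3, c("p5", "p6"))
  expect_equal(des$achieved_ratio, 2)
})

test_that("matching is without replacement and exact copies balance to SMD 0", {
  set.seed(114)
  n <- 40
  cases <- make_participants(n, qrisk2 = runif(n, 5, 20))
  cases$age <- runif(n, 40, 74)
  cases$id <- paste0("c", 1:n)
  pool <- rbind(cases, cases)
  pool$id <- paste0("p", 1:(2 * n))
  ps_c <- plogis(-1 + 0.05 * (cases$age - 57))
  des <- match_controls(cases, pool, ps_c, rep(ps_c, 2), ratio = 2,
                        seed = 7)
  expect_equal(anyDuplicated(des$control_ids), 0L)
  expect_equal(length(des$control_ids), 2 * n)
  expect_true(all(des$smd_table$smd_after < 1e-10))
})

test_that("a zero caliper with no exact ties matches nothing", {
  cases <- make_participants(2, qrisk2 = 10)
  cases$id <- c("c1", "c2")
  pool <- make_participants(4, qrisk2 = 10)
  pool$id <- paste0("p", 1:4)
  des <- match_controls(cases, pool, c(0.3, 0.6),
                        c(0.31, 0.29, 0.61, 0.59), ratio = 2, caliper = 0,
                        seed = 1)
  expect_equal(nrow(des$matches), 0)
  expect_setequal(des$unmatched_cases, c("c1", "c2"))
  expect_error(match_controls(cases, pool[0, ], c(0.3, 0.6), numeric(0)),
               "empty")
})

test_that("matching on an overlapping synthetic cohort balances covariates", {
  cfg <- sim_config(n_subjects = 4000, n_variants = 30, seed = 115)
  gm <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, gm, simulate_weights(gm, seed = 116))
  ps <- fit_propensity(coh)
  cases <- select_cases(coh)
  pool <- coh[coh$event == 0, ]
  des <- match_controls(cases, pool, ps[coh$event == 1],
                        ps[coh$event == 0], seed = 117)
  expect_true(all(des$smd_table$smd_after < 0.1))
  expect_lte(des$achieved_ratio, 2)
})
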