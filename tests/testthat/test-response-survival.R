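traj <- function(lesion, d, times = c(0, 90), is_new = FALSE) {
  data.frame(patient = "p", lesion = lesion, time_days = times,
             diameter_mm = d, is_new = is_new)
}

test_that("per-lesion change hits the RECIST-style thresholds", {
  lc <- lesion_change(traj("a", c(20, 12)))
  expect_equal(lc$best_change_pct, -40)
  expect_equal(lc$category, "regressing")
  lc <- lesion_change(traj("a", c(20, 25)))
  expect_equal(lc$worst_change_pct, 25)
  expect_equal(lc$category, "progressing")
  lc <- lesion_change(traj("a", c(20, 14.5)))  # -27.5%: stable
  expect_equal(lc$category, "stable")
  # a new lesion is progression regardless of size
  lc <- lesion_change(data.frame(patient = "p", lesion = "n", time_days = 90,
                                 diameter_mm = 8, is_new = TRUE))
  expect_true(lc$progressing)
  expect_true(lc$is_new)
  # scans outside the window are ignored
  lc <- lesion_change(traj("a", c(20, 20, 10), times = c(0, 90, 300)))
  expect_equal(lc$category, "stable")
  # no post-baseline scan: inevaluable
  lc <- lesion_change(traj("a", 20, times = 0))
  expect_false(lc$evaluable)
})

test_that("a lesion regressing then progressing counts for both flags", {
  lc <- lesion_change(traj("a", c(20, 12, 26), times = c(0, 60, 120)))
  expect_true(lc$regressing)
  expect_true(lc$progressing)
  expect_equal(lc$category, "progressing")
  # and the patient is a mixed responder off this single lesion
  expect_equal(classify_response(traj("a", c(20, 12, 26),
                                      times = c(0, 60, 120))),
               "mixed_responder")
})

test_that("response trichotomy follows the group definitions", {
  two <- function(d1, d2) rbind(traj("a", d1), traj("b", d2))
  expect_equal(classify_response(two(c(20, 12), c(20, 13))),
               "nonmixed_responder")
  expect_equal(classify_response(two(c(20, 12), c(20, 26))),
               "mixed_responder")
  expect_equal(classify_response(two(c(20, 25), c(20, 28))),
               "nonmixed_nonresponder")
  # regression plus a new lesion is mixed
  les <- rbind(traj("a", c(20, 12)),
               data.frame(patient = "p", lesion = "n", time_days = 90,
                          diameter_mm = 5, is_new = TRUE))
  expect_equal(classify_response(les), "mixed_responder")
  # all stable: outside the three-group taxonomy
  expect_equal(classify_response(two(c(20, 18), c(20, 21))),
               "stable_unclassified")
  # lesion order never changes the group
  expect_equal(classify_response(two(c(20, 26), c(20, 12))),
               "mixed_responder")
})

test_that("tumor burden sums measured lesions at a scan", {
  les <- rbind(traj("a", c(10, 8)), traj("b", c(20, 15)), traj("c", c(15, 9)))
  expect_equal(tumor_burden(les, 0), 45)
  expect_equal(tumor_burden(les, 90), 32)
  expect_equal(tumor_burden(les, 999), 0)
})

test_that("simplified RECIST categories follow burden thresholds", {
  expect_equal(recist_category(traj("a", c(50, 30))), "PR")   # -40%
  expect_equal(recist_category(traj("a", c(50, 40))), "SD")   # -20%
  expect_equal(recist_category(traj("a", c(50, 0))), "CR")
  expect_equal(recist_category(traj("a", c(50, 61))), "PD")   # +22%
  les <- rbind(traj("a", c(50, 50)),
               data.frame(patient = "p", lesion = "n", time_days = 90,
                          diameter_mm = 6, is_new = TRUE))
  expect_equal(recist_category(les), "PD")  # new lesion at stable burden
  # progression from nadir: 50 -> 30 -> 40 is +33% from nadir
  expect_equal(recist_category(traj("a", c(50, 30, 40),
                                    times = c(0, 60, 120))), "PD")
})

test_that("KM estimator equals hand product-limit and empirical survival", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km_survival_at(km, 2), 1 / 3)
  expect_equal(km$median, 2)
  # all censored: flat at 1
  km2 <- km_estimate(c(5, 8, 9), c(0, 0, 0))
  expect_equal(km_survival_at(km2, 100), 1)
  expect_true(is.na(km2$median))
  # hand-worked n = 6 with censoring
  t6 <- c(1, 2, 2, 3, 4, 5); e6 <- c(1, 0, 1, 1, 0, 1)
  km3 <- km_estimate(t6, e6)
  for (at in c(0.5, 1, 2, 3, 4.5, 5)) {
    expect_equal(km_survival_at(km3, at), oracle_km(t6, e6, at))
  }
  # zero censoring: S(t) is the empirical fraction surviving past t
  set.seed(51)
  tt <- rexp(200)
  km4 <- km_estimate(tt, rep(1, 200))
  for (at in quantile(tt, c(0.1, 0.5, 0.9))) {
    expect_equal(km_survival_at(km4, at), mean(tt > at))
  }
  expect_true(all(diff(km4$survival) <= 0))
})

test_that("KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(53)
  tt <- round(rexp(80, 1 / 300)); ev <- rbinom(80, 1, 0.7)
  grp <- sample(c("x", "y"), 80, TRUE)
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  km <- km_estimate(tt, ev)
  expect_equal(km_survival_at(km, fit$time), fit$surv, tolerance = 1e-12)
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  lr <- logrank_test(grp, tt, ev)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-8)
  expect_equal(unname(lr$observed), unname(sd_$obs), tolerance = 1e-12)
  expect_equal(unname(lr$expected), unname(sd_$exp), tolerance = 1e-8)
})

test_that("log-rank is null on identical groups and powered under HR 3", {
  tt <- rep(c(3, 6, 9, 12, 15), 2)
  grp <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(grp, tt, rep(1, 10))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(rep("a", 5), 1:5, rep(1, 5)), "two groups")
  set.seed(57)
  hits <- vapply(1:25, function(i) {
    t1 <- rexp(200, 1); t2 <- rexp(200, 3)
    logrank_test(rep(c("a", "b"), each = 200), c(t1, t2),
                 rep(1, 400))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank p is uniform under label permutation", {
  set.seed(59)
  tt <- rexp(60); ev <- rep(1, 60)
  ps <- vapply(1:300, function(i) {
    logrank_test(sample(rep(c("a", "b"), each = 30)), tt, ev)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort summary reproduces printed-percentage arithmetic", {
  # 70 mixed of 503 -> 13.9%; 13 of 70 locally treated -> 18.6%
  expect_equal(lesionscope:::round_half_up(100 * 70 / 503), 13.9)
  expect_equal(lesionscope:::round_half_up(100 * 13 / 70), 18.6)
  expect_equal(lesionscope:::round_half_up(100 * 0 / 10), 0)
  # half-up, not banker's
  expect_equal(lesionscope:::round_half_up(0.25, 1), 0.3)
})

test_that("synthetic cohort is re-classified with full agreement", {
  sim <- sim_cohort(sim_config(seed = 61, cohort_sizes = c(melanoma = 60,
                                                           NSCLC = 60),
                               group_proportions = c(
                                 nonmixed_responder = 0.4,
                                 mixed_responder = 0.2,
                                 nonmixed_nonresponder = 0.4)))
  cs <- cohort_summary(sim$lesions, sim$patients)
  expect_identical(cs$classified$response_group, sim$truth$planted_group)
  expect_equal(cs$pooled$n, 120)
  sv <- compare_survival(cs$classified, "os")
  expect_named(sv$fits, sort(unique(sim$truth$planted_group)))
  expect_lt(sv$logrank$p_value, 0.05)
})

test_that("cohort CSV round trip feeds the classifier unchanged", {
  sim <- sim_cohort(sim_config(seed = 63, cohort_sizes = c(melanoma = 20)))
  dir <- tempfile(); write_sim_inputs(sim, dir)
  lesions <- read_lesions_csv(file.path(dir, "lesions.csv"))
  patients <- read_patients_csv(file.path(dir, "patients.csv"))
  cs1 <- cohort_summary(sim$lesions, sim$patients)
  cs2 <- cohort_summary(lesions, patients)
  expect_identical(cs1$classified$response_group,
                   cs2$classified$response_group)
})
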