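# a deterministic toy record set: 12 subjects in two colonies, interval
# times 1..3, covariate loosely tied to the event pattern
toy_records <- function() {
  tibble::tibble(
    subject_id = paste0("s", 1:12),
    colony_id = rep(c("c1", "c2"), each = 6),
    timepoint = "2012-summer",
    start = 0,
    stop = c(1, 1, 2, 2, 3, 3, 1, 2, 2, 3, 3, 3),
    event = c(1, 0, 1, 0, 1, 0, 1, 1, 0, 1, 0, 0),
    betweenness = c(.1, .6, .3, .9, .8, .4, .15, .3, .7, .45, .2, .95)
  )
}

test_that("fit_extended_cox agrees with a direct coxph fit", {
  recs <- toy_records()
  fit <- fit_extended_cox(recs, "betweenness")
  direct <- survival::coxph(
    survival::Surv(start, stop, event) ~ betweenness + factor(colony_id),
    data = recs, ties = "efron")
  expect_equal(fit$coefficients$beta[1], unname(coef(direct)[1]))
  expect_equal(fit$n_rows, 12)
  expect_equal(fit$n_events, 6)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic"))
  gl <- glance(fit)
  expect_equal(gl$n_events, 6)
  expect_gt(nrow(fit$baseline), 0)
})

test_that("counting-process rows give delayed entry its due", {
  # one subject entering late must not sit in earlier risk sets
  recs <- dplyr::bind_rows(
    toy_records(),
    tibble::tibble(subject_id = "late", colony_id = "c1",
                   timepoint = "2013-spring", start = 2, stop = 3,
                   event = 0, betweenness = 0.5))
  fit <- fit_extended_cox(recs, "betweenness")
  direct <- survival::coxph(
    survival::Surv(start, stop, event) ~ betweenness + factor(colony_id),
    data = recs, ties = "efron")
  expect_equal(fit$coefficients$beta, unname(coef(direct)))
})

test_that("degenerate inputs are refused with clear errors", {
  recs <- toy_records()
  expect_error(fit_extended_cox(recs, character(0)), "at least one")
  expect_error(fit_extended_cox(recs, "no_such"), "missing column")
  none <- recs; none$event <- 0
  expect_error(fit_extended_cox(none, "betweenness"), "no events")
  const <- recs; const$betweenness <- 1
  expect_error(fit_extended_cox(const, "betweenness"), "constant")
  sep <- recs
  sep$betweenness <- ifelse(sep$event == 1, 0, 1)
  expect_warning(fit_extended_cox(sep, "betweenness"), "separation")
  # the QAP test refuses a separable tested covariate outright
  sep$timepoint <- "2012-summer"
  expect_error(
    suppressWarnings(qap_cox(sep, "betweenness", B = 199, seed = 1)),
    "separable")
})

test_that("missing covariates are dropped as complete cases, with n", {
  recs <- toy_records()
  recs$betweenness[3] <- NA
  expect_message(fit <- fit_extended_cox(recs, "betweenness"),
                 "dropped 1")
  expect_equal(fit$n_rows, 11)
})

test_that("stratified colony term changes the baseline, not the API", {
  recs <- toy_records()
  fs <- fit_extended_cox(recs, "betweenness", colony = "stratum")
  expect_equal(nrow(fs$coefficients), 1)  # no colony coefficient
  ff <- fit_extended_cox(recs, "betweenness", colony = "factor")
  expect_equal(nrow(ff$coefficients), 2)
})

test_that("permutation stays within each colony-by-timepoint map", {
  sim <- fix_small_sim(5)
  recs <- build_survival_records(sim$colonies)
  set.seed(99)
  perm <- permute_within_maps(recs, "betweenness")
  key <- paste(recs$colony_id, recs$timepoint)
  for (k in unique(key)) {
    expect_equal(sort(perm$betweenness[key == k]),
                 sort(recs$betweenness[key == k]))
  }
  # everything but the shuffled column is untouched
  expect_identical(perm[setdiff(names(perm), "betweenness")],
                   recs[setdiff(names(recs), "betweenness")])
  expect_error(permute_within_maps(recs, "no_such"), "not found")
  # single-subject maps can be reported
  one <- recs[1, ]
  expect_message(permute_within_maps(one, "betweenness",
                                     warn_singletons = TRUE), "single")
})

test_that("qap_cox is deterministic and respects the p-value floor", {
  sim <- fix_small_sim(7)
  recs <- build_survival_records(sim$colonies)
  q1 <- qap_cox(recs, "betweenness", B = 199, seed = 42)
  q2 <- qap_cox(recs, "betweenness", B = 199, seed = 42)
  expect_identical(q1$null_stats, q2$null_stats)
  expect_identical(q1$p_value, q2$p_value)
  expect_gte(q1$p_value, 1 / (q1$B_ok + 1))
  expect_lte(q1$p_value, 1)
  expect_equal(q1$B, 199)
  td <- tidy(q1)
  expect_true(all(c("term", "statistic", "p.value") %in% names(td)))
  q3 <- qap_cox(recs, "betweenness", B = 199, seed = 43)
  expect_false(identical(q1$null_stats, q3$null_stats))
})

test_that("the fast refit path matches full model refits exactly", {
  sim <- fix_small_sim(9)
  recs <- build_survival_records(sim$colonies)
  expect_warning(q <- qap_cox(recs, "betweenness", B = 12, seed = 3),
                 "coarse")
  expect_equal(q$n_failed, 0)  # null_stats then align with seed order
  # reproduce the first permutations by hand with full coxph refits
  set.seed(3L)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 12)
  for (b in 1:4) {
    set.seed(sub_seeds[b])
    perm <- q$observed$data
    perm$betweenness <- permute_within_maps(
      perm[, c("colony_id", "timepoint", "betweenness")],
      "betweenness")$betweenness
    ref <- suppressMessages(fit_extended_cox(perm, "betweenness"))
    z_ref <- ref$coefficients$z[ref$coefficients$term == "betweenness"]
    expect_equal(q$null_stats[b], z_ref, tolerance = 1e-8)
  }
})

test_that("tail choices reuse the same null distribution", {
  sim <- fix_small_sim(13)
  recs <- build_survival_records(sim$colonies)
  qt <- qap_cox(recs, "betweenness", B = 199, seed = 8,
                tail = "two_sided")
  ql <- qap_cox(recs, "betweenness", B = 199, seed = 8, tail = "lower")
  qu <- qap_cox(recs, "betweenness", B = 199, seed = 8, tail = "upper")
  expect_identical(qt$null_stats, ql$null_stats)
  B1 <- qt$B_ok + 1
  expect_equal(ql$p_value + qu$p_value,
               (B1 + 1 + sum(qt$null_stats == qt$observed_stat)) / B1)
  expect_gte(qt$p_value, min(ql$p_value, qu$p_value))
})

test_that("co-adjusted covariates keep their observed structure", {
  sim <- fix_small_sim(15)
  recs <- build_survival_records(sim$colonies)
  recs$log_size <- log(recs$size)
  expect_warning(
    q <- qap_cox(recs, c("betweenness", "log_size"),
                 covariate = "betweenness", B = 99, seed = 2),
    "coarse")
  expect_lte(q$B_ok, 99)
  expect_equal(length(q$null_stats), q$B_ok)
  expect_error(qap_cox(recs, "betweenness", covariate = "log_size",
                       B = 199), "must be one of")
})

test_that("raw and model-based survival curves behave", {
  recs <- toy_records()
  cv <- survival_curve(recs)
  expect_equal(cv$time[1], 0)
  expect_equal(cv$survival[1], 1)
  expect_true(all(diff(cv$survival) <= 1e-12))
  fit <- fit_extended_cox(recs, "betweenness")
  cm <- survival_curve(recs, fit,
                       tibble::tibble(betweenness = c(0.1, 0.9),
                                      label = c("lo", "hi")))
  expect_setequal(unique(cm$profile), c("lo", "hi"))
  # higher flow -> lower hazard here? direction: just check ordering is
  # consistent with the fitted coefficient sign
  s_lo <- cm$survival[cm$profile == "lo" & cm$time == max(cm$time)]
  s_hi <- cm$survival[cm$profile == "hi" & cm$time == max(cm$time)]
  if (fit$coefficients$beta[1] < 0) {
    expect_gte(s_hi, s_lo)
  } else {
    expect_lte(s_hi, s_lo)
  }
  expect_error(survival_curve(recs, fit), "profiles")
})
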