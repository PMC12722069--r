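test_that("with zero random-effect variance the mixed model matches OLS", {
  set.seed(41)
  tr <- generator_config()$dyad_truth
  tr$sd_source <- tr$sd_target <- tr$sd_household <- 0
  d <- generate_dyad_records(50, 6, truth = tr)
  # specification 2 contains every generating covariate, so the only
  # remaining structure is iid noise and the variance components sit at zero
  f <- fit_dyad_mixed(d, model_spec = 2)
  X <- lme4::getME(f$fit, "X")
  y <- lme4::getME(f$fit, "y")
  ols <- qr.coef(qr(X), y)
  # at exactly zero variance the mixed-model solution IS least squares
  devf <- lme4::lmer(formula(f$fit), data = f$fit@frame, REML = TRUE,
                     devFunOnly = TRUE)
  invisible(devf(rep(0, length(lme4::getME(f$fit, "theta")))))
  beta0 <- environment(devf)$pp$beta(1)
  expect_equal(unname(beta0), unname(ols), tolerance = 1e-6)
  # and the freely-estimated fit sits close (REML boundary noise only)
  expect_equal(unname(lme4::fixef(f$fit)), unname(ols), tolerance = 0.05)
})

test_that("eating together attenuates the interaction-frequency effect", {
  set.seed(42)
  tr <- generator_config()$dyad_truth
  # importance driven by eating only; interaction matters solely through
  # its correlation with eating (mediation structure)
  tr$b_interact <- 0; tr$b_close <- 0; tr$b_eat <- 0.45
  d <- generate_dyad_records(80, 6, truth = tr, eat_from_interact = TRUE)
  f1 <- fit_dyad_mixed(d, model_spec = 1)  # omits eat_freq
  f2 <- fit_dyad_mixed(d, model_spec = 2)  # includes eat_freq
  b1 <- f1$tidy$estimate[f1$tidy$term == "interact_freq"]
  b2 <- f2$tidy$estimate[f2$tidy$term == "interact_freq"]
  expect_gt(b1, 0.3)                 # picks up the mediated effect
  expect_lt(abs(b2), abs(b1) / 3)    # attenuates toward zero
})

test_that("listwise deletion is accounted record by record", {
  set.seed(43)
  d <- generate_dyad_records(20, 5)
  d$source_health[c(3, 10, 25)] <- NA
  d$target_effort[c(10, 40)] <- NA
  f <- fit_dyad_mixed(d, model_spec = 1)
  expect_equal(f$n_dropped, 4L)  # rows 3, 10 (once), 25, 40
  expect_equal(f$n_used, nrow(d) - 4L)
})

test_that("surveyed-only sensitivity restricts both endpoints", {
  set.seed(44)
  d <- generate_dyad_records(30, 5)
  flip <- sample(nrow(d), 200)
  d$source_surveyed[flip] <- FALSE
  f <- fit_dyad_mixed(d, model_spec = 1, surveyed_only = TRUE)
  expect_lt(f$n_used, nrow(d))
})

test_that("shared and crossed node-effect modes broadly agree", {
  set.seed(45)
  d <- generate_dyad_records(30, 6)
  f1 <- fit_dyad_mixed(d, model_spec = 2)
  f2 <- fit_dyad_mixed(d, model_spec = 2, node_effect_mode = "shared")
  b1 <- f1$tidy$estimate[f1$tidy$term == "closeness"]
  b2 <- f2$tidy$estimate[f2$tidy$term == "closeness"]
  expect_equal(b1, b2, tolerance = 0.05)
})

test_that("specification 3 needs the cultural-scale flags", {
  set.seed(46)
  d <- generate_dyad_records(10, 4)
  expect_error(fit_dyad_mixed(d, model_spec = 3), "attach_scale_flags")
  d$source_hi_high <- sample(c(TRUE, FALSE), nrow(d), replace = TRUE)
  d$source_vc_high <- sample(c(TRUE, FALSE), nrow(d), replace = TRUE)
  f <- fit_dyad_mixed(d, model_spec = 3)
  expect_true(any(grepl("hi_high", f$tidy$term)))
})

test_that("network averages respect scope definitions", {
  net <- fuse_household(triple_report_household())
  av <- compute_network_averages(net, "y1")
  full <- av[av$scope == "full", ]
  expect_equal(full$n_members, 4)
  fr <- av[av$scope == "friends", ]
  expect_equal(fr$n_members, 1)
  expect_equal(fr$avg_health, 7)  # the one friend's perceived health
  # family scope excludes friends
  fam <- av[av$scope == "family_excl_spouse", ]
  expect_equal(fam$n_members, 3)
  # participant who named no friends: no friends row
  av_g <- compute_network_averages(net, "g1")
  expect_false("friends" %in% av_g$scope)
  av_m <- compute_network_averages(net, "m1")
  expect_false("friends" %in% av_m$scope)
  expect_error(compute_network_averages(net, "nobody"), "integrity error")
})

test_that("the family scope excludes the participant's spouse", {
  net <- fuse_household(triple_report_household())
  # mother's spouse is the father node (couple via her "husband" label)
  av_m <- compute_network_averages(net, "m1")
  fam <- av_m[av_m$scope == "family_excl_spouse", ]
  full <- av_m[av_m$scope == "full", ]
  expect_equal(fam$n_members, full$n_members - 2)  # minus spouse and friend
  reg <- net$registry
  non_spouse_fam <- reg[reg$term %in% c("ego", "grandparent"), ]
  expect_equal(fam$avg_health, mean(non_spouse_fam$health))
})

test_that("friends' averages use the paper's worked arithmetic", {
  # two friends with perceived health 5 and 7 average to 6
  hh <- two_reporter_household()
  hh$alters <- rbind(hh$alters, data.frame(
    reporter_id = "y1", alter_label = "friend L", relation_class = "friend",
    sex = "m", age_approx = 30, perceived_health = 5, perceived_effort = 6))
  hh$alters$perceived_health[hh$alters$alter_label == "friend K"] <- 7
  svy <- as_household_surveys(hh$participants, hh$alters, hh$ratings)[[1]]
  net <- fuse_household(svy)
  av <- compute_network_averages(net, "y1")
  expect_equal(av$avg_health[av$scope == "friends"], 6)
})

test_that("diet GEE runs per scope with reference-level invariance", {
  co <- default_cohort()
  svys <- as_household_surveys(co$participants, co$alters, co$ratings,
                               co$overrides)
  nets <- default_networks()
  coded <- code_participants(svys)$coded
  averages <- cohort_network_averages(nets)
  f <- fit_diet_gee(co$participants, coded, averages, "snacks_low",
                    scope = "family_excl_spouse")
  expect_s3_class(f, "gee_fit")
  expect_true(all(c("avg_health", "avg_effort", "avg_eat_freq") %in%
                    f$tidy$term))
  # releveling a covariate changes parameterization, not fitted values
  p2 <- co$participants
  p2$race <- relevel(factor(p2$race), ref = "other")
  f2 <- fit_diet_gee(p2, coded, averages, "snacks_low",
                     scope = "family_excl_spouse")
  expect_equal(f$tidy$estimate[f$tidy$term == "avg_effort"],
               f2$tidy$estimate[f2$tidy$term == "avg_effort"],
               tolerance = 1e-6)
})
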