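test_that("three reporters' views of one man fuse to a single father node", {
  net <- fuse_household(triple_report_household())
  reg <- net$registry
  fathers <- reg[reg$term == "father", ]
  expect_equal(nrow(fathers), 1)
  expect_equal(fathers$reporter_count, 3L)
  expect_false(fathers$surveyed)
  # grandmother's "daughter in law" merged with the surveyed mother
  expect_equal(sum(reg$term == "mother"), 1)
  expect_equal(nrow(reg), 5)  # ego, mother, grandmother, father, friend
})

test_that("a single reporter with distinct alters produces no merges", {
  p <- data.frame(
    participant_id = c("y1", "s1"), household_id = "hh3",
    is_index = c(1, 0), relation_to_index = c("ego", "sister"),
    age = c(30, 34), sex = c("m", "f"), race = "malay", income = "low",
    housing = "hdb_small", bmi = 24, marital_status = "single",
    self_health = 7, self_effort = 7,
    hi1 = 5, hi2 = 5, hi3 = 5, hi4 = 5, vc1 = 5, vc2 = 5, vc3 = 5, vc4 = 5,
    diet_veg = 2, diet_fruit = 2, diet_snacks = 2, diet_fastfood = 2,
    stringsAsFactors = FALSE)
  a <- data.frame(
    reporter_id = "y1",
    alter_label = c("mother", "father", "uncle T", "friend A", "friend B"),
    relation_class = c("family", "family", "family", "friend", "friend"),
    sex = c("f", "m", "m", "m", "f"),
    age_approx = c(58, 60, 50, 31, 29),
    perceived_health = 6, perceived_effort = 6, stringsAsFactors = FALSE)
  a <- rbind(a, data.frame(reporter_id = "s1",
                           alter_label = c("brother", "mother"),
                           relation_class = "family", sex = c("m", "f"),
                           age_approx = c(30, 58), perceived_health = 7,
                           perceived_effort = 7))
  r <- data.frame(reporter_id = "y1", person_a = "y1",
                  person_b = c("mother", "father"),
                  interact_freq = 5, closeness = 5, eat_freq = 5,
                  importance_a_in_b = 5, importance_b_in_a = 5,
                  stringsAsFactors = FALSE)
  svy <- as_household_surveys(p, a, r)[[1]]
  net <- fuse_household(svy)
  # 2 surveyed + 5 distinct alters of y1 (s1's reports merge into existing)
  expect_equal(nrow(net$registry), 7)
  # sister's "brother" resolved to the index adult by age, not a new node
  expect_equal(sum(net$registry$term == "ego"), 1)
})

test_that("merged node attributes and edge ratings average across reporters", {
  net <- fuse_household(triple_report_household())
  reg <- net$registry
  # father seen by three reporters: perceived health (6, 8, 7) -> 7
  expect_equal(reg$health[reg$term == "father"], 7)
  # ego-father tie rated by ego (eat 6) and mother (eat 8) -> 7
  e <- net$edges
  ego_id <- reg$node_id[reg$term == "ego"]
  fa_id <- reg$node_id[reg$term == "father"]
  row <- e[(e$a == ego_id & e$b == fa_id) | (e$a == fa_id & e$b == ego_id), ]
  expect_equal(row$eat_freq, 7)
  expect_equal(row$reporter_count, 2L)
  # surveyed nodes keep self-reports despite other reporters' perceptions
  expect_equal(reg$health[reg$term == "mother"], 6)
})

test_that("single-reporter consolidation is the identity (idempotence)", {
  hh <- two_reporter_household()
  # keep only the index adult's rating rows: every pair has one reporter
  hh$ratings <- hh$ratings[hh$ratings$reporter_id == "y1", ]
  svy <- as_household_surveys(hh$participants, hh$alters, hh$ratings)[[1]]
  net <- fuse_household(svy)
  e <- net$edges
  expect_true(all(e$reporter_count == 1))
  # ratings passed through unchanged
  expect_setequal(e$eat_freq, c(7, 2))
})

test_that("edge count equals the number of distinct rated unordered pairs", {
  co <- generate_cohort(generator_config(n_households = 5, seed = 9))
  svys <- as_household_surveys(co$participants, co$alters, co$ratings,
                               co$overrides)
  for (svy in svys) {
    net <- fuse_household(svy)
    # oracle: map every rating row to its node pair and count unique pairs
    reg <- net$registry
    ref_map <- attr(reg, "ref_map")
    pairs <- vapply(seq_len(nrow(svy$ratings)), function(i) {
      a <- ref_map[[svy$ratings$reporter_id[i]]][[svy$ratings$person_a[i]]]
      b <- ref_map[[svy$ratings$reporter_id[i]]][[svy$ratings$person_b[i]]]
      paste(sort(c(a, b)), collapse = "|")
    }, character(1))
    expect_equal(nrow(net$edges), length(unique(pairs)))
  }
})

test_that("tie classification follows spouse > friend > generation", {
  expect_equal(classify_edge("father", "ego"), "intergenerational")
  expect_equal(classify_edge("sibling", "sibling"), "intragenerational")
  expect_equal(classify_edge("mother", "father"), "spouse_partner")
  expect_equal(classify_edge("ego", "spouse_partner"), "spouse_partner")
  expect_equal(classify_edge("mother", "friend"), "friend")
  expect_equal(classify_edge("grandparent", "grandaunt_uncle"),
               "intragenerational")
  expect_equal(classify_edge("other", "ego"), "other")
  expect_equal(classify_edge("sibling", "sibling", couple = TRUE),
               "spouse_partner")
})

test_that("category counts partition the edgelist", {
  for (net in default_networks()[1:10]) {
    counts <- table(net$edges$category)
    expect_equal(sum(counts), nrow(net$edges))
    expect_true(all(names(counts) %in%
                      c("intergenerational", "intragenerational",
                        "spouse_partner", "friend", "other")))
  }
})

test_that("directed expansion always doubles the tie count", {
  net <- fuse_household(triple_report_household())
  rec <- build_directed_records(net)
  expect_equal(nrow(rec), 2 * nrow(net$edges))
  # the two records of a tie swap source and target and their outcomes
  e1 <- net$edges[1, ]
  r1 <- rec[rec$source_node == e1$a & rec$target_node == e1$b, ]
  r2 <- rec[rec$source_node == e1$b & rec$target_node == e1$a, ]
  expect_equal(r1$outcome, e1$importance_ab)
  expect_equal(r2$outcome, e1$importance_ba)
  # missing covariates do not reduce the record count here
  expect_false(anyNA(rec$outcome))
})

test_that("fusion is invariant to reporter processing order", {
  hh <- triple_report_household()
  rev_hh <- hh
  rev_hh$alters <- hh$alters[rev(seq_len(nrow(hh$alters))), ]
  rev_hh$ratings <- hh$ratings[rev(seq_len(nrow(hh$ratings))), ]
  n1 <- fuse_household(hh)
  n2 <- fuse_household(rev_hh)
  sig <- function(net) {
    reg <- net$registry
    reg <- reg[order(reg$term, reg$age), c("term", "sex", "age", "health",
                                           "reporter_count")]
    rownames(reg) <- NULL
    reg
  }
  expect_equal(sig(n1), sig(n2))
  expect_equal(sort(n1$edges$eat_freq), sort(n2$edges$eat_freq))
})

test_that("two surveyed participants cannot occupy the same kin slot", {
  svy <- triple_report_household()
  svy$participants$relation_to_index[3] <- "mother"  # second surveyed mother
  expect_error(fuse_household(svy), "integrity error")
})
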