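test_that("relation labels map to canonical terms, ignoring qualifiers", {
  expect_equal(parse_relation_label("auntie AZ", "family")$term, "aunt_uncle")
  expect_equal(parse_relation_label("mother", "family"),
               list(term = "mother", sex = "f"))
  expect_equal(parse_relation_label("oldest brother", "family")$term, "sibling")
  expect_equal(parse_relation_label("Mother-in-law", "family")$term,
               "parent_in_law")
  expect_equal(parse_relation_label("ah ma", "family")$term, "grandparent")
  expect_equal(parse_relation_label("gym buddy", "friend")$term, "friend")
  expect_equal(parse_relation_label("colleague", "other")$term, "other")
  expect_error(parse_relation_label("", "family"), "non-empty")
  expect_error(parse_relation_label(NA_character_, "family"), "non-empty")
})

test_that("composition reproduces the multi-reporter renaming cases", {
  # the mother's husband is the index adult's father
  cs <- compose_relations("mother", "spouse_partner", "m")
  expect_equal(cs$candidates, "father")
  expect_false(cs$ambiguous)
  expect_equal(cs$resolution_source, "unique")
  # identity composition for the index adult's own reports
  expect_equal(compose_relations("ego", "father", "m")$candidates, "father")
  # a grandmother's son is either the father or an uncle
  cs <- compose_relations("grandparent", "child", "m")
  expect_true(cs$ambiguous)
  expect_setequal(cs$candidates, c("father", "aunt_uncle"))
  # a parent's child is the index adult or a sibling
  expect_setequal(compose_relations("mother", "child", "m")$candidates,
                  c("ego", "sibling"))
  # non-kin never composes into kin
  expect_equal(compose_relations("mother", "friend")$candidates, "friend")
  expect_equal(compose_relations("friend", "mother", "f")$candidates, "other")
  expect_equal(compose_relations("godparent", "child", "m")$candidates,
               "other")
})

test_that("composition is closed and respects generation arithmetic", {
  kin_terms <- c("ego", "father", "mother", "grandparent", "sibling",
                 "aunt_uncle", "cousin", "child", "niece_nephew",
                 "grandchild", "spouse_partner", "parent_in_law",
                 "sibling_in_law", "child_in_law")
  all_terms <- c(kin_terms, "godparent", "friend", "other")
  for (rr in all_terms) {
    for (rep_ in all_terms) {
      cs <- compose_relations(rr, rep_, "m")
      expect_gte(length(cs$candidates), 1)
      expect_true(all(nzchar(cs$candidates)))
      # unambiguous kin compositions obey offset additivity
      if (!cs$ambiguous && rr %in% kin_terms && rep_ %in% kin_terms &&
          kin_is_family(cs$candidates)) {
        expected <- kin_offset(rr) + kin_offset(rep_)
        got <- kin_offset(cs$candidates)
        if (!is.na(got) && !is.na(expected) && cs$candidates != "other")
          expect_equal(got, expected,
                       label = paste(rr, "o", rep_, "->", cs$candidates))
      }
    }
  }
})

test_that("resolution honours override > cross-reporter match > unresolved", {
  cands <- compose_relations("grandparent", "child", "m")  # father or uncle
  # manual override wins outright
  res <- resolve_candidates(cands, override = "father")
  expect_equal(res$candidates, "father")
  expect_equal(res$resolution_source, "manual_override")
  # cross-reporter: a uniquely-resolved male of matching age
  ctx <- data.frame(term = c("father", "mother"), sex = c("m", "f"),
                    age = c(52, 50), stringsAsFactors = FALSE)
  res <- resolve_candidates(cands, alter_sex = "m", alter_age = 53,
                            registry_context = ctx)
  expect_equal(res$candidates, "father")
  expect_equal(res$resolution_source, "cross_reporter_match")
  # nearest age wins when several candidates match
  ctx2 <- rbind(ctx, data.frame(term = "aunt_uncle", sex = "m", age = 40))
  res <- resolve_candidates(cands, alter_sex = "m", alter_age = 41,
                            registry_context = ctx2)
  expect_equal(res$candidates, "aunt_uncle")
  # out-of-tolerance ages leave the set unresolved
  res <- resolve_candidates(cands, alter_sex = "m", alter_age = 70,
                            registry_context = ctx)
  expect_equal(res$resolution_source, "unresolved")
  # singleton sets pass through as unique
  res <- resolve_candidates(compose_relations("ego", "cousin"))
  expect_equal(res$candidates, "cousin")
  expect_equal(res$resolution_source, "unique")
  # unknown override label is a configuration error
  expect_error(resolve_candidates(cands, override = "stepcat"), "vocabulary")
})

test_that("resolution is deterministic for identical inputs", {
  cands <- compose_relations("grandparent", "child", "m")
  ctx <- data.frame(term = c("father", "aunt_uncle"), sex = c("m", "m"),
                    age = c(52, 45), stringsAsFactors = FALSE)
  r1 <- resolve_candidates(cands, "m", 51, ctx)
  r2 <- resolve_candidates(cands, "m", 51, ctx)
  expect_identical(r1, r2)
})
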