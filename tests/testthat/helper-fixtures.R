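# shared fixtures and independent oracles

# one household where the index adult, their mother and their paternal
# grandmother all describe the same man (father / husband / son)
triple_report_household <- function() {
  p <- data.frame(
    participant_id = c("y1", "m1", "g1"), household_id = "hh1",
    is_index = c(1, 0, 0),
    relation_to_index = c("ego", "mother", "grandmother"),
    age = c(24, 50, 75), sex = c("m", "f", "f"),
    race = "chinese", income = "mid", housing = "hdb_large", bmi = 22,
    marital_status = c("single", "married", "widowed"),
    self_health = c(7, 6, 5), self_effort = c(6, 8, 4),
    hi1 = 5, hi2 = 5, hi3 = 5, hi4 = 5,
    vc1 = 6, vc2 = 6, vc3 = 6, vc4 = 6,
    diet_veg = 3, diet_fruit = 2, diet_snacks = 1, diet_fastfood = 0,
    stringsAsFactors = FALSE)
  a <- data.frame(
    reporter_id = c("y1", "y1", "m1", "m1", "g1", "g1"),
    alter_label = c("father", "friend J", "husband", "son",
                    "son", "daughter in law"),
    relation_class = c("family", "friend", "family", "family",
                       "family", "family"),
    sex = c("m", "m", "m", "m", "m", "f"),
    age_approx = c(52, 25, 52, 24, 52, 50),
    perceived_health = c(6, 7, 8, 7, 7, 6),
    perceived_effort = c(5, 6, 6, 7, 5, 7),
    stringsAsFactors = FALSE)
  r <- data.frame(
    reporter_id = c("y1", "y1", "m1", "g1"),
    person_a = c("y1", "y1", "husband", "son"),
    person_b = c("father", "friend J", "son", "daughter in law"),
    interact_freq = c(6, 3, 7, 5), closeness = c(7, 2, 8, 6),
    eat_freq = c(6, 1, 8, 4),
    importance_a_in_b = c(5, 2, 6, 4), importance_b_in_a = c(7, 2, 6, 5),
    stringsAsFactors = FALSE)
  as_household_surveys(p, a, r)[[1]]
}

# minimal valid household: one index + one family member, enough alters
two_reporter_household <- function() {
  p <- data.frame(
    participant_id = c("y1", "m1"), household_id = "hh2",
    is_index = c(1, 0), relation_to_index = c("ego", "mother"),
    age = c(28, 55), sex = c("f", "f"),
    race = "chinese", income = "mid", housing = "private", bmi = 21,
    marital_status = "single",
    self_health = c(8, 6), self_effort = c(7, 7),
    hi1 = 4, hi2 = 6, hi3 = 7, hi4 = 5,
    vc1 = 8, vc2 = 7, vc3 = 6, vc4 = 7,
    diet_veg = 4, diet_fruit = 3, diet_snacks = 2, diet_fastfood = 1,
    stringsAsFactors = FALSE)
  a <- data.frame(
    reporter_id = c("y1", "y1", "m1", "m1"),
    alter_label = c("mother", "friend K", "daughter", "husband"),
    relation_class = c("family", "friend", "family", "family"),
    sex = c("f", "f", "f", "m"),
    age_approx = c(55, 27, 28, 57),
    perceived_health = c(6, 8, 8, 5),
    perceived_effort = c(7, 8, 7, 4),
    stringsAsFactors = FALSE)
  r <- data.frame(
    reporter_id = c("y1", "y1", "m1"),
    person_a = c("y1", "y1", "m1"),
    person_b = c("mother", "friend K", "daughter"),
    interact_freq = c(8, 4, 8), closeness = c(8, 5, 8), eat_freq = c(7, 2, 7),
    importance_a_in_b = c(6, 3, 7), importance_b_in_a = c(7, 3, 6),
    stringsAsFactors = FALSE)
  list(participants = p, alters = a, ratings = r)
}

# hand-built network object for metric tests (bypasses the survey layer)
toy_network <- function(attrs, edges) {
  # attrs: data.frame(node_id, term, sex, age, health, effort)
  reg <- data.frame(
    node_id = attrs$node_id, term = attrs$term,
    sex = attrs$sex, age = attrs$age, health = attrs$health,
    effort = attrs$effort, surveyed = FALSE,
    participant_id = NA_character_, reporter_count = 1L,
    resolution = "unique", label = NA_character_,
    stringsAsFactors = FALSE)
  attr(reg, "ref_map") <- list()
  attr(reg, "couples") <- list()
  class(reg) <- c("node_registry", "data.frame")
  e <- data.frame(
    a = edges$a, b = edges$b,
    interact_freq = edges$w, closeness = edges$w, eat_freq = edges$w,
    importance_ab = edges$w, importance_ba = edges$w,
    reporter_count = 1L, category = "friend", stringsAsFactors = FALSE)
  structure(list(household_id = "toy", registry = reg, edges = e),
            class = "household_network")
}

# independent brute-force weighted assortativity oracles
brute_assort_numeric <- function(x, a, b, w) {
  xs <- c(x[a], x[b]); ys <- c(x[b], x[a]); ws <- c(w, w)
  keep <- ws > 0
  xs <- xs[keep]; ys <- ys[keep]; ws <- ws[keep]
  W <- sum(ws)
  mx <- sum(ws * xs) / W
  vx <- sum(ws * (xs - mx)^2) / W
  if (vx < 1e-14) return(NA_real_)
  sum(ws * (xs - mx) * (ys - mx)) / W / vx
}

brute_assort_categorical <- function(x, a, b, w) {
  lev <- sort(unique(c(x[a], x[b])))
  if (length(lev) < 2) return(NA_real_)
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (k in seq_along(w)) {
    if (w[k] <= 0) next
    m[x[a[k]], x[b[k]]] <- m[x[a[k]], x[b[k]]] + w[k]
    m[x[b[k]], x[a[k]]] <- m[x[b[k]], x[a[k]]] + w[k]
  }
  if (sum(m) == 0) return(NA_real_)
  m <- m / sum(m)
  ab <- sum(rowSums(m) * colSums(m))
  (sum(diag(m)) - ab) / (1 - ab)
}

# default synthetic cohort, generated once and reused across test files
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cohort_cache$co))
    .cohort_cache$co <- generate_cohort(generator_config(seed = 20260928L))
  .cohort_cache$co
}
default_networks <- function() {
  if (is.null(.cohort_cache$nets)) {
    co <- default_cohort()
    svys <- as_household_surveys(co$participants, co$alters, co$ratings,
                                 co$overrides)
    .cohort_cache$nets <- lapply(svys, fuse_household)
  }
  .cohort_cache$nets
}
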