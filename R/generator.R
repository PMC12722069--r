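#' @title Synthetic household-survey generator
#' @description Generates the three survey tables with known ground truth:
#'   households of an index young adult plus 1--3 co-surveyed family members,
#'   kin and friend alters with deliberate cross-reporter overlaps (including
#'   the father/husband/son renaming pattern), category-dependent tie-strength
#'   distributions, directed health-importance ratings drawn from the dyadic
#'   mixed model, and diet flags drawn from a logistic model on realized
#'   network averages.
#' @name synthetic_data
NULL

#' Default generator configuration
#'
#' Category rating means follow the observed ordering spouse/partner >
#' intergenerational > intragenerational > friend on the 0--9 scale; the
#' dyad-model and diet-model truth coefficients default to magnitudes of the
#' reported fits so that recovery tests double as plausibility checks.
#'
#' @param ... overrides of any default element.
#' @return named list of generator settings.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_households = 36,
    seed = 1L,
    p_female = 0.57,
    # household composition: co-surveyed member sets and optional extra kin
    templates = list(c("mother"), c("mother", "father"), c("father"),
                     c("sibling"), c("mother", "sibling"),
                     c("mother", "father", "sibling"), c("spouse_partner"),
                     c("mother", "grandparent")),
    template_weights = c(0.2, 0.25, 0.05, 0.1, 0.1, 0.15, 0.1, 0.05),
    p_extra = c(sibling = 0.6, sibling2 = 0.3, grandparent = 0.5,
                aunt_uncle = 0.4, cousin = 0.3, spouse_partner = 0.3),
    ego_friend_range = c(2, 4),
    family_friend_range = c(0, 2),
    p_rate_alter_pair = 0.75,    # prob a reporter rates an alter-alter pair
    reporter_noise_sd = 0.6,     # per-reporter rating noise around the truth
    missing_rate = 0.02,         # missing perceived health/effort reports
    # tie-strength means by category (interact, closeness, eat) and sd
    cat_means = list(
      spouse_partner = c(7.2, 7.1, 7.0),
      intergenerational = c(5.3, 5.2, 5.0),
      intragenerational = c(4.5, 4.4, 4.0),
      friend = c(2.0, 2.0, 2.0)),
    rating_sd = 1.5,
    cross_sex_eat = 1.5,         # added to eat-together mean, opposite sexes
    # truth for the directed importance model (predictors centered at 4.5)
    dyad_truth = list(
      intercept = 3.0, b_interact = 0.05, b_close = 0.45, b_eat = 0.43,
      cat = c(friend = 0, intragenerational = 0.2,
              intergenerational_target_older = 0.62,
              intergenerational_target_younger = 0.36,
              spouse_partner = 0.89),
      sd_source = 0.4, sd_target = 0.4, sd_household = 0.3, sd_noise = 1.0),
    # truth for the diet models: log-odds per rating point on the flag
    # (healthy-side) scale, predictors centered at (health 7, effort 6.6,
    # eat 5) on the named scope. Note the flags are the complement of the
    # consumption outcomes, so a consumption odds ratio r appears here as
    # -log(r): more network effort -> higher odds of low snacking / no
    # fast food, higher perceived network health -> lower odds of low
    # snacking.
    diet_truth = list(
      veg_meets = list(scope = "full", intercept = stats::qlogis(0.276),
                       b_health = 0, b_effort = 0, b_eat = 0),
      fruit_meets = list(scope = "full", intercept = stats::qlogis(0.15),
                         b_health = 0, b_effort = 0, b_eat = 0),
      fastfood_none = list(scope = "family_excl_spouse",
                           intercept = stats::qlogis(0.328),
                           b_health = 0, b_effort = -log(0.41), b_eat = 0),
      snacks_low = list(scope = "family_excl_spouse",
                        intercept = stats::qlogis(0.2),
                        b_health = -log(3.21), b_effort = -log(0.50),
                        b_eat = 0)),
    hi_item_mean = 6.9, hi_item_sd = 1.6,
    vc_item_mean = 6.8, vc_item_sd = 1.9,
    health_mean = 7.1, health_sd = 1.64,
    effort_mean = 6.6, effort_sd = 1.95)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

.clipround <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

.draw_sex <- function(n, p_female) ifelse(stats::runif(n) < p_female, "f", "m")

# reporter-relative label for a kin node, or NA when the reporter would not
# plausibly list that person; init disambiguates same-label alters
.rel_label <- function(reporter_rel, node_rel, node_sex, init) {
  sexed <- function(m, f) if (identical(node_sex, "m")) m else f
  lab <- switch(reporter_rel,
    ego = switch(node_rel,
      mother = "mother", father = "father",
      sibling = sexed("brother", "sister"),
      grandparent = sexed("grandpa", "grandma"),
      aunt_uncle = sexed("uncle", "auntie"),
      cousin = "cousin",
      spouse_partner = sexed("husband", "wife"), NA),
    mother = switch(node_rel,
      ego = sexed("son", "daughter"), father = "husband",
      sibling = sexed("son", "daughter"),
      grandparent = "mother in law",
      aunt_uncle = sexed("brother", "sister"),
      cousin = sexed("nephew", "niece"),
      spouse_partner = sexed("son in law", "daughter in law"), NA),
    father = switch(node_rel,
      ego = sexed("son", "daughter"), mother = "wife",
      sibling = sexed("son", "daughter"),
      grandparent = "mother",
      aunt_uncle = sexed("brother in law", "sister in law"),
      cousin = sexed("nephew", "niece"),
      spouse_partner = sexed("son in law", "daughter in law"), NA),
    sibling = switch(node_rel,
      ego = sexed("brother", "sister"),
      mother = "mother", father = "father",
      sibling = sexed("brother", "sister"),
      grandparent = "grandma",
      aunt_uncle = sexed("uncle", "auntie"),
      cousin = "cousin", NA),
    grandparent = switch(node_rel,
      ego = sexed("grandson", "granddaughter"),
      father = "son", mother = "daughter in law",
      sibling = sexed("grandson", "granddaughter"), NA),
    spouse_partner = switch(node_rel,
      ego = sexed("husband", "wife"),
      mother = "mother in law", father = "father in law",
      sibling = sexed("brother in law", "sister in law"), NA),
    NA)
  if (is.na(lab)) return(NA_character_)
  paste(lab, init)
}

.gen_household <- function(h, cfg) {
  hid <- sprintf("h%03d", h)
  # --- truth nodes -------------------------------------------------------
  rels <- c("ego", "mother", "father")
  if (stats::runif(1) < cfg$p_extra["sibling"]) rels <- c(rels, "sibling")
  if (stats::runif(1) < cfg$p_extra["sibling2"]) rels <- c(rels, "sibling")
  if (stats::runif(1) < cfg$p_extra["grandparent"]) rels <- c(rels, "grandparent")
  if (stats::runif(1) < cfg$p_extra["aunt_uncle"]) rels <- c(rels, "aunt_uncle")
  if (stats::runif(1) < cfg$p_extra["cousin"]) rels <- c(rels, "cousin")
  tpl <- cfg$templates[[sample.int(length(cfg$templates), 1,
                                   prob = cfg$template_weights)]]
  if ("spouse_partner" %in% tpl || stats::runif(1) < cfg$p_extra["spouse_partner"])
    rels <- c(rels, "spouse_partner")
  for (t in tpl) if (!(t %in% rels)) rels <- c(rels, t)
  ego_age <- round(stats::runif(1, 21, 35))
  ego_sex <- .draw_sex(1, cfg$p_female)
  n <- length(rels)
  age <- numeric(n); sex <- character(n)
  sib_gap <- sample(c(-8:-3, 3:8), sum(rels == "sibling"))
  si <- 0
  for (i in seq_len(n)) {
    r <- rels[i]
    if (r == "ego") { age[i] <- ego_age; sex[i] <- ego_sex }
    else if (r == "mother") { age[i] <- ego_age + round(stats::runif(1, 25, 32)); sex[i] <- "f" }
    else if (r == "father") { age[i] <- ego_age + round(stats::runif(1, 27, 34)); sex[i] <- "m" }
    else if (r == "sibling") { si <- si + 1; age[i] <- ego_age + sib_gap[si]; sex[i] <- .draw_sex(1, cfg$p_female) }
    else if (r == "grandparent") { age[i] <- ego_age + round(stats::runif(1, 52, 62)); sex[i] <- "f" }
    else if (r == "aunt_uncle") { age[i] <- ego_age + round(stats::runif(1, 18, 38)); sex[i] <- .draw_sex(1, cfg$p_female) }
    else if (r == "cousin") { age[i] <- ego_age + sample(c(-10:-2, 2:10), 1); sex[i] <- .draw_sex(1, cfg$p_female) }
    else if (r == "spouse_partner") { age[i] <- ego_age + sample(-4:4, 1); sex[i] <- if (ego_sex == "m") "f" else "m" }
  }
  nodes <- data.frame(
    tn = paste0(hid, "_n", seq_len(n)), rel = rels, sex = sex, age = age,
    health = .clipround(stats::rnorm(n, cfg$health_mean, cfg$health_sd), 1, 10),
    effort = .clipround(stats::rnorm(n, cfg$effort_mean, cfg$effort_sd), 1, 10),
    owner = NA_character_, stringsAsFactors = FALSE)
  nodes$init <- LETTERS[seq_len(nrow(nodes))]
  # surveyed members: index + template (first matching node per relation)
  surveyed_idx <- c(which(rels == "ego"),
                    vapply(tpl, function(t) which(rels == t)[1], numeric(1)))
  surveyed_idx <- unique(surveyed_idx)
  # friends, owned by their reporter; the name generator allows at most 10
  # alters, so friends are capped by the number of kin the reporter will list
  fr_rows <- list()
  for (k in seq_along(surveyed_idx)) {
    i <- surveyed_idx[k]
    n_kin_labels <- sum(vapply(seq_len(nrow(nodes)), function(j) {
      j != i && !is.na(.rel_label(rels[i], nodes$rel[j], nodes$sex[j], "X"))
    }, logical(1)))
    rng <- if (rels[i] == "ego") cfg$ego_friend_range else cfg$family_friend_range
    nf <- min(sample(seq(rng[1], rng[2]), 1), 10L - n_kin_labels)
    nf <- max(nf, 0L)
    if (nf > 0) {
      fr_rows[[length(fr_rows) + 1]] <- data.frame(
        rel = "friend", sex = .draw_sex(nf, cfg$p_female),
        age = nodes$age[i] + sample(-8:8, nf, replace = TRUE),
        owner = nodes$tn[i], stringsAsFactors = FALSE)
    }
  }
  if (length(fr_rows)) {
    fr <- do.call(rbind, fr_rows)
    fr$tn <- paste0(hid, "_n", nrow(nodes) + seq_len(nrow(fr)))
    fr$health <- .clipround(stats::rnorm(nrow(fr), cfg$health_mean, cfg$health_sd), 1, 10)
    fr$effort <- .clipround(stats::rnorm(nrow(fr), cfg$effort_mean, cfg$effort_sd), 1, 10)
    fr$init <- LETTERS[nrow(nodes) + seq_len(nrow(fr))]
    nodes <- rbind(nodes, fr[names(nodes)])
  }
  nodes$surveyed <- nodes$tn %in% nodes$tn[surveyed_idx]

  # --- truth edges -------------------------------------------------------
  kin_idx <- which(nodes$rel != "friend")
  pair_list <- list()
  if (length(kin_idx) > 1) {
    cmb <- utils::combn(kin_idx, 2)
    for (j in seq_len(ncol(cmb))) pair_list[[length(pair_list) + 1]] <- cmb[, j]
  }
  for (i in which(nodes$rel == "friend")) {
    owner_i <- match(nodes$owner[i], nodes$tn)
    pair_list[[length(pair_list) + 1]] <- c(owner_i, i)
    # friends of the same owner sometimes know each other
    for (j in which(nodes$rel == "friend" & nodes$owner == nodes$owner[i])) {
      if (j > i && stats::runif(1) < 0.5)
        pair_list[[length(pair_list) + 1]] <- c(i, j)
    }
  }
  ncat <- function(i, j) {
    ri <- nodes$rel[i]; rj <- nodes$rel[j]
    pair <- sort(c(ri, rj))
    if (identical(pair, c("father", "mother")) ||
        identical(pair, c("ego", "spouse_partner"))) return("spouse_partner")
    if (ri == "friend" || rj == "friend") return("friend")
    oi <- kin_offset(ri); oj <- kin_offset(rj)
    if (abs(oi - oj) >= 1) "intergenerational" else "intragenerational"
  }
  tr <- cfg$dyad_truth
  u_src <- stats::rnorm(nrow(nodes), 0, tr$sd_source)
  u_tgt <- stats::rnorm(nrow(nodes), 0, tr$sd_target)
  u_hh <- stats::rnorm(1, 0, tr$sd_household)
  edges <- do.call(rbind, lapply(pair_list, function(pr) {
    i <- pr[1]; j <- pr[2]
    cat_ <- ncat(i, j)
    m <- cfg$cat_means[[cat_]]
    eat_mu <- m[3] + if (nodes$sex[i] != nodes$sex[j]) cfg$cross_sex_eat else 0
    interact <- .clipround(stats::rnorm(1, m[1], cfg$rating_sd), 0, 9)
    close <- .clipround(stats::rnorm(1, m[2], cfg$rating_sd), 0, 9)
    eat <- .clipround(stats::rnorm(1, eat_mu, cfg$rating_sd), 0, 9)
    cat_dir <- function(src, tgt) {
      if (cat_ != "intergenerational") return(tr$cat[[cat_]])
      if (kin_offset(nodes$rel[tgt]) > kin_offset(nodes$rel[src]))
        tr$cat[["intergenerational_target_older"]]
      else tr$cat[["intergenerational_target_younger"]]
    }
    lp <- function(src, tgt) {
      tr$intercept + tr$b_interact * (interact - 4.5) +
        tr$b_close * (close - 4.5) + tr$b_eat * (eat - 4.5) +
        cat_dir(src, tgt) + u_src[src] + u_tgt[tgt] + u_hh +
        stats::rnorm(1, 0, tr$sd_noise)
    }
    data.frame(i = i, j = j, category = cat_, interact = interact,
               close = close, eat = eat,
               imp_ij = .clipround(lp(i, j), 0, 9),
               imp_ji = .clipround(lp(j, i), 0, 9))
  }))

  # --- survey tables -----------------------------------------------------
  pid <- stats::setNames(paste0(hid, "_p", seq_along(surveyed_idx)),
                         nodes$tn[surveyed_idx])
  rel_to_index_label <- function(i) {
    r <- nodes$rel[i]
    switch(r, ego = "ego",
           mother = "mother", father = "father",
           sibling = if (nodes$sex[i] == "m") "brother" else "sister",
           grandparent = "grandmother",
           spouse_partner = if (nodes$sex[i] == "m") "husband" else "wife", r)
  }
  participants <- do.call(rbind, lapply(surveyed_idx, function(i) {
    data.frame(
      participant_id = unname(pid[nodes$tn[i]]), household_id = hid,
      is_index = as.integer(nodes$rel[i] == "ego"),
      relation_to_index = rel_to_index_label(i),
      age = nodes$age[i], sex = nodes$sex[i],
      race = sample(c("chinese", "malay", "indian", "other"), 1,
                    prob = c(0.77, 0.1, 0.08, 0.05)),
      income = sample(c("low", "mid", "high"), 1, prob = c(0.25, 0.5, 0.25)),
      housing = sample(c("hdb_small", "hdb_large", "private"), 1,
                       prob = c(0.35, 0.45, 0.2)),
      bmi = round(stats::rnorm(1, 23, 3.5), 1),
      marital_status = if (nodes$rel[i] %in% c("mother", "father"))
        "married" else sample(c("single", "married", "partnered"), 1,
                              prob = c(0.6, 0.2, 0.2)),
      self_health = nodes$health[i], self_effort = nodes$effort[i],
      stringsAsFactors = FALSE)
  }))
  for (k in 1:4) {
    participants[[paste0("hi", k)]] <-
      .clipround(stats::rnorm(nrow(participants), cfg$hi_item_mean,
                              cfg$hi_item_sd), 1, 9)
    participants[[paste0("vc", k)]] <-
      .clipround(stats::rnorm(nrow(participants), cfg$vc_item_mean,
                              cfg$vc_item_sd), 1, 9)
  }

  # alters: each reporter lists kin with a defined relative label + own friends
  alters <- list(); overrides <- list()
  alter_of <- list()  # reporter tn -> data.frame(node idx, label)
  for (i in surveyed_idx) {
    rrel <- nodes$rel[i]
    rows <- list()
    for (j in seq_len(nrow(nodes))) {
      if (j == i) next
      if (nodes$rel[j] == "friend") {
        if (!identical(nodes$owner[j], nodes$tn[i])) next
        lab <- paste("friend", nodes$init[j])
      } else {
        lab <- .rel_label(rrel, nodes$rel[j], nodes$sex[j], nodes$init[j])
        if (is.na(lab)) next
      }
      rows[[length(rows) + 1]] <- data.frame(j = j, label = lab,
                                             stringsAsFactors = FALSE)
    }
    af <- do.call(rbind, rows)
    if (nrow(af) > 10) af <- af[seq_len(10), , drop = FALSE]
    alter_of[[nodes$tn[i]]] <- af
    rc <- ifelse(nodes$rel[af$j] == "friend", "friend", "family")
    miss_h <- stats::runif(nrow(af)) < cfg$missing_rate
    miss_e <- stats::runif(nrow(af)) < cfg$missing_rate
    perc_h <- .clipround(nodes$health[af$j] + stats::rnorm(nrow(af), 0, 0.7), 1, 10)
    perc_e <- .clipround(nodes$effort[af$j] + stats::rnorm(nrow(af), 0, 0.7), 1, 10)
    alters[[length(alters) + 1]] <- data.frame(
      reporter_id = unname(pid[nodes$tn[i]]), alter_label = af$label,
      relation_class = rc, sex = nodes$sex[af$j],
      age_approx = nodes$age[af$j],
      perceived_health = ifelse(miss_h, NA, perc_h),
      perceived_effort = ifelse(miss_e, NA, perc_e),
      stringsAsFactors = FALSE)
    # the study resolved grandparents' parent-child labels by direct contact:
    # ship the clarification as an override row
    if (rrel == "grandparent") {
      for (k in seq_len(nrow(af))) {
        if (nodes$rel[af$j[k]] %in% c("father", "mother")) {
          overrides[[length(overrides) + 1]] <- data.frame(
            household_id = hid, reporter_id = unname(pid[nodes$tn[i]]),
            alter_label = af$label[k],
            resolved_label = nodes$rel[af$j[k]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  alters <- do.call(rbind, alters)

  # ratings: every (self, alter) pair; alter-alter pairs with probability
  # p_rate_alter_pair when a truth edge exists
  ekey <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  ratings <- list()
  for (i in surveyed_idx) {
    af <- alter_of[[nodes$tn[i]]]
    noise <- function(x) .clipround(x + stats::rnorm(length(x), 0,
                                                     cfg$reporter_noise_sd), 0, 9)
    emit <- function(ia, ib, ref_a, ref_b) {
      k <- match(paste(min(ia, ib), max(ia, ib)), ekey)
      if (is.na(k)) return()
      e <- edges[k, ]
      # align truth direction with (ref_a, ref_b)
      imp_ab <- if (e$i == ia) e$imp_ij else e$imp_ji
      imp_ba <- if (e$i == ia) e$imp_ji else e$imp_ij
      ratings[[length(ratings) + 1]] <<- data.frame(
        reporter_id = unname(pid[nodes$tn[i]]),
        person_a = ref_a, person_b = ref_b,
        interact_freq = noise(e$interact), closeness = noise(e$close),
        eat_freq = noise(e$eat),
        importance_a_in_b = noise(imp_ab), importance_b_in_a = noise(imp_ba),
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(af)))
      emit(i, af$j[k], unname(pid[nodes$tn[i]]), af$label[k])
    if (nrow(af) > 1) {
      cmb <- utils::combn(seq_len(nrow(af)), 2)
      for (c2 in seq_len(ncol(cmb))) {
        if (stats::runif(1) < cfg$p_rate_alter_pair) {
          k1 <- cmb[1, c2]; k2 <- cmb[2, c2]
          emit(af$j[k1], af$j[k2], af$label[k1], af$label[k2])
        }
      }
    }
  }
  ratings <- do.call(rbind, ratings)

  # --- diet outcomes from truth network averages -------------------------
  spouse_pairs <- lapply(which(edges$category == "spouse_partner"),
                         function(k) c(edges$i[k], edges$j[k]))
  truth_avgs <- list()
  for (i in surveyed_idx) {
    spouse_i <- unlist(Filter(function(pr) i %in% pr, spouse_pairs))
    spouse_i <- setdiff(spouse_i, i)
    scope_idx <- list(
      full = setdiff(seq_len(nrow(nodes)), i),
      family_excl_spouse = setdiff(which(nodes$rel != "friend"),
                                   c(i, spouse_i)),
      friends = which(nodes$rel == "friend" & nodes$owner == nodes$tn[i]))
    for (sc in names(scope_idx)) {
      ids <- scope_idx[[sc]]
      if (!length(ids)) next
      inc <- edges[(edges$i == i & edges$j %in% ids) |
                     (edges$j == i & edges$i %in% ids), , drop = FALSE]
      truth_avgs[[length(truth_avgs) + 1]] <- data.frame(
        participant_id = unname(pid[nodes$tn[i]]), scope = sc,
        avg_health = mean(nodes$health[ids]),
        avg_effort = mean(nodes$effort[ids]),
        avg_eat = if (nrow(inc)) mean(inc$eat) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  truth_avgs <- do.call(rbind, truth_avgs)
  for (out in names(cfg$diet_truth)) {
    dt <- cfg$diet_truth[[out]]
    col <- switch(out, veg_meets = "diet_veg", fruit_meets = "diet_fruit",
                  fastfood_none = "diet_fastfood", snacks_low = "diet_snacks")
    lev <- integer(nrow(participants))
    for (r in seq_len(nrow(participants))) {
      ta <- truth_avgs[truth_avgs$participant_id ==
                         participants$participant_id[r] &
                         truth_avgs$scope == dt$scope, , drop = FALSE]
      lp <- dt$intercept
      if (nrow(ta) == 1) {
        lp <- lp + dt$b_health * (ta$avg_health - 7) +
          dt$b_effort * (ta$avg_effort - 6.6) +
          (if (!is.na(ta$avg_eat)) dt$b_eat * (ta$avg_eat - 5) else 0)
      }
      flag <- stats::runif(1) < stats::plogis(lp)
      # map the flag back to an ordinal level consistent with the threshold
      lev[r] <- switch(out,
        veg_meets = if (flag) sample(4:6, 1) else sample(0:3, 1),
        fruit_meets = if (flag) sample(3:6, 1) else sample(0:2, 1),
        fastfood_none = if (flag) 0L else sample(1:4, 1),
        snacks_low = if (flag) sample(0:1, 1) else sample(2:6, 1))
    }
    participants[[col]] <- lev
  }

  list(participants = participants, alters = alters, ratings = ratings,
       overrides = if (length(overrides)) do.call(rbind, overrides) else NULL,
       truth = list(household_id = hid, nodes = nodes, edges = edges,
                    truth_avgs = truth_avgs))
}

#' Generate a synthetic survey cohort
#'
#' @param config from [generator_config()]; \code{config$seed} fixes all
#'   randomness (identical config => identical tables).
#' @return list with data frames \code{participants}, \code{alters},
#'   \code{ratings}, \code{overrides}, and \code{truth} (per-household
#'   ground-truth node/edge tables plus the generating config).
#' @export
generate_cohort <- function(config = generator_config()) {
  if (config$n_households < 1)
    stop("config error: n_households must be >= 1", call. = FALSE)
  if (!all(vapply(config$templates, length, numeric(1)) >= 1))
    stop("config error: each template needs >= 1 co-surveyed member",
         call. = FALSE)
  set.seed(config$seed)
  hh <- lapply(seq_len(config$n_households), .gen_household, cfg = config)
  overrides <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(hh, `[[`, "overrides")))
  if (is.null(overrides))
    overrides <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 4)),
                                 .override_cols)
  structure(list(
    participants = do.call(rbind, lapply(hh, `[[`, "participants")),
    alters = do.call(rbind, lapply(hh, `[[`, "alters")),
    ratings = do.call(rbind, lapply(hh, `[[`, "ratings")),
    overrides = overrides,
    truth = c(lapply(hh, `[[`, "truth"), list(config = config))),
    class = "kinnet_cohort")
}

#' Remove clarifications to force ambiguity resolution by matching
#'
#' The default cohort ships manual-override rows for labels whose kinship
#' composition is ambiguous without clarification (a grandparent reporting a
#' "son" who may be the index adult's father or uncle). This helper deletes
#' those override rows for a fraction \code{rate} of the eligible labels so
#' the pipeline must resolve them by cross-reporter matching, and returns the
#' expected resolutions as a key for testing.
#'
#' @param cohort a \code{kinnet_cohort}.
#' @param rate fraction of eligible override-backed labels to strip, in
#'   [0, 1]. Rate 0 returns the cohort unchanged.
#' @return the cohort with reduced \code{overrides} plus an
#'   \code{ambiguity_key} data frame (household_id, reporter_id, alter_label,
#'   true_relation).
#' @export
inject_ambiguity <- function(cohort, rate = 0.1) {
  stopifnot(rate >= 0, rate <= 1)
  ov <- cohort$overrides
  if (rate == 0 || !nrow(ov)) {
    cohort$ambiguity_key <- ov[0, ]
    return(cohort)
  }
  n_strip <- ceiling(rate * nrow(ov))
  strip <- sort(sample.int(nrow(ov), n_strip))
  key <- ov[strip, , drop = FALSE]
  names(key)[names(key) == "resolved_label"] <- "true_relation"
  cohort$overrides <- ov[-strip, , drop = FALSE]
  cohort$ambiguity_key <- key
  cohort
}

#' Fast path: directed dyad records straight from the mixed model
#'
#' Bypasses the survey-table representation and fusion to generate directed
#' dyad records directly from the importance model, for parameter-recovery
#' and calibration simulations at many replicates.
#'
#' @param n_households number of households.
#' @param nodes_per_household nodes per household.
#' @param truth dyad-model truth list (as in [generator_config()]'s
#'   \code{dyad_truth}); category effects applied via random categories.
#' @param eat_from_interact make eating frequency a deterministic-plus-noise
#'   function of interaction frequency (mediation structure).
#' @param discretize round and clamp the outcome to the survey's 0--9 grid.
#'   The default keeps the linear-model outcome continuous so that recovery
#'   simulations test the estimator against the exact generating
#'   coefficients; the full survey generator always discretizes.
#' @return data frame consumable by [fit_dyad_mixed()].
#' @export
generate_dyad_records <- function(n_households = 200, nodes_per_household = 6,
                                  truth = generator_config()$dyad_truth,
                                  eat_from_interact = FALSE,
                                  discretize = FALSE) {
  npn <- nodes_per_household
  cmb <- utils::combn(npn, 2)
  npairs <- ncol(cmb)
  H <- n_households
  # node-level draws, one row per (household, node)
  n_nodes <- H * npn
  age <- round(stats::runif(n_nodes, 20, 75))
  sex <- .draw_sex(n_nodes, 0.5)
  health <- .clipround(stats::rnorm(n_nodes, 7, 1.6), 1, 10)
  effort <- .clipround(stats::rnorm(n_nodes, 6.6, 1.9), 1, 10)
  u_src <- stats::rnorm(n_nodes, 0, truth$sd_source)
  u_tgt <- stats::rnorm(n_nodes, 0, truth$sd_target)
  u_hh <- rep(stats::rnorm(H, 0, truth$sd_household), each = npairs)
  # pair-level draws, one row per (household, pair)
  np <- H * npairs
  hh <- rep(seq_len(H), each = npairs)
  i_idx <- (hh - 1) * npn + rep(cmb[1, ], H)
  j_idx <- (hh - 1) * npn + rep(cmb[2, ], H)
  interact <- sample(0:9, np, replace = TRUE)
  close <- sample(0:9, np, replace = TRUE)
  eat <- if (eat_from_interact)
    .clipround(interact + stats::rnorm(np, 0, 0.8), 0, 9)
  else sample(0:9, np, replace = TRUE)
  cat_ <- sample(c("friend", "intragenerational", "intergenerational",
                   "spouse_partner"), np, replace = TRUE,
                 prob = c(0.35, 0.2, 0.39, 0.06))
  inter <- cat_ == "intergenerational"
  sub_ij <- ifelse(inter, sample(c("target_older", "target_younger"), np,
                                 replace = TRUE), "same")
  sub_ji <- ifelse(inter, ifelse(sub_ij == "target_older", "target_younger",
                                 "target_older"), "same")
  ce <- function(sub) ifelse(inter, truth$cat[paste0("intergenerational_", sub)],
                             truth$cat[cat_])
  lp_common <- truth$intercept + truth$b_interact * (interact - 4.5) +
    truth$b_close * (close - 4.5) + truth$b_eat * (eat - 4.5) + u_hh
  out_ij <- lp_common + ce(sub_ij) + u_src[i_idx] + u_tgt[j_idx] +
    stats::rnorm(np, 0, truth$sd_noise)
  out_ji <- lp_common + ce(sub_ji) + u_src[j_idx] + u_tgt[i_idx] +
    stats::rnorm(np, 0, truth$sd_noise)
  if (discretize) {
    out_ij <- .clipround(out_ij, 0, 9)
    out_ji <- .clipround(out_ji, 0, 9)
  }
  hid <- sprintf("h%03d", hh)
  node_id <- function(k) paste0(sprintf("h%03d", (k - 1) %/% npn + 1),
                                "_n", (k - 1) %% npn + 1)
  mk <- function(src, tgt, outc, sub) data.frame(
    household_id = hid, interact_freq = interact, closeness = close,
    eat_freq = eat, category = cat_,
    source_node = node_id(src), target_node = node_id(tgt), outcome = outc,
    direction_subtype = sub,
    source_age = age[src], source_sex = sex[src], source_health = health[src],
    source_effort = effort[src], source_surveyed = TRUE,
    source_participant = NA_character_,
    target_age = age[tgt], target_sex = sex[tgt], target_health = health[tgt],
    target_effort = effort[tgt], target_surveyed = TRUE,
    stringsAsFactors = FALSE)
  out <- rbind(mk(i_idx, j_idx, out_ij, sub_ij),
               mk(j_idx, i_idx, out_ji, sub_ji))
  rownames(out) <- NULL
  out
}

#' Fast path: clustered binary outcomes for the diet models
#'
#' Generates household-clustered participants with network-average
#' covariates and a binary outcome from a marginal logistic model (plus an
#' optional latent household effect inducing within-cluster correlation).
#'
#' @param n_households number of household clusters.
#' @param size_range participants per household (inclusive range).
#' @param beta named vector: intercept and log-odds for avg_health,
#'   avg_effort, avg_eat.
#' @param sd_household latent household effect sd (0 = independent).
#' @return data frame with household_id, avg_health, avg_effort, avg_eat, y.
#' @export
generate_gee_data <- function(n_households = 300, size_range = c(2, 4),
                              beta = c(intercept = -0.5, avg_health = 0,
                                       avg_effort = log(0.5), avg_eat = 0),
                              sd_household = 0.3) {
  rows <- list()
  for (h in seq_len(n_households)) {
    n <- sample(seq(size_range[1], size_range[2]), 1)
    u <- stats::rnorm(1, 0, sd_household)
    avg_health <- stats::rnorm(n, 7, 1)
    avg_effort <- stats::rnorm(n, 6.6, 1)
    avg_eat <- stats::rnorm(n, 5, 1.5)
    lp <- beta[["intercept"]] + beta[["avg_health"]] * (avg_health - 7) +
      beta[["avg_effort"]] * (avg_effort - 6.6) +
      beta[["avg_eat"]] * (avg_eat - 5) + u
    rows[[h]] <- data.frame(
      household_id = sprintf("h%03d", h), avg_health = avg_health,
      avg_effort = avg_effort, avg_eat = avg_eat,
      y = as.numeric(stats::runif(n) < stats::plogis(lp)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
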