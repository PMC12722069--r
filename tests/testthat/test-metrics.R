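test_that("network size summary computes cohort moments", {
  nets <- default_networks()
  s <- summarize_networks(nets[1:2])
  n1 <- nrow(nets[[1]]$registry); n2 <- nrow(nets[[2]]$registry)
  expect_equal(s$cohort$mean[s$cohort$measure == "n_nodes"], mean(c(n1, n2)))
  expect_equal(s$cohort$sd[s$cohort$measure == "n_nodes"], sd(c(n1, n2)))
  # degenerate single network: sd undefined
  s1 <- summarize_networks(nets[1])
  expect_true(is.na(s1$cohort$sd[1]))
  # hand-checked: sizes 8 and 12 give mean 10, sd 2.83
  expect_equal(sd(c(8, 12)), 2.8284, tolerance = 1e-4)
})

test_that("category means pool directed records and split by direction", {
  net <- fuse_household(triple_report_household())
  cm <- category_means(list(net))
  fr <- cm[cm$category == "friend", ]
  expect_equal(fr$closeness, 2)          # both directions of the one friend tie
  expect_equal(fr$n_records, 2L)
  inter <- cm[cm$category == "intergenerational", ]
  expect_setequal(inter$direction, c("target_older", "target_younger"))
  # importance splits by direction: child->father 5.5, father->child 6.5
  expect_equal(inter$importance[inter$direction == "target_older"], 5.5)
  expect_equal(inter$importance[inter$direction == "target_younger"], 6.5)
  # absent categories yield no row rather than a zero
  expect_false("intragenerational" %in% cm$category)
})

test_that("numeric assortativity matches the brute-force oracle", {
  # path graph A(1)-B(2)-C(3), equal weights
  nw <- toy_network(
    data.frame(node_id = c("A", "B", "C"), term = "friend", sex = "m",
               age = c(1, 2, 3), health = c(1, 2, 3), effort = 1),
    data.frame(a = c("A", "B"), b = c("B", "C"), w = c(1, 1)))
  oracle <- brute_assort_numeric(c(A = 1, B = 2, C = 3), c("A", "B"),
                                 c("B", "C"), c(1, 1))
  expect_equal(assortativity_numeric(nw, "age", "eat_freq"), oracle)
  # all-equal attribute: undefined
  nw2 <- toy_network(
    data.frame(node_id = c("A", "B"), term = "friend", sex = "m",
               age = 5, health = 5, effort = 5),
    data.frame(a = "A", b = "B", w = 2))
  expect_true(is.na(assortativity_numeric(nw2, "age", "eat_freq")))
})

test_that("equal weights reduce to the classical coefficient (igraph oracle)", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, 0.6)
    if (igraph::ecount(g) < 2) next
    x <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    el <- igraph::as_edgelist(g)
    ids <- paste0("n", seq_len(n))
    nw <- toy_network(
      data.frame(node_id = ids, term = "friend", sex = "m", age = x,
                 health = x, effort = x),
      data.frame(a = ids[el[, 1]], b = ids[el[, 2]], w = 1))
    expect_equal(assortativity_numeric(nw, "age", "eat_freq"),
                 igraph::assortativity(g, values = x), tolerance = 1e-10)
  }
})

test_that("categorical assortativity has the closed-form extremes", {
  # two same-sex couples eating only within couple: perfectly assortative
  nw <- toy_network(
    data.frame(node_id = c("A", "B", "C", "D"), term = "friend",
               sex = c("m", "m", "f", "f"), age = 1, health = 1, effort = 1),
    data.frame(a = c("A", "C"), b = c("B", "D"), w = c(3, 2)))
  expect_equal(assortativity_categorical(nw, "sex", "eat_freq"), 1)
  # complete bipartite male-female: perfectly disassortative
  nw2 <- toy_network(
    data.frame(node_id = c("A", "B", "C", "D"), term = "friend",
               sex = c("m", "m", "f", "f"), age = 1, health = 1, effort = 1),
    data.frame(a = c("A", "A", "B", "B"), b = c("C", "D", "C", "D"), w = 1))
  expect_equal(assortativity_categorical(nw2, "sex", "eat_freq"), -1)
  # single category: undefined
  nw3 <- toy_network(
    data.frame(node_id = c("A", "B"), term = "friend", sex = "m",
               age = 1, health = 1, effort = 1),
    data.frame(a = "A", b = "B", w = 1))
  expect_true(is.na(assortativity_categorical(nw3, "sex", "eat_freq")))
})

test_that("coefficients are invariant to weight scaling and relabelling", {
  set.seed(72)
  attrs <- data.frame(node_id = paste0("n", 1:5), term = "friend",
                      sex = c("m", "f", "m", "f", "m"),
                      age = c(20, 45, 70, 33, 51),
                      health = c(5, 7, 3, 8, 6), effort = c(2, 9, 4, 6, 5))
  edges <- data.frame(a = c("n1", "n1", "n2", "n3", "n4"),
                      b = c("n2", "n3", "n4", "n5", "n5"),
                      w = c(1, 3, 2, 2, 1))
  nw <- toy_network(attrs, edges)
  base_num <- assortativity_numeric(nw, "self_health", "eat_freq")
  base_cat <- assortativity_categorical(nw, "sex", "eat_freq")
  scaled <- toy_network(attrs, transform(edges, w = w * 7.3))
  expect_equal(assortativity_numeric(scaled, "self_health", "eat_freq"),
               base_num)
  expect_equal(assortativity_categorical(scaled, "sex", "eat_freq"), base_cat)
  # permute node labels
  perm <- c(n1 = "x4", n2 = "x1", n3 = "x5", n4 = "x2", n5 = "x3")
  attrs2 <- transform(attrs, node_id = unname(perm[node_id]))
  edges2 <- transform(edges, a = unname(perm[a]), b = unname(perm[b]))
  nw2 <- toy_network(attrs2[order(attrs2$node_id), ], edges2)
  expect_equal(assortativity_numeric(nw2, "self_health", "eat_freq"), base_num)
  expect_equal(assortativity_categorical(nw2, "sex", "eat_freq"), base_cat)
})

test_that("zero-weight edges contribute nothing", {
  attrs <- data.frame(node_id = c("A", "B", "C"), term = "friend",
                      sex = c("m", "f", "m"), age = c(1, 2, 9),
                      health = c(1, 2, 9), effort = 1)
  with_zero <- toy_network(attrs, data.frame(a = c("A", "A"), b = c("B", "C"),
                                             w = c(2, 0)))
  without <- toy_network(attrs, data.frame(a = "A", b = "B", w = 2))
  expect_equal(assortativity_numeric(with_zero, "age", "eat_freq"),
               assortativity_numeric(without, "age", "eat_freq"))
})

test_that("cohort assortativity drops undefined networks with a count", {
  nets <- default_networks()
  tab <- assortativity_cohort(nets[1:8])
  expect_equal(unique(tab$n_networks + tab$n_undefined), 8)
  expect_true(all(abs(tab$mean[!is.na(tab$mean)]) <= 1))
})
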