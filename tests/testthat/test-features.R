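test_that("neighborhood enumerates neighbour weights and common neighbours", {
  net <- net_from("i j 10", "i k 4", "j k 6")
  nv <- neighborhood(net, "i", "j")
  expect_setequal(nv$neighbor_weights, c(4, 6))
  expect_equal(nv$common$k, "k")
  expect_equal(nv$common$w_ik, 4)
  expect_equal(nv$common$w_jk, 6)

  nv2 <- neighborhood(net_from("i j 5", "i k 7"), "i", "j")
  expect_equal(nv2$neighbor_weights, 7)
  expect_equal(nrow(nv2$common), 0L)

  nv3 <- neighborhood(net_from("i j 3"), "i", "j")
  expect_length(nv3$neighbor_weights, 0L)
  expect_error(neighborhood(net, "i", "zz"), "not an edge")
})

test_that("the seven features match their hand-computed definitions", {
  net <- net_from("i j 10", "i k 4", "j k 6")
  dom <- domain_annotation(list(i = c(d1 = 2L, d2 = 1L), j = c(d3 = 1L)))
  expect_equal(compute_features(net, dom, "i", "j"),
               c(F1 = 10, F2 = 6, F3 = 4, F4 = 4, F5 = 2, F6 = 3, F7 = 1))

  # isolated edge: neighbourhood features default to zero
  expect_equal(compute_features(net_from("i j 7.5"), domain_annotation(), "i", "j"),
               c(F1 = 7.5, F2 = 0, F3 = 0, F4 = 0, F5 = 0, F6 = 0, F7 = 0))

  # neighbour of one member only: no common neighbour, F4 = F5 = 0
  net3 <- net_from("i j 5", "i k 7")
  dom3 <- domain_annotation(list(i = c(d1 = 1L), j = c(d1 = 1L)))
  expect_equal(compute_features(net3, dom3, "i", "j"),
               c(F1 = 5, F2 = 7, F3 = 7, F4 = 0, F5 = 0, F6 = 1, F7 = 1))
})

test_that("the alternative F5 readings are linear in F1-F3", {
  net <- net_from("i j 10", "i k 4", "j m 6")
  d0 <- domain_annotation()
  expect_equal(unname(compute_features(net, d0, "i", "j", "range")[["F5"]]), 2)
  expect_equal(unname(compute_features(net, d0, "i", "j", "inside_minus_min")[["F5"]]), 6)
  expect_equal(unname(compute_features(net, d0, "i", "j")[["F5"]]), 0)  # no common
})

test_that("feature computation is symmetric and satisfies ordering bounds", {
  set.seed(5)
  for (rep in 1:60) {
    net <- random_network(10)
    dom <- random_domains(net$vertices)
    e <- net$edges[sample(nrow(net$edges), 1), ]
    fij <- compute_features(net, dom, e$a, e$b)
    fji <- compute_features(net, dom, e$b, e$a)
    expect_equal(fij, fji)
    expect_gte(fij[["F2"]], fij[["F4"]])
    expect_gte(fij[["F2"]], fij[["F3"]])
    expect_gte(fij[["F6"]], fij[["F7"]])
  }
})

test_that("weight features agree with a brute-force edge scan on random graphs", {
  set.seed(6)
  for (rep in 1:100) {
    net <- random_network(10)
    e <- net$edges[sample(nrow(net$edges), 1), ]
    got <- compute_features(net, domain_annotation(), e$a, e$b)[1:5]
    expect_equal(got, brute_features_w(net, e$a, e$b))
  }
})

test_that("adding a neighbouring edge never decreases F2", {
  set.seed(8)
  for (rep in 1:30) {
    net <- random_network(8)
    e <- net$edges[sample(nrow(net$edges), 1), ]
    f2_before <- compute_features(net, domain_annotation(), e$a, e$b)[["F2"]]
    new_edge <- data.frame(a = e$a, b = sprintf("zz%d", rep),
                           weight = round(runif(1, 0.1, 12), 3))
    net2 <- ppi_network(rbind(net$edges, new_edge))
    f2_after <- compute_features(net2, domain_annotation(), e$a, e$b)[["F2"]]
    expect_gte(f2_after, f2_before)
  }
})

test_that("min-max scaling is fit on training rows only", {
  sc <- scale_features(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(as.vector(sc$train), c(0, 0.5, 1))

  sc2 <- scale_features(matrix(c(0, 10), ncol = 1), matrix(20, ncol = 1))
  expect_equal(as.vector(sc2$apply), 2)   # no clipping outside the train range

  sc3 <- scale_features(matrix(c(3, 3), ncol = 1))
  expect_equal(as.vector(sc3$train), c(0, 0))
  expect_error(scale_features(matrix(numeric(0), ncol = 7)), "non-empty")
})

test_that("feature subsets parse shorthand names", {
  ft <- toy_feature_table(1:3, c(1L, -1L, 1L))
  expect_equal(colnames(feature_columns(ft, "F1-5")), paste0("F", 1:5))
  expect_equal(colnames(feature_columns(ft, "F1-5,7")), paste0("F", c(1:5, 7)))
  expect_equal(colnames(feature_columns(ft, c("F2", "F6"))), c("F2", "F6"))
  expect_error(feature_columns(ft, "F1-9"), "unknown feature")
})
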