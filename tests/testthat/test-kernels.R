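test_that("protein equivalence is exact multiset identity", {
  expect_true(protein_equivalent(c(d1 = 2L, d2 = 1L), c(d2 = 1L, d1 = 2L)))
  expect_false(protein_equivalent(c(d1 = 2L), c(d1 = 1L)))
  comp <- c(a = 3L, b = 1L)
  expect_true(protein_equivalent(comp, comp))
})

test_that("set equivalence matches under a crossed permutation", {
  dom <- domain_annotation(list(
    p1 = c(a = 2L, b = 1L), p2 = c(c = 1L),
    q1 = c(c = 1L), q2 = c(a = 2L, b = 1L),
    r2 = c(a = 1L, b = 1L)))
  expect_true(set_equivalent(c("p1", "p2"), c("q1", "q2"), dom))
  expect_equal(kdc(c("p1", "p2"), c("q1", "q2"), dom), 1)
  # a direct position-by-position rule would reject the crossed matching
  expect_false(protein_equivalent(domain_composition(dom, "p1"),
                                  domain_composition(dom, "q1")))
  expect_false(set_equivalent(c("p1", "p2"), c("q1", "r2"), dom))
  expect_equal(kdc(c("p1", "p2"), c("q1", "r2"), dom), 0)
  expect_true(set_equivalent(c("p1", "p2"), c("p1", "p2"), dom))
  expect_false(set_equivalent(c("p1"), c("q1", "q2"), dom))
})

test_that("canonical-form equivalence agrees with permutation enumeration", {
  set.seed(13)
  for (rep in 1:60) {
    prots <- sprintf("s%d", 1:8)
    dom <- random_domains(prots, vocab = 3, annotate_prob = 0.8)
    n <- sample(1:4, 1)
    X <- sample(prots, n); Y <- sample(prots, n)
    expect_identical(set_equivalent(X, Y, dom),
                     perm_set_equivalent(X, Y, dom))
  }
})

test_that("set equivalence is an equivalence relation", {
  set.seed(17)
  prots <- sprintf("t%d", 1:9)
  dom <- random_domains(prots, vocab = 2, annotate_prob = 0.7)
  sets <- lapply(1:12, function(i) sample(prots, 2))
  for (x in sets) expect_true(set_equivalent(x, x, dom))       # reflexive
  for (x in sets) for (y in sets) {
    expect_identical(set_equivalent(x, y, dom), set_equivalent(y, x, dom))
    for (z in sets)                                             # transitive
      if (set_equivalent(x, y, dom) && set_equivalent(y, z, dom))
        expect_true(set_equivalent(x, z, dom))
  }
})

test_that("unannotated proteins are self-equivalent but not cross-equivalent by default", {
  dom <- domain_annotation(list(p1 = c(a = 1L)))
  expect_true(set_equivalent(c("u1", "p1"), c("u1", "p1"), dom))
  expect_false(set_equivalent(c("u1"), c("u2"), dom))
  expect_true(set_equivalent(c("u1"), c("u2"), dom, unannotated = "empty"))
})

test_that("combined kernel honours the mixing limits and both forms", {
  fx <- c(1, 2); fy <- c(0.5, 1)
  expect_equal(combined_kernel(fx, fy, 1, kernel_config(0)), sum(fx * fy))
  expect_equal(combined_kernel(fx, fy, 1, kernel_config(0, form = "additive")),
               sum(fx * fy))
  expect_equal(combined_kernel(fx, fy, 0, kernel_config(1)), 0)
  expect_equal(combined_kernel(fx, fy, 1, kernel_config(1)), 1)
  expect_equal(combined_kernel(c(2, 0), c(1, 5), 1, kernel_config(0.5)), 1.5)
  expect_equal(combined_kernel(fx, fy, 1, kernel_config(2, form = "additive")),
               sum(fx * fy) + 2)
  expect_error(kernel_config(1.5), "alpha")
  expect_error(kernel_config(-0.1, form = "additive"), "alpha")
})

test_that("the indicator Gram is block-structured over equivalence classes", {
  dom <- domain_annotation(list(a1 = c(x = 1L), a2 = c(y = 1L),
                                b1 = c(x = 1L), b2 = c(y = 1L),
                                c1 = c(z = 2L), c2 = c(z = 1L)))
  ex <- data.frame(protein_a = c("a1", "b1", "c1"),
                   protein_b = c("a2", "b2", "c2"), stringsAsFactors = FALSE)
  K <- kdc_gram(ex, dom)
  expect_equal(K, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  # all distinct classes with alpha = 1 convex: the identity matrix
  ex2 <- data.frame(protein_a = c("a1", "c1"), protein_b = c("c2", "c2"))
  X <- matrix(0, 2, 2)
  expect_equal(build_gram(ex2, X, dom, kernel_config(1)), diag(2))
})

test_that("class-bucketed Gram equals brute-force pairwise permutation kernel", {
  set.seed(19)
  for (rep in 1:10) {
    prots <- sprintf("g%d", 1:10)
    dom <- random_domains(prots, vocab = 2, annotate_prob = 0.8)
    ex <- data.frame(protein_a = sample(prots, 8, replace = TRUE),
                     protein_b = sample(prots, 8, replace = TRUE),
                     stringsAsFactors = FALSE)
    K <- kdc_gram(ex, dom)
    brute <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
      as.numeric(perm_set_equivalent(c(ex$protein_a[[i]], ex$protein_b[[i]]),
                                     c(ex$protein_a[[j]], ex$protein_b[[j]]),
                                     dom))))
    expect_equal(K, brute)
  }
})

test_that("indicator and convex-combination Grams are positive semidefinite", {
  set.seed(23)
  for (rep in 1:25) {
    prots <- sprintf("h%d", 1:12)
    dom <- random_domains(prots, vocab = 3)
    ex <- data.frame(protein_a = sample(prots, 20, replace = TRUE),
                     protein_b = sample(prots, 20, replace = TRUE),
                     stringsAsFactors = FALSE)
    K <- kdc_gram(ex, dom)
    expect_true(isSymmetric(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    X <- matrix(rnorm(20 * 7), 20)
    Kc <- build_gram(ex, X, dom, kernel_config(runif(1)))
    expect_gte(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(Kc)))
  }
})

test_that("build_gram rejects inconsistent indexing", {
  ex <- data.frame(protein_a = "a", protein_b = "b")
  expect_error(build_gram(ex, matrix(0, 2, 7), domain_annotation(),
                          kernel_config(0)), "inconsistent")
})
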