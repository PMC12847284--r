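fixture_model <- function(n = 2L) {
  we <- worked_example()
  nsbc_from_bits(we$bit_strings, we$labels, profile = we$profile, n = n)
}

test_that("hamming counts differing positions and matches a naive oracle", {
  expect_identical(hamming("110010", "101111"), 4L)
  x <- "10110"
  expect_identical(hamming(x, x), 0L)
  expect_identical(hamming("10110", "01001"), 5L)
  withr::with_seed(21, {
    for (rep in 1:20) {
      a <- sample(0:1, 64, replace = TRUE)
      b <- sample(0:1, 64, replace = TRUE)
      expect_identical(hamming(a, b), hamming_oracle(a, b))
    }
  })
  expect_error(hamming("101", "10"), "equal length")
})

test_that("memory fitting records class structure", {
  m <- fixture_model()
  expect_identical(m$K, c(A = 2L, B = 3L))
  expect_identical(m$K_min, 2L)
  expect_identical(m$u, 6L)
  expect_error(nsbc_from_bits(c("01", "10"), c("a", "a")), "two classes")
  expect_error(nsbc_from_bits(c("01", "10"), c("a")), "one label per pattern")
})

test_that("similarity vector is u minus Hamming distance, in stored order", {
  m <- fixture_model()
  z <- similarity_vector(m, "110010")
  expect_identical(z, c(2L, 4L, 3L, 4L, 5L))
  # query equal to a stored pattern scores u there
  expect_identical(similarity_vector(m, "111110")[2], 6L)
  expect_error(similarity_vector(m, "1100"), "bits")
})

test_that("similarity + distance conserve the bit length", {
  withr::with_seed(22, {
    bits <- rand_bits(30, 40)
    labs <- rep(c("a", "b", "c"), each = 10)
    m <- nsbc_from_bits(bits, labs)
    q <- sample(0:1, 40, replace = TRUE)
    z <- similarity_vector(m, q)
    H <- apply(bits, 1, function(row) hamming_oracle(row, q))
    expect_true(all(z + H == 40L))
    expect_true(all(z >= 0L & z <= 40L))
  })
})

test_that("top-n class scores match a sort-and-sum oracle", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      bits <- rand_bits(24, 16)
      labs <- sample(c("a", "b", "c"), 24, replace = TRUE)
      if (length(unique(labs)) < 3 || min(table(labs)) < 3) next
      m <- nsbc_from_bits(bits, labs, n = 3)
      q <- sample(0:1, 16, replace = TRUE)
      z <- similarity_vector(m, q)
      sc <- class_scores(m, z, n = 3)
      expect_equal(sc$scores, topn_oracle(z, labs, 3))
      # selected indices really carry the score
      for (cls in names(sc$scores)) {
        expect_equal(sum(z[sc$selected[[cls]]]), unname(sc$scores[cls]))
      }
    }
  })
})

test_that("n larger than a class clamps with a warning and sums the whole class", {
  m <- fixture_model()
  z <- similarity_vector(m, "110010")
  expect_warning(sc <- class_scores(m, z, n = 10), "K_min")
  expect_equal(unname(sc$scores), c(sum(z[1:2]), sum(z[3:5])))
  expect_identical(unname(sc$n_used), c(2L, 3L))
})

test_that("decision is one-hot over maxima with lowest-index tie-break", {
  m <- fixture_model()
  sc <- class_scores(m, c(2L, 4L, 3L, 4L, 5L), n = 2)
  expect_identical(sc$onehot, c(A = 0L, B = 1L))
  expect_identical(sc$predicted, "B")
  # engineered tie: query at equal aggregate similarity to both classes
  z_tie <- c(5L, 4L, 3L, 4L, 5L)
  sc2 <- class_scores(m, z_tie, n = 2)
  expect_identical(sc2$onehot, c(A = 1L, B = 1L))
  expect_identical(sc2$predicted, "A")
})

test_that("with n = 1 and a unique best match the decision is Hamming 1-NN", {
  withr::with_seed(24, {
    for (rep in 1:10) {
      bits <- rand_bits(20, 24)
      labs <- rep(c("a", "b"), each = 10)
      m <- nsbc_from_bits(bits, labs, n = 1)
      q <- sample(0:1, 24, replace = TRUE)
      z <- similarity_vector(m, q)
      if (sum(z == max(z)) != 1L) next
      nn_class <- labs[which.max(z)]
      expect_identical(predict(m, matrix(q, nrow = 1), n = 1), nn_class)
    }
  })
})

test_that("prediction is invariant to training-row order", {
  withr::with_seed(25, {
    d <- simulate_table(n_samples = 90, n_classes = 3, seed = 9,
                        missing_rate = 0.05)
    q <- d[1:15, setdiff(names(d), "class")]
    m1 <- nsbc_fit(d, label = "class", n = 3)
    perm <- sample.int(nrow(d))
    m2 <- nsbc_fit(d[perm, ], label = "class", n = 3)
    expect_identical(m1$K, m2$K)
    expect_identical(predict(m1, q), predict(m2, q))
  })
})

test_that("duplicating majority patterns beyond the top-n leaves scores unchanged", {
  m <- fixture_model()
  z <- similarity_vector(m, "110010")
  base <- class_scores(m, z, n = 2)$scores
  # append three copies of the weakest B pattern (z = 3); the top-2 B
  # evidence and hence every score must not move
  bits2 <- c(worked_example()$bit_strings, rep("010001", 3))
  labs2 <- c(worked_example()$labels, rep("B", 3))
  m2 <- nsbc_from_bits(bits2, labs2, profile = worked_example()$profile)
  z2 <- similarity_vector(m2, "110010")
  expect_equal(class_scores(m2, z2, n = 2)$scores, base)
})

test_that("batch prediction equals row-wise prediction", {
  withr::with_seed(26, {
    d <- simulate_table(n_samples = 60, seed = 4, missing_rate = 0.05)
    m <- nsbc_fit(d, label = "class", n = 3)
    q <- d[sample.int(60, 12), ]
    batch <- predict(m, q)
    single <- vapply(seq_len(nrow(q)),
                     function(i) predict(m, q[i, , drop = FALSE]), "")
    expect_identical(batch, single)
  })
})

test_that("explanations decompose each score into per-feature matches", {
  m <- fixture_model()
  ex <- explain(m, "110010")
  expect_identical(ex$predicted, "B")
  expect_equal(ex$margin, 3)
  ev <- ex$evidence
  seg_cols <- grep("^match\\.", names(ev))
  expect_true(all(rowSums(ev[, seg_cols, drop = FALSE]) == ev$z))
  # a query equal to a stored pattern matches every segment fully
  ex2 <- explain(m, "110000")
  self <- ex2$evidence[ex2$evidence$pattern == 5L, ]
  expect_identical(unname(unlist(self[seg_cols])), c(3L, 3L))
  expect_identical(self$match, "111111")
})

test_that("relabeling class tokens permutes but does not change decisions", {
  withr::with_seed(27, {
    bits <- rand_bits(20, 12)
    labs <- rep(c("a", "b"), each = 10)
    m1 <- nsbc_from_bits(bits, labs, n = 2)
    m2 <- nsbc_from_bits(bits, ifelse(labs == "a", "zzz", "mmm"), n = 2)
    q <- rand_bits(8, 12)
    s1 <- predict(m1, q, type = "scores")
    untied <- s1[, 1] != s1[, 2]   # the documented tie-break is index-based
    p1 <- predict(m1, q)
    p2 <- predict(m2, q)
    expect_identical(ifelse(p1 == "a", "zzz", "mmm")[untied], p2[untied])
  })
})
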