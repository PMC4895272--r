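test_that("cohesiveness matches direct substitution and handles degenerate sets", {
  # s_ab = 2, external sum = 1, alpha = 2 -> 2 / (2 + 1 + 4) = 2/7
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["a", "b"] <- M["b", "a"] <- 2
  M["a", "c"] <- M["c", "a"] <- 1
  expect_equal(cohesiveness(c("a", "b"), M, alpha = 2), 2 / 7, tolerance = 1e-12)

  # isolated clique, no external edges, alpha = 0 -> exactly 1
  clique <- block_collab(3, inside = 0.7)
  expect_identical(cohesiveness(rownames(clique), clique, alpha = 0), 1)

  # singleton with no edges and positive penalty -> 0
  lone <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(cohesiveness("a", lone, alpha = 1), 0)

  expect_error(cohesiveness(c("a", "zz"), M), class = "mircore_membership_error")
})

test_that("cohesiveness equals the pair-summation oracle on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    ids <- sprintf("v%02d", seq_len(n))
    M <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    M <- (M + t(M)) / 2
    diag(M) <- 0
    members <- sample(ids, sample(1:n, 1))
    alpha <- sample(c(0, 1, 2), 1)
    expect_equal(cohesiveness(members, M, alpha),
                 cohesiveness_oracle(members, M, alpha), tolerance = 1e-12)
  }
})

test_that("growth from a seed recovers its clique in a two-clique graph", {
  M <- block_collab(c(3, 3), inside = 1, outside = 0)
  p0 <- grouping_params(alpha = 0)
  gA <- grow_group("v01", M, p0)
  expect_identical(gA$members, c("v01", "v02", "v03"))
  expect_identical(gA$cohesiveness, 1)
  gB <- grow_group("v05", M, p0)
  expect_identical(gB$members, c("v04", "v05", "v06"))
})

test_that("growth decisions match the brute-force move oracle step by step", {
  # star: hub connected to 5 leaves, no leaf-leaf edges
  ids <- c("hub", sprintf("leaf%d", 1:5))
  M <- matrix(0, 6, 6, dimnames = list(ids, ids))
  M["hub", -1] <- M[-1, "hub"] <- 1
  attr(M, "side") <- "mirna"
  for (alpha in c(0, 1, 2)) {
    params <- grouping_params(alpha = alpha)
    for (seed in c("hub", "leaf3")) {
      expect_identical(grow_group(seed, M, params)$members,
                       grow_oracle(seed, M, alpha),
                       info = sprintf("alpha=%s seed=%s", alpha, seed))
    }
  }
  # random weighted graphs too
  set.seed(32)
  for (rep in 1:10) {
    n <- 7
    ids <- sprintf("w%02d", seq_len(n))
    M <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n, n,
                dimnames = list(ids, ids))
    M <- (M + t(M)) / 2
    diag(M) <- 0
    attr(M, "side") <- "mirna"
    seed <- sample(ids, 1)
    expect_identical(grow_group(seed, M, grouping_params(alpha = 1))$members,
                     grow_oracle(seed, M, 1))
  }
})

test_that("a seed with no neighbours stays a singleton", {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["b", "c"] <- M["c", "b"] <- 1
  attr(M, "side") <- "mirna"
  g <- grow_group("a", M, grouping_params(alpha = 2))
  expect_identical(g$members, "a")
})

test_that("discover_groups recovers planted disjoint blocks and applies size filters", {
  M <- block_collab(c(4, 5), inside = 1, outside = 0)
  groups <- discover_groups(M, grouping_params(alpha = 0, min_size = 3))
  expect_length(groups, 2)
  sets <- lapply(groups, `[[`, "members")
  expect_true(any(vapply(sets, identical, logical(1), sprintf("v%02d", 1:4))))
  expect_true(any(vapply(sets, identical, logical(1), sprintf("v%02d", 5:9))))

  # a block of 2 falls below min_size = 3 and is absent
  M2 <- block_collab(c(4, 2), inside = 1, outside = 0)
  groups2 <- discover_groups(M2, grouping_params(alpha = 0, min_size = 3))
  expect_length(groups2, 1)
  expect_identical(groups2[[1]]$members, sprintf("v%02d", 1:4))

  # max_size discards the big block
  groups3 <- discover_groups(M, grouping_params(alpha = 0, min_size = 3,
                                                max_size = 4))
  expect_length(groups3, 1)
  expect_identical(groups3[[1]]$members, sprintf("v%02d", 1:4))
})

test_that("overlap score and redundancy merging behave as documented", {
  expect_equal(overlap_score(letters[1:10], letters[2:11]), 81 / 100)
  expect_identical(overlap_score(c("a", "b"), c("c", "d")), 0)
  expect_identical(overlap_score(letters[1:4], letters[1:4]), 1)

  # two groups sharing 9 of 10 members merge at omega = 0.8
  ids <- sprintf("x%02d", 1:11)
  M <- matrix(0.5, 11, 11, dimnames = list(ids, ids))
  diag(M) <- 0
  g1 <- mircore:::new_feature_group(ids[1:10], cohesiveness(ids[1:10], M, 2), "mirna")
  g2 <- mircore:::new_feature_group(ids[2:11], cohesiveness(ids[2:11], M, 2), "mirna")
  merged <- mircore:::merge_overlapping(list(g1, g2), M,
                                        grouping_params(merge_overlap = 0.8), "mirna")
  expect_length(merged, 1)
  expect_identical(merged[[1]]$members, ids)
  expect_equal(merged[[1]]$cohesiveness, cohesiveness(ids, M, 2), tolerance = 1e-12)

  # below the threshold nothing merges
  kept <- mircore:::merge_overlapping(list(g1, g2), M,
                                      grouping_params(merge_overlap = 0.9), "mirna")
  expect_length(kept, 2)
})

test_that("emitted groups carry exact cohesiveness, obey filters, and are deterministic", {
  set.seed(33)
  n <- 40
  ids <- sprintf("r%02d", seq_len(n))
  M <- matrix(runif(n * n) * rbinom(n * n, 1, 0.15), n, n,
              dimnames = list(ids, ids))
  M <- (M + t(M)) / 2
  diag(M) <- 0
  attr(M, "side") <- "mirna"
  params <- grouping_params(alpha = 1, min_size = 2, max_size = 20)
  groups <- discover_groups(M, params)
  for (g in groups) {
    expect_equal(g$cohesiveness, cohesiveness_oracle(g$members, M, 1),
                 tolerance = 1e-12)
    expect_true(length(g$members) >= 2 && length(g$members) <= 20)
  }
  again <- discover_groups(M, params)
  expect_identical(lapply(groups, `[[`, "members"), lapply(again, `[[`, "members"))
  expect_identical(vapply(groups, `[[`, numeric(1), "cohesiveness"),
                   vapply(again, `[[`, numeric(1), "cohesiveness"))
})

test_that("a disjoint union of equal cliques yields exactly the cliques", {
  M <- block_collab(rep(4, 3), inside = 0.8, outside = 0)
  groups <- discover_groups(M, grouping_params(alpha = 0, min_size = 2))
  expect_length(groups, 3)
  expect_identical(sort(unlist(lapply(groups, `[[`, "members"))), rownames(M))
  for (g in groups) expect_length(g$members, 4)
})

test_that("grouping_params validates its inputs", {
  expect_error(grouping_params(alpha = -1), class = "mircore_parameter_error")
  expect_error(grouping_params(min_size = 0), class = "mircore_parameter_error")
  expect_error(grouping_params(min_size = 5, max_size = 3),
               class = "mircore_parameter_error")
  expect_error(grouping_params(merge_overlap = 0), class = "mircore_parameter_error")
})
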