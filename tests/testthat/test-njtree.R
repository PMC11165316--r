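test_that("three taxa solve in closed form", {
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["A"]], 0.05)
  expect_equal(len[["B"]], 0.15)
  expect_equal(len[["C"]], 0.25)
})

test_that("a zero matrix yields an all-zero tree and errors are caught", {
  lab <- sprintf("L%d", 1:5)
  d0 <- matrix(0, 5, 5, dimnames = list(lab, lab))
  tr <- nj_tree(d0)
  expect_true(all(tr$edge.length == 0))
  expect_setequal(tr$tip.label, lab)
  d0[1, 2] <- 0.5   # asymmetric
  expect_error(nj_tree(d0), "symmetric")
  d0[1, 2] <- NA; d0[2, 1] <- NA
  expect_error(nj_tree(d0), "NA")
})

test_that("additive matrices are recovered exactly (topology and path lengths)", {
  # a fixed 4-leaf case first: ((A:1,B:2):3,(C:4,D:5))
  tr0 <- ape::read.tree(text = "((A:1,B:2):1.5,C:4,D:5);")
  d <- stats::cophenetic(tr0)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  tr <- nj_tree(d)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  set.seed(201)
  for (rep in 1:60) {
    case <- random_additive_case(sample(4:7, 1))
    tr <- nj_tree(case$d)
    got <- stats::cophenetic(tr)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(got - case$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(case$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("topology agrees with ape's independent NJ on random matrices", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    lab <- sprintf("T%02d", 1:n)
    m <- matrix(runif(n * n, 0.05, 1), n, n, dimnames = list(lab, lab))
    d <- (m + t(m)) / 2; diag(d) <- 0
    mine <- nj_tree(d)
    theirs <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("tie-breaking is deterministic and negative estimates are clamped", {
  lab <- c("B", "A", "D", "C")
  d0 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  t1 <- nj_tree(d0)
  # identical input gives the identical newick string
  expect_identical(ape::write.tree(t1), ape::write.tree(nj_tree(d0)))
  # permuted input still joins the same label pairs (same unrooted topology)
  tp <- nj_tree(d0[c(4, 3, 2, 1), c(4, 3, 2, 1)])
  expect_true(ape::all.equal.phylo(ape::unroot(t1), ape::unroot(tp),
                                   use.edge.length = FALSE))
  # a matrix known to force a negative NJ estimate
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.45, 0.4,
                0.4, 0.45, 0, 0.05,
                0.45, 0.4, 0.05, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("clades_of yields every internal node with its leaf set, preorder", {
  # caterpillar of 4 leaves: two non-trivial clades below the root
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  cl <- clades_of(tr)
  sets <- lapply(cl, `[[`, "leaves")
  expect_equal(sets[[1]], sort(c("A", "B", "C", "D")))  # root first
  expect_true(any(vapply(sets, identical, TRUE, y = c("A", "B", "C"))))
  expect_true(any(vapply(sets, identical, TRUE, y = c("A", "B"))))
  expect_length(cl, 3)
  # 3-leaf star: a single internal node holding all three leaves
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  cl3 <- clades_of(star)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$leaves, c("A", "B", "C"))
})
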