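test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_build(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # three-point formulas: a=(3+4-5)/2=1, b=(3+5-4)/2=2, c=(4+5-3)/2=3
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(nj_build(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive 4-taxon trees with exact branch lengths", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- cophenetic(tr)
  nj <- nj_build(D)
  expect_true(is_monophyletic(nj, c("a", "b")))  # split ab|cd
  fit <- ols_fit(nj, D)
  expect_lt(fit$sse, 1e-20)
  expect_equal(fit$tree_length, 11)
  tips <- setNames(fit$tree$edge.length[match(seq_len(4), fit$tree$edge[, 2])],
                   fit$tree$tip.label)
  expect_equal(tips[c("a", "b", "c", "d")], c(a = 1, b = 2, c = 3, d = 4))
})

test_that("NJ is invariant to taxon input order", {
  tr <- random_additive_tree(7, seed = 31)
  D <- cophenetic(tr)
  t1 <- nj_build(D)
  perm <- sample(rownames(D))
  t2 <- nj_build(D[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  expect_equal(sort(mitocomp:::bipartition_keys(t1)),
               sort(mitocomp:::bipartition_keys(t2)))
})

test_that("NJ topology agrees with an independent implementation", {
  set.seed(33)
  for (i in 1:3) {
    n <- sample(5:9, 1)
    D <- as.matrix(dist(matrix(runif(n * 4), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(phangorn::RF.dist(nj_build(D), ape::unroot(ape::nj(D))), 0)
  }
})

test_that("NJ+OLS matches a brute-force scan over all unrooted topologies on additive data", {
  for (n in 4:5) {
    tr <- random_additive_tree(n, seed = 40 + n)
    D <- cophenetic(tr)
    all_tops <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = rownames(D))
    sses <- vapply(all_tops, function(t) ols_fit(t, D)$sse, numeric(1))
    # exactly one topology fits perfectly, and NJ finds it
    expect_equal(sum(sses < 1e-16), 1L)
    best <- all_tops[[which.min(sses)]]
    expect_equal(phangorn::RF.dist(nj_build(D), best), 0)
    expect_equal(phangorn::RF.dist(best, tr), 0)
  }
})

test_that("ME refinement is a fixed point on additive data and repairs a bad start", {
  tr <- random_additive_tree(5, seed = 50)
  D <- cophenetic(tr)
  start <- nj_build(D)
  refined <- me_refine(start, D)
  expect_equal(phangorn::RF.dist(refined, start), 0)
  expect_lt(attr(refined, "sse"), 1e-16)

  # start from a deliberately wrong topology: refinement recovers the truth
  wrong <- phangorn::allTrees(5, rooted = FALSE,
                              tip.label = tr$tip.label)
  sses <- vapply(wrong, function(t) ols_fit(t, D)$sse, numeric(1))
  bad_start <- wrong[[which.max(sses)]]
  fixed <- me_refine(bad_start, D)
  expect_equal(phangorn::RF.dist(fixed, tr), 0)
})

test_that("ME tree length never increases along the search", {
  set.seed(55)
  for (i in 1:3) {
    n <- 7
    D <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    start <- nj_build(D)
    l0 <- ols_fit(start, D)$tree_length
    refined <- me_refine(start, D)
    expect_lte(attr(refined, "tree_length"), l0 + 1e-12)
    expect_true(all(refined$edge.length >= 0))  # OLS clamped
  }
})

test_that("unrooted binary trees have n-3 internal bipartitions and support monophyly queries", {
  tr <- random_additive_tree(8, seed = 60)
  keys <- mitocomp:::bipartition_keys(tr)
  expect_length(keys, 8 - 3)
  for (k in keys)
    expect_true(is_monophyletic(tr, strsplit(k, "|", fixed = TRUE)[[1]]))

  star <- ape::read.tree(
    text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_true(is_monophyletic(star, c("a", "b")))
  expect_true(is_monophyletic(star, c("c", "d", "e", "f")))  # complement side
  expect_false(is_monophyletic(star, c("a", "c")))
  expect_false(is_monophyletic(star, c("a", "b", "c")))
})

test_that("newick writing round-trips topology, lengths and support labels", {
  tr <- nj_build(cophenetic(random_additive_tree(6, seed = 70)))
  tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  o <- match(back$tip.label, tr$tip.label)
  expect_equal(sort(round(back$edge.length, 6)),
               sort(round(tr$edge.length, 6)))
  expect_equal(sort(back$node.label), sort(tr$node.label))

  t3 <- nj_build(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                        dimnames = list(letters[1:3], letters[1:3])))
  write_newick(t3, tmp)
  expect_match(readLines(tmp), "^\\(.*a.*b.*c.*\\);$|^\\(.*\\);$")
})
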