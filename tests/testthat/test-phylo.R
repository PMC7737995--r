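test_that("nj_tree solves the 3-taxon path equations exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens, c(a = 1, b = 2, c = 3))
})

test_that("nj_tree recovers the generating 4-taxon tree and handles k = 2", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  # split AB|CD present, internal branch 1, tip lengths 1,2,3,4
  sp <- tree_splits(tr)
  expect_equal(sort(unlist(sp$tips[1])), c("A", "B"))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
  tip_len <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 4],
                             labs[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(tip_len[labs], c(A = 1, B = 2, C = 3, D = 4))
  # additivity: path lengths reproduce the matrix
  expect_equal(unname(ape::cophenetic.phylo(tr)[labs, labs]), unname(d))

  tr2 <- nj_tree(matrix(c(0, 0.4, 0.4, 0), 2,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sum(tr2$edge.length), 0.4)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("nj_tree is exact on random additive matrices (4-8 taxa)", {
  set.seed(17)
  for (n in 4:8) {
    for (rep in 1:3) {
      true <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
      d <- ape::cophenetic.phylo(true)
      labs <- rownames(d)
      est <- nj_tree(d)
      # topology identical (independent oracle: Robinson-Foulds distance)
      expect_equal(phangorn::RF.dist(ape::unroot(est), true), 0)
      # branch lengths reproduce the input matrix through path sums
      expect_equal(ape::cophenetic.phylo(est)[labs, labs], d,
                   tolerance = 1e-9)
    }
  }
})

test_that("nj_tree result is invariant to input label order", {
  set.seed(23)
  true <- ape::unroot(ape::rtree(6, br = function(k) runif(k, 0.1, 1)))
  d <- ape::cophenetic.phylo(true)
  perm <- sample(nrow(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
})

test_that("nj_tree agrees topologically with an independent NJ", {
  set.seed(29)
  al <- generate_dataset(k = 6, L = 150, pops = c(P = 6), divergence = c(2, 20),
                         seed = 5)$alignment
  hs <- collapse_haplotypes(al)
  d <- hamming_matrix(stats::setNames(hs$sequence, hs$haplotype))
  mine <- nj_tree(d)
  theirs <- ape::nj(stats::as.dist(d))
  expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(theirs)), 0)
})

test_that("bootstrap support is 100 on a clean split and seed-reproducible", {
  al <- toy_alignment(
    paste0(c(strrep("A", 20), strrep("A", 20), strrep("C", 20), strrep("C", 20)),
           c("A", "C", "G", "T")),
    labels = c("A", "B", "C", "D"))
  bt <- bootstrap_support(al, B = 100, seed = 7)
  st <- support_table(bt)
  expect_equal(nrow(st), 1L)
  expect_equal(sort(unlist(st$tips[1])), c("A", "B"))
  expect_equal(st$support, 100L)
  expect_identical(bootstrap_support(al, B = 100, seed = 7)$node.label,
                   bt$node.label)
  expect_true(all(st$support >= 0 & st$support <= 100))

  # B = 1: pigeonhole, supports are 0 or 100
  b1 <- bootstrap_support(al, B = 1, seed = 3)
  expect_true(all(stats::na.omit(b1$node.label) %in% c(0L, 100L)))
})

test_that("supports on a signal-free alignment stay below certainty", {
  set.seed(13)
  al <- toy_alignment(replicate(6, paste(sample(c("A", "G"), 40, TRUE),
                                         collapse = "")),
                      labels = paste0("t", 1:6))
  bt <- bootstrap_support(al, B = 50, seed = 99)
  st <- support_table(bt)
  expect_true(all(st$support >= 0 & st$support <= 100))
  expect_lt(min(st$support), 100)
})

test_that("bin_support follows the cut() convention, flag flips boundaries", {
  expect_equal(as.character(bin_support(c(90, 85, 70, 50, 30, 0))),
               c("strong", "moderate", "weak", "poor", "poor", "poor"))
  expect_equal(as.character(bin_support(c(85, 70, 50), closed_left = TRUE)),
               c("strong", "moderate", "weak"))
  # total monotone step function
  s <- seq(0, 100, by = 0.5)
  b <- bin_support(s)
  expect_false(any(is.na(b)))
  expect_true(all(diff(as.integer(b)) >= 0))
  expect_error(bin_support(101), "0, 100")
  expect_error(bin_support(-1), "0, 100")
})

test_that("newick writer round-trips topology, lengths, labels and supports", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(nj_tree(d)), "(A:0.2,B:0.2);")

  set.seed(41)
  true <- ape::unroot(ape::rtree(20))
  s <- write_newick(true)
  back <- read_newick(text = s)
  expect_equal(phangorn::RF.dist(true, back), 0)
  expect_equal(sort(back$edge.length), sort(true$edge.length),
               tolerance = 1e-9)

  # metacharacter labels survive quoting
  qt <- nj_tree(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                       dimnames = rep(list(c("Bayatbadem 24", "Kumluca_6",
                                             "x(1):z")), 2)))
  back2 <- read_newick(text = write_newick(qt))
  expect_setequal(back2$tip.label, qt$tip.label)

  # supports emitted as internal node labels
  al <- toy_alignment(
    paste0(c(strrep("A", 20), strrep("A", 20), strrep("C", 20), strrep("C", 20)),
           c("A", "C", "G", "T")),
    labels = c("A", "B", "C", "D"))
  bt <- bootstrap_support(al, B = 10, seed = 1)
  expect_match(write_newick(bt), "\\)100")
})
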