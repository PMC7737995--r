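test_that("build_network handles the toy cases from first principles", {
  # two haplotypes: one MST link carrying the full distance
  hs2 <- fake_hapset(c("H1", "H2"))
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("H1", "H2"),
                                                 c("H1", "H2")))
  net2 <- build_network(d2, hs2, level = "individual")
  expect_equal(nrow(net2$links), 1L)
  expect_equal(net2$links$weight, 3L)
  expect_equal(net2$links$kind, "mst")
  expect_equal(mst_total_weight(net2), 3L)

  # triangle (1,1,2): the weight-2 pair is absent
  ids <- c("H1", "H2", "H3")
  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, dimnames = list(ids, ids))
  net <- build_network(d, fake_hapset(ids), level = "individual")
  expect_equal(sum(net$links$kind == "mst"), 2L)
  expect_equal(net$links$weight[net$links$kind == "mst"], c(1L, 1L))
  expect_equal(sum(net$links$kind == "alternative"), 0L)

  # equilateral triangle: 2 MST links + 1 equal-cost alternative
  de <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(de) <- 0
  nete <- build_network(de, fake_hapset(ids), level = "individual")
  expect_equal(sum(nete$links$kind == "mst"), 2L)
  expect_equal(sum(nete$links$kind == "alternative"), 1L)
  expect_equal(nete$links$weight[nete$links$kind == "alternative"], 1L)

  expect_error(build_network(d / 2, fake_hapset(ids), level = "individual"),
               "integer")
  expect_error(build_network(d, fake_hapset(c("A", "B", "C")),
                             level = "individual"), "match")
})

test_that("MST weight equals the exhaustive minimum on random matrices", {
  set.seed(37)
  for (k in 3:6) {
    for (rep in 1:8) {
      d <- random_integer_distance(k)
      net <- build_network(d, fake_hapset(rownames(d)), level = "individual")
      expect_equal(sum(net$links$kind == "mst"), k - 1L)
      expect_equal(mst_total_weight(net), bf_mst_weight(d))
    }
  }
})

test_that("cycle property holds and link weights equal the distances", {
  set.seed(43)
  for (rep in 1:6) {
    d <- random_integer_distance(6)
    ids <- rownames(d)
    net <- build_network(d, fake_hapset(ids), level = "individual",
                         alt_threshold = max(d))
    # every link weight equals the Hamming distance of its endpoints
    for (r in seq_len(nrow(net$links))) {
      expect_equal(net$links$weight[r],
                   d[net$links$from[r], net$links$to[r]], ignore_attr = TRUE)
    }
    # no non-tree link is strictly lighter than the heaviest link on the
    # MST path between its endpoints
    alt <- net$links[net$links$kind == "alternative", ]
    for (r in seq_len(nrow(alt))) {
      expect_gte(alt$weight[r],
                 mst_path_max(net$links, alt$from[r], alt$to[r]))
    }
  }
})

test_that("network is deterministic and independent of label order", {
  set.seed(47)
  d <- random_integer_distance(6)
  ids <- rownames(d)
  net1 <- build_network(d, fake_hapset(ids), level = "individual")
  perm <- sample(6)
  hs_p <- fake_hapset(ids[perm])
  net2 <- build_network(d[perm, perm], hs_p, level = "individual")
  key <- function(net) {
    l <- net$links[net$links$kind == "mst", ]
    sort(paste(l$from, l$to, l$weight))
  }
  expect_equal(key(net1), key(net2))
})

test_that("node sizes and composition agree with the frequency matrix", {
  al <- synthetic_reference_alignment()
  hs <- collapse_haplotypes(al)
  pm <- build_population_map(al, groups = reference_groups)
  d <- hamming_matrix(variable_sites(hs))
  net <- build_network(d, hs, pm, level = "population")
  expect_equal(sum(net$nodes$size), 120L)
  pmx <- population_matrix(hs, pm)
  comp_sum <- tapply(net$composition$count, net$composition$haplotype, sum)
  expect_equal(as.vector(comp_sum[hs$haplotype]), hs$hf)
  # per-population composition matches the matrix columns
  for (p in setdiff(names(pmx), "haplotype")) {
    cc <- net$composition[net$composition$category == p, ]
    got <- stats::setNames(rep(0L, nrow(pmx)), pmx$haplotype)
    got[cc$haplotype] <- cc$count
    expect_equal(unname(got), pmx[[p]])
  }

  # group level
  netg <- build_network(d, hs, pm, level = "group")
  expect_setequal(unique(netg$composition$category),
                  c("greenhouse", "firm", "nature"))
})

test_that("the reference 20-haplotype matrix gives the anchored MST weight", {
  d <- load_table3_fixture()
  hs <- collapse_haplotypes(synthetic_reference_alignment())
  net <- build_network(d, hs, level = "individual")
  # regression anchor computed once with an independent Prim's-algorithm
  # oracle on the printed matrix
  expect_equal(mst_total_weight(net), 96L)
  expect_equal(sum(net$links$kind == "mst"), 19L)
})

test_that("alt_threshold widens the link set monotonically", {
  d <- load_table3_fixture()
  hs <- collapse_haplotypes(synthetic_reference_alignment())
  n_links <- vapply(c(0L, 2L, 5L, 35L), function(tt) {
    nrow(build_network(d, hs, level = "individual",
                       alt_threshold = tt)$links)
  }, integer(1))
  expect_true(all(diff(n_links) >= 0))
  expect_equal(n_links[4], 190L)  # every pair admitted at the max distance
})

test_that("write_network emits edge list, node table and JSON", {
  ids <- c("H1", "H2", "H3")
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, dimnames = list(ids, ids))
  net <- build_network(d, fake_hapset(ids), level = "individual")
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_network(net, ep, np, jp)
  edges <- utils::read.delim(ep)
  expect_named(edges, c("from", "to", "weight", "kind"))
  expect_equal(nrow(edges), 2L)
  js <- jsonlite::read_json(jp)
  expect_equal(length(js$nodes), 3L)
  expect_equal(js$level, "individual")
})
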