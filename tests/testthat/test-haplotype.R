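test_that("collapse_haplotypes partitions by exact sequence identity", {
  al <- toy_alignment(c("ACGT", "ACGT", "ACGA", "ACGT", "AC-T"),
                      labels = paste0("P_", 1:5))
  hs <- collapse_haplotypes(al)
  expect_equal(hs$haplotype, c("H1", "H2", "H3"))  # first-appearance order
  expect_equal(hs$hf, c(3L, 1L, 1L))
  expect_equal(hs$members[[1]], c("P_1", "P_2", "P_4"))
  expect_equal(attr(hs, "n_samples"), 5L)
  # gaps are literal states, never wildcards
  expect_equal(hs$sequence[3], "AC-T")

  mono <- collapse_haplotypes(toy_alignment(rep("AAAA", 5)))
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$hf, 5L)
  expect_equal(mono$pct, 100)
})

test_that("collapsing then expanding members reproduces the input multiset", {
  set.seed(3)
  for (rep in 1:5) {
    pool <- replicate(4, paste(sample(c("A", "C"), 12, TRUE), collapse = ""))
    al <- toy_alignment(sample(pool, 30, TRUE), labels = paste0("s", 1:30))
    hs <- collapse_haplotypes(al)
    rebuilt <- stats::setNames(
      rep(hs$sequence, lengths(hs$members)),
      unlist(hs$members)
    )
    expect_equal(sort(names(rebuilt)), sort(al$label))
    expect_equal(unname(rebuilt[al$label]), al$sequence)
    expect_equal(sum(hs$hf), 30L)
    # pct values sum to 100 within rounding slack
    expect_lt(abs(sum(hs$pct) - 100), 0.05 * nrow(hs) + 1e-9)
  }
})

test_that("variable_sites returns exactly the polymorphic columns", {
  hs <- collapse_haplotypes(toy_alignment(c("AAAA", "AATA")))
  vst <- variable_sites(hs)
  expect_equal(attr(vst, "positions"), 3L)
  expect_equal(vst$sites, c("A", "T"))

  # single haplotype: empty table, no error
  vst1 <- variable_sites(collapse_haplotypes(toy_alignment("ACGT")))
  expect_length(attr(vst1, "positions"), 0L)
  expect_equal(vst1$sites, "")

  # brute-force oracle on random 10 x 50 sets
  set.seed(11)
  for (rep in 1:5) {
    seqs <- unique(replicate(10, paste(
      sample(c("A", "C", "G", "T"), 50, TRUE, prob = c(.85, .05, .05, .05)),
      collapse = "")))
    hs <- collapse_haplotypes(toy_alignment(seqs))
    vst <- variable_sites(hs)
    expect_equal(attr(vst, "positions"), bf_variable_positions(hs$sequence))
  }
})

test_that("acgt_only ignores gap/N-driven variability", {
  hs <- collapse_haplotypes(toy_alignment(c("A-GT", "ANGT", "A-GA")))
  expect_equal(attr(variable_sites(hs), "positions"), c(2L, 4L))
  expect_equal(attr(variable_sites(hs, acgt_only = TRUE), "positions"), 4L)
})

test_that("dot notation renders against the reference row and inverts", {
  vst <- tibble::tibble(haplotype = c("H1", "H2", "H3"),
                        sites = c("ACGT", "ACTT", "ACGT"))
  dots <- dot_notation(vst)
  expect_equal(dots$pattern, c("ACGT", "..T.", "...."))
  expect_equal(dot_expand(dots$pattern, dots$pattern[1]), vst$sites)

  # non-default reference row
  dots2 <- dot_notation(vst, reference_row = 2)
  expect_equal(dots2$pattern[2], "ACTT")
  expect_equal(dots2$pattern[1], "..G.")
  expect_error(dot_notation(vst, reference_row = 9), "reference_row")

  # round-trip property on random tables
  set.seed(5)
  for (rep in 1:5) {
    sites <- replicate(6, paste(sample(c("A", "C"), 15, TRUE), collapse = ""))
    v <- tibble::tibble(haplotype = paste0("H", 1:6), sites = sites)
    d <- dot_notation(v)
    expect_equal(dot_expand(d$pattern, d$pattern[1]), sites)
  }
})

test_that("population_matrix cells count members per category", {
  al <- toy_alignment(c("ACGT", "ACGT", "ACGA", "ACGT"),
                      labels = c("Aksu_1", "Demre_1", "Aksu_2", "Aksu_3"))
  hs <- collapse_haplotypes(al)
  pm <- build_population_map(al, groups = c(Aksu = "g1", Demre = "g2"))
  px <- population_matrix(hs, pm)
  expect_equal(px$Aksu, c(2L, 1L))
  expect_equal(px$Demre, c(1L, 0L))
  # row sums equal hf at both levels
  expect_equal(rowSums(px[-1]), hs$hf, ignore_attr = TRUE)
  gx <- population_matrix(hs, pm, level = "group")
  expect_equal(rowSums(gx[-1]), hs$hf, ignore_attr = TRUE)
  expect_equal(colnames(gx)[-1], c("g1", "g2"))

  # 1x1 case
  al1 <- toy_alignment("ACGT", labels = "X_1")
  hs1 <- collapse_haplotypes(al1)
  px1 <- population_matrix(hs1, build_population_map(al1))
  expect_equal(px1$X, 1L)

  bad_pm <- tibble::tibble(label = "Aksu_1", population = "Aksu")
  expect_error(population_matrix(hs, bad_pm), "missing from the population map")
})

test_that("tidy and glance summarise a hapset", {
  al <- toy_alignment(c("ACGT", "ACGT", "ACGA"), labels = paste0("P_", 1:3))
  hs <- collapse_haplotypes(al)
  td <- tidy(hs)
  expect_named(td, c("haplotype", "hf", "pct", "sequence"))
  gl <- glance(hs)
  expect_equal(gl$n_haplotypes, 2L)
  expect_equal(gl$modal_haplotype, "H1")
  expect_equal(gl$modal_pct, 66.67)  # round-half-up of 66.666...
})
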