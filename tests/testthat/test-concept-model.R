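test_that("relation_of maps the five legal zone patterns onto the five relations", {
  expect_identical(relation_of(FALSE, TRUE, FALSE), "==")
  expect_identical(relation_of(TRUE, TRUE, FALSE), ">")
  expect_identical(relation_of(FALSE, TRUE, TRUE), "<")
  expect_identical(relation_of(TRUE, TRUE, TRUE), "><")
  expect_identical(relation_of(TRUE, FALSE, TRUE), "!")
  # remaining patterns imply an empty region
  expect_error(relation_of(FALSE, FALSE, TRUE), "nonempty")
  expect_error(relation_of(TRUE, FALSE, FALSE), "nonempty")
  expect_error(relation_of(FALSE, FALSE, FALSE), "nonempty")
})

test_that("the five relations are jointly exhaustive and pairwise disjoint (universe <= 4)", {
  # brute force over all pairs of nonempty subsets of a small universe:
  # exactly one relation holds for each pair, and all five occur
  for (n in 2:4) {
    subsets <- lapply(seq_len(2^n - 1L), function(m) which(bitwAnd(m, 2^(0:(n - 1))) != 0))
    seen <- character(0)
    for (a in subsets) for (b in subsets) {
      r <- relation_of(length(setdiff(a, b)) > 0,
                       length(intersect(a, b)) > 0,
                       length(setdiff(b, a)) > 0)
      expect_true(r %in% rcc5_relations())
      # the zone pattern determines the relation uniquely: check the
      # defining conditions directly
      expect_identical(r == "==", setequal(a, b))
      expect_identical(r == ">", all(b %in% a) && !setequal(a, b))
      expect_identical(r == "<", all(a %in% b) && !setequal(a, b))
      expect_identical(r == "!", length(intersect(a, b)) == 0)
      seen <- union(seen, r)
    }
    if (n >= 3) expect_setequal(seen, rcc5_relations())
  }
})

test_that("relation set parsing and rendering round-trip", {
  expect_identical(parse_relset("=="), "==")
  expect_identical(parse_relset("{< ><}"), c("<", "><"))
  expect_identical(render_relset(c("><", "<")), "{< ><}")
  expect_identical(render_relset("=="), "==")
  expect_error(parse_relset("equalz"), "invalid")
  expect_error(parse_relset("{}"), "invalid")
  expect_identical(rcc5_converse(c("<", ">", "==", "><", "!")),
                   c(">", "<", "==", "><", "!"))
})

test_that("validate_problem reports violations as data", {
  p <- two_singletons("==")
  expect_length(validate_problem(p), 0L)

  # same-taxonomy articulation
  bad <- p
  bad$articulations <- data.frame(left = "A.x", relation = "==", right = "A.x")
  expect_length(validate_problem(bad), 1L)
  expect_match(validate_problem(bad), "same taxonomy")

  # taxonomy count bound (6 taxonomies)
  taxa6 <- lapply(1:6, function(i)
    taxonomy(paste0("T", i), list(r = character(0))))
  bad6 <- structure(list(taxonomies = taxa6,
                         articulations = p$articulations[0, ]),
                    class = "alignment_problem")
  expect_length(validate_problem(bad6), 1L)
  expect_match(validate_problem(bad6), "2-5")

  # undeclared concept and invalid relation are both reported
  bad2 <- p
  bad2$articulations <- data.frame(left = "A.z", relation = "??", right = "B.y")
  v <- validate_problem(bad2)
  expect_length(v, 2L)
})

test_that("taxonomy constructor enforces structural invariants", {
  expect_error(taxonomy("t", list(P = c("a", "a"))), "repeated child")
  expect_error(taxonomy("t", list(P = "a", Q = "a")), "two parents")
  expect_error(taxonomy("t", list(P = "a"), not_covered = "a"),
               "without children")
  tx <- taxonomy("t", list(P = c("a", "b")), not_covered = "P")
  expect_false(tx$covered[["P"]])
})

test_that("canonical order is taxonomy order then preorder", {
  a <- taxonomy("A", list(r = c("s", "t"), s = "u"))
  b <- taxonomy("B", list(v = "w"))
  p <- alignment_problem(list(a, b))
  expect_identical(concept_labels(p),
                   c("A.r", "A.s", "A.u", "A.t", "B.v", "B.w"))
  cp <- cross_pairs(p)
  expect_identical(nrow(cp), 8L) # 4 * 2
  expect_identical(cp$left[1:2], c("A.r", "A.r"))
  expect_identical(cp$right[1:2], c("B.v", "B.w"))
})

test_that("cross pair count equals the sum over taxonomy pairs of |Ti||Tj|", {
  for (seed in 1:10) {
    cs <- synthetic_case(seed, n_tax = 2L + seed %% 3, universe = 6L)
    sizes <- vapply(cs$problem$taxonomies, function(t) length(t$concepts), 1L)
    expected <- sum(outer(sizes, sizes)[upper.tri(diag(length(sizes)))])
    expect_identical(nrow(cross_pairs(cs$problem)), as.integer(expected))
  }
})
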