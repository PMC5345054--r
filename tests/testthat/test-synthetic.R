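test_that("spec validation enforces the documented bounds", {
  expect_error(synthetic_spec(10, 1), "between 2 and 5")
  expect_error(synthetic_spec(10, 6), "between 2 and 5")
  expect_error(synthetic_spec(2, 3), "at least n_taxonomies")
  expect_error(synthetic_spec(10, 3, p_gap = 1.5), "\\[0, 1\\]")
})

test_that("generation is deterministic under the seed", {
  s <- synthetic_spec(8, 3, seed = 11)
  w1 <- sample_world(s)
  w2 <- sample_world(s)
  expect_identical(w1$regions, w2$regions)
  expect_identical(write_eulerx(emit_problem(w1)), write_eulerx(emit_problem(w2)))
  w3 <- sample_world(synthetic_spec(8, 3, seed = 12))
  expect_false(identical(w1$regions, w3$regions))
})

test_that("a single-atom universe makes all root concepts congruent", {
  w <- sample_world(synthetic_spec(2, 2, max_depth = 0L, seed = 1))
  tr <- derive_true_relations(w)
  expect_true(all(tr$relation == "=="))
})

test_that("children partition their parent exactly when p_gap = 0", {
  for (seed in 1:6) {
    w <- sample_world(synthetic_spec(10, 2, p_gap = 0, max_depth = 3L,
                                     seed = seed))
    for (tax in w$taxonomies) {
      expect_true(all(tax$covered))
      for (p in names(tax$children)) {
        kid_atoms <- unlist(lapply(tax$children[[p]], function(k)
          w$regions[[concept_label(tax$tag, k)]]))
        expect_setequal(kid_atoms, w$regions[[concept_label(tax$tag, p)]])
        expect_identical(length(kid_atoms), length(unique(kid_atoms)))
      }
    }
  }
})

test_that("non-covered parents hold a nonempty residue", {
  w <- sample_world(synthetic_spec(12, 2, p_gap = 1, max_depth = 2L, seed = 3))
  found <- FALSE
  for (tax in w$taxonomies) for (p in names(tax$children)) {
    if (isTRUE(tax$covered[[p]])) next
    found <- TRUE
    kid_atoms <- unlist(lapply(tax$children[[p]], function(k)
      w$regions[[concept_label(tax$tag, k)]]))
    expect_gt(length(setdiff(w$regions[[concept_label(tax$tag, p)]],
                             kid_atoms)), 0L)
  }
  expect_true(found)
})

test_that("true relations agree with relation_of semantics on every pair", {
  w <- sample_world(synthetic_spec(7, 3, seed = 21, p_gap = 0.3))
  tr <- derive_true_relations(w)
  for (k in seq_len(nrow(tr))) {
    a <- w$regions[[tr$left[k]]]
    b <- w$regions[[tr$right[k]]]
    expect_identical(tr$relation[k],
                     relation_of(length(setdiff(a, b)) > 0,
                                 length(intersect(a, b)) > 0,
                                 length(setdiff(b, a)) > 0))
  }
})

test_that("articulation density controls the emitted subset", {
  w <- sample_world(synthetic_spec(8, 2, seed = 5))
  n_pairs <- nrow(derive_true_relations(w))
  expect_identical(nrow(emit_problem(w, density = 0)$articulations), 0L)
  expect_identical(nrow(emit_problem(w, density = 1)$articulations), n_pairs)
  half <- emit_problem(w, density = 0.5, seed = 9)
  expect_identical(nrow(half$articulations), as.integer(round(0.5 * n_pairs)))
  expect_identical(half$articulations,
                   emit_problem(w, density = 0.5, seed = 9)$articulations)
  expect_true(is_consistent(emit_problem(w, density = 0))$consistent)
})

test_that("full articulation recovers the truth as singleton MIR", {
  for (seed in c(2, 4)) {
    cs <- synthetic_case(seed, n_tax = 2L + seed %% 2, universe = 6L)
    mir <- compute_mir(cs$problem)
    expect_true(all(lengths(mir$relset) == 1L))
    expect_identical(vapply(mir$relset, `[[`, "", 1L), cs$truth$relation)
  }
})

test_that("injected contradictions are detected and explained", {
  cs <- synthetic_case(3, n_tax = 2L, universe = 5L, density = 1)
  bad <- perturb_inconsistent(cs$problem, seed = 8)
  res <- is_consistent(bad)
  expect_false(res$consistent)
  inj <- attr(bad, "injected")
  hit <- any(res$conflict$left == inj$left &
             res$conflict$right == inj$right &
             res$conflict$relation == inj$relation)
  expect_true(hit)
  # seed determinism of the injected choice
  expect_identical(attr(perturb_inconsistent(cs$problem, seed = 8), "injected"),
                   inj)
  # a perturbed in-paper fixture is caught too
  expect_false(is_consistent(perturb_inconsistent(scelianoma_problem()))$consistent)
})

test_that("perturbation requires a fully resolved pair", {
  p <- two_singletons() # no articulations: every MIR has all five relations
  expect_error(perturb_inconsistent(p), "no fully resolved pair")
})
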