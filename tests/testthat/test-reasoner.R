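test_that("contradictory articulations on one pair are inconsistent, with a conflict report", {
  a <- taxonomy("A", list(x = character(0)))
  b <- taxonomy("B", list(y = character(0)))
  p <- alignment_problem(list(a, b), data.frame(
    left = c("A.x", "A.x"), relation = c("==", "!"), right = c("B.y", "B.y")))
  res <- is_consistent(p)
  expect_false(res$consistent)
  expect_null(res$world)
  expect_identical(nrow(res$conflict), 2L) # both needed for the clash
})

test_that("the Scelianoma alignment is consistent with a witness world", {
  res <- is_consistent(scelianoma_problem())
  expect_true(res$consistent)
  expect_s3_class(res$world, "rcc5_world")
  expect_identical(induced_relation(res$world, "2009.Scelianoma",
                                    "2012.Scelianoma"), "==")
})

test_that("problems emitted from a ground-truth world are consistent by construction", {
  for (seed in 1:8) {
    cs <- synthetic_case(seed, n_tax = 2L + seed %% 3, universe = 6L,
                         density = 1, p_gap = 0.25)
    expect_true(is_consistent(cs$problem)$consistent)
  }
})

test_that("induced_relation agrees with direct set comparison over all worlds of a small problem", {
  p <- parent_pair_problem()
  ps <- build_places(p)
  bw <- brute_worlds(ps)
  labels <- concept_labels(p)
  expect_gt(length(bw$codes), 0L)
  for (code in bw$codes) {
    w <- new_world(ps, code_to_places(code, ps$n))
    sets <- lapply(labels, function(l) intersect(ps$under[[l]], w$occupied))
    names(sets) <- labels
    for (a in labels) for (b in labels) {
      expected <- relation_of(length(setdiff(sets[[a]], sets[[b]])) > 0,
                              length(intersect(sets[[a]], sets[[b]])) > 0,
                              length(setdiff(sets[[b]], sets[[a]])) > 0)
      expect_identical(induced_relation(w, a, b), expected)
    }
  }
  # identity always induces congruence
  w <- new_world(ps, code_to_places(bw$codes[1], ps$n))
  expect_identical(induced_relation(w, "A.C", "A.C"), "==")
})

test_that("MIR of fully determined toys is the expected singleton", {
  # equals articulation on two singleton taxonomies
  mir <- compute_mir(two_singletons("=="))
  expect_identical(nrow(mir), 1L)
  expect_identical(mir$relset[[1]], "==")

  # C == P with P a covered parent of two children: C properly includes D
  mir2 <- mir_relsets(compute_mir(parent_pair_problem()))
  expect_identical(mir2[["A.C|B.D"]], ">")
  expect_identical(mir2[["A.C|B.E"]], ">")
  expect_identical(mir2[["A.C|B.P"]], "==")
})

test_that("MIR is empty (flagged inconsistent) exactly when the problem is inconsistent", {
  a <- taxonomy("A", list(x = character(0)))
  b <- taxonomy("B", list(y = character(0)))
  bad <- alignment_problem(list(a, b), data.frame(
    left = c("A.x", "A.x"), relation = c("<", "!"), right = c("B.y", "B.y")))
  for (backend in c("brute", "solver")) {
    mir <- compute_mir(bad, backend = backend)
    expect_false(attr(mir, "consistent"))
    expect_true(all(lengths(mir$relset) == 0L))
  }
})

test_that("solver and brute-force backends agree on seeded small problems", {
  checked <- 0L
  seed <- 0L
  while (checked < 40L) {
    seed <- seed + 1L
    cs <- synthetic_case(seed, n_tax = 2L + seed %% 2, universe = 4L,
                         density = c(1, 0.5, 0.25)[1L + seed %% 3], p_gap = 0.3,
                         max_children = 2L)
    ps <- build_places(cs$problem)
    if (ps$n > 16L) next
    m1 <- compute_mir(cs$problem, backend = "brute", places = ps)
    m2 <- compute_mir(cs$problem, backend = "solver", places = ps)
    expect_identical(m1$relation, m2$relation)
    checked <- checked + 1L
  }
})

test_that("MIR symmetry: swapping a pair gives the converse relation set", {
  cs <- synthetic_case(5, n_tax = 3L, universe = 6L, density = 0.4)
  mir <- compute_mir(cs$problem)
  ps <- build_places(cs$problem)
  # recompute each pair's relset with arguments swapped via direct probes
  for (k in sample(nrow(mir), 5L)) {
    z <- pair_zones(ps, mir$right[k], mir$left[k])
    swapped <- Filter(function(r) {
      con <- relation_constraint(r, z)
      base <- compile_articulations(ps)
      base$forbid <- unique(c(base$forbid, con$forbid))
      base$pos <- c(base$pos, con$pos)
      !is.null(solve_places(ps, base))
    }, rcc5_relations())
    expect_setequal(rcc5_converse(swapped), mir$relset[[k]])
  }
})

test_that("adding articulations never enlarges MIR relation sets", {
  for (seed in 1:6) {
    cs <- synthetic_case(seed, n_tax = 2L, universe = 6L, density = 0.3)
    full <- emit_problem(cs$world, density = 0.8, seed = seed)
    m_sparse <- mir_relsets(compute_mir(cs$problem))
    m_full <- mir_relsets(compute_mir(full))
    for (k in names(m_sparse))
      expect_true(all(m_full[[k]] %in% m_sparse[[k]]))
  }
})

test_that("relaxing coverage never shrinks MIR relation sets", {
  for (seed in 1:6) {
    cs <- synthetic_case(seed, n_tax = 2L, universe = 6L, density = 0.5,
                         p_gap = 0)
    p <- cs$problem
    # relax coverage on the first parent of the first taxonomy
    t1 <- p$taxonomies[[1]]
    parents <- names(t1$children)
    if (length(parents) == 0L) next
    t1$covered[[parents[1]]] <- FALSE
    relaxed <- alignment_problem(c(list(t1), p$taxonomies[-1]), p$articulations)
    m0 <- mir_relsets(compute_mir(p))
    m1 <- mir_relsets(compute_mir(relaxed))
    for (k in names(m0))
      expect_true(all(m0[[k]] %in% m1[[k]]))
  }
})

test_that("world pattern enumeration matches MIR structure", {
  # fully articulated Scelianoma: every MIR singleton, hence one pattern
  pats <- enumerate_worlds(scelianoma_problem())
  expect_length(pats, 1L)
  expect_false(attr(pats, "truncated"))
  expect_identical(unname(pats[[1]]$relations[1]), "==")

  # two unarticulated singleton concepts: one pattern per base relation
  pats5 <- enumerate_worlds(two_singletons())
  expect_length(pats5, 5L)
  expect_setequal(vapply(pats5, function(p) p$relations[[1]], ""),
                  rcc5_relations())

  # brute and solver enumerations agree on the pattern set
  pats5b <- enumerate_worlds(two_singletons(), backend = "solver")
  expect_setequal(vapply(pats5b, function(p) p$relations[[1]], ""),
                  rcc5_relations())

  # inconsistent input yields no patterns and the flag
  a <- taxonomy("A", list(x = character(0)))
  b <- taxonomy("B", list(y = character(0)))
  bad <- alignment_problem(list(a, b), data.frame(
    left = c("A.x", "A.x"), relation = c("==", "!"), right = c("B.y", "B.y")))
  expect_length(enumerate_worlds(bad), 0L)
  expect_false(attr(enumerate_worlds(bad), "consistent"))

  # the cap truncates and flags
  capped <- enumerate_worlds(two_singletons(), cap = 2L)
  expect_length(capped, 2L)
  expect_true(attr(capped, "truncated"))
})

test_that("each enumerated witness world actually induces its pattern", {
  cs <- synthetic_case(9, n_tax = 2L, universe = 5L, density = 0.3)
  pats <- enumerate_worlds(cs$problem, cap = 50L)
  expect_gt(length(pats), 0L)
  for (p in head(pats, 10L)) {
    for (nm in names(p$relations)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      expect_identical(induced_relation(p$witness, ab[1], ab[2]),
                       unname(p$relations[[nm]]))
    }
  }
})
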