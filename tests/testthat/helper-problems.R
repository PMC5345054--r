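# shared builders for toy alignment problems

expect_same_problem <- function(p, q) {
  expect_identical(p[c("taxonomies", "articulations")],
                   q[c("taxonomies", "articulations")])
}

# two single-concept taxonomies, optionally articulated
two_singletons <- function(relation = NULL) {
  a <- taxonomy("A", list(x = character(0)))
  b <- taxonomy("B", list(y = character(0)))
  art <- if (is.null(relation)) NULL else
    data.frame(left = "A.x", relation = relation, right = "B.y",
               stringsAsFactors = FALSE)
  alignment_problem(list(a, b), art)
}

# taxonomy B: covered parent P with two children; A: single concept C
# articulated C == P
parent_pair_problem <- function() {
  a <- taxonomy("A", list(C = character(0)))
  b <- taxonomy("B", list(P = c("D", "E")))
  alignment_problem(list(a, b),
                    data.frame(left = "A.C", relation = "==", right = "B.P",
                               stringsAsFactors = FALSE))
}

# seeded synthetic problem; returns list(world, problem, truth)
synthetic_case <- function(seed, n_tax = 2L, universe = 5L, density = 1,
                           p_gap = 0.15, max_children = 3L, max_depth = 2L) {
  spec <- synthetic_spec(universe, n_tax, max_depth = max_depth,
                         max_children = max_children, p_gap = p_gap,
                         articulation_density = density, seed = seed)
  w <- sample_world(spec)
  list(world = w, problem = emit_problem(w),
       truth = derive_true_relations(w))
}

mir_relsets <- function(mir) {
  stats::setNames(mir$relset, paste(mir$left, mir$right, sep = "|"))
}
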