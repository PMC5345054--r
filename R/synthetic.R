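#' Specification for a synthetic multi-classification world
#'
#' Parameters of the ground-truth generator: a shared universe of
#' atomic regions is partitioned independently by each of 2-5
#' classification hierarchies, emulating multiple treatments of one
#' fauna with nested nonempty circumscriptions, occasional
#' purposefully undersampled parents (coverage gaps) and a tunable
#' fraction of expert articulations.
#'
#' @param universe_size number of atomic regions (at least
#'   `n_taxonomies`).
#' @param n_taxonomies number of hierarchies, 2-5.
#' @param max_depth maximum splitting depth below each root.
#' @param max_children maximum children per parent.
#' @param p_gap probability that a split parent keeps an unsampled
#'   nonempty residue (coverage relaxed, the "nc" device).
#' @param articulation_density fraction of cross-taxonomy pairs
#'   emitted as articulations by [emit_problem()].
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(universe_size, n_taxonomies, max_depth = 2L,
                           max_children = 3L, p_gap = 0.15,
                           articulation_density = 1, seed = 1L) {
  if (n_taxonomies < 2L || n_taxonomies > 5L)
    stop("n_taxonomies must be between 2 and 5")
  if (universe_size < n_taxonomies)
    stop("universe_size must be at least n_taxonomies")
  if (p_gap < 0 || p_gap > 1 || articulation_density < 0 || articulation_density > 1)
    stop("probabilities must lie in [0, 1]")
  if (max_children < 2L) stop("max_children must be at least 2")
  structure(list(universe_size = as.integer(universe_size),
                 n_taxonomies = as.integer(n_taxonomies),
                 max_depth = as.integer(max_depth),
                 max_children = as.integer(max_children),
                 p_gap = p_gap, articulation_density = articulation_density,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a ground-truth world of nested regions
#'
#' Builds each taxonomy by recursive partition of the atom universe:
#' every concept's atom set is nonempty, children partition their
#' parent exactly (covered) or leave a nonempty unsampled residue with
#' probability `p_gap` (coverage relaxed). Deterministic under the
#' spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `"concept_world"`: list with `spec`,
#'   `taxonomies` (list of [taxonomy()]), and `regions` (named list of
#'   atom index vectors per concept label).
#' @export
sample_world <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  taxonomies <- vector("list", spec$n_taxonomies)
  regions <- list()
  for (ti in seq_len(spec$n_taxonomies)) {
    tag <- paste0("tax", ti)
    groups <- list(); not_covered <- character(0)
    counter <- 0L
    new_name <- function() {
      counter <<- counter + 1L
      sprintf("c%02d", counter)
    }
    split_node <- function(name, atoms, depth) {
      regions[[concept_label(tag, name)]] <<- sort(atoms)
      if (depth >= spec$max_depth || length(atoms) < 2L) return(invisible())
      gap_n <- if (length(atoms) >= 3L && stats::runif(1) < spec$p_gap) 1L else 0L
      avail <- length(atoms) - gap_n
      krange <- 2:min(spec$max_children, avail)
      k <- if (length(krange) == 1L) krange else sample(krange, 1L)
      shuffled <- sample(atoms)
      child_atoms <- shuffled[seq_len(length(atoms) - gap_n)]
      # random composition of child_atoms into k nonempty blocks
      cuts <- sort(sample(seq_len(length(child_atoms) - 1L), k - 1L))
      blocks <- split(child_atoms,
                      findInterval(seq_along(child_atoms), cuts + 1L) + 1L)
      kids <- vapply(seq_len(k), function(i) new_name(), "")
      groups[[name]] <<- kids
      if (gap_n > 0L) not_covered <<- c(not_covered, name)
      for (i in seq_len(k)) split_node(kids[i], blocks[[i]], depth + 1L)
    }
    root <- new_name()
    if (length(groups) == 0L) groups[[root]] <- character(0)
    split_node(root, seq_len(spec$universe_size), 0L)
    taxonomies[[ti]] <- taxonomy(tag, groups, title = "synthetic",
                                 not_covered = unique(not_covered))
  }
  structure(list(spec = spec, taxonomies = taxonomies, regions = regions),
            class = "concept_world")
}

#' @export
print.concept_world <- function(x, ...) {
  cat("Synthetic world: ", x$spec$universe_size, " atoms, ",
      length(x$taxonomies), " taxonomies, ", length(x$regions),
      " concepts\n", sep = "")
  invisible(x)
}

#' Ground-truth RCC-5 relations of a synthetic world
#'
#' The true base relation of every cross-taxonomy concept pair by
#' direct atom-set comparison; the oracle for recovery tests.
#'
#' @param world a [sample_world()] result.
#' @return `data.frame` with columns `left`, `relation`, `right` in
#'   canonical pair order.
#' @export
derive_true_relations <- function(world) {
  stopifnot(inherits(world, "concept_world"))
  prob <- alignment_problem(world$taxonomies)
  pairs <- cross_pairs(prob)
  rel <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- world$regions[[pairs$left[k]]]
    b <- world$regions[[pairs$right[k]]]
    relation_of(length(setdiff(a, b)) > 0L,
                length(intersect(a, b)) > 0L,
                length(setdiff(b, a)) > 0L)
  }, "")
  data.frame(left = pairs$left, relation = rel, right = pairs$right,
             stringsAsFactors = FALSE)
}

#' Emit an alignment problem from a synthetic world
#'
#' Articulations are a seeded random subset of the cross-taxonomy
#' pairs, each asserted as its true singleton relation; density 1
#' yields the complete articulation set, density 0 a problem without
#' articulations (always consistent).
#'
#' @param world a [sample_world()] result.
#' @param density fraction of cross pairs to articulate; defaults to
#'   the spec's `articulation_density`.
#' @param seed seed for the subset draw; defaults to the spec seed.
#' @return An [alignment_problem()].
#' @export
emit_problem <- function(world, density = world$spec$articulation_density,
                         seed = world$spec$seed) {
  stopifnot(inherits(world, "concept_world"))
  truth <- derive_true_relations(world)
  n <- nrow(truth)
  m <- round(density * n)
  set.seed(seed)
  idx <- sort(sample.int(n, m))
  alignment_problem(world$taxonomies, truth[idx, , drop = FALSE])
}

#' Inject a contradiction into a consistent problem
#'
#' Picks (seeded) a cross-taxonomy pair whose MIR is already a
#' singleton and appends an articulation asserting a different
#' relation on it; the result is guaranteed inconsistent and the
#' injected articulation belongs to every conflict explanation.
#'
#' @param problem an [alignment_problem()].
#' @param seed integer seed for the pair choice.
#' @return The perturbed [alignment_problem()], with the injected
#'   articulation attached as `attr(, "injected")`.
#' @export
perturb_inconsistent <- function(problem, seed = 1L) {
  mir <- compute_mir(problem)
  if (!isTRUE(attr(mir, "consistent")))
    stop("problem is already inconsistent")
  singles <- which(lengths(mir$relset) == 1L)
  if (length(singles) == 0L)
    stop("no fully resolved pair to contradict")
  set.seed(seed)
  pick <- singles[sample.int(length(singles), 1L)]
  have <- mir$relset[[pick]][1]
  contradiction <- if (have == "==") "!" else "=="
  inj <- data.frame(left = mir$left[pick], relation = contradiction,
                    right = mir$right[pick], stringsAsFactors = FALSE)
  out <- alignment_problem(problem$taxonomies,
                           rbind(problem$articulations, inj))
  attr(out, "injected") <- inj
  out
}
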