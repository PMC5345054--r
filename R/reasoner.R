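# RCC-5 constraint reasoning over the finite place-occupancy model.
#
# Every constraint of the encoding is one of two shapes over the boolean
# place-occupancy variables:
#   * a forced-empty place (a negative unit literal), contributed by the
#     empty zones of an asserted relation, or
#   * an at-least-one clause over a set of places (all-positive),
#     contributed by concept nonemptiness and the nonempty zones of an
#     asserted relation.
# For a fixed choice of one disjunct per disjunctive articulation the
# formula is therefore monotone: deleting the forbidden places and
# checking that every positive clause retains a member decides
# satisfiability exactly, and occupying all remaining places is a
# witness world. Disjunctive articulations are handled by depth-first
# search over their disjuncts. The brute-force backend enumerates all
# nonempty occupancy sets as bitmasks and is the independent oracle.

# constraint contributed by asserting relation `rel` on zones z:
# list(forbid = places that must be empty, pos = list of place sets that
# must each contain an occupied place)
relation_constraint <- function(rel, z) {
  switch(rel,
    "==" = list(forbid = c(z$za, z$zb), pos = list(z$zab)),
    ">"  = list(forbid = z$zb, pos = list(z$za, z$zab)),
    "<"  = list(forbid = z$za, pos = list(z$zb, z$zab)),
    "><" = list(forbid = integer(0), pos = list(z$za, z$zab, z$zb)),
    "!"  = list(forbid = z$zab, pos = list(z$za, z$zb)),
    stop("unknown relation '", rel, "'"))
}

# Compile a problem's articulations (optionally restricted to indices
# `keep`) into fixed constraints plus per-articulation disjunct options.
compile_articulations <- function(ps, keep = NULL, extra = NULL) {
  art <- ps$problem$articulations
  idx <- if (is.null(keep)) seq_len(nrow(art)) else keep
  fixed_forbid <- integer(0)
  fixed_pos <- list()
  disj <- list()
  add_one <- function(left, right, relset) {
    z <- pair_zones(ps, left, right)
    if (length(relset) == 1L) {
      con <- relation_constraint(relset, z)
      fixed_forbid <<- c(fixed_forbid, con$forbid)
      fixed_pos <<- c(fixed_pos, con$pos)
    } else {
      disj[[length(disj) + 1L]] <<- lapply(relset, relation_constraint, z = z)
    }
  }
  for (i in idx)
    add_one(art$left[i], art$right[i], parse_relset(art$relation[i]))
  if (!is.null(extra))
    for (e in extra) add_one(e$left, e$right, e$relset)
  list(forbid = unique(fixed_forbid), pos = fixed_pos, disj = disj)
}

# Decide satisfiability of nonemptiness + compiled constraints.
# Returns the witness world as an integer vector of occupied places
# (all places not forbidden on the satisfying branch), or NULL.
solve_places <- function(ps, cons) {
  alive <- rep(TRUE, ps$n)
  alive[cons$forbid] <- FALSE
  base_pos <- c(unname(ps$under), cons$pos)
  ok_so_far <- function(alive, clauses) {
    for (cl in clauses) if (!any(alive[cl])) return(FALSE)
    TRUE
  }
  if (!ok_so_far(alive, base_pos)) return(NULL)
  if (length(cons$disj) == 0L) return(which(alive))
  recurse <- function(alive, pending, d) {
    if (d > length(cons$disj)) return(which(alive))
    for (opt in cons$disj[[d]]) {
      a2 <- alive
      a2[opt$forbid] <- FALSE
      if (ok_so_far(a2, c(base_pos, pending, opt$pos))) {
        res <- recurse(a2, c(pending, opt$pos), d + 1L)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  recurse(alive, list(), 1L)
}

#' Decide logical consistency of an alignment problem
#'
#' A problem is consistent when at least one possible world satisfies
#' every taxonomy's structure (sibling disjointness, parent inclusion,
#' coverage where it applies), every concept's nonemptiness, and every
#' articulation. On success a witness world is returned; on failure a
#' best-effort minimal conflicting subset of the articulations is
#' identified by iterative deletion.
#'
#' @param problem an [alignment_problem()].
#' @param places optionally a precomputed [build_places()] result.
#' @param sibling_disjoint passed to [build_places()].
#' @return A list with elements `consistent` (logical), `world` (an
#'   `rcc5_world`, or `NULL`), and `conflict` (`data.frame` of
#'   articulations in the conflict set; empty when consistent).
#' @export
#' @examples
#' is_consistent(scelianoma_problem())$consistent # TRUE
is_consistent <- function(problem, places = NULL, sibling_disjoint = TRUE) {
  ps <- places %||NULL% build_places(problem, sibling_disjoint = sibling_disjoint)
  w <- solve_places(ps, compile_articulations(ps))
  if (!is.null(w))
    return(list(consistent = TRUE,
                world = new_world(ps, w),
                conflict = problem$articulations[0, ]))
  # iterative deletion: drop articulations that are not needed for the
  # contradiction; what remains is a minimal (not necessarily minimum)
  # conflicting subset
  keep <- seq_len(nrow(problem$articulations))
  for (i in rev(keep)) {
    trial <- setdiff(keep, i)
    if (is.null(solve_places(ps, compile_articulations(ps, keep = trial))))
      keep <- trial
  }
  list(consistent = FALSE, world = NULL,
       conflict = problem$articulations[keep, , drop = FALSE])
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

new_world <- function(ps, occupied) {
  structure(list(space = ps, occupied = sort(unique(as.integer(occupied)))),
            class = "rcc5_world")
}

#' @export
print.rcc5_world <- function(x, ...) {
  cat("Possible world: ", length(x$occupied), " of ", x$space$n,
      " places occupied\n", sep = "")
  invisible(x)
}

#' Relation induced between two concepts by a possible world
#'
#' Classifies the occupancy of the three zones (under the first concept
#' only, under both, under the second only) via [relation_of()].
#'
#' @param world an `rcc5_world` as returned by [is_consistent()].
#' @param a,b concept labels (`"tag.name"`).
#' @return One of the symbols in [rcc5_relations()].
#' @export
induced_relation <- function(world, a, b) {
  stopifnot(inherits(world, "rcc5_world"))
  z <- pair_zones(world$space, a, b)
  occ <- world$occupied
  if (!any(occ %in% c(z$za, z$zab)) || !any(occ %in% c(z$zb, z$zab)))
    stop("concept with empty region in this world; not a valid world ",
         "for the pair ('", a, "', '", b, "')")
  relation_of(any(occ %in% z$za), any(occ %in% z$zab), any(occ %in% z$zb))
}

# ---- brute-force backend -------------------------------------------------

# Enumerate every valid world of a problem as occupancy bitmasks.
# Returns list(codes = integer vector of valid occupancy bitmasks,
#              masks = named list of per-concept place bitmasks, ps = ps).
brute_worlds <- function(ps, extra = NULL, limit = 20L) {
  if (ps$n > limit)
    stop("brute-force enumeration limited to ", limit, " places (problem has ",
         ps$n, "); use the solver backend")
  bit <- as.integer(2^(seq_len(ps$n) - 1L))
  msk <- function(idx) as.integer(sum(as.double(bit[idx])))
  codes <- seq_len(2^ps$n - 1L)
  for (u in ps$under)
    codes <- codes[bitwAnd(codes, msk(u)) != 0L]
  art <- ps$problem$articulations
  asserts <- lapply(seq_len(nrow(art)), function(i)
    list(left = art$left[i], right = art$right[i],
         relset = parse_relset(art$relation[i])))
  asserts <- c(asserts, extra)
  for (a in asserts) {
    z <- pair_zones(ps, a$left, a$right)
    za <- bitwAnd(codes, msk(z$za)) != 0L
    zab <- bitwAnd(codes, msk(z$zab)) != 0L
    zb <- bitwAnd(codes, msk(z$zb)) != 0L
    keep <- rep(FALSE, length(codes))
    for (r in a$relset)
      keep <- keep | switch(r,
        "==" = !za & zab & !zb,
        ">"  =  za & zab & !zb,
        "<"  = !za & zab &  zb,
        "><" =  za & zab &  zb,
        "!"  =  za & !zab & zb)
    codes <- codes[keep]
  }
  list(codes = codes, msk = msk, ps = ps)
}

code_to_places <- function(code, n) which(bitwAnd(code, as.integer(2^(seq_len(n) - 1L))) != 0L)

# induced relation ids (index into rcc5_relations()) for one pair across
# all valid codes, vectorized
brute_pair_relations <- function(bw, a, b) {
  z <- pair_zones(bw$ps, a, b)
  za <- bitwAnd(bw$codes, bw$msk(z$za)) != 0L
  zab <- bitwAnd(bw$codes, bw$msk(z$zab)) != 0L
  zb <- bitwAnd(bw$codes, bw$msk(z$zb)) != 0L
  # nonemptiness guaranteed by the concept filters
  ifelse(zab,
         ifelse(za, ifelse(zb, 4L, 3L), ifelse(zb, 2L, 1L)),
         5L)
}

# ---- MIR -----------------------------------------------------------------

#' Compute the table of Maximally Informative Relations (MIR)
#'
#' For every cross-taxonomy concept pair, the MIR is the set of base
#' relations realized in at least one possible world of the alignment;
#' a singleton MIR means the relation is fully resolved by the input
#' constraints. The table has exactly one row per cross-taxonomy pair
#' (\eqn{\sum_{i<j} |T_i||T_j|} rows) in canonical order. If the
#' problem is inconsistent every relation set is empty and the table
#' carries `attr(, "consistent") == FALSE`.
#'
#' @param problem an [alignment_problem()].
#' @param backend `"auto"` (solver, or brute force for small spaces
#'   when asked), `"solver"` (satisfiability probing over
#'   place-occupancy variables) or `"brute"` (exhaustive world
#'   enumeration; requires a small place space).
#' @param places optionally a precomputed [build_places()] result.
#' @param sibling_disjoint passed to [build_places()].
#' @return A `data.frame` of class `"mir_table"` with columns `left`,
#'   `relation` (rendered set, e.g. `"=="` or `"{< ><}"`), `right`,
#'   and a list column `relset`; attributes `consistent` and `problem`.
#' @export
#' @examples
#' mir <- compute_mir(scelianoma_problem())
#' nrow(mir) # 16
compute_mir <- function(problem, backend = c("auto", "solver", "brute"),
                        places = NULL, sibling_disjoint = TRUE) {
  backend <- match.arg(backend)
  ps <- places %||NULL% build_places(problem, sibling_disjoint = sibling_disjoint)
  pairs <- cross_pairs(problem)
  np <- nrow(pairs)
  rels <- rcc5_relations()
  if (backend == "brute" || (backend == "auto" && ps$n <= 14L)) {
    bw <- brute_worlds(ps)
    if (length(bw$codes) == 0L) {
      relsets <- rep(list(character(0)), np)
    } else {
      relsets <- lapply(seq_len(np), function(k)
        rels[sort(unique(brute_pair_relations(bw, pairs$left[k], pairs$right[k])))])
    }
  } else {
    base <- compile_articulations(ps)
    zones <- lapply(seq_len(np), function(k)
      pair_zones(ps, pairs$left[k], pairs$right[k]))
    known <- matrix(NA, nrow = np, ncol = 5L)
    mark_witness <- function(w) {
      for (k in seq_len(np)) {
        z <- zones[[k]]
        r <- relation_of(any(w %in% z$za), any(w %in% z$zab), any(w %in% z$zb))
        known[k, match(r, rels)] <<- TRUE
      }
    }
    w0 <- solve_places(ps, base)
    if (is.null(w0)) {
      relsets <- rep(list(character(0)), np)
    } else {
      mark_witness(w0)
      for (k in seq_len(np)) for (ri in seq_len(5L)) {
        if (!is.na(known[k, ri])) next
        con <- relation_constraint(rels[ri], zones[[k]])
        probe <- base
        probe$forbid <- unique(c(probe$forbid, con$forbid))
        probe$pos <- c(probe$pos, con$pos)
        w <- solve_places(ps, probe)
        if (is.null(w)) known[k, ri] <- FALSE else mark_witness(w)
      }
      relsets <- lapply(seq_len(np), function(k) rels[which(known[k, ])])
    }
  }
  out <- data.frame(left = pairs$left,
                    relation = vapply(relsets, render_relset, ""),
                    right = pairs$right, stringsAsFactors = FALSE)
  out$relset <- relsets
  attr(out, "consistent") <- any(lengths(relsets) > 0L) || np == 0L
  attr(out, "problem") <- problem
  class(out) <- c("mir_table", "data.frame")
  out
}

#' Enumerate the distinct possible-world relation patterns
#'
#' Two worlds are regarded as the same outcome of the alignment when
#' they induce the same base relation on every cross-taxonomy pair.
#' This enumerates the distinct patterns (each with one witness world),
#' up to `cap`.
#'
#' @inheritParams compute_mir
#' @param cap maximum number of patterns to return; if reached the
#'   result carries `attr(, "truncated") == TRUE`.
#' @return List of patterns; each has `relations` (named character
#'   vector, names `"left|right"`) and `witness` (an `rcc5_world`).
#'   Attributes `truncated` and `consistent`.
#' @export
#' @examples
#' length(enumerate_worlds(scelianoma_problem())) # 1
enumerate_worlds <- function(problem, cap = 100L,
                             backend = c("auto", "solver", "brute"),
                             places = NULL, sibling_disjoint = TRUE) {
  backend <- match.arg(backend)
  ps <- places %||NULL% build_places(problem, sibling_disjoint = sibling_disjoint)
  pairs <- cross_pairs(problem)
  np <- nrow(pairs)
  pair_names <- paste(pairs$left, pairs$right, sep = "|")
  rels <- rcc5_relations()
  patterns <- list()
  truncated <- FALSE
  if (backend == "brute" || (backend == "auto" && ps$n <= 14L)) {
    bw <- brute_worlds(ps)
    if (length(bw$codes) > 0L) {
      relmat <- vapply(seq_len(np), function(k)
        brute_pair_relations(bw, pairs$left[k], pairs$right[k]),
        integer(length(bw$codes)))
      relmat <- matrix(relmat, nrow = length(bw$codes))
      key <- apply(relmat, 1L, paste, collapse = ",")
      first <- !duplicated(key)
      idx <- which(first)
      if (length(idx) > cap) { idx <- idx[seq_len(cap)]; truncated <- TRUE }
      patterns <- lapply(idx, function(i) list(
        relations = stats::setNames(rels[relmat[i, ]], pair_names),
        witness = new_world(ps, code_to_places(bw$codes[i], ps$n))))
    }
  } else {
    mir <- compute_mir(problem, backend = "solver", places = ps)
    if (attr(mir, "consistent")) {
      base <- compile_articulations(ps)
      zones <- lapply(seq_len(np), function(k)
        pair_zones(ps, pairs$left[k], pairs$right[k]))
      dfs <- function(d, probe, chosen) {
        if (truncated) return()
        if (d > np) {
          w <- solve_places(ps, probe)
          if (!is.null(w)) {
            if (length(patterns) >= cap) { truncated <<- TRUE; return() }
            patterns[[length(patterns) + 1L]] <<- list(
              relations = stats::setNames(chosen, pair_names),
              witness = new_world(ps, w))
          }
          return()
        }
        for (r in mir$relset[[d]]) {
          con <- relation_constraint(r, zones[[d]])
          p2 <- probe
          p2$forbid <- unique(c(p2$forbid, con$forbid))
          p2$pos <- c(p2$pos, con$pos)
          if (!is.null(solve_places(ps, p2))) dfs(d + 1L, p2, c(chosen, r))
        }
      }
      dfs(1L, base, character(0))
    }
  }
  attr(patterns, "truncated") <- truncated
  attr(patterns, "consistent") <- length(patterns) > 0L
  patterns
}
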