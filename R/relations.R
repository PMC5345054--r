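#' The five RCC-5 base relations
#'
#' Canonical symbols for the five jointly exhaustive, pairwise disjoint
#' base relations between two nonempty regions: `==` congruence, `<`
#' (inverse) proper inclusion of the left in the right, `>` proper
#' inclusion of the right in the left, `><` overlap, `!` exclusion
#' (disjointness).
#'
#' @return Character vector of the five relation symbols, in canonical
#'   order.
#' @export
#' @examples
#' rcc5_relations()
rcc5_relations <- function() c("==", "<", ">", "><", "!")

# keyword spelling used in alignment input files, in the same order
.rel_keywords <- c("equals", "is_included_in", "includes", "overlaps", "disjoint")

#' Classify the RCC-5 relation of two nonempty regions from zone occupancy
#'
#' Two nonempty regions A and B partition their union into three zones:
#' A minus B, the intersection, and B minus A. The emptiness pattern of
#' those zones determines the base relation uniquely.
#'
#' @param a_only logical; is A \\ B nonempty?
#' @param both logical; is the intersection nonempty?
#' @param b_only logical; is B \\ A nonempty?
#' @return One of the symbols in [rcc5_relations()].
#' @export
#' @examples
#' relation_of(FALSE, TRUE, FALSE) # "=="
#' relation_of(TRUE, TRUE, FALSE)  # ">" : A properly includes B
relation_of <- function(a_only, both, b_only) {
  stopifnot(is.logical(a_only), is.logical(both), is.logical(b_only))
  if (!both && !(a_only && b_only))
    stop("zone pattern implies an empty region; RCC-5 relations are defined ",
         "for nonempty regions only")
  if (both) {
    if (a_only && b_only) return("><")
    if (a_only) return(">")
    if (b_only) return("<")
    return("==")
  }
  "!" # a_only && b_only && !both
}

#' Converse of an RCC-5 relation (or relation set)
#'
#' Swapping the two arguments of a relation maps `<` to `>` and fixes
#' `==`, `><` and `!`.
#'
#' @param rel character vector of relation symbols.
#' @return Character vector of the converse symbols.
#' @export
rcc5_converse <- function(rel) {
  conv <- c("==" = "==", "<" = ">", ">" = "<", "><" = "><", "!" = "!")
  unname(conv[rel])
}

# Parse a rendered relation-set string ("==", "{< ><}") into a character
# vector of symbols, validated and put in canonical order.
parse_relset <- function(x) {
  x <- trimws(x)
  if (grepl("^\\{.*\\}$", x))
    x <- trimws(substr(x, 2, nchar(x) - 1L))
  syms <- strsplit(x, "[[:space:]]+")[[1]]
  syms <- syms[nzchar(syms)]
  bad <- setdiff(syms, rcc5_relations())
  if (length(syms) == 0L || length(bad) > 0L)
    stop("invalid RCC-5 relation set: '", x, "'")
  intersect(rcc5_relations(), unique(syms))
}

# Render a character vector of symbols back to the string form.
render_relset <- function(syms) {
  syms <- intersect(rcc5_relations(), syms)
  if (length(syms) == 0L) return("{}")
  if (length(syms) == 1L) return(syms)
  paste0("{", paste(syms, collapse = " "), "}")
}
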