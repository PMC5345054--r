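#' The three-treatment Scelianoma alignment
#'
#' Reconstruction of the published alignment of the weevil genus
#' *Scelianoma* across three treatments: the 2009 original description
#' (genus with its single species *S. elydimorpha*), the 2012 cladistic
#' revision (same circumscription), and the 2017 treatment adding the
#' fossil species *S. compacta*. Species-level congruences and
#' genus-level articulations are asserted; all parents obey the
#' coverage constraint.
#'
#' With 2 + 2 + 3 concepts the alignment has 16 cross-taxonomy concept
#' pairs, all of whose Maximally Informative Relations are singletons;
#' the merged graph shows the earlier, less inclusive genus
#' circumscription properly included in the 2017 one.
#'
#' @return An [alignment_problem()] with three taxonomies.
#' @export
#' @examples
#' p <- scelianoma_problem()
#' nrow(compute_mir(p)) # 16
scelianoma_problem <- function() {
  t2009 <- taxonomy("2009", list(Scelianoma = "Scelianoma_elydimorpha"),
                    title = "original description 2009")
  t2012 <- taxonomy("2012", list(Scelianoma = "Scelianoma_elydimorpha"),
                    title = "cladistic revision 2012")
  t2017 <- taxonomy("2017", list(Scelianoma = c("Scelianoma_elydimorpha",
                                                "Scelianoma_compacta")),
                    title = "fossil treatment 2017")
  art <- data.frame(
    left = c("2009.Scelianoma", "2009.Scelianoma_elydimorpha",
             "2012.Scelianoma", "2012.Scelianoma_elydimorpha"),
    relation = c("==", "==", "<", "=="),
    right = c("2012.Scelianoma", "2012.Scelianoma_elydimorpha",
              "2017.Scelianoma", "2017.Scelianoma_elydimorpha"),
    stringsAsFactors = FALSE)
  alignment_problem(list(t2009, t2012, t2017), art)
}

# Character codings of the three Dominican amber fossils, characters
# 1-143 of the underlying cladistic matrix, transcribed block by block
# as printed (1-25, 26-50, 51-75, 76-100; 101-143 are all missing).
# '-' inapplicable, '?' missing information.
.fossil_blocks <- list(
  Scelianoma_compacta = c(
    "0 0 2 0 0 0 1 0 0 0 0 0 0 0 0 0 - 1 0 0 0 0 0 0 0",
    "1 0 0 0 0 0 0 0 1 1 0 0 0 0 0 0 0 0 0 0 - - 0 ? ?",
    "0 0 0 0 0 0 0 2 0 0 0 1 0 0 0 1 0 0 0 0 - - 0 - 0",
    "0 0 0 0 0 - - 1 - - 0 0 0 ? ? ? ? ? ? ? ? ? ? ? ?"),
  Tropirhinus_palpebratus = c(
    "0 0 2 0 0 0 1 0 1 0 0 0 0 0 0 1 0 0 0 0 0 0 1 0 0",
    "0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 - - 0 ? ?",
    "0 0 0 0 0 0 0 2 0 0 0 0 0 0 0 0 1 0 0 0 - - 0 - 0",
    "0 0 0 0 0 0 0 ? ? ? 0 0 0 ? ? ? ? ? ? ? ? ? ? ? ?"),
  Diaprepes_anticus = c(
    "0 0 2 0 0 0 1 0 0 0 0 0 0 1 0 1 1 0 0 0 0 0 0 0 0",
    "0 0 1 2 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 1 - - 0 ? ?",
    "0 0 0 0 0 0 0 2 0 0 0 0 0 0 0 0 0 0 0 0 - - 0 - 0",
    "0 0 0 0 0 - - 0 0 0 1 0 0 ? ? ? ? ? ? ? ? ? ? ? ?"))

.fossil_rows <- vapply(.fossil_blocks, function(blocks)
  paste0(paste(gsub(" ", "", blocks), collapse = ""), strrep("?", 43)), "")

#' Character codings of the three amber fossils
#'
#' The 3 x 143 extension rows of the underlying cladistic character
#' matrix coding the Dominican amber fossils *Scelianoma compacta*,
#' *Tropirhinus palpebratus* and *Diaprepes anticus*. `'-'` marks an
#' inapplicable character, `'?'` missing information; characters
#' 89-143 could not be assessed on the amber inclusions.
#'
#' @return A [character_matrix()] with 3 taxa and 143 characters.
#' @export
#' @examples
#' coded_stats(fossil_matrix())$max_coded_index # 88
fossil_matrix <- function() {
  cells <- do.call(rbind, lapply(.fossil_rows, function(s)
    strsplit(s, "")[[1]]))
  rownames(cells) <- names(.fossil_rows)
  character_matrix(cells)
}
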