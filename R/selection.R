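# Bioactivity-guided fragment selection: structural-constraint filtering
# (RFset1/AFset1 style) and similarity-based bioactive-like selection with
# inactive-neighborhood removal (RFset2/AFset2 style).

#' Structural criteria for ring-fragment selection (RFset1 defaults)
#'
#' Defaults follow the bioactive-like RF selection: up to two rings, largest
#' ring size up to seven, up to three heteroatoms, up to three acyclic
#' atoms, restricted to exclusive fragments.
#'
#' @param max_rings,max_ring_size,max_heteroatoms,max_acyclic_atoms bounds.
#' @param require_exclusive restrict to fragments in the supplied exclusive set.
#' @return object of class `rf_criteria`.
#' @export
rf_criteria <- function(max_rings = 2, max_ring_size = 7, max_heteroatoms = 3,
                        max_acyclic_atoms = 3, require_exclusive = TRUE) {
  stopifnot(max_rings >= 0, max_ring_size >= 0, max_heteroatoms >= 0,
            max_acyclic_atoms >= 0)
  structure(list(max_rings = max_rings, max_ring_size = max_ring_size,
                 max_heteroatoms = max_heteroatoms,
                 max_acyclic_atoms = max_acyclic_atoms,
                 require_exclusive = isTRUE(require_exclusive)),
            class = c("rf_criteria", "molfrag_criteria"))
}

#' Structural criteria for acyclic-fragment selection (AFset1 defaults)
#'
#' Defaults follow the bioactive-like AF selection: no quaternary center, up
#' to one triple bond, up to four heteroatoms, up to four terminal atoms,
#' restricted to exclusive fragments.
#'
#' @param max_quaternary,max_triple_bonds,max_heteroatoms,max_terminal_atoms bounds.
#' @param require_exclusive restrict to fragments in the supplied exclusive set.
#' @return object of class `af_criteria`.
#' @export
af_criteria <- function(max_quaternary = 0, max_triple_bonds = 1,
                        max_heteroatoms = 4, max_terminal_atoms = 4,
                        require_exclusive = TRUE) {
  stopifnot(max_quaternary >= 0, max_triple_bonds >= 0, max_heteroatoms >= 0,
            max_terminal_atoms >= 0)
  structure(list(max_quaternary = max_quaternary,
                 max_triple_bonds = max_triple_bonds,
                 max_heteroatoms = max_heteroatoms,
                 max_terminal_atoms = max_terminal_atoms,
                 require_exclusive = isTRUE(require_exclusive)),
            class = c("af_criteria", "molfrag_criteria"))
}

#' Filter fragments by structural bounds
#'
#' Applies all bounds of the criteria (computed by [rf_profile()] /
#' [af_profile()]) and, when `require_exclusive`, membership in
#' `exclusive_set`.
#'
#' @param fragments character vector of fragment SMILES (RFs for
#'   `rf_criteria`, AFs for `af_criteria`).
#' @param criteria an `rf_criteria` or `af_criteria` object.
#' @param exclusive_set character vector of exclusive fragment keys
#'   (required when `criteria$require_exclusive`).
#' @return character vector: the fragments passing all constraints.
#' @export
filter_structural <- function(fragments, criteria, exclusive_set = NULL) {
  if (!inherits(criteria, "molfrag_criteria")) .usage_error("criteria must be rf_criteria() or af_criteria()")
  if (criteria$require_exclusive && is.null(exclusive_set)) {
    .usage_error("criteria require exclusivity but no exclusive_set was given")
  }
  if (!length(fragments)) return(character(0))
  if (inherits(criteria, "rf_criteria")) {
    p <- rf_profile(fragments)
    ok <- p$n_rings <= criteria$max_rings &
      p$largest_ring_size <= criteria$max_ring_size &
      p$n_heteroatoms <= criteria$max_heteroatoms &
      p$n_acyclic_atoms <= criteria$max_acyclic_atoms
  } else {
    p <- af_profile(fragments)
    ok <- p$n_quaternary <= criteria$max_quaternary &
      p$n_triple_bonds <= criteria$max_triple_bonds &
      p$n_heteroatoms <= criteria$max_heteroatoms &
      p$n_terminal_atoms <= criteria$max_terminal_atoms
  }
  if (criteria$require_exclusive) ok <- ok & (p$smiles %in% exclusive_set)
  fragments[ok]
}

#' Select bioactive-like fragments by similarity screening
#'
#' Retains candidates within `d_max` (MinHash Jaccard distance) of at least
#' one active reference fragment, then removes every candidate within
#' `d_max` of any inactive reference; removal takes precedence, so a
#' candidate near both an active and an inactive reference is dropped. The
#' result is a set difference and therefore independent of screening order.
#'
#' @param candidates character vector of candidate fragment SMILES.
#' @param active_refs,inactive_refs non-empty character vectors of reference
#'   fragment SMILES.
#' @param d_max,dimensions,radii,seed see [screen_within()].
#' @return character vector: the selected candidates.
#' @export
select_bioactive_like <- function(candidates, active_refs, inactive_refs,
                                  d_max = 0.6, dimensions = 256L,
                                  radii = c(1L, 2L), seed = 42L) {
  if (!length(active_refs) || !length(inactive_refs)) {
    .usage_error("select_bioactive_like needs non-empty active and inactive reference sets")
  }
  near_active <- screen_within(candidates, active_refs, d_max, dimensions, radii, seed)
  near_inactive <- screen_within(candidates, inactive_refs, d_max, dimensions, radii, seed)
  setdiff(near_active, near_inactive)
}

#' Annotate fragments with exclusivity against other collections
#'
#' @param selected character vector of fragment SMILES.
#' @param other_indexes list of `fragment_index` objects to compare against.
#' @return data frame with columns `fragment` and `exclusive` (`TRUE` iff
#'   absent from every supplied index).
#' @export
annotate_exclusivity <- function(selected, other_indexes) {
  if (inherits(other_indexes, "fragment_index")) other_indexes <- list(other_indexes)
  seen <- unique(unlist(lapply(other_indexes, function(o) names(.check_index(o)$counts))))
  data.frame(
    fragment = selected,
    exclusive = !(selected %in% seen),
    stringsAsFactors = FALSE
  )
}
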