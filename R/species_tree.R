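#' Default six-species guide tree
#'
#' Rooted topology over the six study taxa with the primate clade
#' (human, (macaque, marmoset)) sister to pig and the rodents (mouse, rat)
#' outermost. Branch lengths (expected substitutions per site) are calibrated
#' so that the human-to-species path divergences, converted through the
#' Jukes-Cantor model, reproduce typical CDS-level mean identities observed
#' between human and these species (macaque ~96.8%, marmoset ~94.7%,
#' pig ~89.4%, mouse ~86.7%, rat ~86.5%).
#'
#' @return An [ape::read.tree()] `phylo` object with six leaves.
#' @examples
#' tr <- default_species_tree()
#' ape::is.rooted(tr)
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(((human:0.012,(macaque:0.010,marmoset:0.033):0.0105):0.010,",
    "pig:0.092):0.008,(mouse:0.0967,rat:0.0982):0.020);"
  )
  ape::read.tree(text = txt)
}

validate_species_tree <- function(tree, taxa = study_species()) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  }
  if (length(tree$tip.label) != length(taxa) ||
      anyDuplicated(tree$tip.label) > 0 ||
      !setequal(tree$tip.label, taxa)) {
    stop("tree must have exactly ", length(taxa),
         " uniquely named leaves: ", paste(taxa, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("all branch lengths must be present and >= 0", call. = FALSE)
  }
  invisible(tree)
}

#' Tree depth and rescaling
#'
#' `tree_depth()` is the maximum root-to-leaf path length;
#' `rescale_tree_depth()` multiplies all branch lengths so the depth equals
#' `depth`.
#'
#' @param tree A `phylo` object.
#' @param depth Target depth (expected substitutions per site).
#' @return `tree_depth()` a scalar; `rescale_tree_depth()` a `phylo`.
#' @export
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' @rdname tree_depth
#' @export
rescale_tree_depth <- function(tree, depth) {
  stopifnot(depth > 0)
  d0 <- tree_depth(tree)
  if (d0 <= 0) stop("tree has zero depth; cannot rescale", call. = FALSE)
  tree$edge.length <- tree$edge.length * depth / d0
  tree
}

# leaf-to-leaf path lengths as a named matrix
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}
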