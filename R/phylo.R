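#' Concatenate conserved-group alignments into a supermatrix
#'
#' Blocks are ordered by the human chromosome (1-22, X, Y) and then by the
#' human CDS's genomic start coordinate, and the six rows are joined per
#' species, recording each block's column span.
#'
#' @param blocks Named list of [msa_block()]s keyed by human CDS id; every
#'   block must contain all six taxa.
#' @param human_cds Human CDS metadata tibble (`cds_id`, `chromosome`,
#'   `exons`).
#' @return Object of class `"supermatrix"`: list with `aln` (6-row character
#'   matrix) and `spans` (tibble `human_cds_id`, `start`, `end`).
#' @export
concatenate_blocks <- function(blocks, human_cds) {
  stopifnot(length(blocks) >= 1)
  taxa <- study_species()
  for (id in names(blocks)) {
    missing <- setdiff(taxa, rownames(blocks[[id]]))
    if (length(missing)) {
      stop("block ", id, " is missing species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  meta <- human_cds |>
    dplyr::filter(.data$cds_id %in% names(blocks)) |>
    dplyr::mutate(start = vapply(.data$exons, function(e) min(e[, 1]),
                                 numeric(1))) |>
    dplyr::arrange(chrom_rank(.data$chromosome), .data$start)
  ord <- meta$cds_id
  widths <- vapply(blocks[ord], ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  aln <- matrix("", nrow = length(taxa), ncol = sum(widths),
                dimnames = list(taxa, NULL))
  for (i in seq_along(ord)) {
    aln[taxa, starts[i]:ends[i]] <- blocks[[ord[i]]][taxa, , drop = FALSE]
  }
  structure(
    list(aln = aln,
         spans = tibble::tibble(human_cds_id = ord, start = as.integer(starts),
                                end = as.integer(ends))),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", nrow(x$aln), " taxa x ", ncol(x$aln), " columns (",
      nrow(x$spans), " blocks)\n", sep = "")
  invisible(x)
}

#' Extract one block's span from a supermatrix
#'
#' @param sm A [concatenate_blocks()] result.
#' @param human_cds_id Block id.
#' @return Character matrix of the block's columns.
#' @export
supermatrix_block <- function(sm, human_cds_id) {
  i <- match(human_cds_id, sm$spans$human_cds_id)
  if (is.na(i)) stop("unknown block id ", human_cds_id, call. = FALSE)
  sm$aln[, sm$spans$start[i]:sm$spans$end[i], drop = FALSE]
}

#' Pairwise distances from an alignment
#'
#' Pairwise-deletion distances: for each taxon pair, columns gapped (or `N`)
#' in either row are ignored; `p` is the mismatch proportion over the
#' remaining sites. Under the Jukes-Cantor model,
#' `d = -(3/4) log(1 - 4p/3)`, which is undefined (an error) at `p >= 0.75`.
#'
#' @param x A `"supermatrix"`, an [msa_block()], or a character matrix with
#'   taxon rownames.
#' @param model `"JC"` (default) or `"p"` (raw p-distance).
#' @return Symmetric numeric matrix with zero diagonal and a `model`
#'   attribute.
#' @export
seq_distances <- function(x, model = c("JC", "p")) {
  model <- match.arg(model)
  aln <- if (inherits(x, "supermatrix")) x$aln else x
  stopifnot(is.matrix(aln), !is.null(rownames(aln)), ncol(aln) >= 1)
  codes <- matrix(match(aln, c(ALPHABET, "-")) - 1L, nrow = nrow(aln))
  codes[codes == 5L] <- -1L
  cnt <- pair_mismatch_cpp(codes)
  if (any(cnt$valid[upper.tri(cnt$valid)] == 0)) {
    stop("a taxon pair shares no ungapped sites", call. = FALSE)
  }
  p <- cnt$mismatch / pmax(cnt$valid, 1L)
  d <- if (model == "p") {
    p
  } else {
    if (any(p[upper.tri(p)] >= 0.75)) {
      stop("Jukes-Cantor distance undefined: mismatch proportion >= 0.75",
           call. = FALSE)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(aln), rownames(aln))
  attr(d, "model") <- model
  d
}

# rank species chromosome labels numerically, then X, then Y
species_chrom_rank <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(n), n, ifelse(x == "X", 1e3, ifelse(x == "Y", 1e3 + 1, 1e3 + 2)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei with the Studier-Keppler Q
#' criterion): at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined, with branch lengths from
#' the standard formulas. Ties on Q are broken by the lexicographically
#' smallest (representative-taxon) pair; negative branch lengths are clamped
#' to 0 with a message. Returns an unrooted tree.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (n >= 3).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 3,
            !is.null(rownames(dm)))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix not symmetric",
                                        call. = FALSE)
  labels <- rownames(dm)
  D <- dm
  sub <- stats::setNames(as.list(labels), labels) # newick fragments
  rep_name <- stats::setNames(labels, labels)     # tie-break representative
  clamped <- FALSE
  br <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        key <- sort(c(rep_name[rownames(D)[i]], rep_name[rownames(D)[j]]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(q = q, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    a <- rownames(D)[i]; b <- rownames(D)[j]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    u <- paste0("(", sub[[a]], ":", br(bi), ",", sub[[b]], ":", br(bj), ")")
    others <- setdiff(rownames(D), c(a, b))
    du <- (D[a, others] + D[b, others] - D[a, b]) / 2
    D2 <- D[others, others, drop = FALSE]
    D2 <- rbind(cbind(D2, u = du), u = c(du, 0))
    rownames(D2)[nrow(D2)] <- "u" # placeholder, renamed below
    new_label <- paste0("node_", a, "_", b)
    rownames(D2)[nrow(D2)] <- colnames(D2)[ncol(D2)] <- new_label
    D <- D2
    sub[[new_label]] <- u
    rep_name[new_label] <- min(rep_name[a], rep_name[b])
  }
  l <- rownames(D)
  ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[[l[1]]], ":", br(ba), ",", sub[[l[2]]], ":", br(bb),
                ",", sub[[l[3]]], ":", br(bc), ");")
  if (clamped) message("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions of an unrooted tree, canonicalised
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  all_tips <- sort(tr$tip.label)
  internal <- tr$edge[, 2][tr$edge[, 2] > ntip]
  splits <- character(0)
  for (nd in internal) {
    s <- sort(desc[[nd]])
    if (length(s) < 2 || length(s) > ntip - 2) next
    if (all_tips[1] %in% s) s <- setdiff(all_tips, s)
    splits <- c(splits, paste(s, collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets (0 means identical unrooted topologies).
#'
#' @param tree_a,tree_b `phylo` objects over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  sa <- tree_splits(tree_a)
  sb <- tree_splits(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Human-referenced synteny map of the conserved CDS set
#'
#' For each human chromosome and model species, lists the species
#' chromosomes carrying that chromosome's conserved orthologs, ordered by
#' descending mapped-CDS count (ties: chromosome label order, numeric then
#' X then Y). A cell is "intact" when a single source chromosome carries
#' them all.
#'
#' @param conserved A [build_conserved_set()] result.
#' @param cds CDS metadata tibble for all species (`cds_id`, `species`,
#'   `chromosome`).
#' @return Tibble of class `"synteny_map"`: `human_chromosome`, `species`,
#'   `sources` (list of ordered chromosome labels), `counts` (list),
#'   `source_str`, `intact`, `n_conserved`.
#' @export
synteny_map <- function(conserved, cds) {
  keep <- dplyr::filter(conserved, .data$conserved)
  if (nrow(keep) == 0) stop("no conserved CDSs", call. = FALSE)
  chrom_of <- stats::setNames(cds$chromosome, cds$cds_id)
  human_chrom <- chrom_of[keep$human_cds_id]
  if (anyNA(human_chrom)) stop("missing chromosome for a human CDS",
                               call. = FALSE)
  long <- purrr::map_dfr(model_species(), function(sp) {
    sp_cds <- unlist(keep[[paste0(sp, "_cds")]])
    tibble::tibble(human_chromosome = unname(human_chrom),
                   species = sp,
                   chromosome = unname(chrom_of[sp_cds]))
  })
  if (anyNA(long$chromosome)) {
    stop("missing chromosome label for a conserved species CDS", call. = FALSE)
  }
  out <- long |>
    dplyr::count(.data$human_chromosome, .data$species, .data$chromosome) |>
    dplyr::group_by(.data$human_chromosome, .data$species) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   species_chrom_rank(.data$chromosome), .by_group = TRUE) |>
    dplyr::summarise(sources = list(.data$chromosome), counts = list(.data$n),
                     .groups = "drop") |>
    dplyr::mutate(
      source_str = vapply(.data$sources, paste, character(1), collapse = ", "),
      intact = lengths(.data$sources) == 1,
      n_conserved = vapply(.data$counts, sum, numeric(1))
    ) |>
    dplyr::arrange(chrom_rank(.data$human_chromosome),
                   match(.data$species, model_species()))
  class(out) <- c("synteny_map", class(out))
  out
}

#' Wide, publication-style synteny table
#'
#' One row per human chromosome: total human CDS count, conserved CDS count,
#' and each species' ordered source-chromosome list.
#'
#' @param map A [synteny_map()] result.
#' @param conserved The [build_conserved_set()] result.
#' @param cds CDS metadata tibble (all species).
#' @return Tibble with one column per model species.
#' @export
synteny_table <- function(map, conserved, cds) {
  human <- dplyr::filter(cds, .data$species == "human")
  totals <- human |> dplyr::count(.data$chromosome, name = "total_cds")
  cons_tot <- human |>
    dplyr::filter(.data$cds_id %in%
                    conserved$human_cds_id[conserved$conserved]) |>
    dplyr::count(.data$chromosome, name = "conserved_cds")
  wide <- map |>
    dplyr::select("human_chromosome", "species", "source_str") |>
    tidyr::pivot_wider(names_from = "species", values_from = "source_str")
  totals |>
    dplyr::left_join(cons_tot, by = "chromosome") |>
    dplyr::mutate(conserved_cds = dplyr::coalesce(.data$conserved_cds, 0L)) |>
    dplyr::rename(human_chromosome = "chromosome") |>
    dplyr::right_join(wide, by = "human_chromosome") |>
    dplyr::arrange(chrom_rank(.data$human_chromosome))
}
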