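
encode_seq <- function(s) {
  codes <- match(strsplit(toupper(s), "")[[1]], c(ALPHABET, "-")) - 1L
  if (anyNA(codes)) stop("sequence contains non-IUPAC characters", call. = FALSE)
  codes[codes == 5L] <- -1L
  codes
}

decode_row <- function(codes) {
  out <- character(length(codes))
  out[codes >= 0] <- ALPHABET[codes[codes >= 0] + 1L]
  out[codes < 0] <- "-"
  paste(out, collapse = "")
}

#' Construct / validate an MSA block
#'
#' An MSA block is a six-way gapped alignment of one conserved ortholog
#' group, stored as a character matrix (one row per taxon, one column per
#' alignment column, gap `"-"`), human-referenced via its `human_cds_id`
#' attribute.
#'
#' @param aligned Named character vector of equal-length aligned sequences
#'   (names are taxa and must include `"human"`), or a character matrix with
#'   taxon rownames.
#' @param human_cds_id Identifier of the human CDS in the group.
#' @param inputs Optional named character vector of the ungapped input
#'   sequences; if given, each aligned row must de-gap to its input exactly.
#' @return A character matrix of class `"msa_block"`.
#' @export
msa_block <- function(aligned, human_cds_id, inputs = NULL) {
  if (is.matrix(aligned)) {
    m <- aligned
  } else {
    stopifnot(is.character(aligned), !is.null(names(aligned)))
    w <- unique(nchar(aligned))
    if (length(w) != 1) stop("aligned rows differ in length", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(aligned), ""))
    rownames(m) <- names(aligned)
  }
  if (!"human" %in% rownames(m)) stop("block lacks a human row", call. = FALSE)
  if (!is.null(inputs)) {
    for (sp in rownames(m)) {
      if (!sp %in% names(inputs)) stop("missing input for taxon ", sp,
                                       call. = FALSE)
      degapped <- paste(m[sp, m[sp, ] != "-"], collapse = "")
      if (!identical(degapped, toupper(inputs[[sp]]))) {
        stop("aligned row for ", sp, " does not de-gap to its input",
             call. = FALSE)
      }
    }
  }
  structure(m, human_cds_id = human_cds_id, class = c("msa_block", "matrix"))
}

#' @export
print.msa_block <- function(x, ...) {
  cat("<msa_block> ", attr(x, "human_cds_id"), ": ", nrow(x), " taxa x ",
      ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' Tree-guided progressive alignment of one ortholog group
#'
#' Aligns the six sequences of a conserved ortholog group by progressive
#' profile alignment: leaves are merged in the guide tree's postorder, each
#' merge being a global affine-gap (Gotoh) alignment of the two child
#' profiles with mean-pairwise column scoring. Alternatively accepts a
#' pre-computed alignment (`prealigned`), whose rows are validated to de-gap
#' back to the inputs.
#'
#' @param seqs Named character vector, one ungapped sequence per guide-tree
#'   taxon (must include `"human"`).
#' @param tree Guide tree (`phylo`) whose tip labels equal `names(seqs)`.
#' @param human_cds_id Identifier recorded on the block.
#' @param prealigned Optional named character vector of aligned rows to use
#'   instead of computing the alignment.
#' @param scoring Alignment scoring parameters, as in [best_hits()].
#' @return An [msa_block()].
#' @export
align_group <- function(seqs, tree = default_species_tree(),
                        human_cds_id = "group", prealigned = NULL,
                        scoring = default_scoring()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  validate_species_tree(tree, taxa = names(seqs))
  if (!is.null(prealigned)) {
    return(msa_block(prealigned, human_cds_id, inputs = seqs))
  }
  if (any(nchar(seqs) == 0)) stop("empty input sequence", call. = FALSE)

  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  profiles <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    m <- matrix(encode_seq(seqs[[tree$tip.label[i]]]), nrow = 1)
    rownames(m) <- tree$tip.label[i]
    profiles[[i]] <- m
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    if (is.null(profiles[[parent]])) {
      profiles[[parent]] <- profiles[[child]]
    } else {
      profiles[[parent]] <- merge_profiles(profiles[[parent]],
                                           profiles[[child]], scoring)
    }
  }
  aln <- profiles[[ntip + 1L]]
  rows <- vapply(rownames(aln), function(sp) decode_row(aln[sp, ]),
                 character(1))
  msa_block(rows[names(seqs)], human_cds_id, inputs = seqs)
}

merge_profiles <- function(a, b, scoring) {
  p <- nw_profile_cpp(a, b, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_ext)
  n <- length(p$path_a)
  out <- matrix(-1L, nrow = nrow(a) + nrow(b), ncol = n)
  rownames(out) <- c(rownames(a), rownames(b))
  ia <- p$path_a > 0
  ib <- p$path_b > 0
  out[seq_len(nrow(a)), ia] <- a[, p$path_a[ia], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), ib] <- b[, p$path_b[ib], drop = FALSE]
  out
}

#' Align every conserved ortholog group
#'
#' @param cds Tibble of all species' CDSs (as in `simulate_orthologs()$cds`
#'   or read from FASTA + metadata).
#' @param conserved A [build_conserved_set()] result; only rows with
#'   `conserved == TRUE` are aligned.
#' @param tree Guide tree over the six taxa.
#' @param scoring Alignment scoring parameters.
#' @return Named list of [msa_block()]s keyed by human CDS id.
#' @export
align_conserved_groups <- function(cds, conserved,
                                   tree = default_species_tree(),
                                   scoring = default_scoring()) {
  species <- model_species()
  keep <- dplyr::filter(conserved, .data$conserved)
  seq_of <- stats::setNames(cds$sequence, cds$cds_id)
  blocks <- lapply(seq_len(nrow(keep)), function(i) {
    ids <- c(human = keep$human_cds_id[i],
             stats::setNames(unlist(keep[i, paste0(species, "_cds")]), species))
    align_group(stats::setNames(seq_of[ids], names(ids)), tree,
                human_cds_id = keep$human_cds_id[i], scoring = scoring)
  })
  stats::setNames(blocks, keep$human_cds_id)
}

#' Extract human-referenced variant columns from an MSA block
#'
#' A column is a variant column iff the human row is not gapped there and at
#' least one non-human row differs from the human base (a gap in a non-human
#' row counts as a difference for detection, but can never match an allele).
#' Columns gapped in the human row are skipped entirely: human coordinates
#' are the analysis frame.
#'
#' @param block An [msa_block()].
#' @return Tibble: `human_cds_id`, `column`, `cds_pos`, `ref` (human base),
#'   and one base column per non-human taxon.
#' @export
extract_variant_columns <- function(block) {
  stopifnot(inherits(block, "msa_block"))
  others <- setdiff(rownames(block), "human")
  human <- block["human", ]
  not_gap <- human != "-"
  diff_any <- colSums(block[others, , drop = FALSE] !=
                        matrix(human, nrow = length(others),
                               ncol = ncol(block), byrow = TRUE)) > 0
  cols <- which(not_gap & diff_any)
  cds_pos <- cumsum(not_gap)
  out <- tibble::tibble(
    human_cds_id = attr(block, "human_cds_id"),
    column = cols,
    cds_pos = cds_pos[cols],
    ref = human[cols]
  )
  for (sp in others) out[[sp]] <- unname(block[sp, cols])
  out
}

#' Project an alignment column to a human CDS position
#'
#' The CDS position is the count of non-gap human characters in columns
#' `1..column`; errors if the human row is gapped at `column`.
#'
#' @param block An [msa_block()].
#' @param column Alignment column (1-based).
#' @return Integer CDS position.
#' @export
project_column <- function(block, column) {
  human <- block["human", ]
  stopifnot(column >= 1, column <= length(human))
  if (human[column] == "-") {
    stop("human row is gapped at column ", column, call. = FALSE)
  }
  sum(human[seq_len(column)] != "-")
}

#' Locate the alignment column of a human CDS position
#'
#' Inverse of [project_column()].
#'
#' @param block An [msa_block()].
#' @param cds_pos Human CDS position (1-based).
#' @return Integer alignment column.
#' @export
locate_column <- function(block, cds_pos) {
  human <- block["human", ]
  idx <- which(human != "-")
  if (cds_pos < 1 || cds_pos > length(idx)) {
    stop("cds_pos out of range [1, ", length(idx), "]", call. = FALSE)
  }
  idx[cds_pos]
}

#' Map a human SNP catalog through the six-way alignments
#'
#' Locates every catalog SNP whose genomic position falls inside a conserved
#' human CDS, projects it to its alignment column, reads each model species'
#' residue there, and flags whether it equals the catalog major allele
#' ("identified in" that species; a gap never matches). SNPs whose human
#' reference base disagrees with the catalog major allele are excluded and
#' reported separately (with a message), not silently matched.
#'
#' @param blocks Named list of [msa_block()]s keyed by human CDS id.
#' @param human_cds Tibble of human CDS metadata (`cds_id`, `chromosome`,
#'   `strand`, `exons` list-column, `sequence`).
#' @param catalog SNP catalog tibble (`rsid`, `chrom`, `pos`, `major_allele`,
#'   `minor_alleles`); duplicate (chrom, pos) entries are an error.
#' @return List: `mapped` (tibble: `rsid`, `human_cds_id`, `column`,
#'   `cds_pos`, `chrom`, `pos`, `major_allele`, one `<species>_allele` and
#'   one `<species>_match` column per model species), `counts` (per-species
#'   identified-SNP counts), `excluded` (major-allele-mismatch rows).
#' @export
match_catalog <- function(blocks, human_cds, catalog) {
  dup <- catalog |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate catalog positions: ",
         paste(sprintf("%s:%d", dup$chrom, dup$pos), collapse = ", "),
         call. = FALSE)
  }
  species <- model_species()
  meta <- dplyr::filter(human_cds, .data$cds_id %in% names(blocks))
  pidx <- position_index(meta)
  located <- dplyr::inner_join(
    catalog[, c("rsid", "chrom", "pos", "major_allele")], pidx,
    by = c("chrom", "pos")
  )

  empty_mapped <- tibble::tibble(
    rsid = character(), human_cds_id = character(), column = integer(),
    cds_pos = integer(), chrom = character(), pos = integer(),
    major_allele = character()
  )
  for (sp in species) {
    empty_mapped[[paste0(sp, "_allele")]] <- character()
    empty_mapped[[paste0(sp, "_match")]] <- logical()
  }
  if (nrow(located) == 0) {
    counts <- tibble::tibble(species = species, n_identified = 0L)
    return(list(mapped = empty_mapped, counts = counts,
                excluded = empty_mapped))
  }

  rows <- purrr::map_dfr(split(located, located$cds_id), function(d) {
    block <- blocks[[d$cds_id[1]]]
    human <- block["human", ]
    col_of <- which(human != "-")
    cols <- col_of[d$cds_pos]
    out <- tibble::tibble(
      rsid = d$rsid, human_cds_id = d$cds_id, column = cols,
      cds_pos = d$cds_pos, chrom = d$chrom, pos = d$pos,
      major_allele = d$major_allele, ref = human[cols]
    )
    for (sp in species) {
      al <- unname(block[sp, cols])
      out[[paste0(sp, "_allele")]] <- al
      out[[paste0(sp, "_match")]] <- al != "-" & al == d$major_allele
    }
    out
  })
  rows <- dplyr::arrange(rows, chrom_rank(.data$chrom), .data$pos)

  bad <- rows$ref != rows$major_allele
  excluded <- rows[bad, , drop = FALSE]
  if (nrow(excluded) > 0) {
    message(nrow(excluded), " catalog SNP(s) excluded: human base differs ",
            "from the catalog major allele")
  }
  mapped <- rows[!bad, setdiff(names(rows), "ref"), drop = FALSE]
  counts <- tibble::tibble(
    species = species,
    n_identified = vapply(species, function(sp) {
      sum(mapped[[paste0(sp, "_match")]])
    }, integer(1), USE.NAMES = FALSE)
  )
  list(mapped = mapped, counts = counts,
       excluded = excluded[, setdiff(names(excluded), "ref"), drop = FALSE])
}
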