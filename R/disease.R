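#' Join identified SNPs to disease associations, per species
#'
#' Produces one record per (species, rsid, disease, category, gene) for every
#' catalog SNP identified in that species (i.e. the species carries the human
#' major allele at the orthologous site). Association rows whose rsID does
#' not occur among the mapped SNPs are ignored, with the count reported in a
#' message.
#'
#' @param mapped The `mapped` tibble from [match_catalog()].
#' @param associations Association tibble: `rsid`, `disease`, `category`,
#'   `gene`.
#' @param categories Optional category vocabulary (24 labels); if supplied,
#'   an association row with a category outside it is an error.
#' @return Tibble: `species`, `rsid`, `disease`, `category`, `gene`.
#' @export
annotate_snp_diseases <- function(mapped, associations, categories = NULL) {
  stopifnot(all(c("rsid", "disease", "category", "gene") %in%
                  names(associations)))
  if (!is.null(categories)) {
    bad <- setdiff(unique(associations$category), categories)
    if (length(bad)) {
      stop("association categories outside the 24-label vocabulary: ",
           paste(head(bad, 5), collapse = "; "), call. = FALSE)
    }
  }
  unknown <- setdiff(unique(associations$rsid), mapped$rsid)
  if (length(unknown)) {
    message(length(unknown), " association rsID(s) not among mapped SNPs; ",
            "ignored")
  }
  purrr::map_dfr(model_species(), function(sp) {
    hit <- mapped$rsid[mapped[[paste0(sp, "_match")]]]
    associations |>
      dplyr::filter(.data$rsid %in% hit) |>
      dplyr::transmute(species = sp, .data$rsid, .data$disease,
                       .data$category, .data$gene)
  })
}

# case-folded disease key; first-seen spelling kept for display
disease_key <- function(x) tolower(trimws(x))

#' Conserved and species-specific disease sets
#'
#' From per-species disease records, computes the diseases identified in all
#' five model species (conserved), those identified in exactly one
#' (species-specific), and the full upset-style membership pattern counts.
#' Disease identity is the case-folded disease-name string.
#'
#' @param records Tibble from [annotate_snp_diseases()].
#' @return Object of class `"specificity_report"`: list with `conserved`
#'   (tibble: `disease`, `genes` list-column, `n_genes`), `specific`
#'   (tibble: `species`, `disease`, `genes`, `n_genes`), `patterns`
#'   (tibble: `pattern` in [model_species()] order, `n`), and `sets`
#'   (named list of per-species disease-key vectors).
#' @export
disease_specificity <- function(records) {
  species <- model_species()
  records <- dplyr::mutate(records, key = disease_key(.data$disease))
  display <- records |>
    dplyr::distinct(.data$key, .keep_all = TRUE) |>
    dplyr::select("key", "disease")
  genes_of <- records |>
    dplyr::distinct(.data$key, .data$gene) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(genes = list(sort(unique(.data$gene))), .groups = "drop")

  sets <- lapply(stats::setNames(nm = species), function(sp) {
    sort(unique(records$key[records$species == sp]))
  })
  all_keys <- sort(unique(unlist(sets)))
  member <- vapply(species, function(sp) all_keys %in% sets[[sp]],
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(all_keys, species))
  n_in <- rowSums(member)
  pattern <- apply(member, 1, function(f) paste(as.integer(f), collapse = ""))

  describe <- function(keys) {
    tibble::tibble(key = keys) |>
      dplyr::left_join(display, by = "key") |>
      dplyr::left_join(genes_of, by = "key") |>
      dplyr::mutate(n_genes = lengths(.data$genes)) |>
      dplyr::select("disease", "genes", "n_genes")
  }
  conserved <- describe(all_keys[n_in == length(species)])
  specific <- purrr::map_dfr(species, function(sp) {
    keys <- all_keys[n_in == 1 & member[, sp]]
    if (!length(keys)) return(NULL)
    dplyr::mutate(describe(keys), species = sp, .before = 1)
  })
  if (nrow(specific) == 0) {
    specific <- tibble::tibble(species = character(), disease = character(),
                               genes = list(), n_genes = integer())
  }
  patterns <- tibble::tibble(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pattern)

  structure(list(conserved = conserved, specific = specific,
                 patterns = patterns, sets = sets),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report>\n")
  cat("  conserved diseases (all five species):", nrow(x$conserved), "\n")
  tab <- table(factor(x$specific$species, levels = model_species()))
  cat("  species-specific:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Per-species disease category percentage profiles
#'
#' For each species: the percentage of its unique identified diseases falling
#' in each of the 24 categories (100 x category count / total disease
#' count). For every category, the species attaining the maximal percentage
#' is flagged (ties: all tied species flagged). A species with no diseases
#' gets an all-zero profile with a warning.
#'
#' @param records Tibble from [annotate_snp_diseases()].
#' @param categories The 24-category vocabulary; defaults to the categories
#'   present in `records` padded with [disease_categories()] as needed.
#' @return Tibble of class `"disease_profile"`: `species`, `category`, `n`,
#'   `pct`, `is_max`, 24 rows per species.
#' @export
category_profile <- function(records, categories = NULL) {
  if (is.null(categories)) {
    seen <- sort(unique(records$category))
    categories <- if (length(seen) == 24) seen else {
      unique(c(seen, disease_categories()))[1:24]
    }
  }
  if (length(categories) != 24) {
    stop("category vocabulary must have 24 labels", call. = FALSE)
  }
  uniq <- records |>
    dplyr::mutate(key = disease_key(.data$disease)) |>
    dplyr::distinct(.data$species, .data$key, .data$category)
  multi <- uniq |>
    dplyr::count(.data$species, .data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop("disease(s) mapped to more than one category: ",
         paste(head(unique(multi$key), 5), collapse = "; "), call. = FALSE)
  }
  out <- purrr::map_dfr(model_species(), function(sp) {
    d <- dplyr::filter(uniq, .data$species == sp)
    n <- vapply(categories, function(ct) sum(d$category == ct), integer(1))
    if (nrow(d) == 0) {
      warning("species ", sp, " has no identified diseases; all-zero profile",
              call. = FALSE)
      pct <- rep(0, 24)
    } else {
      pct <- 100 * n / nrow(d)
    }
    tibble::tibble(species = sp, category = categories, n = n, pct = pct)
  })
  out <- out |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(is_max = .data$pct == max(.data$pct) & max(.data$pct) > 0) |>
    dplyr::ungroup()
  class(out) <- c("disease_profile", class(out))
  out
}

#' Per-gene disease summaries
#'
#' Counts unique diseases per (species, gene), the genes common to all five
#' species, and -- per human chromosome and species -- the gene with the most
#' disease associations (ties broken alphabetically).
#'
#' @param records Tibble from [annotate_snp_diseases()].
#' @param gene_chrom Tibble mapping `gene` to human `chromosome` (from the
#'   human CDS metadata); required for the per-chromosome table.
#' @return List: `per_gene` (tibble `species`, `gene`, `n_diseases`),
#'   `common_genes` (character vector, genes present in all five species),
#'   `top_by_chromosome` (tibble `chromosome`, `species`, `gene`,
#'   `n_diseases`).
#' @export
gene_summaries <- function(records, gene_chrom = NULL) {
  per_gene <- records |>
    dplyr::mutate(key = disease_key(.data$disease)) |>
    dplyr::distinct(.data$species, .data$gene, .data$key) |>
    dplyr::count(.data$species, .data$gene, name = "n_diseases") |>
    dplyr::arrange(.data$species, dplyr::desc(.data$n_diseases), .data$gene)

  gene_sets <- split(per_gene$gene, per_gene$species)
  common_genes <- if (length(gene_sets) == length(model_species())) {
    sort(Reduce(intersect, gene_sets))
  } else {
    character(0)
  }

  top_by_chromosome <- NULL
  if (!is.null(gene_chrom)) {
    stopifnot(all(c("gene", "chromosome") %in% names(gene_chrom)))
    top_by_chromosome <- per_gene |>
      dplyr::inner_join(dplyr::distinct(gene_chrom, .data$gene,
                                        .data$chromosome),
                        by = "gene") |>
      dplyr::group_by(.data$chromosome, .data$species) |>
      dplyr::arrange(dplyr::desc(.data$n_diseases), .data$gene,
                     .by_group = TRUE) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup() |>
      dplyr::arrange(chrom_rank(.data$chromosome), .data$species) |>
      dplyr::select("chromosome", "species", "gene", "n_diseases")
  }
  list(per_gene = per_gene, common_genes = common_genes,
       top_by_chromosome = top_by_chromosome)
}
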