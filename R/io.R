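#' Write per-species CDS FASTA files and the metadata sidecar
#'
#' One FASTA per species (record names are CDS ids) plus a single metadata
#' TSV with columns `cds_id`, `gene`, `species`, `chromosome`, `strand`, and
#' `exons` as a `"start-end"` semicolon list (1-based inclusive, CDS 5'->3'
#' order).
#'
#' @param cds CDS tibble (as produced by [simulate_orthologs()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named vector; metadata last).
#' @export
write_cds_set <- function(cds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (sp in unique(cds$species)) {
    d <- dplyr::filter(cds, .data$species == sp)
    x <- Biostrings::DNAStringSet(stats::setNames(d$sequence, d$cds_id))
    p <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    paths[sp] <- p
  }
  meta <- cds |>
    dplyr::mutate(exons = vapply(.data$exons, exons_to_string, character(1))) |>
    dplyr::select("cds_id", "gene", "species", "chromosome", "strand", "exons")
  mp <- file.path(dir, "cds_metadata.tsv")
  readr::write_tsv(meta, mp)
  invisible(c(paths, metadata = mp))
}

#' Read a per-species CDS set from FASTA + metadata
#'
#' @param fasta_paths Named character vector of FASTA paths (names = species).
#' @param metadata_path Path to the metadata TSV written by
#'   [write_cds_set()].
#' @return CDS tibble with an `exons` list-column; errors if a sequence
#'   length disagrees with its exon intervals.
#' @export
read_cds_set <- function(fasta_paths, metadata_path) {
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  seqs <- purrr::imap_dfr(as.list(fasta_paths), function(p, sp) {
    x <- Biostrings::readDNAStringSet(p)
    tibble::tibble(species = sp, cds_id = names(x),
                   sequence = unname(as.character(x)))
  })
  out <- dplyr::inner_join(seqs, meta, by = c("cds_id", "species")) |>
    dplyr::mutate(exons = lapply(.data$exons, string_to_exons)) |>
    dplyr::select("species", "cds_id", "gene", "chromosome", "strand",
                  "exons", "sequence")
  widths <- vapply(out$exons, function(e) sum(e[, 2] - e[, 1] + 1L), numeric(1))
  bad <- widths != nchar(out$sequence)
  if (any(bad)) {
    stop("sequence length != sum of exon lengths for: ",
         paste(head(out$cds_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write / read the SNP catalog TSV
#'
#' Columns: `rsid`, `chrom`, `pos_1based`, `major_allele`, `minor_alleles`
#' (comma-separated).
#'
#' @param catalog Catalog tibble.
#' @param path File path.
#' @return `read_snp_catalog()` a tibble with `pos` as integer.
#' @export
write_snp_catalog <- function(catalog, path) {
  readr::write_tsv(
    dplyr::transmute(catalog, .data$rsid, .data$chrom,
                     pos_1based = .data$pos, .data$major_allele,
                     .data$minor_alleles),
    path
  )
  invisible(path)
}

#' @rdname write_snp_catalog
#' @export
read_snp_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(pos_1based = "i",
                                          .default = "c")) |>
    dplyr::rename(pos = "pos_1based")
}

#' Write / read the SNP-disease association TSV
#'
#' Columns: `rsid`, `disease`, `category`, `gene`.
#' @param associations Association tibble.
#' @param path File path.
#' @export
write_associations <- function(associations, path) {
  readr::write_tsv(
    associations[, c("rsid", "disease", "category", "gene")], path
  )
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write one MSA block as aligned FASTA
#'
#' @param block An [msa_block()].
#' @param path File path.
#' @export
write_msa_fasta <- function(block, path) {
  rows <- apply(block, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an aligned FASTA into an MSA block
#'
#' @param path Aligned FASTA (records named by taxon).
#' @param human_cds_id Block identifier.
#' @export
read_msa_fasta <- function(path, human_cds_id = basename(path)) {
  x <- Biostrings::readBStringSet(path)
  msa_block(stats::setNames(as.character(x), names(x)), human_cds_id)
}

write_distance_tsv <- function(dm, path) {
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(taxon = rownames(dm)),
                     tibble::as_tibble(as.data.frame(dm))),
    path
  )
  invisible(path)
}
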