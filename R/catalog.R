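#' Plant a dbSNP-style catalog into the simulated human CDS set
#'
#' Samples `n_snps` distinct human CDS positions, assigns each an rsID-style
#' identifier (`"rs"` + sequential integer), a major allele equal to the human
#' reference base at the site, one or two distinct minor alleles, and a minor
#' allele frequency drawn from the configured range. Genomic coordinates come
#' from the CDS exon structures via [cds_to_genome()]. Truth labels record,
#' per planted SNP and model species, whether that species carries the human
#' major allele at the orthologous site (a site lost to deletion never
#' matches).
#'
#' @param sim An [simulate_orthologs()] result.
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @return List with elements `catalog` (tibble: `rsid`, `chrom`, `pos`,
#'   `major_allele`, `minor_alleles`, `maf`, plus provenance columns `cds_id`,
#'   `cds_pos`, `gene`) and `truth` (tibble with one logical match column per
#'   model species).
#' @examples
#' sim <- simulate_orthologs(sim_config(n_cds = 3, n_snps = 20, seed = 2))
#' snps <- plant_snp_catalog(sim)
#' head(snps$catalog)
#' @export
plant_snp_catalog <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "ortholog_sim"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)

  human <- dplyr::filter(sim$cds, .data$species == "human")
  lens <- nchar(human$sequence)
  total <- sum(lens)
  if (config$n_snps > total) {
    stop("requested ", config$n_snps, " SNPs but only ", total,
         " human CDS positions exist", call. = FALSE)
  }
  empty <- tibble::tibble(
    rsid = character(), chrom = character(), pos = integer(),
    major_allele = character(), minor_alleles = character(), maf = double(),
    cds_id = character(), cds_pos = integer(), gene = character()
  )
  if (config$n_snps == 0) {
    return(list(catalog = empty, truth = empty[0, 1:4]))
  }

  flat <- sample.int(total, config$n_snps)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  row <- findInterval(flat, starts)
  cds_pos <- flat - starts[row] + 1L

  major <- substring(human$sequence[row], cds_pos, cds_pos)
  minors <- vapply(major, function(b) {
    paste(resample(setdiff(DNA_BASES, b), resample(1:2, 1)), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  gpos <- vapply(seq_along(row), function(i) {
    cds_to_genome(cds_pos[i], human$exons[[row[i]]], human$strand[row[i]])
  }, integer(1))

  catalog <- tibble::tibble(
    chrom = human$chromosome[row],
    pos = gpos,
    major_allele = major,
    minor_alleles = minors,
    maf = runif(config$n_snps, config$maf_range[1], config$maf_range[2]),
    cds_id = human$cds_id[row],
    cds_pos = cds_pos,
    gene = human$gene[row],
    group = human$group[row]
  ) |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos) |>
    dplyr::mutate(rsid = sprintf("rs%06d", dplyr::row_number()),
                  .before = 1)

  # truth: does each model species carry the human major allele at the
  # orthologous (same site-lineage) position?
  flags <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    grp <- sim$groups[[catalog$group[i]]]
    site <- grp$human$ids[catalog$cds_pos[i]]
    out <- lapply(stats::setNames(nm = model_species()), function(sp) {
      j <- match(site, grp[[sp]]$ids)
      !is.na(j) && grp[[sp]]$bases[j] == catalog$major_allele[i]
    })
    tibble::as_tibble(out)
  })
  truth <- dplyr::bind_cols(
    catalog[, c("rsid", "cds_id", "cds_pos", "chrom", "pos", "major_allele")],
    flags
  )
  catalog$group <- NULL
  list(catalog = catalog, truth = truth)
}

#' Build a synthetic SNP-disease association table
#'
#' Emulates a ClinVar/GWAS/DisGeNET-style join: each synthetic disease is
#' assigned one of the 24 configured categories and one gene symbol, and is
#' linked to 1-5 catalog rsIDs within that gene.
#'
#' @param catalog SNP catalog tibble from [plant_snp_catalog()] (must carry a
#'   `gene` column).
#' @param config A [sim_config()].
#' @return Tibble: `rsid`, `disease`, `category`, `gene`.
#' @export
make_disease_table <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- tibble::tibble(rsid = character(), disease = character(),
                          category = character(), gene = character())
  if (config$n_diseases == 0 || nrow(catalog) == 0) return(empty)
  if (!"gene" %in% names(catalog)) {
    stop("catalog must carry a `gene` column to plant diseases", call. = FALSE)
  }
  set.seed(config$seed + 2000L)
  by_gene <- split(catalog$rsid, catalog$gene)
  genes <- names(by_gene)
  purrr::map_dfr(seq_len(config$n_diseases), function(d) {
    gene <- resample(genes, 1)
    rsids <- resample(by_gene[[gene]],
                      min(resample(1:5, 1), length(by_gene[[gene]])))
    tibble::tibble(
      rsid = rsids,
      disease = sprintf("disease_%04d", d),
      category = resample(config$categories, 1),
      gene = gene
    )
  })
}
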