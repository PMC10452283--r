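#' Simulation configuration
#'
#' Parameters for the synthetic six-species ortholog generator. Defaults
#' define the package's standard desk-scale study conditions: 100 orthologous
#' CDS groups of 300-900 nt evolved without indels, 500 planted catalog SNPs,
#' and 100 planted diseases over 24 categories.
#'
#' @param n_cds Number of ancestral CDSs (ortholog groups), >= 1.
#' @param cds_length_range Two positive integers, both multiples of 3; CDS
#'   lengths are drawn uniformly (in codons) from this range.
#' @param indel_rate Indel events per site per unit branch length, >= 0.
#' @param indel_frame_preserving If `TRUE` (default) indel lengths are
#'   multiples of 3, keeping CDS reading frames plausible; `FALSE` allows
#'   frame-breaking indels for robustness testing.
#' @param n_snps Number of SNPs planted into the human CDS set.
#' @param maf_range Minor allele frequency range, both in (0, 0.5].
#' @param n_diseases Number of synthetic diseases in the association table.
#' @param categories Character vector of exactly 24 disease category labels.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_cds = 5, n_snps = 10, n_diseases = 4, seed = 1)
#' @export
sim_config <- function(n_cds = 100,
                       cds_length_range = c(300L, 900L),
                       indel_rate = 0,
                       indel_frame_preserving = TRUE,
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       n_diseases = 100,
                       categories = disease_categories(),
                       seed = 1L) {
  stopifnot(
    length(n_cds) == 1, n_cds >= 1,
    length(cds_length_range) == 2,
    all(cds_length_range > 0),
    cds_length_range[1] <= cds_length_range[2],
    length(indel_rate) == 1, indel_rate >= 0,
    is.logical(indel_frame_preserving),
    length(n_snps) == 1, n_snps >= 0,
    length(maf_range) == 2,
    all(maf_range > 0), all(maf_range <= 0.5),
    maf_range[1] <= maf_range[2],
    length(n_diseases) == 1, n_diseases >= 0,
    length(seed) == 1, is.finite(seed)
  )
  if (any(cds_length_range %% 3 != 0)) {
    stop("`cds_length_range` bounds must be multiples of 3", call. = FALSE)
  }
  if (length(categories) != 24 || anyDuplicated(categories) > 0) {
    stop("`categories` must be 24 unique labels", call. = FALSE)
  }
  structure(
    list(
      n_cds = as.integer(n_cds),
      cds_length_range = as.integer(cds_length_range),
      indel_rate = indel_rate,
      indel_frame_preserving = isTRUE(indel_frame_preserving),
      n_snps = as.integer(n_snps),
      maf_range = maf_range,
      n_diseases = as.integer(n_diseases),
      categories = as.character(categories),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_cds:", x$n_cds, " length:", paste(x$cds_length_range, collapse = "-"),
      "nt\n")
  cat("  indel_rate:", x$indel_rate,
      if (x$indel_frame_preserving) "(frame-preserving)" else "(frame-breaking)",
      "\n")
  cat("  n_snps:", x$n_snps, " maf:",
      paste(format(x$maf_range), collapse = "-"), "\n")
  cat("  n_diseases:", x$n_diseases, " categories: 24  seed:", x$seed, "\n")
  invisible(x)
}
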