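#' Project CDS positions to genomic coordinates
#'
#' Walks a CDS's exon intervals in CDS (5'->3') order. On the plus strand
#' positions ascend within each exon; on the minus strand the CDS walks the
#' genome descending, so exon intervals are listed high-to-low and positions
#' descend. All coordinates are 1-based inclusive.
#'
#' @param cds_pos Integer vector of CDS positions (1-based).
#' @param exons Two-column `start`/`end` matrix, rows in CDS 5'->3' order,
#'   each row with `start <= end` in genome coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of genomic positions.
#' @examples
#' ex <- cbind(start = c(100, 200), end = c(102, 203))
#' cds_to_genome(c(3, 4), ex, "+") # 102, 200
#' @export
cds_to_genome <- function(cds_pos, exons, strand) {
  stopifnot(is.matrix(exons), ncol(exons) == 2, strand %in% c("+", "-"))
  widths <- exons[, 2] - exons[, 1] + 1L
  if (any(widths <= 0)) stop("exon with end < start", call. = FALSE)
  total <- sum(widths)
  if (any(cds_pos < 1 | cds_pos > total)) {
    stop("cds_pos out of range [1, ", total, "]", call. = FALSE)
  }
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  idx <- findInterval(cds_pos, starts)
  within <- cds_pos - starts[idx] + 1L
  if (strand == "+") {
    as.integer(exons[idx, 1] + within - 1L)
  } else {
    as.integer(exons[idx, 2] - within + 1L)
  }
}

#' Project genomic positions to CDS coordinates
#'
#' Inverse of [cds_to_genome()]. Positions outside every exon return `NA`.
#'
#' @param genomic_pos Integer vector of 1-based genomic positions.
#' @inheritParams cds_to_genome
#' @return Integer vector of CDS positions (NA where not exonic).
#' @export
genome_to_cds <- function(genomic_pos, exons, strand) {
  stopifnot(is.matrix(exons), ncol(exons) == 2, strand %in% c("+", "-"))
  widths <- exons[, 2] - exons[, 1] + 1L
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- rep(NA_integer_, length(genomic_pos))
  for (i in seq_len(nrow(exons))) {
    inside <- genomic_pos >= exons[i, 1] & genomic_pos <= exons[i, 2]
    if (!any(inside)) next
    within <- if (strand == "+") {
      genomic_pos[inside] - exons[i, 1] + 1L
    } else {
      exons[i, 2] - genomic_pos[inside] + 1L
    }
    out[inside] <- as.integer(starts[i] + within - 1L)
  }
  out
}

# exon matrix <-> "start-end;start-end" metadata string
exons_to_string <- function(exons) {
  paste(sprintf("%d-%d", exons[, 1], exons[, 2]), collapse = ";")
}

string_to_exons <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

# flat (chrom, genomic pos) -> (cds_id, cds_pos) lookup over a CDS tibble
position_index <- function(cds_tbl) {
  purrr::pmap_dfr(
    list(cds_tbl$cds_id, cds_tbl$chromosome, cds_tbl$strand, cds_tbl$exons,
         nchar(cds_tbl$sequence)),
    function(id, chrom, strand, exons, len) {
      cp <- seq_len(len)
      tibble::tibble(
        chrom = chrom,
        pos = cds_to_genome(cp, exons, strand),
        cds_id = id,
        cds_pos = cp
      )
    }
  )
}
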