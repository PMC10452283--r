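
# sample() without the scalar-x surprise
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# autosome counts used for the toy species genomes (plus X and Y)
species_autosomes <- function() {
  c(macaque = 20L, marmoset = 22L, pig = 18L, mouse = 19L, rat = 20L)
}

#' Evolve six-species orthologous CDS sets along a known tree
#'
#' Generates `n_cds` ancestral coding sequences, assigns each a human gene
#' with a 1-5 exon structure on a toy genome (both strands, 1-based inclusive
#' coordinates), and evolves every CDS independently down the guide tree under
#' the Jukes-Cantor substitution model: on a branch of length `d` each site
#' substitutes with probability `(3/4)(1 - exp(-4d/3))`, choosing uniformly
#' among the three other bases. Optional indel events occur at
#' `indel_rate * length * d` expected events per branch, frame-preserving
#' (length a multiple of 3) by default. Site lineages are tracked so that
#' orthologous positions remain identifiable after indels; a deletion that
#' would empty a sequence is rejected and redrawn (with a message).
#'
#' @param config A [sim_config()].
#' @param tree Guide tree (`phylo`, six uniquely named leaves, branch
#'   lengths >= 0). Default [default_species_tree()].
#' @return An object of class `"ortholog_sim"`: a list with
#'   \describe{
#'     \item{cds}{tibble of all six species' CDSs: `species`, `cds_id`,
#'       `gene`, `chromosome`, `strand`, `exons` (list of two-column
#'       start/end matrices in CDS 5'->3' order), `sequence`, `group`.}
#'     \item{orthologs}{truth table pairing each non-human CDS with the human
#'       CDS it descends from.}
#'     \item{groups}{per-group site-lineage records used by
#'       [plant_snp_catalog()] to compute truth labels.}
#'     \item{config, tree}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_orthologs(sim_config(n_cds = 3, seed = 7))
#' dplyr::count(sim$cds, species)
#' @export
simulate_orthologs <- function(config, tree = default_species_tree()) {
  stopifnot(inherits(config, "sim_config"))
  validate_species_tree(tree)
  set.seed(config$seed)

  n <- config$n_cds
  lens <- 3L * resample(
    seq.int(config$cds_length_range[1] %/% 3L, config$cds_length_range[2] %/% 3L),
    n, replace = TRUE
  )

  layout <- human_genome_layout(n, lens)
  chrom_maps <- lapply(
    stats::setNames(nm = model_species()),
    function(sp) species_chrom_map(species_autosomes()[[sp]])
  )

  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  groups <- vector("list", n)
  rows <- vector("list", n * 6L)
  r <- 0L
  for (g in seq_len(n)) {
    anc <- resample(DNA_BASES, lens[g], replace = TRUE)
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- list(bases = anc, ids = seq_len(lens[g]))
    id_counter <- new.env(parent = emptyenv())
    id_counter$next_id <- lens[g] + 1L
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      node_seq[[child]] <- evolve_branch(
        node_seq[[parent]], tree$edge.length[e], config, id_counter
      )
    }
    leaves <- stats::setNames(
      lapply(seq_len(ntip), function(i) node_seq[[i]]),
      tree$tip.label
    )
    groups[[g]] <- leaves

    gene <- sprintf("GENE%04d", g)
    for (sp in study_species()) {
      seq_g <- leaves[[sp]]
      r <- r + 1L
      if (sp == "human") {
        rows[[r]] <- tibble::tibble(
          species = sp,
          cds_id = sprintf("human_cds%04d", g),
          gene = gene,
          chromosome = layout$chromosome[g],
          strand = layout$strand[g],
          exons = list(layout$exons[[g]]),
          sequence = paste(seq_g$bases, collapse = ""),
          group = g
        )
      } else {
        rows[[r]] <- tibble::tibble(
          species = sp,
          cds_id = sprintf("%s_cds%04d", sp, g),
          gene = gene,
          chromosome = map_species_chrom(layout$chromosome[g], chrom_maps[[sp]]),
          strand = "+",
          exons = list(NULL), # filled below once per-species offsets are known
          sequence = paste(seq_g$bases, collapse = ""),
          group = g
        )
      }
    }
  }
  cds <- dplyr::bind_rows(rows)

  # toy single-exon coordinates for non-human species, laid out sequentially
  # along each species chromosome
  cds <- cds |>
    dplyr::group_by(.data$species, .data$chromosome) |>
    dplyr::mutate(exons = assign_species_exons(
      .data$exons, nchar(.data$sequence), .data$species[1] == "human"
    )) |>
    dplyr::ungroup()

  human_ids <- sprintf("human_cds%04d", seq_len(n))
  orthologs <- cds |>
    dplyr::filter(.data$species != "human") |>
    dplyr::transmute(
      human_cds_id = human_ids[.data$group],
      species = .data$species,
      species_cds_id = .data$cds_id
    )

  structure(
    list(cds = cds, orthologs = orthologs, groups = groups,
         config = config, tree = tree),
    class = "ortholog_sim"
  )
}

#' @export
print.ortholog_sim <- function(x, ...) {
  cat("<ortholog_sim> ", x$config$n_cds, " ortholog groups x ",
      length(study_species()), " species\n", sep = "")
  invisible(x)
}

# Jukes-Cantor substitutions + optional indels on one branch.
evolve_branch <- function(node, d, config, id_counter) {
  bases <- node$bases
  ids <- node$ids
  n <- length(bases)
  if (d > 0 && n > 0) {
    p <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- which(runif(n) < p)
    if (length(hit)) {
      code <- match(bases[hit], DNA_BASES)
      shift <- resample(1:3, length(hit), replace = TRUE)
      bases[hit] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
    }
    if (config$indel_rate > 0) {
      n_events <- rpois(1, config$indel_rate * n * d)
      for (k in seq_len(n_events)) {
        for (attempt in 1:25) {
          len <- if (config$indel_frame_preserving) {
            3L * resample(1:3, 1)
          } else {
            resample(1:9, 1)
          }
          if (runif(1) < 0.5) { # insertion
            at <- resample(0:length(bases), 1)
            ins <- resample(DNA_BASES, len, replace = TRUE)
            new_ids <- seq.int(id_counter$next_id, length.out = len)
            id_counter$next_id <- id_counter$next_id + len
            bases <- append(bases, ins, after = at)
            ids <- append(ids, new_ids, after = at)
            break
          } else { # deletion
            if (length(bases) - len <= 0) {
              if (attempt == 25) {
                message("indel event dropped: deletion would empty the CDS")
              } else {
                next # resample the event
              }
            } else {
              at <- resample(seq_len(length(bases) - len + 1L), 1)
              keep <- -(at:(at + len - 1L))
              bases <- bases[keep]
              ids <- ids[keep]
            }
            break
          }
        }
      }
    }
  }
  list(bases = bases, ids = ids)
}

# Chromosome, strand, and 1-5 exon intervals for each human CDS.
human_genome_layout <- function(n, lens) {
  w <- c(seq(2.2, 1.0, length.out = 22), 1.4, 0.15)
  chromosome <- chrom_levels()[
    sample.int(24, n, replace = TRUE, prob = w / sum(w))
  ]
  strand <- resample(c("+", "-"), n, replace = TRUE)
  exons <- vector("list", n)
  offset <- stats::setNames(rep(1L, 24), chrom_levels())
  # lay CDSs left-to-right per chromosome in group order
  for (g in seq_len(n)) {
    chr <- chromosome[g]
    k <- resample(1:5, 1)
    k <- min(k, lens[g]) # guard tiny CDSs
    parts <- exon_partition(lens[g], k)
    introns <- if (k > 1) resample(50:5000, k - 1, replace = TRUE) else integer(0)
    start <- offset[[chr]] + resample(1000:10000, 1)
    iv <- matrix(0L, nrow = k, ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    pos <- start
    for (i in seq_len(k)) {
      iv[i, 1] <- pos
      iv[i, 2] <- pos + parts[i] - 1L
      pos <- iv[i, 2] + (if (i < k) introns[i] else 0L) + 1L
    }
    offset[[chr]] <- iv[k, 2] + 1L
    if (strand[g] == "-") iv <- iv[rev(seq_len(k)), , drop = FALSE]
    exons[[g]] <- iv
  }
  list(chromosome = chromosome, strand = strand, exons = exons)
}

# split len into k positive parts
exon_partition <- function(len, k) {
  if (k == 1) return(len)
  cuts <- sort(resample(seq_len(len - 1L), k - 1L))
  diff(c(0L, cuts, len))
}

# human chromosome -> species chromosome assignment; ~35% of human autosomes
# are split over two species chromosomes (emulating fragmented synteny)
species_chrom_map <- function(n_auto) {
  labels <- as.character(seq_len(n_auto))
  primary <- resample(labels, 22, replace = TRUE)
  secondary <- ifelse(runif(22) < 0.35, resample(labels, 22, replace = TRUE), NA)
  list(primary = primary, secondary = secondary)
}

map_species_chrom <- function(human_chr, cmap) {
  if (human_chr %in% c("X", "Y")) return(human_chr)
  i <- as.integer(human_chr)
  if (!is.na(cmap$secondary[i]) && cmap$secondary[i] != cmap$primary[i] &&
      runif(1) < 0.25) {
    cmap$secondary[i]
  } else {
    cmap$primary[i]
  }
}

# sequential single-exon toy coordinates for non-human CDSs
assign_species_exons <- function(exons, lens, is_human) {
  if (is_human) return(exons)
  start <- 1L + c(0L, cumsum(lens + 5000L))[seq_along(lens)]
  lapply(seq_along(lens), function(i) {
    matrix(c(start[i], start[i] + lens[i] - 1L), nrow = 1,
           dimnames = list(NULL, c("start", "end")))
  })
}
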