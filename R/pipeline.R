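PIPELINE_STAGES <- c("simulate", "conserve", "msa", "variants", "diseases",
                     "phylo", "synteny")

#' Pipeline configuration
#'
#' Declares either a simulation section ([sim_config()]) or paths to real
#' inputs (per-species FASTA + metadata TSV, SNP catalog TSV, association
#' TSV), the conservation thresholds (default: the 50% identity / 50%
#' coverage filters), the output directory, and which stages to run.
#'
#' @param out_dir Output directory.
#' @param simulate A [sim_config()], or `NULL` when real inputs are given.
#' @param inputs `NULL`, or a list with `fasta` (named paths, one per
#'   species), `metadata`, `catalog`, `associations`.
#' @param tree Guide tree over the six taxa.
#' @param min_identity,min_coverage Conservation filter thresholds.
#' @param stages Character subset of
#'   `c("simulate","conserve","msa","variants","diseases","phylo","synteny")`.
#' @param max_candidates Candidate prescreen width for [best_hits()]
#'   (default 10; `Inf` disables the prescreen).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = sim_config(),
                            inputs = NULL,
                            tree = default_species_tree(),
                            min_identity = 50,
                            min_coverage = 0.5,
                            stages = PIPELINE_STAGES,
                            max_candidates = 10) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("either a simulation section or real-input paths must be given",
         call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(inputs)) {
    stopifnot(all(c("fasta", "metadata", "catalog", "associations") %in%
                    names(inputs)))
  }
  stopifnot(all(stages %in% PIPELINE_STAGES))
  validate_species_tree(tree)
  structure(
    list(out_dir = out_dir, simulate = simulate, inputs = inputs, tree = tree,
         min_identity = min_identity, min_coverage = min_coverage,
         stages = stages, max_candidates = max_candidates),
    class = "pipeline_config"
  )
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order -- simulate (or load real inputs),
#' conservation filtering, per-group MSA, SNP projection, disease profiling,
#' phylogeny, synteny -- writing each stage's tables under `out_dir` and
#' finishing with a manifest (file list + MD5 content hashes + configuration
#' echo + package version). Identical configuration and seed give
#' byte-identical outputs and hence identical manifests. A stage failure
#' aborts with the stage name in the error.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest` (tibble `file`, `md5`) and `manifest_path`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    say("stage ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  on <- function(name) name %in% config$stages

  # --- inputs -------------------------------------------------------------
  if (on("simulate") && !is.null(config$simulate)) {
    stage("simulate", {
      res$sim <- simulate_orthologs(config$simulate, config$tree)
      snps <- plant_snp_catalog(res$sim)
      res$catalog <- snps$catalog
      res$snp_truth <- snps$truth
      res$associations <- make_disease_table(res$catalog, config$simulate)
      idir <- file.path(out, "inputs")
      write_cds_set(res$sim$cds, idir)
      write_snp_catalog(res$catalog, file.path(idir, "snp_catalog.tsv"))
      write_associations(res$associations,
                         file.path(idir, "associations.tsv"))
      readr::write_tsv(res$snp_truth, file.path(idir, "snp_truth.tsv"))
      res$cds <- res$sim$cds
    })
  } else if (!is.null(config$inputs)) {
    say("loading real inputs")
    res$cds <- read_cds_set(config$inputs$fasta, config$inputs$metadata)
    res$catalog <- read_snp_catalog(config$inputs$catalog)
    res$associations <- read_associations(config$inputs$associations)
  }
  human <- dplyr::filter(res$cds, .data$species == "human")

  # --- conservation -------------------------------------------------------
  stage("conserve", {
    hit_tables <- lapply(stats::setNames(nm = model_species()), function(sp) {
      q <- dplyr::filter(res$cds, .data$species == sp)
      h <- best_hits(q, human, max_candidates = config$max_candidates)
      readr::write_tsv(h, file.path(out, paste0("hits_", sp, ".tsv")))
      h
    })
    res$hits <- dplyr::bind_rows(hit_tables, .id = "species")
    filtered <- lapply(hit_tables, filter_hits,
                       min_identity = config$min_identity,
                       min_coverage = config$min_coverage)
    res$conserved <- build_conserved_set(filtered, human$cds_id)
    readr::write_tsv(
      dplyr::as_tibble(res$conserved),
      file.path(out, "conserved_set.tsv")
    )
    readr::write_tsv(intersection_counts(res$conserved),
                     file.path(out, "intersection_counts.tsv"))
    res$filtered_hits <- dplyr::bind_rows(filtered, .id = "species")
    res$stats <- identity_stats(
      res$filtered_hits,
      conserved_ids = res$conserved$human_cds_id[res$conserved$conserved]
    )
    readr::write_tsv(res$stats, file.path(out, "identity_stats.tsv"))
    res$anova <- compare_identity_groups(res$filtered_hits)
    readr::write_tsv(tidy(res$anova), file.path(out, "identity_anova.tsv"))
  })

  # --- msa ----------------------------------------------------------------
  stage("msa", {
    res$blocks <- align_conserved_groups(res$cds, res$conserved, config$tree)
    mdir <- file.path(out, "msa")
    dir.create(mdir, showWarnings = FALSE)
    for (id in names(res$blocks)) {
      write_msa_fasta(res$blocks[[id]], file.path(mdir, paste0(id, ".fasta")))
    }
  })

  # --- variants -----------------------------------------------------------
  stage("variants", {
    res$variant_columns <- purrr::map_dfr(res$blocks,
                                           extract_variant_columns)
    readr::write_tsv(res$variant_columns,
                     file.path(out, "variant_columns.tsv"))
    m <- match_catalog(res$blocks, human, res$catalog)
    res$mapped <- m$mapped
    res$snp_counts <- m$counts
    res$excluded_snps <- m$excluded
    readr::write_tsv(m$mapped, file.path(out, "mapped_snps.tsv"))
    readr::write_tsv(m$counts, file.path(out, "snp_counts.tsv"))
  })

  # --- diseases -----------------------------------------------------------
  stage("diseases", {
    res$records <- annotate_snp_diseases(res$mapped, res$associations)
    res$specificity <- disease_specificity(res$records)
    readr::write_tsv(
      res$specificity$specific |>
        dplyr::mutate(genes = vapply(.data$genes, paste, character(1),
                                     collapse = ",")),
      file.path(out, "species_specific_diseases.tsv")
    )
    readr::write_tsv(res$specificity$patterns,
                     file.path(out, "disease_patterns.tsv"))
    res$profile <- category_profile(res$records)
    readr::write_tsv(dplyr::as_tibble(res$profile),
                     file.path(out, "category_profile.tsv"))
    res$genes <- gene_summaries(
      res$records,
      gene_chrom = dplyr::distinct(human, gene = .data$gene,
                                   chromosome = .data$chromosome)
    )
    readr::write_tsv(res$genes$per_gene, file.path(out, "gene_summary.tsv"))
    readr::write_tsv(res$genes$top_by_chromosome,
                     file.path(out, "top_gene_per_chromosome.tsv"))
  })

  # --- phylo --------------------------------------------------------------
  stage("phylo", {
    res$supermatrix <- concatenate_blocks(res$blocks, human)
    res$distances <- seq_distances(res$supermatrix, model = "JC")
    write_distance_tsv(res$distances, file.path(out, "distances.tsv"))
    res$tree <- nj_tree(res$distances)
    ape::write.tree(res$tree, file.path(out, "nj_tree.nwk"), digits = 6)
  })

  # --- synteny ------------------------------------------------------------
  stage("synteny", {
    res$synteny <- synteny_map(res$conserved, res$cds)
    readr::write_tsv(
      synteny_table(res$synteny, res$conserved, res$cds),
      file.path(out, "synteny_table.tsv")
    )
  })

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(
    list.files(out, recursive = TRUE),
    "manifest.json"
  ))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files)))
  )
  cfg_echo <- config[c("min_identity", "min_coverage", "stages",
                       "max_candidates")]
  cfg_echo$simulate <- if (!is.null(config$simulate)) {
    unclass(config$simulate)
  }
  cfg_echo$tree <- ape::write.tree(config$tree)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(files = manifest, config = cfg_echo,
         package_version = as.character(utils::packageVersion("orthosnp"))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  res$manifest <- manifest
  res$manifest_path <- manifest_path
  say("done: ", nrow(manifest), " output files")
  invisible(res)
}
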