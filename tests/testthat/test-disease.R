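mapped_fixture <- function(flags) {
  # flags: named list rsid -> logical[5] in model_species() order
  out <- tibble::tibble(
    rsid = names(flags),
    human_cds_id = "human_cds0001", column = seq_along(flags),
    cds_pos = seq_along(flags), chrom = "1", pos = seq_along(flags),
    major_allele = "A"
  )
  m <- do.call(rbind, flags)
  for (i in seq_along(model_species())) {
    sp <- model_species()[i]
    out[[paste0(sp, "_allele")]] <- ifelse(m[, i], "A", "C")
    out[[paste0(sp, "_match")]] <- m[, i]
  }
  out
}

test_that("annotation joins only identified SNPs, per species", {
  mp <- mapped_fixture(list(
    rs1 = c(FALSE, FALSE, TRUE, FALSE, FALSE), # pig only
    rs2 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    rs3 = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  ))
  assoc <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs_unknown"),
    disease = c("colon cancer", "asthma", "gout"),
    category = c("Cancer", "Respiratory Tract Diseases", "Cancer"),
    gene = c("APC", "IL4", "X")
  )
  expect_message(rec <- annotate_snp_diseases(mp, assoc), "1 association")
  pig_only <- rec[rec$rsid == "rs1", ]
  expect_equal(nrow(pig_only), 1)
  expect_equal(pig_only$species, "pig")
  expect_equal(nrow(rec[rec$rsid == "rs3", ]), 0) # no association, no record
  expect_equal(sum(rec$rsid == "rs2"), 5)
  expect_error(
    annotate_snp_diseases(mp, assoc, categories = c("Other")),
    "vocabulary"
  )
})

test_that("annotation record count equals a brute-force nested-loop join", {
  set.seed(71)
  n <- 40
  flags <- lapply(seq_len(n), function(i) runif(5) < 0.6)
  names(flags) <- sprintf("rs%03d", seq_len(n))
  mp <- mapped_fixture(flags)
  assoc <- tibble::tibble(
    rsid = sample(names(flags), 100, TRUE),
    disease = sample(paste0("dis", 1:25), 100, TRUE),
    category = sample(disease_categories(), 100, TRUE),
    gene = sample(paste0("G", 1:10), 100, TRUE)
  )
  rec <- suppressMessages(annotate_snp_diseases(mp, assoc))
  # oracle: explicit nested loop
  want <- 0L
  for (sp in model_species()) {
    for (r in seq_len(nrow(assoc))) {
      i <- match(assoc$rsid[r], names(flags))
      if (flags[[i]][match(sp, model_species())]) want <- want + 1L
    }
  }
  expect_equal(nrow(rec), want)
})


test_that("specificity separates conserved from species-specific diseases", {
  sets <- list(
    macaque = c("shared", "mac only", "pair"),
    marmoset = c("shared", "pair"),
    pig = "shared", mouse = "shared", rat = "shared"
  )
  rep <- disease_specificity(records_fixture(sets))
  expect_equal(rep$conserved$disease, "shared")
  expect_equal(rep$specific$disease, "mac only")
  expect_equal(rep$specific$species, "macaque")
  # disjointness
  expect_length(intersect(rep$conserved$disease, rep$specific$disease), 0)
  # disease names compare case-folded
  rec2 <- records_fixture(list(macaque = "Colon Cancer", marmoset = "colon cancer",
                               pig = "colon cancer", mouse = "colon cancer",
                               rat = "colon cancer"))
  expect_equal(nrow(disease_specificity(rec2)$conserved), 1)
})

test_that("specificity pattern counts match brute-force enumeration", {
  set.seed(73)
  pool <- paste0("disease", 1:30)
  sets <- lapply(setNames(nm = model_species()),
                 function(sp) sample(pool, sample(5:25, 1)))
  rep <- disease_specificity(records_fixture(sets))
  want <- pattern_counts_oracle(sets, sort(unique(unlist(sets))))
  got <- setNames(rep$patterns$n, rep$patterns$pattern)
  expect_equal(got[names(want)], want)
  # conserved + sum of specific never exceeds the union
  expect_lte(nrow(rep$conserved) + nrow(rep$specific),
             length(unique(unlist(sets))))
})

test_that("category percentages are normalised and max-flagged", {
  rec <- dplyr::bind_rows(
    tibble::tibble(species = "pig", rsid = c("r1", "r2", "r3"),
                   disease = c("colon cancer", "Colon Cancer", "ms"),
                   category = c("Cancer", "Cancer", "Nervous System Diseases"),
                   gene = "G"),
    tibble::tibble(species = "mouse", rsid = "r4", disease = "obesity",
                   category = "Nutritional and Metabolic Diseases", gene = "G")
  )
  prof <- suppressWarnings(category_profile(rec))
  pig <- prof[prof$species == "pig", ]
  # duplicates deduplicate case-folded: 2 unique diseases
  expect_equal(unname(pig$pct[pig$category == "Cancer"]), 50)
  expect_equal(sum(pig$pct), 100, tolerance = 1e-9)
  # one-species categories flag that species as max
  expect_true(prof$is_max[prof$species == "mouse" &
                            prof$category == "Nutritional and Metabolic Diseases"])
  # forced arithmetic: {cancer, cancer, nervous} -> 66.67 / 33.33
  rec2 <- tibble::tibble(
    species = "rat", rsid = paste0("r", 1:3),
    disease = c("lung cancer", "gastric cancer", "epilepsy"),
    category = c("Cancer", "Cancer", "Nervous System Diseases"), gene = "G"
  )
  p2 <- suppressWarnings(category_profile(rec2))
  expect_equal(unname(p2$pct[p2$species == "rat" & p2$category == "Cancer"]),
               66.67, tolerance = 1e-2)
  # empty species: warning + all-zero profile
  w <- testthat::capture_warnings(category_profile(rec2))
  expect_true(any(grepl("no identified diseases", w)))
  # a disease in two categories is an error
  bad <- rec2
  bad$category[2] <- "Cancer"; bad$disease[2] <- "lung cancer"
  bad$category[1] <- "Infections"
  expect_error(suppressWarnings(category_profile(bad)), "more than one")
})

test_that("profiles are invariant to record order and sum to 100", {
  set.seed(79)
  rec <- tibble::tibble(
    species = sample(model_species(), 200, TRUE),
    rsid = paste0("r", 1:200),
    disease = sample(paste0("d", 1:40), 200, TRUE),
    category = NA_character_, gene = "G"
  )
  cat24 <- disease_categories()
  rec$category <- cat24[1 + (as.integer(factor(rec$disease)) %% 24)]
  p1 <- suppressWarnings(category_profile(rec))
  p2 <- suppressWarnings(category_profile(rec[sample(nrow(rec)), ]))
  expect_equal(dplyr::arrange(p1, species, category),
               dplyr::arrange(p2, species, category))
  sums <- tapply(p1$pct, p1$species, sum)
  expect_true(all(abs(sums - 100) < 1e-9 | sums == 0))
})

test_that("gene summaries count, intersect, and tie-break deterministically", {
  rec <- dplyr::bind_rows(lapply(model_species(), function(sp) {
    tibble::tibble(
      species = sp,
      rsid = paste0("r", 1:7),
      disease = c("d1", "d2", "d3", "d1", "d2", "d3", "d4"),
      category = "Cancer",
      gene = c("B", "B", "B", "A", "A", "A", "C")
    )
  }))
  gc <- tibble::tibble(gene = c("A", "B", "C"), chromosome = "7")
  gs <- gene_summaries(rec, gene_chrom = gc)
  # A and B tie at 3 diseases; alphabetical tie-break -> A
  top <- gs$top_by_chromosome
  expect_true(all(top$gene == "A"))
  expect_true(all(top$n_diseases == 3))
  expect_setequal(gs$common_genes, c("A", "B", "C"))
  # brute-force group-by oracle
  want <- with(unique(rec[, c("species", "gene", "disease")]),
               table(species, gene))
  for (i in seq_len(nrow(gs$per_gene))) {
    expect_equal(gs$per_gene$n_diseases[i],
                 unname(want[gs$per_gene$species[i], gs$per_gene$gene[i]]))
  }
})
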