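test_that("best_hit handles exact and near-exact matches", {
  subjects <- c(h1 = "ACGTACGTACGTACGTACGT", h2 = "TTTTTTTTTTGGGGGGGGGG")
  exact <- best_hit("ACGTACGTACGTACGTACGT", subjects)
  expect_equal(exact$subject, "h1")
  expect_equal(exact$pident, 100)
  expect_equal(exact$coverage, 1)

  h <- best_hit("ACGAACGT", c(h1 = "ACGTACGT"))
  expect_equal(h$pident, 87.5) # 7 of 8 columns identical
  expect_equal(h$coverage, 1)

  expect_error(best_hit("ACGU", subjects), "non-IUPAC")
})

test_that("best_hit scores equal the exhaustive Smith-Waterman oracle", {
  set.seed(2024)
  for (k in 1:20) {
    n <- sample(80:250, 1)
    a <- random_dna(n)
    b <- if (k %% 2 == 0) random_dna(sample(80:250, 1)) else mutate_dna(a, 0.2)
    got <- orthosnp:::sw_affine_cpp(a, b, 1, -2, -5, -2)
    expect_equal(got$score, sw_score_oracle(a, b), info = paste("pair", k))
  }
})

test_that("best_hit agrees with Biostrings local alignment scores", {
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (k in 1:5) {
    a <- mutate_dna(random_dna(200), 0.15)
    b <- mutate_dna(a, 0.15)
    ours <- orthosnp:::sw_affine_cpp(a, b, 1, -2, -5, -2)$score
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("tie-breaks are deterministic: score, identity, then subject id", {
  # two identical subjects -> lexicographically smallest id wins
  h <- best_hit("ACGTACGTAA", c(z_sub = "ACGTACGTAA", a_sub = "ACGTACGTAA"))
  expect_equal(h$subject, "a_sub")
})

test_that("the k-mer prescreen agrees with the full search on ortholog data", {
  sim <- tiny_sim(n_cds = 8, seed = 21)
  human <- dplyr::filter(sim$cds, species == "human")
  q <- dplyr::filter(sim$cds, species == "rat")
  full <- best_hits(q, human)
  screened <- best_hits(q, human, max_candidates = 3)
  expect_equal(screened, full)
})

test_that("filter thresholds are inclusive at-least bounds", {
  hits <- tibble::tibble(
    query = paste0("q", 1:4), subject = paste0("s", 1:4),
    pident = c(50.0, 49.99, 90, 90),
    length = 100L,
    coverage = c(0.5, 0.9, 0.499, 0.5),
    score = 10
  )
  kept <- filter_hits(hits)
  expect_setequal(kept$query, c("q1", "q4")) # boundary retained, below excluded
  expect_identical(nrow(filter_hits(hits[0, ])), 0L)
  # idempotent and order-independent
  expect_equal(filter_hits(kept), kept)
  expect_equal(dplyr::arrange(filter_hits(hits[4:1, ]), query), kept)
})

test_that("conserved-set patterns match brute-force enumeration on 50 CDSs", {
  set.seed(31)
  ids <- sprintf("human_cds%04d", 1:50)
  sets <- lapply(setNames(nm = model_species()),
                 function(sp) sample(ids, sample(20:45, 1)))
  cs <- build_conserved_set(lapply(sets, fake_hits), ids)
  got <- intersection_counts(cs, drop_empty = FALSE)
  want <- pattern_counts_oracle(sets, ids)
  expect_equal(setNames(got$n, got$pattern)[names(want)], want)
  # conserved iff present in all five
  manual <- vapply(ids, function(id) all(vapply(sets, function(s) id %in% s,
                                                logical(1))), logical(1))
  expect_equal(cs$conserved, unname(manual))
  expect_lte(sum(cs$conserved), min(lengths(sets)))
  # unknown subject id errors
  expect_error(build_conserved_set(list(macaque = fake_hits("nope")), ids),
               "unknown")
})

test_that("true ortholog pairings are recovered at low divergence", {
  tr <- rescale_tree_depth(default_species_tree(), 0.04) # all paths <= 0.1
  sim <- tiny_sim(n_cds = 10, seed = 33, tree = tr)
  human <- dplyr::filter(sim$cds, species == "human")
  for (sp in c("macaque", "rat")) {
    hits <- best_hits(dplyr::filter(sim$cds, species == sp), human)
    truth <- sim$orthologs[sim$orthologs$species == sp, ]
    expect_equal(hits$subject[match(truth$species_cds_id, hits$query)],
                 truth$human_cds_id)
  }
})

test_that("identity summaries use standard conventions", {
  one <- tibble::tibble(species = "pig", subject = "s1", pident = 90)
  s <- identity_stats(one)
  expect_equal(unlist(s[, c("mean", "median", "min", "max")]),
               c(mean = 90, median = 90, min = 90, max = 90))
  three <- tibble::tibble(species = "pig", subject = paste0("s", 1:3),
                          pident = c(80, 90, 100))
  s3 <- identity_stats(three)
  expect_equal(s3$mean, 90)
  expect_equal(s3$median, 90)
  expect_equal(c(s3$min, s3$max), c(80, 100))
  expect_error(identity_stats(three[0, ]), "no hits")
})

test_that("conserved-subset mean >= all-hits mean under identity-linked dropout", {
  # low-identity hits are the ones missing from other species' tables,
  # emulating divergence-correlated dropout
  set.seed(41)
  ids <- sprintf("human_cds%04d", 1:40)
  pid <- seq(55, 99, length.out = 40)
  keep_hi <- ids[pid > 70]
  tables <- lapply(setNames(nm = model_species()), function(sp) {
    fake_hits(unique(c(keep_hi, sample(ids, 10))), )
  })
  cs <- build_conserved_set(tables, ids)
  hits <- dplyr::bind_rows(lapply(tables, function(t) {
    t$pident <- pid[match(t$subject, ids)]
    t
  }), .id = "species")
  st <- identity_stats(hits, conserved_ids = cs$human_cds_id[cs$conserved])
  wide <- tidyr::pivot_wider(st[, c("species", "subset", "mean")],
                             names_from = "subset", values_from = "mean")
  expect_true(all(wide$conserved >= wide$all))
})

test_that("one-way ANOVA matches hand computation and degenerate rules", {
  fit <- compare_identity_groups(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(fit$f_statistic, 27) # SSB = 54 on 2 df, SSW = 6 on 6 df
  expect_equal(fit$df, c(2, 6))

  same <- compare_identity_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)

  flat <- compare_identity_groups(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$p_value, 1)

  # Bonferroni: adjusted = min(1, raw * n_pairs)
  td <- tidy(fit)
  expect_equal(td$p_bonferroni, pmin(1, td$p_raw * 3))
  gl <- glance(fit)
  expect_equal(gl$statistic, 27)
  expect_equal(gl$nobs, 9L)
})
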