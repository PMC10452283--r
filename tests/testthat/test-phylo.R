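test_that("concatenation orders blocks and records spans", {
  rows1 <- six_rows("ACGT")
  rows2 <- six_rows("AAACGG")
  b1 <- block_from_rows(rows1, id = "cdsA")
  b2 <- block_from_rows(rows2, id = "cdsB")
  human <- tibble::tibble(
    cds_id = c("cdsA", "cdsB"), chromosome = c("2", "1"),
    exons = list(cbind(start = 100L, end = 103L),
                 cbind(start = 10L, end = 15L))
  )
  sm <- concatenate_blocks(list(cdsA = b1, cdsB = b2), human)
  # chromosome 1 block first, widths 6 then 4
  expect_equal(sm$spans$human_cds_id, c("cdsB", "cdsA"))
  expect_equal(sm$spans$start, c(1L, 7L))
  expect_equal(sm$spans$end, c(6L, 10L))
  expect_equal(ncol(sm$aln), 10)
  # round trip: extracting a span reproduces the block
  expect_equal(supermatrix_block(sm, "cdsA"), unclass(b1)[study_species(), ],
               ignore_attr = TRUE)
  # single block: supermatrix identical to the block
  sm1 <- concatenate_blocks(list(cdsA = b1), human[1, ])
  expect_equal(unname(sm1$aln), unname(unclass(b1)[study_species(), ]))
  # missing species errors
  b_bad <- b1[-2, ]
  class(b_bad) <- class(b1)
  expect_error(concatenate_blocks(list(cdsA = b_bad), human), "missing species")
})

test_that("distances follow pairwise deletion and the Jukes-Cantor transform", {
  m <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
             b = strsplit("AAAAAAATTT", "")[[1]])
  d <- seq_distances(m, model = "p")
  expect_equal(d["a", "b"], 0.3)
  expect_equal(unname(diag(d)), c(0, 0))
  djc <- seq_distances(m, model = "JC")
  expect_equal(djc["a", "b"], -0.75 * log(1 - 0.4), tolerance = 1e-9)
  expect_equal(djc["a", "b"], 0.383119, tolerance = 1e-6)
  # identical rows -> 0; gapped sites ignored per pair
  g <- rbind(a = strsplit("AA-AA", "")[[1]],
             b = strsplit("AATAA", "")[[1]],
             c = strsplit("AATAA", "")[[1]])
  dg <- seq_distances(g, model = "p")
  expect_equal(dg["a", "b"], 0) # the mismatch column is gapped in a
  expect_equal(dg["b", "c"], 0)
  expect_true(isSymmetric(unclass(dg)))
  # saturation errors under JC
  s <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("TTTT", "")[[1]])
  expect_error(seq_distances(s, model = "JC"), "0.75")
})

test_that("supermatrix distances equal block-weighted pairwise accounting", {
  sim <- tiny_sim(n_cds = 6, seed = 83)
  blocks <- blocks_from_truth(sim)
  human <- dplyr::filter(sim$cds, species == "human")
  sm <- concatenate_blocks(blocks, human)
  d_all <- seq_distances(sm, model = "p")
  # oracle: accumulate mismatches and valid sites per block
  mm <- 0; vv <- 0
  for (id in names(blocks)) {
    b <- blocks[[id]]
    hum <- b["human", ]; rat <- b["rat", ]
    ok <- hum != "-" & rat != "-"
    mm <- mm + sum(hum[ok] != rat[ok])
    vv <- vv + sum(ok)
  }
  expect_equal(d_all["human", "rat"], mm / vv)
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand additive matrix from ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(rf_distance(tr, ref), 0)
  # additivity: path lengths reproduce the input distances
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)

  # 10 random additive matrices, up to 8 taxa
  set.seed(87)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(x) runif(x, 0.1, 1))
    gen <- ape::unroot(gen)
    D2 <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(D2)
    expect_equal(rf_distance(rec, gen), 0, info = paste("matrix", k))
    expect_equal(ape::cophenetic.phylo(rec)[rownames(D2), colnames(D2)], D2,
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(D[1:2, 1:2]))
})

test_that("our NJ agrees with ape::nj as an independent implementation", {
  set.seed(89)
  for (k in 1:5) {
    n <- sample(5:8, 1)
    D <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    ours <- nj_tree(D)
    theirs <- ape::nj(as.dist(D))
    expect_equal(rf_distance(ours, theirs), 0)
  }
})

test_that("Robinson-Foulds matches independent bipartition computations", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
  skip_if_not_installed("phangorn")
  set.seed(91)
  for (k in 1:8) {
    n <- sample(5:8, 1)
    a <- ape::rtree(n) # rtree labels tips t1..tn, so leaf sets agree
    b <- ape::rtree(n)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
})

test_that("synteny maps order source chromosomes and flag intact ones", {
  ids <- sprintf("human_cds%04d", 1:8)
  # human chr 7; mouse sources: chrA x3 on cds 1-3... build cds table directly
  cds <- dplyr::bind_rows(
    tibble::tibble(species = "human", cds_id = ids, chromosome = "7"),
    purrr::map_dfr(model_species(), function(sp) {
      tibble::tibble(species = sp, cds_id = paste0(sp, "_", ids),
                     chromosome = if (sp == "mouse") {
                       c("5", "5", "5", "11", rep("5", 4))
                     } else "2")
    })
  )
  tables <- lapply(setNames(nm = model_species()), function(sp)
    fake_hits(ids) |> dplyr::mutate(query = paste0(sp, "_", ids)))
  cs <- build_conserved_set(tables, ids)
  sm <- synteny_map(cs, cds)
  mouse <- sm[sm$species == "mouse", ]
  expect_equal(mouse$sources[[1]], c("5", "11")) # descending count order
  expect_false(mouse$intact)
  expect_true(all(sm$intact[sm$species != "mouse"]))
  expect_equal(unique(sm$n_conserved), 8)
})

test_that("synteny ordering equals a brute-force count-and-sort oracle", {
  set.seed(93)
  sim <- tiny_sim(n_cds = 30, seed = 17)
  cs <- conserve_sim(sim)
  sm <- synteny_map(cs, sim$cds)
  chrom_of <- setNames(sim$cds$chromosome, sim$cds$cds_id)
  keep <- cs[cs$conserved, ]
  for (r in sample(nrow(sm), 10)) {
    hc <- sm$human_chromosome[r]; sp <- sm$species[r]
    rows <- keep[chrom_of[keep$human_cds_id] == hc, ]
    tab <- table(chrom_of[unlist(rows[[paste0(sp, "_cds")]])])
    ord <- names(tab)[order(-tab, orthosnp:::species_chrom_rank(names(tab)))]
    expect_equal(sm$sources[[r]], ord)
    expect_equal(sm$intact[r], length(tab) == 1)
  }
})
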