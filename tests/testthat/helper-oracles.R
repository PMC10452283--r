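# Independent oracles and fixture builders, deliberately written with
# different algorithms/data structures than the package implementation.

# Exhaustive Smith-Waterman (Gotoh) best score, pure R matrix DP.
# Same gap convention as the package: a gap of length L costs go + L * ge.
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            go = -5, ge = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# mutate a sequence with point substitutions at rate p
mutate_dna <- function(s, p) {
  x <- strsplit(s, "")[[1]]
  hit <- runif(length(x)) < p
  x[hit] <- vapply(x[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                              1), character(1))
  paste(x, collapse = "")
}

# brute-force membership-pattern counts: loop over every id and every one of
# the 2^k patterns
pattern_counts_oracle <- function(sets, ids) {
  k <- length(sets)
  pats <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE], 1,
                paste, collapse = "")
  counts <- setNames(integer(length(pats)), pats)
  for (id in ids) {
    p <- paste(vapply(sets, function(s) as.integer(id %in% s), integer(1)),
               collapse = "")
    counts[p] <- counts[p] + 1L
  }
  counts[counts > 0]
}

# a synthetic hit tibble for one species over given subject ids
fake_hits <- function(subjects, pident = NULL, coverage = NULL) {
  n <- length(subjects)
  tibble::tibble(
    query = paste0("q_", subjects),
    subject = subjects,
    pident = pident %||% rep(90, n),
    length = rep(100L, n),
    coverage = coverage %||% rep(0.9, n),
    score = seq(100, 100 + n - 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a hand-built six-row MSA block
block_from_rows <- function(rows, id = "human_cds0001") {
  msa_block(rows, human_cds_id = id)
}

# all six taxa with the same aligned row except named overrides
six_rows <- function(base, ...) {
  over <- list(...)
  rows <- setNames(rep(base, 6), study_species())
  for (nm in names(over)) rows[nm] <- over[[nm]]
  rows
}

# small simulated dataset shared across tests (indel-free, fast)
tiny_sim <- function(n_cds = 12, n_snps = 60, n_diseases = 15, seed = 42,
                     tree = default_species_tree(), ...) {
  simulate_orthologs(
    sim_config(n_cds = n_cds, cds_length_range = c(300L, 600L),
               n_snps = n_snps, n_diseases = n_diseases, seed = seed, ...),
    tree
  )
}

# conservation stage on a simulation, small and exact (no prescreen)
conserve_sim <- function(sim, max_candidates = Inf) {
  human <- dplyr::filter(sim$cds, species == "human")
  tables <- lapply(setNames(nm = model_species()), function(sp) {
    filter_hits(best_hits(dplyr::filter(sim$cds, species == sp), human,
                          max_candidates = max_candidates))
  })
  build_conserved_set(tables, human$cds_id)
}

# indel-free groups align trivially: build blocks straight from the truth
# pairings (rows validated by msa_block)
blocks_from_truth <- function(sim) {
  seq_of <- setNames(sim$cds$sequence, sim$cds$cds_id)
  human_ids <- unique(sim$orthologs$human_cds_id)
  blocks <- lapply(human_ids, function(hid) {
    o <- sim$orthologs[sim$orthologs$human_cds_id == hid, ]
    rows <- c(seq_of[hid], setNames(seq_of[o$species_cds_id], o$species))
    names(rows)[1] <- "human"
    msa_block(rows, human_cds_id = hid)
  })
  setNames(blocks, human_ids)
}

# per-species disease records from named sets of disease names
records_fixture <- function(sets) {
  purrr::imap_dfr(sets, function(ds, sp) {
    if (!length(ds)) return(NULL)
    tibble::tibble(species = sp, rsid = paste0("rs_", ds), disease = ds,
                   category = "Cancer", gene = paste0("G_", ds))
  })
}
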