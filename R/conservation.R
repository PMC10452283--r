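default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_ext = -2)
}

as_seq_vector <- function(x, what = "sequences") {
  if (is.data.frame(x)) {
    stopifnot(all(c("cds_id", "sequence") %in% names(x)))
    stats::setNames(x$sequence, x$cds_id)
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop(what, " must be a tibble with cds_id/sequence or a named character ",
         "vector", call. = FALSE)
  }
}

# unique k-mer sets per sequence, for the optional candidate prescreen
kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Best-hit local alignment of query CDSs against the human CDS set
#'
#' For each query, computes an affine-gap Smith-Waterman local alignment
#' against every human CDS, keeps exactly one highest-scoring local alignment
#' (HSP) per subject, and returns the single best subject per query --
#' blastn-style `-max_hsps 1 -max_target_seqs 1` semantics. Ties are broken
#' deterministically: higher score, then higher percent identity, then
#' lexicographically smallest subject id. Percent identity is
#' `100 * identities / alignment columns` (gap columns included); coverage is
#' the aligned span on the human (subject) CDS divided by its full length.
#'
#' @param queries Non-human CDSs: tibble with `cds_id` and `sequence`
#'   columns, or a named character vector.
#' @param subjects Human CDSs, same formats.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (a gap of length L costs `gap_open + L * gap_ext`). Defaults
#'   +1/-2/-5/-2.
#' @param max_candidates If finite, each query is aligned only against the
#'   `max_candidates` subjects sharing the most 8-mers with it (a word-hash
#'   prescreen for speed); `Inf` (default) aligns against every subject.
#' @return Tibble, one row per query with at least one scoring alignment:
#'   `query`, `subject`, `pident`, `length` (alignment columns), `coverage`,
#'   `score`.
#' @examples
#' best_hits(c(q1 = "ACGAACGT"), c(h1 = "ACGTACGT"))
#' @export
best_hits <- function(queries, subjects, scoring = default_scoring(),
                      max_candidates = Inf) {
  q <- as_seq_vector(queries, "queries")
  s <- as_seq_vector(subjects, "subjects")
  if (length(q) == 0 || length(s) == 0) {
    stop("queries and subjects must be non-empty", call. = FALSE)
  }
  if (any(nchar(q) == 0) || any(nchar(s) == 0)) {
    stop("empty sequence in input", call. = FALSE)
  }
  s_ord <- s[order(names(s))] # lexicographic subject order fixes tie-breaks
  screen <- is.finite(max_candidates) && max_candidates < length(s_ord)
  if (screen) subj_kmers <- kmer_sets(s_ord, k = 8L)

  rows <- purrr::map(seq_along(q), function(i) {
    cand <- seq_along(s_ord)
    if (screen) {
      qk <- unique(substring(q[i], 1:(nchar(q[i]) - 7L), 8:nchar(q[i])))
      shared <- vapply(subj_kmers, function(ks) sum(ks %in% qk), numeric(1))
      cand <- order(shared, decreasing = TRUE)[seq_len(max_candidates)]
      cand <- sort(cand) # keep lexicographic order for tie-breaks
    }
    best <- NULL
    for (j in cand) {
      a <- sw_affine_cpp(q[[i]], s_ord[[j]], scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext)
      if (a$score <= 0) next
      pid <- 100 * a$n_ident / a$aln_len
      if (is.null(best) || a$score > best$score ||
          (a$score == best$score && pid > best$pident)) {
        best <- list(subject = names(s_ord)[j], score = a$score, pident = pid,
                     length = a$aln_len,
                     coverage = (a$s_end - a$s_start + 1) / nchar(s_ord[[j]]))
      }
    }
    if (is.null(best)) return(NULL)
    tibble::tibble(query = names(q)[i], subject = best$subject,
                   pident = best$pident, length = best$length,
                   coverage = best$coverage, score = best$score)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(query = character(), subject = character(),
                          pident = double(), length = integer(),
                          coverage = double(), score = double())
  }
  out
}

#' Single-query convenience wrapper around [best_hits()]
#'
#' @param query A single unnamed CDS string.
#' @inheritParams best_hits
#' @return One-row hit tibble, or a zero-row tibble if nothing aligns.
#' @export
best_hit <- function(query, subjects, scoring = default_scoring(),
                     max_candidates = Inf) {
  best_hits(c(query_1 = unname(query)), subjects, scoring, max_candidates)
}

#' Apply the conservation filters to a hit table
#'
#' A hit is retained iff it shares at least `min_identity` percent identity
#' with the human CDS and covers at least `min_coverage` of the human CDS
#' length. Both bounds are inclusive ("at least 50%"), so hits at exactly
#' 50.0 / 0.5 pass.
#'
#' @param hits Hit tibble from [best_hits()].
#' @param min_identity Percent identity threshold in \[0, 100\] (default 50).
#' @param min_coverage Coverage threshold in \[0, 1\] (default 0.5).
#' @return The retained rows, same columns.
#' @export
filter_hits <- function(hits, min_identity = 50, min_coverage = 0.5) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1)
  dplyr::filter(hits, .data$pident >= min_identity,
                .data$coverage >= min_coverage)
}

#' Five-way conserved CDS set and intersection pattern counts
#'
#' Combines one filtered hit table per model species into a per-human-CDS
#' membership pattern (upset-style). A human CDS is conserved iff it has a
#' retained best hit in all five comparisons.
#'
#' @param hit_tables Named list of filtered hit tibbles, one per model
#'   species (names must be species names).
#' @param human_ids Character vector of all human CDS ids.
#' @return A tibble of class `"conserved_set"`: `human_cds_id`, one logical
#'   membership column and one `<species>_cds` ortholog-id column per
#'   species, `pattern` (e.g. `"11011"`, columns in `names(hit_tables)`
#'   order), and `conserved`.
#' @export
build_conserved_set <- function(hit_tables, human_ids) {
  stopifnot(is.list(hit_tables), !is.null(names(hit_tables)),
            length(human_ids) > 0)
  species <- names(hit_tables)
  out <- tibble::tibble(human_cds_id = human_ids)
  for (sp in species) {
    h <- hit_tables[[sp]]
    bad <- setdiff(h$subject, human_ids)
    if (length(bad)) {
      stop("hit table for ", sp, " references unknown human CDS id(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    # a subject can be hit by several queries; keep the best-scoring one
    h <- h |>
      dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$pident),
                     .data$query) |>
      dplyr::distinct(.data$subject, .keep_all = TRUE)
    out[[sp]] <- out$human_cds_id %in% h$subject
    out[[paste0(sp, "_cds")]] <- h$query[match(out$human_cds_id, h$subject)]
  }
  flags <- as.matrix(out[species])
  out$pattern <- apply(flags, 1, function(f) paste(as.integer(f), collapse = ""))
  out$conserved <- rowSums(flags) == length(species)
  class(out) <- c("conserved_set", class(out))
  out
}

#' Upset-style intersection counts of a conserved set
#'
#' @param cs A [build_conserved_set()] result.
#' @param drop_empty Drop the all-absent pattern (default TRUE).
#' @return Tibble `pattern`, `n`, sorted by decreasing count.
#' @export
intersection_counts <- function(cs, drop_empty = TRUE) {
  out <- cs |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pattern)
  if (drop_empty) {
    empty <- strrep("0", nchar(out$pattern[1] %||% ""))
    out <- dplyr::filter(out, .data$pattern != empty)
  }
  out
}

#' Per-species percent-identity summaries
#'
#' Mean, median (midpoint convention), min and max percent identity per
#' species, over all retained hits and over the conserved subset.
#'
#' @param hits Tibble with `species`, `subject`, `pident` columns (filtered
#'   hits from all five comparisons bound together).
#' @param conserved_ids Optional character vector of conserved human CDS ids;
#'   if supplied, a second set of rows restricted to those subjects is added.
#' @return Tibble: `species`, `subset` ("all" or "conserved"), `n`, `mean`,
#'   `median`, `min`, `max`.
#' @export
identity_stats <- function(hits, conserved_ids = NULL) {
  if (nrow(hits) == 0) stop("no hits to summarise", call. = FALSE)
  summarise_one <- function(d, label) {
    d |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        subset = label, n = dplyr::n(), mean = mean(.data$pident),
        median = median(.data$pident), min = min(.data$pident),
        max = max(.data$pident), .groups = "drop"
      )
  }
  out <- summarise_one(hits, "all")
  if (!is.null(conserved_ids)) {
    out <- dplyr::bind_rows(
      out,
      summarise_one(dplyr::filter(hits, .data$subject %in% conserved_ids),
                    "conserved")
    )
  }
  out
}

#' One-way ANOVA with Bonferroni pairwise comparisons on identity values
#'
#' Classical one-way ANOVA of percent identity across species, followed by
#' all pairwise two-sample Welch t-tests with Bonferroni correction
#' (raw p multiplied by the number of pairs, capped at 1). The degenerate
#' all-identical case (zero variance everywhere, equal means) reports F = 0
#' with p = 1.
#'
#' @param groups Named list of numeric vectors (one per species), or a tibble
#'   with `species` and `pident` columns.
#' @return Object of class `"identity_anova"` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
compare_identity_groups <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$pident, groups$species)
  }
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))

  if (var(values) == 0) {
    f <- 0; p <- 1; df <- c(length(groups) - 1L, length(values) - length(groups))
  } else {
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    f <- s$`F value`[1]; p <- s$`Pr(>F)`[1]; df <- s$Df
  }

  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    a <- groups[[pairs[1, k]]]; b <- groups[[pairs[2, k]]]
    raw <- if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
    tibble::tibble(group1 = pairs[1, k], group2 = pairs[2, k],
                   mean_diff = mean(a) - mean(b), p_raw = raw,
                   p_bonferroni = min(1, raw * n_pairs))
  })

  structure(
    list(f_statistic = f, p_value = p, df = df[1:2],
         n_groups = length(groups), n = length(values), pairwise = pairwise),
    class = "identity_anova"
  )
}

#' @export
print.identity_anova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$f_statistic, digits = 5), ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  cat("Bonferroni pairwise comparisons (", nrow(x$pairwise), " pairs):\n",
      sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Tidy and glance methods for identity ANOVA fits
#'
#' `tidy()` returns the Bonferroni-adjusted pairwise comparison table;
#' `glance()` a one-row model summary.
#'
#' @param x An `"identity_anova"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.identity_anova <- function(x, ...) x$pairwise

#' @rdname tidy.identity_anova
#' @export
glance.identity_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df[1], df.residual = x$df[2],
                 n_groups = x$n_groups, nobs = x$n)
}
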