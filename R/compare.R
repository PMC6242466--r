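#' A compiled external gene-score dataset
#'
#' @param scores Named numeric vector, one score per gene.
#' @param category Study category the scores were compiled from.
#' @param ranking Optional explicit gene ranking; default ranks by absolute
#'   score, descending, ties broken by gene id.
#' @return List of class `ranked_dataset` with `scores`, `category`,
#'   `ranking`.
#' @export
ranked_dataset <- function(scores, category = "generic", ranking = NULL) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  if (is.null(ranking)) {
    ord <- order(-abs(scores), names(scores))
    ranking <- names(scores)[ord]
  } else if (!setequal(ranking, names(scores))) {
    stop("ranking must be a permutation of the gene set")
  }
  structure(list(scores = scores, category = category, ranking = ranking),
            class = "ranked_dataset")
}

#' Compile heterogeneous per-gene source records into one score per gene
#'
#' Category rules:
#' * `deletion_fitness`: per-source calls in \{-1, 0, +1\} (+1 increased
#'   resistance, -1 increased sensitivity) are summed across sources.
#' * `mrna`: the mean change across the sources in which a gene appears.
#' * `protein_abundance`: each source is divided by its own standard
#'   deviation, then values are summed across sources.
#' * `flux`: records are per-compartment/timepoint top Z-score lists; a
#'   gene's score is the sum of the absolute Z-scores of every list it
#'   appears in; genes of the `universe` absent from all lists score 0.
#' * `phospho`: sources flagged `qualitative` contribute their -1/+1 calls
#'   as-is; quantitative sources are SD-normalized first; everything is
#'   summed.
#'
#' @param records Data frame with columns `gene_id`, `value`, and (where the
#'   category needs them) `source_id`, `source_type`, `compartment`,
#'   `timepoint`.
#' @param category One of the five category names above.
#' @param universe For `flux`: the full gene library; absentees score 0.
#' @return A [ranked_dataset()].
#' @export
compile_dataset <- function(records, category, universe = NULL) {
  if (!category %in% c("deletion_fitness", "mrna", "protein_abundance",
                       "flux", "phospho"))
    stop("unknown category: ", category)
  stopifnot(all(c("gene_id", "value") %in% names(records)))
  if (category == "flux" && any(is.na(records$value)))
    stop("flux records missing Z-scores")

  src <- if ("source_id" %in% names(records)) records$source_id else
    rep("s1", nrow(records))

  scores <- switch(category,
    deletion_fitness = tapply(records$value, records$gene_id, sum),
    mrna = tapply(records$value, records$gene_id, mean),
    protein_abundance = {
      sds <- tapply(records$value, src, stats::sd)
      v <- records$value / sds[src]
      tapply(v, records$gene_id, sum)
    },
    flux = {
      s <- tapply(abs(records$value), records$gene_id, sum)
      if (!is.null(universe)) {
        full <- stats::setNames(numeric(length(universe)), universe)
        full[names(s)] <- s
        full
      } else s
    },
    phospho = {
      qual <- if ("source_type" %in% names(records))
        records$source_type == "qualitative" else rep(FALSE, nrow(records))
      v <- records$value
      if (any(!qual)) {
        sds <- tapply(records$value[!qual], src[!qual], stats::sd)
        v[!qual] <- records$value[!qual] / sds[src[!qual]]
      }
      tapply(v, records$gene_id, sum)
    })
  scores <- stats::setNames(as.numeric(scores), names(scores))
  ranked_dataset(scores, category)
}

#' Rank screen test results for cross-dataset comparison
#'
#' Collapses per-day test results to one row per strain (the day with the
#' smallest adjusted p-value) and ranks by p-value ascending — ranking by
#' p-value rather than colony-size difference damps the noise of small
#' colonies — with ties broken by `|delta|` descending, then strain id. In
#' `signed` mode the ranking runs from the lowest-p decreased-signal strain
#' through non-significant strains to the lowest-p increased-signal strain.
#'
#' @param day_results Stacked results from [test_screen()].
#' @param mode `"pvalue"` (default) or `"signed"`.
#' @return A [ranked_dataset()] whose scores are `-log10(p_adj)` (signed by
#'   direction in `signed` mode).
#' @export
rank_screen_results <- function(day_results, mode = c("pvalue", "signed")) {
  mode <- match.arg(mode)
  dr <- day_results[!is.na(day_results$p_adj), ]
  best <- dr[order(dr$strain_id, dr$p_adj, -abs(dr$delta)), ]
  best <- best[!duplicated(best$strain_id), ]
  p <- pmax(best$p_adj, 1e-300)
  if (mode == "pvalue") {
    ord <- order(best$p_adj, -abs(best$delta), best$strain_id)
    scores <- stats::setNames(-log10(p), best$strain_id)
  } else {
    key <- ifelse(best$delta < 0, best$p_adj, 2 - best$p_adj)
    ord <- order(key, -abs(best$delta), best$strain_id)
    scores <- stats::setNames(sign(best$delta) * -log10(p), best$strain_id)
  }
  ranked_dataset(scores, category = paste0("screen_", mode),
                 ranking = best$strain_id[ord])
}

#' Hypergeometric significance of top-fraction overlap between two rankings
#'
#' For each fraction of the grid, takes the top fraction of both rankings
#' (restricted to the shared universe; size = `floor(f * universe)`, at
#' least 1) and computes the one-sided over-representation p-value of their
#' intersection under the hypergeometric null. The minimum over the grid is
#' reported uncorrected, as is conventional for this scan; a Bonferroni-
#' corrected copy is emitted alongside.
#'
#' @param dsA,dsB [ranked_dataset()] objects.
#' @param fractions Top-fraction grid.
#' @return List of class `overlap_result`: `grid` (fraction, size_a, size_b,
#'   overlap, p), `min_p`, `neg_log10_min_p`, `min_p_corrected`,
#'   `universe_size`.
#' @export
overlap_significance <- function(dsA, dsB,
                                 fractions = c(0.01, 0.05, 0.10,
                                               0.15, 0.20, 0.25)) {
  uni <- intersect(dsA$ranking, dsB$ranking)
  N <- length(uni)
  if (N == 0) stop("empty shared universe")
  if (N < 20) warning("shared universe smaller than 20 genes")
  ra <- dsA$ranking[dsA$ranking %in% uni]
  rb <- dsB$ranking[dsB$ranking %in% uni]
  grid <- lapply(fractions, function(f) {
    k <- max(1L, floor(f * N))
    top_a <- ra[seq_len(k)]
    top_b <- rb[seq_len(k)]
    ov <- length(intersect(top_a, top_b))
    p <- stats::phyper(ov - 1, length(top_a), N - length(top_a),
                       length(top_b), lower.tail = FALSE)
    data.frame(fraction = f, size_a = length(top_a), size_b = length(top_b),
               overlap = ov, p = p)
  })
  grid <- do.call(rbind, grid)
  min_p <- min(grid$p)
  structure(list(grid = grid, min_p = min_p,
                 neg_log10_min_p = -log10(min_p),
                 min_p_corrected = min(1, min_p * nrow(grid)),
                 universe_size = N),
            class = "overlap_result")
}

#' Running overlap of an external top set along a ranking
#'
#' Walks down a ranking and smooths the binary is-in-the-external-top-set
#' indicator with a degree-1 local regression, giving the local overlap
#' fraction at each rank position (an enrichment-by-rank curve).
#'
#' @param ranking Character vector, the ranked universe.
#' @param external_top Gene set (subset of `ranking`).
#' @param span Smoothing span as a fraction of the ranking length.
#' @return Data frame with `rank`, `member` (0/1) and `fraction` (smoothed,
#'   clamped to `[0, 1]`).
#' @export
running_overlap_curve <- function(ranking, external_top, span = 0.3) {
  if (length(external_top) == 0) stop("empty external top set")
  if (!all(external_top %in% ranking))
    stop("external_top must be contained in the ranking")
  member <- as.integer(ranking %in% external_top)
  n <- length(member)
  sm <- stats::lowess(seq_len(n), member, f = span, iter = 0)
  data.frame(rank = seq_len(n), member = member,
             fraction = pmin(1, pmax(0, sm$y)))
}

#' Pairwise -log10 minimum overlap p matrix of several datasets
#'
#' @param datasets Named list of [ranked_dataset()] objects.
#' @param fractions Passed to [overlap_significance()].
#' @return Symmetric numeric matrix of `-log10(min_p)` values (diagonal
#'   `NA`).
#' @export
overlap_matrix <- function(datasets,
                           fractions = c(0.01, 0.05, 0.10, 0.15, 0.20,
                                         0.25)) {
  n <- length(datasets)
  m <- matrix(NA_real_, n, n,
              dimnames = list(names(datasets), names(datasets)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- overlap_significance(datasets[[i]], datasets[[j]], fractions)
      m[i, j] <- m[j, i] <- r$neg_log10_min_p
    }
  }
  m
}
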