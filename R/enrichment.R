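#' A rooted ontology DAG with gene annotations
#'
#' Validates acyclicity, propagates annotations from children to ancestors
#' (so every child's gene set is a subset of each parent's), and records a
#' deterministic bottom-up testing order (every term after all of its
#' descendants, ties between siblings broken by term id).
#'
#' @param edges Data frame with columns `child`, `parent`.
#' @param annotations Data frame with columns `term_id`, `gene_id` (direct
#'   annotations; propagation is performed here).
#' @return List of class `ontology_dag`: `edges`, `annotations`
#'   (propagated), `term_genes` (named list of gene sets), `order`
#'   (bottom-up term order), `terms`, `genes`, `root` (terms without
#'   parents).
#' @export
ontology_dag <- function(edges, annotations) {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("term_id", "gene_id") %in% names(annotations)))
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term_id)))
  ord <- topological_order(edges, terms)
  parents_of <- split(edges$parent, edges$child)
  term_genes <- lapply(split(annotations$gene_id, annotations$term_id),
                       unique)
  term_genes <- term_genes[intersect(terms, names(term_genes))]
  for (tm in ord) {   # bottom-up: children processed before parents
    g <- term_genes[[tm]]
    if (is.null(g)) next
    for (pa in parents_of[[tm]])
      term_genes[[pa]] <- union(term_genes[[pa]], g)
  }
  term_genes <- term_genes[order(names(term_genes))]
  ann <- data.frame(
    term_id = rep(names(term_genes), lengths(term_genes)),
    gene_id = unlist(term_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, annotations = ann, term_genes = term_genes,
                 order = ord, terms = terms,
                 genes = sort(unique(annotations$gene_id)),
                 root = setdiff(terms, edges$child)),
            class = "ontology_dag")
}

# Kahn's algorithm on child -> parent edges; children come out first.
# Ties (terms simultaneously available) resolved lexicographically.
topological_order <- function(edges, terms) {
  remaining <- lapply(split(edges$parent, edges$child), unique)
  children_of <- lapply(split(edges$child, edges$parent), unique)
  n_desc <- vapply(terms, function(tm) {
    ch <- children_of[[tm]]
    if (is.null(ch)) 0L else length(ch)
  }, 0L)
  pending <- stats::setNames(n_desc, terms)
  out <- character(0)
  avail <- sort(names(pending)[pending == 0L])
  pending <- pending[pending > 0L]
  while (length(avail) > 0) {
    tm <- avail[1]
    avail <- avail[-1]
    out <- c(out, tm)
    for (pa in remaining[[tm]]) {
      pending[pa] <- pending[pa] - 1L
      if (pending[pa] == 0L) {
        avail <- sort(c(avail, pa))
        pending <- pending[names(pending) != pa]
      }
    }
  }
  if (length(out) != length(terms)) stop("cyclic ontology graph")
  out
}

ancestors_of <- function(dag) {
  parents_of <- lapply(split(dag$edges$parent, dag$edges$child), unique)
  anc <- stats::setNames(rep(list(character(0)), length(dag$terms)),
                         dag$terms)
  # top-down (reverse of the bottom-up order), so parents are done first
  for (tm in rev(dag$order)) {
    pa <- parents_of[[tm]]
    if (!is.null(pa))
      anc[[tm]] <- unique(c(pa, unlist(anc[pa], use.names = FALSE)))
  }
  anc
}

#' One-sided hypergeometric over-representation p-value
#'
#' `P(X >= |hits n target|)` for the overlap of two gene sets drawn from a
#' finite universe.
#'
#' @param hits,target Gene sets (subsets of `universe`).
#' @param universe The finite universe.
#' @return The one-sided p-value.
#' @export
hypergeom_overrep <- function(hits, target, universe) {
  hits <- unique(hits); target <- unique(target)
  if (!all(hits %in% universe) || !all(target %in% universe))
    stop("hits and target must be contained in the universe")
  k <- length(intersect(hits, target))
  stats::phyper(k - 1, length(target), length(universe) - length(target),
                length(hits), lower.tail = FALSE)
}

#' Conditional (DAG-aware) gene-set enrichment
#'
#' Tests terms bottom-up. When a term comes out significant (raw p below
#' `alpha`), its currently annotated genes are removed from the annotations
#' of all of its ancestors before those are tested, so parents must earn
#' significance from genes their significant children do not explain. The
#' global universe is left untouched. An unconditioned flat ontology
#' therefore reduces to independent per-term hypergeometric tests.
#'
#' @param hits Gene set of interest (subset of `universe`).
#' @param universe Finite gene universe (typically all strains tested).
#' @param dag An [ontology_dag()].
#' @param alpha Raw-p significance cutoff for a term (and for triggering
#'   conditioning).
#' @return Data frame, one row per term in testing order: term_id,
#'   size_annotated (conditioned size), overlap, p, p_adj (BH across
#'   terms, informational), enriched; attribute `term_genes` holds the
#'   conditioned gene sets of enriched terms.
#' @export
conditional_enrichment <- function(hits, universe, dag, alpha = 0.05) {
  stopifnot(inherits(dag, "ontology_dag"))
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hits must be contained in the universe")
  term_genes <- lapply(dag$term_genes, function(g) intersect(g, universe))
  anc <- ancestors_of(dag)
  rows <- vector("list", length(dag$order))
  enriched_sets <- list()
  for (i in seq_along(dag$order)) {
    tm <- dag$order[i]
    g <- term_genes[[tm]]
    k <- length(intersect(hits, g))
    p <- if (length(g) == 0) 1 else
      stats::phyper(k - 1, length(g), length(universe) - length(g),
                    length(hits), lower.tail = FALSE)
    sig <- p < alpha
    rows[[i]] <- data.frame(term_id = tm, size_annotated = length(g),
                            overlap = k, p = p, enriched = sig,
                            stringsAsFactors = FALSE)
    if (sig) {
      enriched_sets[[tm]] <- g
      for (a in anc[[tm]])
        term_genes[[a]] <- setdiff(term_genes[[a]], g)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("term_id", "size_annotated", "overlap", "p", "p_adj",
                 "enriched")]
  attr(out, "term_genes") <- enriched_sets
  out
}

#' Jaccard-weighted enrichment-map edges
#'
#' Links every unordered pair of terms whose gene sets have a Jaccard
#' coefficient strictly above the threshold; the coefficient is the edge
#' weight. Terms with empty gene sets are dropped with a warning.
#'
#' @param term_sets Named list of gene sets (e.g. the `term_genes` attribute
#'   of [conditional_enrichment()]).
#' @param threshold Strict lower bound on the Jaccard coefficient.
#' @return Data frame with `term_a`, `term_b`, `jaccard`.
#' @export
enrichment_map <- function(term_sets, threshold = 0.25) {
  empty <- lengths(term_sets) == 0
  if (any(empty)) {
    warning("dropping terms with empty gene sets: ",
            paste(names(term_sets)[empty], collapse = ", "))
    term_sets <- term_sets[!empty]
  }
  nm <- sort(names(term_sets))
  out <- list()
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in (i + 1):length(nm)) {
        a <- term_sets[[nm[i]]]; b <- term_sets[[nm[j]]]
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac > threshold)
          out[[length(out) + 1L]] <- data.frame(term_a = nm[i],
                                                term_b = nm[j],
                                                jaccard = jac,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(term_a = character(0), term_b = character(0),
                      jaccard = numeric(0)))
  do.call(rbind, out)
}

#' Pearson chi-square test of independence
#'
#' Classic chi-square statistic against the independence expectation of a
#' 2 x k (or r x k) contingency table, without continuity correction.
#'
#' @param counts Matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Overlap of disease-associated SNP homolog sets with screen hits
#'
#' Filters SNP association records to case-control studies with association
#' p below the threshold, collapses the surviving records per disease to
#' the set of yeast homologs of the implicated human genes, and tests each
#' disease set for over-representation among the screen hits.
#'
#' @param snps Data frame with columns snp_id, disease, study_design
#'   (records equal to `"case_control"` pass), assoc_p, human_gene,
#'   yeast_homolog (the homolog mapping, supplied as a table; `NA` = no
#'   homolog).
#' @param hits Screen hit gene set.
#' @param universe Gene universe for the test.
#' @param p_threshold SNP-association p-value cutoff.
#' @return Data frame, one row per disease: disease, n_snps, n_genes,
#'   overlap, p.
#' @export
gwas_overlap <- function(snps, hits, universe, p_threshold = 1e-5) {
  need <- c("snp_id", "disease", "study_design", "assoc_p",
            "human_gene", "yeast_homolog")
  if (!all(need %in% names(snps)))
    stop("missing mapping columns: ",
         paste(setdiff(need, names(snps)), collapse = ", "))
  keep <- snps$study_design == "case_control" & snps$assoc_p < p_threshold &
    !is.na(snps$yeast_homolog)
  sub <- snps[keep, , drop = FALSE]
  diseases <- sort(unique(snps$disease))
  out <- lapply(diseases, function(d) {
    ds <- sub[sub$disease == d, , drop = FALSE]
    genes <- intersect(unique(ds$yeast_homolog), universe)
    data.frame(disease = d, n_snps = nrow(ds), n_genes = length(genes),
               overlap = length(intersect(genes, hits)),
               p = if (length(genes) == 0) 1 else
                 hypergeom_overrep(hits, genes, universe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
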