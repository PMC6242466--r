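#' Parameters for a simulated colony-array screen
#'
#' Bundles the generative parameters for [simulate_screen()]. Defaults emulate
#' the scale of a genome-wide homodimerization (hdPCA) screen: 3,504 strains
#' pinned in 1,536 format across three plates, four replicate plate sets per
#' condition, photographed on nine days.
#'
#' The drug condition adds three layers on the log2 density scale:
#' a smooth monotone basal penalty that hits small colonies hardest
#' (what cyclic LOESS is meant to remove), an additive technical shift per
#' replicate plate set (what quantile normalization is meant to remove), and
#' a sparse set of spiked true effects (what the regularized t-test is meant
#' to recover).
#'
#' @param n_strains Number of strains in the screen.
#' @param n_replicates Replicate plate sets per condition.
#' @param days Integer imaging days.
#' @param plate_format Colonies per plate, 384 or 1536.
#' @param spike_fraction Fraction of strains given a true drug effect.
#' @param effect_size_log2 Magnitude of each spiked effect (log2 units).
#' @param noise_sd_log2 SD of strain-level replicate noise (log2 units).
#' @param plate_effect_sd SD of the additive technical shift drawn once per
#'   replicate plate set and condition (log2 units).
#' @param basal_drug_curve Named vector `c(max_penalty, midpoint, steepness)`
#'   for the logistic basal penalty
#'   `-max_penalty / (1 + exp(steepness * (b - midpoint)))` applied to a
#'   strain with baseline log2 density `b`; monotone increasing in `b`, so
#'   small colonies suffer more. `max_penalty = 0` switches it off.
#' @param baseline_mean_log2,baseline_sd_log2 Distribution of per-strain
#'   baseline log2 integrated density.
#' @param growth_max_log2,growth_halftime Saturating day-growth curve: log2
#'   density gained by day `d` is `growth_max_log2 * d / (d + growth_halftime)`.
#' @param effect_days Days on which spiked effects apply (`NULL` = all days).
#' @param seed Integer seed; fixes every draw.
#' @return A list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_strains = 3504L,
                              n_replicates = 4L,
                              days = c(1:5, 7L, 10L, 12L, 14L),
                              plate_format = 1536L,
                              spike_fraction = 0.05,
                              effect_size_log2 = 0.5,
                              noise_sd_log2 = 0.15,
                              plate_effect_sd = 0.2,
                              basal_drug_curve = c(max_penalty = 0.6,
                                                   midpoint = 10,
                                                   steepness = 1),
                              baseline_mean_log2 = 10,
                              baseline_sd_log2 = 1,
                              growth_max_log2 = 3,
                              growth_halftime = 3,
                              effect_days = NULL,
                              seed = 1L) {
  if (!plate_format %in% c(384L, 1536L))
    stop("plate_format must be 384 or 1536")
  if (n_strains < 1L) stop("n_strains must be positive")
  if (n_replicates < 2L) stop("n_replicates must be at least 2")
  if (length(days) < 1L || any(days <= 0) || anyDuplicated(days))
    stop("days must be distinct positive integers")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must lie in [0, 1]")
  if (noise_sd_log2 < 0 || plate_effect_sd < 0 || baseline_sd_log2 < 0)
    stop("standard deviations must be non-negative")
  curve <- basal_drug_curve
  if (!all(c("max_penalty", "midpoint", "steepness") %in% names(curve)))
    stop("basal_drug_curve needs max_penalty, midpoint, steepness")
  if (!is.null(effect_days) && !all(effect_days %in% days))
    stop("effect_days must be a subset of days")
  structure(list(n_strains = as.integer(n_strains),
                 n_replicates = as.integer(n_replicates),
                 days = as.integer(sort(days)),
                 plate_format = as.integer(plate_format),
                 spike_fraction = spike_fraction,
                 effect_size_log2 = effect_size_log2,
                 noise_sd_log2 = noise_sd_log2,
                 plate_effect_sd = plate_effect_sd,
                 basal_drug_curve = curve,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 growth_max_log2 = growth_max_log2,
                 growth_halftime = growth_halftime,
                 effect_days = effect_days,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

basal_penalty <- function(baseline_log2, curve) {
  -curve[["max_penalty"]] /
    (1 + exp(curve[["steepness"]] * (baseline_log2 - curve[["midpoint"]])))
}

#' Simulate a colony-array screen with known ground truth
#'
#' Draws per-strain baselines, spikes a sparse set of signed drug effects,
#' and emits one integrated-density value per strain x condition x replicate
#' x day, with plate-level shifts, a colony-size-dependent basal drug
#' penalty, and heteroscedasticity-free Gaussian replicate noise, all on the
#' log2 scale and exponentiated to raw densities.
#'
#' @param params A [screen_sim_params()] object.
#' @return A list with `truth` (strain_id, baseline_log2, true_effect_log2,
#'   direction) and `table`, a raw-stage density table with columns
#'   strain_id, condition, replicate, day, plate_id, density.
#' @export
simulate_screen <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  set.seed(params$seed)
  n <- params$n_strains
  strain_id <- sprintf("S%04d", seq_len(n))

  baseline <- stats::rnorm(n, params$baseline_mean_log2, params$baseline_sd_log2)
  n_spike <- round(params$spike_fraction * n)
  effect <- numeric(n)
  if (n_spike > 0) {
    spiked <- sample.int(n, n_spike)
    effect[spiked] <- sample(c(-1, 1), n_spike, replace = TRUE) *
      params$effect_size_log2
  }
  direction <- ifelse(effect > 0, "increased",
                      ifelse(effect < 0, "decreased", "null"))
  truth <- data.frame(strain_id = strain_id,
                      baseline_log2 = baseline,
                      true_effect_log2 = effect,
                      direction = direction,
                      stringsAsFactors = FALSE)

  n_plates <- ceiling(n / params$plate_format)
  plate_of <- (seq_len(n) - 1L) %/% params$plate_format + 1L
  conditions <- c("control", "drug")
  # one technical shift per replicate plate set and condition, shared across
  # imaging days: a constant column shift of the kind quantile normalization
  # across replicates removes
  plate_shift <- matrix(stats::rnorm(2 * params$n_replicates,
                                     0, params$plate_effect_sd),
                        nrow = 2)
  basal <- basal_penalty(baseline, params$basal_drug_curve)
  eff_days <- if (is.null(params$effect_days)) params$days else params$effect_days

  blocks <- vector("list", 2L * params$n_replicates * length(params$days))
  b <- 0L
  for (ci in seq_along(conditions)) {
    for (r in seq_len(params$n_replicates)) {
      for (d in params$days) {
        growth <- params$growth_max_log2 * d / (d + params$growth_halftime)
        mu <- baseline + growth + plate_shift[ci, r]
        if (conditions[ci] == "drug") {
          mu <- mu + basal
          if (d %in% eff_days) mu <- mu + effect
        }
        val <- mu + stats::rnorm(n, 0, params$noise_sd_log2)
        b <- b + 1L
        blocks[[b]] <- data.frame(
          strain_id = strain_id,
          condition = conditions[ci],
          replicate = r,
          day = d,
          plate_id = sprintf("%s_r%d_p%d", conditions[ci], r, plate_of),
          density = 2^val,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, blocks)
  rownames(table) <- NULL
  attr(table, "stage") <- "raw"
  list(truth = truth, table = table)
}

#' Simulate an external per-gene dataset correlated with screen truth
#'
#' Emits a compiled external dataset of the kind the screen is compared
#' against, with a tunable rank correlation to the simulated ground truth.
#' Continuous categories (`mrna`, `protein_abundance`, `phospho`) mix the
#' scaled true effects with Gaussian noise; `deletion_fitness` emits signed
#' \{-1, 0, +1\} calls whose sign agrees with the truth with probability
#' `(1 + corr) / 2` and whose false-positive rate on null strains shrinks to
#' zero as `corr` approaches 1; `flux` builds per-compartment/timepoint
#' Z-score top lists and compiles them by the absolute-sum rule.
#'
#' @param truth Truth table from [simulate_screen()].
#' @param category One of `deletion_fitness`, `mrna`, `protein_abundance`,
#'   `flux`, `phospho`.
#' @param corr Correlation strength in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_compartments,n_timepoints,top_n Structure of the `flux` category.
#' @param null_call_rate Baseline nonzero-call rate on null strains for
#'   `deletion_fitness` (scaled by `1 - corr`).
#' @return A [ranked_dataset()] whose scores cover the truth's strains.
#' @export
simulate_external_dataset <- function(truth, category, corr = 0.5, seed = 1L,
                                      n_compartments = 16L, n_timepoints = 2L,
                                      top_n = 100L, null_call_rate = 0.05) {
  categories <- c("deletion_fitness", "mrna", "protein_abundance",
                  "flux", "phospho")
  if (!category %in% categories)
    stop("unknown category: ", category)
  if (corr < 0 || corr > 1) stop("corr must lie in [0, 1]")
  set.seed(seed)
  genes <- truth$strain_id
  n <- length(genes)
  eff <- truth$true_effect_log2
  scaled <- if (stats::sd(eff) > 0) as.numeric(scale(eff)) else numeric(n)

  if (category %in% c("mrna", "protein_abundance", "phospho")) {
    score <- corr * scaled + sqrt(max(0, 1 - corr^2)) * stats::rnorm(n)
    names(score) <- genes
    return(ranked_dataset(score, category))
  }

  if (category == "deletion_fitness") {
    score <- integer(n)
    nz <- eff != 0
    called <- nz & stats::runif(n) < 0.9  # most true effects are detectable
    agree <- stats::runif(n) < (1 + corr) / 2
    score[called] <- ifelse(agree[called], sign(eff[called]), -sign(eff[called]))
    fp <- !nz & stats::runif(n) < null_call_rate * (1 - corr)
    score[fp] <- sample(c(-1L, 1L), sum(fp), replace = TRUE)
    names(score) <- genes
    return(ranked_dataset(score, category))
  }

  # flux: Z-scores per compartment/timepoint list, truncated to top lists
  recs <- list()
  for (cp in seq_len(n_compartments)) {
    for (tp in seq_len(n_timepoints)) {
      z <- corr * scaled + sqrt(max(0, 1 - corr^2)) * stats::rnorm(n)
      keep <- order(abs(z), decreasing = TRUE)[seq_len(min(top_n, n))]
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = genes[keep], value = z[keep],
        compartment = paste0("C", cp), timepoint = tp,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  ds <- compile_dataset(records, "flux", universe = genes)
  attr(ds, "records") <- records
  ds
}

#' Simulate a toy gene ontology
#'
#' Builds a rooted directed acyclic graph of terms with gene annotations in
#' which, by construction, every child's annotated genes are a subset of each
#' parent's (genes are assigned to leaves and propagated upward). A few extra
#' cross edges can give terms multiple parents.
#'
#' @param n_terms Number of terms (including the root).
#' @param n_genes Number of genes, named `G0001`, ...
#' @param seed Integer seed.
#' @param extra_edges Number of additional (multi-parent) DAG edges to add.
#' @return A list of class `ontology_dag`: `edges` (child, parent),
#'   `annotations` (term_id, gene_id, propagated), `root`, `terms`, `genes`.
#' @export
simulate_ontology <- function(n_terms, n_genes = 100L, seed = 1L,
                              extra_edges = 0L) {
  if (n_terms < 1L) stop("n_terms must be at least 1")
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (n_terms == 1L) {
    dag <- ontology_dag(edges = data.frame(child = character(0),
                                           parent = character(0)),
                        annotations = data.frame(term_id = terms[1],
                                                 gene_id = genes,
                                                 stringsAsFactors = FALSE))
    return(dag)
  }
  # random recursive tree: each term attaches to an earlier term
  parent <- c(NA_character_,
              terms[vapply(2:n_terms,
                           function(i) sample.int(i - 1L, 1L), 1L)])
  edges <- data.frame(child = terms[-1], parent = parent[-1],
                      stringsAsFactors = FALSE)
  if (extra_edges > 0L) {
    for (k in seq_len(extra_edges)) {
      i <- sample(2:n_terms, 1L)          # child must not be the root
      j <- sample.int(i - 1L, 1L)         # parent earlier => acyclic
      if (terms[j] != parent[i])
        edges <- rbind(edges, data.frame(child = terms[i], parent = terms[j]))
    }
    edges <- unique(edges)
  }
  is_leaf <- !(terms %in% edges$parent)
  leaves <- terms[is_leaf]
  assigned <- sample(leaves, n_genes, replace = TRUE)
  annotations <- data.frame(term_id = assigned, gene_id = genes,
                            stringsAsFactors = FALSE)
  ontology_dag(edges, annotations)
}
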