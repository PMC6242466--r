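#' Configuration for an end-to-end screen run
#'
#' A single declarative configuration for [run_screen()]: data source
#' (simulation parameters, a density table, or plate images plus layout),
#' stage parameters, stage toggles, seed, and an optional output directory.
#'
#' @param sim [screen_sim_params()] for a simulated screen, or `NULL` when
#'   `density_table` / `images` provide the input.
#' @param density_table A pre-quantified raw density table.
#' @param images Named list of plate images (or file paths) with a matching
#'   `layout`; quantified when given.
#' @param layout Layout table (plate_id, row, col, strain_id) for `images`.
#' @param grid [grid_spec()] used for quantification of `images`.
#' @param pseudocount,loess,test Stage parameters ([loess_params()],
#'   [test_params()]).
#' @param stages Character subset of
#'   `c("quantify", "normalize", "test", "hits")` to run (later stages
#'   require earlier ones).
#' @param external Optional named list of [ranked_dataset()] objects to
#'   compare hits against.
#' @param ontology Optional [ontology_dag()] for hit-set enrichment.
#' @param enrich_alpha Term significance cutoff for the enrichment stage.
#' @param seed Integer seed for the whole run.
#' @param output_dir Optional directory; when set, every stage writes its
#'   TSV artifact there.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(sim = screen_sim_params(),
                          density_table = NULL,
                          images = NULL, layout = NULL, grid = NULL,
                          pseudocount = 1,
                          loess = loess_params(),
                          test = test_params(),
                          stages = c("normalize", "test", "hits"),
                          external = NULL,
                          ontology = NULL,
                          enrich_alpha = 0.05,
                          seed = 1L,
                          output_dir = NULL) {
  known <- c("quantify", "normalize", "test", "hits")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  if (!is.null(images) && (is.null(layout) || is.null(grid)))
    stop("images require a layout and a grid")
  structure(list(sim = sim, density_table = density_table, images = images,
                 layout = layout, grid = grid, pseudocount = pseudocount,
                 loess = loess, test = test, stages = stages,
                 external = external, ontology = ontology,
                 enrich_alpha = enrich_alpha, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "screen_config")
}

stage_log <- function(manifest, stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, note))
  manifest$stages[[stage]] <- list(rows_in = n_in, rows_out = n_out,
                                   note = note)
  manifest
}

#' Run the screen pipeline end-to-end
#'
#' Executes, per the configuration: simulation (or table/image loading),
#' colony quantification, log2 + quantile + cyclic-LOESS normalization,
#' per-day regularized t-tests with BH adjustment, multi-day hit calling,
#' and optionally overlap comparison against external datasets and
#' conditional enrichment of the two directional hit sets. A manifest
#' records parameters, seed, package version, and per-stage row counts;
#' identical configuration and seed give identical output.
#'
#' @param config A [screen_config()].
#' @return List of class `screen_result` with (as toggled) `truth`,
#'   `density`, `normalized`, `tests`, `hits`, `overlaps`, `enrichment`,
#'   and `manifest`.
#' @export
run_screen <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("colonyscreen")),
                   parameters = list(pseudocount = config$pseudocount,
                                     loess = unclass(config$loess),
                                     test = unclass(config$test),
                                     enrich_alpha = config$enrich_alpha),
                   stages = list())
  out <- list()
  odir <- config$output_dir
  if (!is.null(odir) && !dir.exists(odir))
    dir.create(odir, recursive = TRUE)
  emit <- function(tab, name) {
    if (!is.null(odir)) {
      if (identical(name, "density") || identical(name, "normalized"))
        write_density_table(tab, file.path(odir, paste0(name, ".tsv")))
      else write_tsv(tab, file.path(odir, paste0(name, ".tsv")))
    }
  }

  # --- input: simulate, load, or quantify -------------------------------
  if (!is.null(config$images)) {
    rows <- list()
    for (nm in names(config$images)) {
      img <- config$images[[nm]]
      if (is.character(img)) img <- read_plate_image(img)
      lay <- config$layout[config$layout$plate_id == nm, , drop = FALSE]
      q <- quantify_plate(img, config$grid, lay)
      q$plate_id <- nm
      # plate-level metadata (condition/replicate/day) rides on the layout
      for (meta in c("condition", "replicate", "day"))
        q[[meta]] <- if (meta %in% names(lay)) lay[[meta]][1] else
          switch(meta, condition = "control", replicate = 1L, day = 1L)
      rows[[nm]] <- q
    }
    q <- do.call(rbind, rows)
    manifest <- stage_log(manifest, "quantify", length(config$images),
                          nrow(q))
    density <- data.frame(strain_id = q$strain_id,
                          condition = q$condition,
                          replicate = q$replicate,
                          day = q$day,
                          plate_id = q$plate_id,
                          density = ifelse(q$missing, NA_real_,
                                           q$integrated_density),
                          stringsAsFactors = FALSE)
    density <- density[!is.na(density$strain_id), ]
    attr(density, "stage") <- "raw"
    out$quantified <- q
  } else if (!is.null(config$density_table)) {
    density <- config$density_table
    if (is.character(density)) density <- read_density_table(density)
    manifest <- stage_log(manifest, "load", nrow(density), nrow(density))
  } else {
    sim <- simulate_screen(config$sim)
    out$truth <- sim$truth
    density <- sim$table
    manifest <- stage_log(manifest, "simulate", config$sim$n_strains,
                          nrow(density))
    if (!is.null(odir)) write_tsv(sim$truth, file.path(odir, "truth.tsv"))
  }
  out$density <- density
  emit(density, "density")

  # --- normalization -----------------------------------------------------
  if ("normalize" %in% config$stages) {
    norm <- normalize_screen(density, config$pseudocount, config$loess)
    manifest <- stage_log(manifest, "normalize", nrow(density), nrow(norm))
    out$normalized <- norm
    emit(norm, "normalized")
  }

  # --- per-day tests and hit calling ------------------------------------
  if ("test" %in% config$stages) {
    if (is.null(out$normalized)) stop("test stage requires normalize")
    tests <- test_screen(out$normalized, config$test)
    manifest <- stage_log(manifest, "test", nrow(out$normalized),
                          nrow(tests))
    out$tests <- tests
    emit(tests, "tests")
  }
  if ("hits" %in% config$stages) {
    if (is.null(out$tests)) stop("hits stage requires test")
    hits <- call_hits(out$tests, config$test)
    manifest <- stage_log(manifest, "hits", nrow(out$tests), nrow(hits),
                          sprintf("n_hits=%d", sum(hits$is_hit)))
    out$hits <- hits
    emit(hits, "hits")
  }

  # --- optional comparison and enrichment -------------------------------
  if (!is.null(config$external) && !is.null(out$tests)) {
    screen_ranked <- rank_screen_results(out$tests)
    out$overlaps <- lapply(config$external, function(ds)
      overlap_significance(screen_ranked, ds))
    manifest <- stage_log(manifest, "compare", length(config$external),
                          length(out$overlaps))
  }
  if (!is.null(config$ontology) && !is.null(out$hits)) {
    uni <- out$hits$strain_id
    enr <- list()
    for (dir in c("increased", "decreased")) {
      hs <- out$hits$strain_id[out$hits$is_hit & out$hits$direction == dir]
      enr[[dir]] <- conditional_enrichment(hs, uni, config$ontology,
                                           config$enrich_alpha)
    }
    out$enrichment <- enr
    manifest <- stage_log(manifest, "enrich", sum(out$hits$is_hit),
                          sum(vapply(enr, function(e) sum(e$enriched), 0L)))
  }

  out$manifest <- manifest
  if (!is.null(odir)) {
    mf <- manifest
    mf$stages <- NULL
    writeLines(utils::capture.output(utils::str(manifest)),
               file.path(odir, "manifest.txt"))
  }
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result\n")
  for (nm in setdiff(names(x), "manifest"))
    cat(sprintf("  %-11s %s\n", nm, paste(class(x[[nm]])[1],
                                          collapse = ",")))
  if (!is.null(x$hits))
    cat(sprintf("  hits: %d increased, %d decreased (of %d strains)\n",
                sum(x$hits$is_hit & x$hits$direction == "increased"),
                sum(x$hits$is_hit & x$hits$direction == "decreased"),
                nrow(x$hits)))
  invisible(x)
}
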