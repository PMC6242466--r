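#' Log2-transform a raw density table
#'
#' @param table Raw-stage density table.
#' @param pseudocount Added before taking log2 (guards zero densities of
#'   missing colonies).
#' @return The table with `density` replaced by `log2(density + pseudocount)`
#'   and stage `logged`.
#' @export
log_transform <- function(table, pseudocount = 1) {
  if (!identical(attr(table, "stage"), "raw"))
    stop("log_transform expects a raw-stage table")
  if (any(table$density < 0, na.rm = TRUE))
    stop("negative densities")
  table$density <- log2(table$density + pseudocount)
  attr(table, "stage") <- "logged"
  table
}

#' Quantile-normalize a set of value columns
#'
#' Forces equal-length columns to share one empirical distribution: the
#' value at rank r of every column becomes the mean across columns of the
#' rank-r values, with ties averaged and missing values left in place
#' (backed by `limma::normalizeQuantiles(ties = TRUE)`).
#'
#' @param mat Numeric matrix, one column per replicate plate.
#' @return Matrix of the same shape with identical sorted columns.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) {
    warning("fewer than 2 columns: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Cyclic LOESS parameters
#'
#' @param span Local-regression bandwidth as a fraction of points.
#' @param epsilon Convergence threshold on the maximum per-column mean
#'   squared correction of a cycle.
#' @param maxit Maximum number of cycles over all pairs.
#' @param log_input If `FALSE` (default) the inputs are already logged.
#' @return List of class `loess_params`.
#' @export
loess_params <- function(span = 0.05, epsilon = 1, maxit = 5,
                         log_input = FALSE) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (maxit < 1) stop("maxit must be at least 1")
  structure(list(span = span, epsilon = epsilon, maxit = as.integer(maxit),
                 log_input = log_input),
            class = "loess_params")
}

#' Cyclic LOESS normalization over plate pairs
#'
#' For each pair of matched plate columns, fits a degree-1 tricube local
#' regression of the difference M = x_i - x_j on the average
#' A = (x_i + x_j) / 2 and moves each column half the fitted trend toward
#' the other (scaled by the number of pairs a column participates in, with
#' all corrections of a cycle applied simultaneously). Cycling repeats until
#' the maximum per-column mean squared correction falls below `epsilon` or
#' `maxit` cycles are reached. This removes trends in the between-plate
#' difference that depend on colony size, such as a drug's stronger basal
#' effect on small colonies.
#'
#' @param mat Numeric matrix, columns indexed by `pairs`, rows = strains.
#' @param pairs Two-column integer matrix of column-index pairs.
#' @param params A [loess_params()].
#' @return The corrected matrix.
#' @export
cyclic_loess <- function(mat, pairs, params = loess_params()) {
  mat <- as.matrix(mat)
  if (params$log_input) mat <- log2(mat)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  for (cycle in seq_len(params$maxit)) {
    corr <- matrix(0, nrow(mat), ncol(mat))
    cnt <- integer(ncol(mat))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      A <- (mat[ok, i] + mat[ok, j]) / 2
      M <- mat[ok, i] - mat[ok, j]
      if (sum(ok) < 10 || stats::sd(A) == 0) {
        warning("degenerate pair (", i, ",", j, ") skipped")
        next
      }
      fit <- stats::lowess(A, M, f = params$span, iter = 0, delta = 0)
      m <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
      corr[ok, i] <- corr[ok, i] - m / 2
      corr[ok, j] <- corr[ok, j] + m / 2
      cnt[i] <- cnt[i] + 1L
      cnt[j] <- cnt[j] + 1L
    }
    active <- cnt > 0L
    if (!any(active)) break
    corr[, active] <- sweep(corr[, active, drop = FALSE], 2, cnt[active], "/")
    mat <- mat + corr
    change <- max(colMeans(corr[, active, drop = FALSE]^2))
    if (change < params$epsilon) break
  }
  if (params$log_input) mat <- 2^mat
  mat
}

table_matrix <- function(sub, columns) {
  # strains x columns matrix of densities; `columns` is a factor key
  strains <- sort(unique(sub$strain_id))
  cols <- sort(unique(columns))
  m <- matrix(NA_real_, length(strains), length(cols),
              dimnames = list(strains, cols))
  m[cbind(match(sub$strain_id, strains), match(columns, cols))] <- sub$density
  m
}

#' Quantile-normalize a density table within (condition, day) groups
#'
#' Within each condition and day, the logged densities of the replicate
#' plate sets are forced to a common distribution, removing plate-to-plate
#' technical variability.
#'
#' @param table Logged-stage density table.
#' @return The table at stage `quantile`.
#' @export
quantile_normalize_table <- function(table) {
  if (!identical(attr(table, "stage"), "logged"))
    stop("quantile_normalize_table expects a logged-stage table")
  for (cond in unique(table$condition)) {
    for (d in unique(table$day)) {
      idx <- table$condition == cond & table$day == d
      sub <- table[idx, , drop = FALSE]
      m <- table_matrix(sub, as.character(sub$replicate))
      m <- quantile_normalize(m)
      table$density[idx] <- m[cbind(match(sub$strain_id, rownames(m)),
                                    match(as.character(sub$replicate),
                                          colnames(m)))]
    }
  }
  attr(table, "stage") <- "quantile"
  table
}

#' Cyclic-LOESS-correct a density table between conditions
#'
#' For each day, pairs the control and drug columns of the same replicate
#' index (the default pairing; `pairing = "all"` uses every column pair
#' within the day) and applies [cyclic_loess()], removing the colony-size-
#' dependent basal drug effect.
#'
#' @param table Quantile- or logged-stage density table.
#' @param params A [loess_params()].
#' @param pairing `"condition"` (default) or `"all"`.
#' @return The table at stage `loess`.
#' @export
loess_normalize_table <- function(table, params = loess_params(),
                                  pairing = c("condition", "all")) {
  pairing <- match.arg(pairing)
  if (!attr(table, "stage") %in% c("logged", "quantile"))
    stop("loess_normalize_table expects a logged or quantile-stage table")
  for (d in unique(table$day)) {
    idx <- table$day == d
    sub <- table[idx, , drop = FALSE]
    key <- paste(sub$condition, sub$replicate, sep = ".")
    m <- table_matrix(sub, key)
    cols <- colnames(m)
    if (pairing == "condition") {
      reps <- sort(unique(sub$replicate))
      pr <- cbind(match(paste0("control.", reps), cols),
                  match(paste0("drug.", reps), cols))
      pr <- pr[stats::complete.cases(pr), , drop = FALSE]
    } else {
      pr <- t(utils::combn(seq_along(cols), 2))
    }
    m <- cyclic_loess(m, pr, params)
    table$density[idx] <- m[cbind(match(sub$strain_id, rownames(m)),
                                  match(key, colnames(m)))]
  }
  attr(table, "stage") <- "loess"
  table
}

#' Full normalization of a raw density table
#'
#' log2 transform, within-condition quantile normalization across replicate
#' plate sets, then cyclic LOESS correction between condition pairs.
#'
#' @param table Raw-stage density table.
#' @param pseudocount Passed to [log_transform()].
#' @param params A [loess_params()].
#' @param pairing Passed to [loess_normalize_table()].
#' @return The table at stage `loess`.
#' @export
normalize_screen <- function(table, pseudocount = 1,
                             params = loess_params(),
                             pairing = "condition") {
  table <- log_transform(table, pseudocount)
  table <- quantile_normalize_table(table)
  loess_normalize_table(table, params, pairing)
}
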