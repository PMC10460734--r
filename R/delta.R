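#' Kernel density estimate on an explicit grid
#'
#' Gaussian-kernel density evaluated on a shared, equally spaced grid. The
#' shared grid is what makes conditional and unconditional densities directly
#' comparable in the L1 sense. With `bandwidth = "auto"` Silverman's rule of
#' thumb is computed on the supplied values, floored at `1e-12` times the
#' grid range so that nearly degenerate classes still yield a proper density.
#'
#' @param values numeric vector, at least 8 finite values.
#' @param grid strictly increasing, equally spaced evaluation grid. It should
#'   span at least three pooled bandwidths beyond the data range.
#' @param bandwidth positive bandwidth, or `"auto"` for Silverman's rule.
#' @return an object of class `density_on_grid`: list with `grid`, `density`,
#'   `bandwidth`.
#' @export
estimate_density <- function(values, grid, bandwidth = "auto") {
  values <- values[is.finite(values)]
  if (length(values) < 8) stop("need at least 8 finite values")
  if (max(values) == min(values)) stop("degenerate output: constant values")
  if (identical(bandwidth, "auto")) bandwidth <- silverman_bw(values, grid)
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      from = grid[1], to = grid[length(grid)],
                      n = length(grid))
  structure(list(grid = grid, density = d$y, bandwidth = bandwidth),
            class = "density_on_grid")
}

# Silverman's rule of thumb with a floor tied to the evaluation range.
silverman_bw <- function(x, grid = range(x)) {
  floor_bw <- 1e-12 * (max(grid) - min(grid))
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  spread <- min(s, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- if (s > 0) s else 0
  bw <- 0.9 * spread * length(x)^(-1 / 5)
  max(bw, floor_bw)
}

# Trapezoid integral on an equally spaced grid.
trapz_grid <- function(grid, y) {
  h <- grid[2] - grid[1]
  h * (sum(y) - (y[1] + y[length(y)]) / 2)
}

#' L1 separation between an unconditional and a conditional output density
#'
#' The shift imposed on the output density by conditioning on an input is
#' measured as the integrated absolute difference between the two densities,
#' a quantity in `[0, 2]` (0 for identical densities, 2 for disjoint ones).
#'
#' @param f_uncond,f_cond two [estimate_density()] results on the same grid.
#' @return the trapezoid approximation of `integral |f_uncond - f_cond| dY`.
#' @export
separation_measure <- function(f_uncond, f_cond) {
  if (!isTRUE(all.equal(f_uncond$grid, f_cond$grid)))
    stop("densities must share the same grid")
  trapz_grid(f_uncond$grid, abs(f_uncond$density - f_cond$density))
}

# Drop rows whose output is non-finite, keeping X and Y aligned.
drop_nonfinite_rows <- function(X, Y) {
  keep <- is.finite(Y)
  list(X = X[keep, , drop = FALSE], Y = Y[keep], dropped = sum(!keep))
}

# Default partition count: ~sqrt(n)/10 classes, clamped to [10, 50];
# 30 at the reference sample size n = 1e5.
default_partitions <- function(n) {
  max(10L, min(50L, as.integer(floor(sqrt(n) / 10))))
}

# Boundaries of M equal-frequency consecutive blocks over n sorted items.
class_bounds <- function(n, M) round(seq(0L, n, length.out = M + 1L))

# Core given-data delta computation for one column ordering.
# ord: permutation sorting the column; Y: outputs; grid/f0: pooled density.
.delta_one <- function(ord, Y, grid, f0, bounds) {
  M <- length(bounds) - 1L
  n <- length(Y)
  acc <- 0
  for (m in seq_len(M)) {
    idx <- ord[(bounds[m] + 1L):bounds[m + 1L]]
    ym <- Y[idx]
    fm <- stats::density(ym, bw = silverman_bw(ym, grid), kernel = "gaussian",
                         from = grid[1], to = grid[length(grid)],
                         n = length(grid))$y
    acc <- acc + (length(ym) / n) * trapz_grid(grid, abs(f0 - fm))
  }
  acc / 2
}

# Shared machinery: validate, build pooled grid/density, return per-column
# delta estimates for the given row subset (indices into X rows).
.delta_all <- function(X, Y, partitions, cols = colnames(X),
                       ranks = NULL, idx = NULL) {
  n <- length(Y)
  if (is.null(idx)) idx <- seq_len(n)
  Ysub <- Y[idx]
  h0 <- silverman_bw(Ysub)
  grid <- seq(min(Ysub) - 3 * h0, max(Ysub) + 3 * h0, length.out = 512L)
  f0 <- stats::density(Ysub, bw = h0, kernel = "gaussian",
                       from = grid[1], to = grid[512L], n = 512L)$y
  bounds <- class_bounds(length(idx), partitions)
  out <- numeric(length(cols))
  names(out) <- cols
  for (j in seq_along(cols)) {
    rv <- ranks[idx, cols[j]]
    ord <- order(rv, method = "radix")
    out[j] <- .delta_one(ord, Ysub, grid, f0, bounds)
  }
  pmin(pmax(out, 0), 1)
}

#' Estimate delta sensitivity indices from given data
#'
#' Implements the given-data estimator of the moment-independent delta
#' index: each input column is sorted and split into `partitions`
#' equal-frequency classes; the class-conditional output densities are
#' compared to the pooled output density on a common 512-point grid and the
#' index is the half of the class-weighted average L1 distance. Values are
#' clipped to `[0, 1]`. Equal-frequency partitioning depends only on the
#' ranks of an input, which makes the estimate exactly invariant under
#' strictly monotone transformations of any input column.
#'
#' Constant input columns are excluded with a warning (the conditional
#' density given a constant is undefined); rows with non-finite output are
#' dropped in tandem from X and Y and the count reported via attribute
#' `dropped`.
#'
#' @param X numeric sample matrix with named columns (inputs, possibly
#'   including a `"Noise"` column).
#' @param Y numeric output vector, row-aligned with `X`.
#' @param partitions number of equal-frequency classes, or `"auto"` for a
#'   `sqrt(n)`-scaled default (30 at n = 1e5). Requires `n >= 50 * partitions`.
#' @return named numeric vector of point estimates in `[0, 1]`, with
#'   attribute `dropped` (count of non-finite-output rows removed).
#' @examples
#' X <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' d <- estimate_delta(X, X[, "a"], partitions = 10)
#' @export
estimate_delta <- function(X, Y, partitions = "auto") {
  stopifnot(is.matrix(X), nrow(X) == length(Y))
  dn <- drop_nonfinite_rows(X, Y)
  X <- dn$X; Y <- dn$Y
  n <- length(Y)
  if (identical(partitions, "auto")) partitions <- default_partitions(n)
  partitions <- as.integer(partitions)
  if (n < 50L * partitions)
    stop("too few samples: need n >= 50 * partitions")
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    warning("constant input column(s) excluded from delta estimation: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  ranks <- apply(X, 2, rank, ties.method = "first")
  est <- .delta_all(X, Y, partitions, ranks = ranks)
  attr(est, "dropped") <- dn$dropped
  est
}

#' Bootstrap uncertainty for delta estimates
#'
#' Resamples rows of the joint (X, Y) table with replacement `B` times,
#' recomputing the whole given-data estimate (including the equal-frequency
#' partitioning) per replicate. Per column it reports the full-data point
#' estimate, the bootstrap median, and equal-tail 2.5/97.5 bootstrap
#' percentiles. The per-replicate values are retained (needed by
#' [noise_threshold()]).
#'
#' @inheritParams estimate_delta
#' @param B number of bootstrap replicates (>= 2); the reference protocol
#'   uses 1000.
#' @param seed integer seed governing all resampling.
#' @return an object of class `delta_bootstrap`: list with `estimates` (a
#'   data.frame: `name, point, bootstrap_median, ci_low, ci_high,
#'   significant, zeroed_value`), `replicates` (B x p matrix of per-replicate
#'   delta values), `partitions`, `B`, `seed`, `dropped`.
#' @export
bootstrap_deltas <- function(X, Y, partitions = "auto", B = 1000, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(Y))
  B <- as.integer(B)
  if (B < 2) stop("B must be at least 2")
  dn <- drop_nonfinite_rows(X, Y)
  X <- dn$X; Y <- dn$Y
  n <- length(Y)
  if (identical(partitions, "auto")) partitions <- default_partitions(n)
  partitions <- as.integer(partitions)
  if (n < 50L * partitions)
    stop("too few samples: need n >= 50 * partitions")
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    warning("constant input column(s) excluded from delta estimation: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  cols <- colnames(X)
  ranks <- apply(X, 2, rank, ties.method = "first")
  point <- .delta_all(X, Y, partitions, ranks = ranks)
  reps <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .delta_all(X, Y, partitions, ranks = ranks, idx = idx)
    }, numeric(length(cols))))
  })
  colnames(reps) <- cols
  qs <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  est <- data.frame(
    name = cols,
    point = as.numeric(point),
    bootstrap_median = qs[2, ],
    ci_low = qs[1, ],
    ci_high = qs[3, ],
    significant = NA,
    zeroed_value = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = est, replicates = reps,
                 partitions = partitions, B = B, seed = as.integer(seed),
                 dropped = dn$dropped),
            class = "delta_bootstrap")
}

#' Significance threshold from the Noise negative control
#'
#' The 97.5th percentile (linear-interpolation quantile) of the bootstrap
#' delta values obtained for the spurious standard-normal "Noise" input. A
#' parameter whose bootstrap-median delta falls below this threshold cannot
#' be distinguished from estimator bias and is treated as zero.
#'
#' @param noise_bootstrap numeric vector of bootstrap delta values for the
#'   Noise column.
#' @return the 97.5th percentile.
#' @export
noise_threshold <- function(noise_bootstrap) {
  if (length(noise_bootstrap) == 0) stop("empty bootstrap vector")
  unname(stats::quantile(noise_bootstrap, probs = 0.975, type = 7))
}

#' Apply the noise significance threshold to delta estimates
#'
#' A parameter is significant when its bootstrap-median delta is at least
#' the threshold; otherwise its delta is considered equal to zero
#' (`zeroed_value = 0`).
#'
#' @param boot a [bootstrap_deltas()] result (or its `estimates` data.frame).
#' @param threshold non-negative threshold, typically [noise_threshold()].
#' @return the input with `significant` and `zeroed_value` filled in and
#'   attribute/field `threshold` set.
#' @export
apply_significance <- function(boot, threshold) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  est <- if (inherits(boot, "delta_bootstrap")) boot$estimates else boot
  est$significant <- est$bootstrap_median >= threshold
  est$zeroed_value <- ifelse(est$significant, est$bootstrap_median, 0)
  if (inherits(boot, "delta_bootstrap")) {
    boot$estimates <- est
    boot$threshold <- threshold
    boot
  } else {
    attr(est, "threshold") <- threshold
    est
  }
}

#' Write delta results to CSV
#'
#' Columns: `name,point,bootstrap_median,ci_low,ci_high,significant,`
#' `zeroed_value,threshold`.
#'
#' @param boot a [delta_bootstrap] with significance applied.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_csv <- function(boot, path) {
  est <- if (inherits(boot, "delta_bootstrap")) boot$estimates else boot
  thr <- if (inherits(boot, "delta_bootstrap")) boot$threshold
         else attr(boot, "threshold")
  est$threshold <- if (is.null(thr)) NA_real_ else thr
  utils::write.csv(est, path, row.names = FALSE)
  invisible(path)
}
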