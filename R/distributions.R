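#' Parameter specifications for a joint input distribution
#'
#' A parameter specification table holds, per input parameter, its typical
#' value (interpreted as the lognormal median, the standard pharmacometric
#' convention), its fractional coefficient of variation on the natural scale,
#' and its marginal family. Zero-CV parameters are legal and are carried as
#' constants; they are automatically excluded from delta estimation because a
#' conditional density given a constant is undefined.
#'
#' @param name character vector of unique parameter names.
#' @param typical_value numeric vector of typical values; must be strictly
#'   positive for lognormal marginals.
#' @param cv numeric vector of fractional CVs (0.2 means 20%); non-negative.
#' @param family marginal family per parameter, `"lognormal"` or `"normal"`.
#'   Recycled if length 1.
#' @param units optional character vector of units, for bookkeeping only.
#' @return a `data.frame` of class `parameter_spec` with columns
#'   `name`, `typical_value`, `cv`, `family`, `units`.
#' @examples
#' parameter_spec(c("k2", "IC50"), c(0.129, 2.53e-2), c(0.20, 0.10))
#' @export
parameter_spec <- function(name, typical_value, cv,
                           family = "lognormal", units = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("parameter names must be unique")
  p <- length(name)
  typical_value <- as.numeric(typical_value)
  cv <- as.numeric(cv)
  family <- rep_len(match.arg(family, c("lognormal", "normal"),
                              several.ok = TRUE), p)
  units <- rep_len(as.character(units), p)
  stopifnot(length(typical_value) == p, length(cv) == p)
  if (any(!is.finite(typical_value)) || any(!is.finite(cv)))
    stop("typical values and CVs must be finite")
  if (any(cv < 0)) stop("cv must be non-negative")
  if (any(family == "lognormal" & typical_value <= 0))
    stop("lognormal marginals require strictly positive typical values")
  out <- data.frame(name = name, typical_value = typical_value, cv = cv,
                    family = family, units = units,
                    stringsAsFactors = FALSE)
  class(out) <- c("parameter_spec", "data.frame")
  out
}

#' Read a parameter table from CSV
#'
#' Expected columns: `name,value,cv_percent,family,units` (CVs as
#' percentages, e.g. 20 for a 20% CV). `family` and `units` are optional;
#' `family` defaults to lognormal.
#'
#' @param path path to a CSV file.
#' @return a [parameter_spec] table.
#' @export
read_parameter_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "value", "cv_percent")
  if (!all(need %in% names(d)))
    stop("parameter CSV must contain columns: ", paste(need, collapse = ", "))
  parameter_spec(
    name = d$name,
    typical_value = d$value,
    cv = d$cv_percent / 100,
    family = if ("family" %in% names(d)) d$family else "lognormal",
    units = if ("units" %in% names(d)) d$units else NA_character_
  )
}

#' Partially specified correlation template
#'
#' A square symmetric grid of pairwise correlations on the underlying
#' Gaussian (log) scale in which some entries may be unknown (`NA`). Unknown
#' entries are later filled in by [complete_correlation()].
#'
#' @param mat square numeric matrix with unit diagonal; `NA` marks an unknown
#'   entry; known off-diagonal values must lie in `[-1, 1]`. The known/unknown
#'   pattern and the known values must be symmetric.
#' @param names optional parameter names; defaults to the matrix dimnames.
#' @return a matrix of class `correlation_template`.
#' @export
correlation_template <- function(mat, names = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("correlation template must be square")
  if (is.null(names)) names <- rownames(mat)
  if (is.null(names)) names <- paste0("X", seq_len(nrow(mat)))
  dimnames(mat) <- list(names, names)
  if (!isTRUE(all.equal(diag(mat), rep(1, nrow(mat)), check.attributes = FALSE)))
    stop("correlation template must have a unit diagonal")
  na_pat <- is.na(mat)
  if (!identical(na_pat, t(na_pat)))
    stop("unknown-entry pattern must be symmetric")
  known <- mat; known[na_pat] <- 0
  if (max(abs(known - t(known))) > 1e-12)
    stop("known correlation values must be symmetric")
  if (any(abs(mat) > 1, na.rm = TRUE))
    stop("known correlations must lie in [-1, 1]")
  class(mat) <- c("correlation_template", "matrix")
  mat
}

#' Read a correlation template from CSV
#'
#' The CSV is square with a header row and a leading name column; cells hold
#' numeric correlations or the literal token `NA` for unknown entries.
#'
#' @param path path to a CSV file.
#' @return a [correlation_template].
#' @export
read_correlation_template <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  correlation_template(as.matrix(d), names = rownames(d))
}

#' Write a correlation template (or completed matrix) to CSV
#'
#' @param mat square correlation matrix or template.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(unclass(mat)), path, row.names = TRUE)
  invisible(path)
}

#' Build a joint input distribution
#'
#' Combines marginal specifications with a correlation matrix into a joint
#' distribution with lognormal (or normal) marginals coupled through a
#' Gaussian copula. For a lognormal parameter with typical value theta and
#' natural-scale CV, the Gaussian-scale location is `log(theta)` (so theta is
#' the median) and the scale is `sqrt(log(1 + cv^2))`. Correlations act on
#' the underlying Gaussian scale, which keeps every positive-definite matrix
#' attainable.
#'
#' @param specs a [parameter_spec] table.
#' @param correlation optional completed correlation matrix (symmetric,
#'   positive definite, unit diagonal) with dimension matching `specs`;
#'   `NULL` means independence (identity).
#' @return an object of class `joint_input_distribution` with elements
#'   `names`, `family`, `log_location`, `log_scale`, `correlation`, `units`.
#' @examples
#' specs <- parameter_spec(c("a", "b"), c(1, 2), c(0.3, 0.5))
#' joint <- build_joint(specs)
#' @export
build_joint <- function(specs, correlation = NULL) {
  stopifnot(inherits(specs, "parameter_spec"), nrow(specs) > 0)
  p <- nrow(specs)
  loc <- ifelse(specs$family == "lognormal",
                log(specs$typical_value), specs$typical_value)
  scl <- ifelse(specs$family == "lognormal",
                sqrt(log(1 + specs$cv^2)), specs$cv * abs(specs$typical_value))
  if (is.null(correlation)) {
    correlation <- diag(p)
    dimnames(correlation) <- list(specs$name, specs$name)
  } else {
    correlation <- as.matrix(correlation)
    if (nrow(correlation) != p || ncol(correlation) != p)
      stop("correlation dimension does not match the number of parameters")
    if (max(abs(correlation - t(correlation))) > 1e-10)
      stop("correlation matrix must be symmetric")
    if (!isTRUE(all.equal(diag(correlation), rep(1, p),
                          check.attributes = FALSE)))
      stop("correlation matrix must have a unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("correlation matrix must be positive definite ",
           "(smallest eigenvalue ", format(min(ev)), ")")
    dimnames(correlation) <- list(specs$name, specs$name)
  }
  structure(
    list(names = specs$name, family = specs$family,
         log_location = stats::setNames(loc, specs$name),
         log_scale = stats::setNames(scl, specs$name),
         correlation = correlation, units = specs$units),
    class = "joint_input_distribution")
}

#' @export
print.joint_input_distribution <- function(x, ...) {
  p <- length(x$names)
  off <- x$correlation[upper.tri(x$correlation)]
  cat("Joint input distribution:", p, "parameters\n")
  cat("  marginals:", paste(unique(x$family), collapse = "/"),
      " | nonzero correlations:", sum(abs(off) > 0), "\n")
  invisible(x)
}

#' Complete a partially specified correlation matrix
#'
#' Unknown entries are initialised at zero (the maximum-entropy choice). If
#' the resulting matrix is already positive definite it is returned as is, so
#' a fully specified positive-definite template passes through unchanged.
#' Otherwise an alternating-projection scheme is run: project onto the cone
#' of symmetric matrices with eigenvalues at least `eig_floor`, then
#' re-impose the known entries and the unit diagonal, until the Frobenius
#' change drops below `tol` (at most `max_iter` iterations). If the scheme
#' does not converge with the known entries held fixed, the constraint is
#' relaxed: the final positive-definite projection is returned and the
#' maximum absolute perturbation of a known entry is reported with a warning
#' (and attached as attribute `max_perturbation`).
#'
#' @param template a [correlation_template] (or plain matrix with `NA`s for
#'   unknowns and unit diagonal).
#' @param eig_floor smallest admissible eigenvalue of the result.
#' @param max_iter,tol iteration cap and Frobenius convergence tolerance.
#' @return a symmetric positive-definite correlation matrix with unit
#'   diagonal and attribute `max_perturbation` (0 when all known entries are
#'   preserved exactly).
#' @examples
#' tpl <- correlation_template(matrix(c(1, 0.95, 0.95,
#'                                      0.95, 1, NA,
#'                                      0.95, NA, 1), 3, 3))
#' R <- complete_correlation(tpl)
#' @export
complete_correlation <- function(template, eig_floor = 1e-8,
                                 max_iter = 1000, tol = 1e-10) {
  if (!inherits(template, "correlation_template"))
    template <- correlation_template(template)
  R0 <- unclass(template)
  p <- nrow(R0)
  known <- !is.na(R0)
  R <- R0
  R[!known] <- 0

  min_eig <- function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig(R) >= eig_floor) {
    attr(R, "max_perturbation") <- 0
    return(R)
  }

  proj_psd <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% (pmax(e$values, eig_floor) * t(e$vectors))
  }
  X <- R
  for (it in seq_len(max_iter)) {
    Y <- proj_psd(X)
    Z <- Y
    Z[known] <- R0[known]
    diag(Z) <- 1
    Z <- (Z + t(Z)) / 2
    done <- sqrt(sum((Z - X)^2)) < tol
    X <- Z
    if (done) break
  }
  # known entries were re-imposed on every iterate; accept if the result is
  # (numerically) positive definite with them in place
  if (min_eig(X) >= eig_floor * 0.1) {
    attr(X, "max_perturbation") <- 0
    return(X)
  }
  # No PD completion with the known entries fixed: relax, report perturbation.
  Y <- proj_psd(X)
  d <- 1 / sqrt(diag(Y))
  Y <- Y * tcrossprod(d) # rescale to unit diagonal
  diag(Y) <- 1
  Y <- (Y + t(Y)) / 2
  pert <- max(abs(Y[known] - R0[known]))
  warning(sprintf(
    "no positive-definite completion preserves the known entries exactly; max absolute perturbation %.3g",
    pert))
  dimnames(Y) <- dimnames(R0)
  attr(Y, "max_perturbation") <- pert
  Y
}

#' Draw correlated (or independent) Monte Carlo samples
#'
#' Samples are generated through the Gaussian copula: standard-normal draws
#' are correlated through the Cholesky factor of the Gaussian-scale
#' correlation matrix, then mapped through each marginal. With
#' `independent = TRUE` the off-diagonal correlations are ignored while the
#' marginals stay identical — the device used by the two-stage protocol's
#' Step 1.
#'
#' @param joint a [build_joint()] distribution.
#' @param n number of rows to draw (>= 2).
#' @param seed integer seed; identical seeds give identical matrices.
#' @param independent logical; drop the correlation structure but keep the
#'   marginals.
#' @return a numeric matrix with `n` rows and one named column per parameter,
#'   with attributes `seed` and `independent`.
#' @export
draw_samples <- function(joint, n, seed, independent = FALSE) {
  stopifnot(inherits(joint, "joint_input_distribution"))
  n <- as.integer(n)
  if (n < 2) stop("n must be at least 2")
  p <- length(joint$names)
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  if (!independent && p > 1) {
    L <- chol(joint$correlation)
    Z <- Z %*% L
  }
  G <- sweep(Z, 2, joint$log_scale, `*`)
  G <- sweep(G, 2, joint$log_location, `+`)
  X <- G
  ln <- joint$family == "lognormal"
  if (any(ln)) X[, ln] <- exp(G[, ln, drop = FALSE])
  colnames(X) <- joint$names
  attr(X, "seed") <- as.integer(seed)
  attr(X, "independent") <- independent
  X
}

#' Append the spurious standard-normal "Noise" input
#'
#' Adds a standard-normal column, independent of every model parameter, used
#' as a negative control: the delta index estimated for pure noise quantifies
#' the positive bias of the numerical estimator, and its bootstrap 97.5th
#' percentile serves as the significance threshold.
#'
#' @param samples a sample matrix without a `"Noise"` column.
#' @param seed integer seed for the noise draws.
#' @return the matrix with one extra column named `"Noise"`.
#' @export
append_noise_column <- function(samples, seed) {
  if ("Noise" %in% colnames(samples))
    stop("samples already contain a 'Noise' column")
  noise <- with_seed(seed, stats::rnorm(nrow(samples)))
  out <- cbind(samples, Noise = noise)
  attr(out, "seed") <- attr(samples, "seed")
  attr(out, "independent") <- attr(samples, "independent")
  out
}

#' Read/write a sample matrix CSV
#'
#' Full double precision round-trip: values are written with 17 significant
#' digits.
#'
#' @param x sample matrix.
#' @param path CSV path.
#' @return `read_sample_csv` returns a numeric matrix; `write_sample_csv`
#'   returns `path` invisibly.
#' @export
write_sample_csv <- function(x, path) {
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                          scientific = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
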