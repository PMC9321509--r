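#' Construct a pairwise comparison matrix
#'
#' Validates a Saaty-style reciprocal comparison matrix: square, order 1-10,
#' all entries positive, unit diagonal, and `a[j,i] = 1/a[i,j]` to relative
#' tolerance 1e-6. Entries are typically drawn from the 1-9 scale and its
#' reciprocals.
#'
#' @param entries square numeric matrix of positive comparisons
#' @return an object of class `esp_pairwise`
#' @export
pairwise_matrix <- function(entries) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (n != ncol(entries)) stop("comparison matrix must be square")
  if (n < 1L || n > 10L) stop("matrix order must be between 1 and 10")
  if (any(!is.finite(entries)) || any(entries <= 0))
    stop("all comparisons must be positive finite numbers")
  if (any(abs(diag(entries) - 1) > 1e-9))
    stop("diagonal entries must all equal 1")
  rel <- abs(entries * t(entries) - 1)
  if (any(rel > 1e-6))
    stop("matrix is not reciprocal: a[j,i] must equal 1/a[i,j]")
  structure(list(n = n, entries = entries), class = "esp_pairwise")
}

#' Read a pairwise comparison matrix from a text file
#'
#' Plain-text format: `n` lines of `n` whitespace-separated entries.
#' Fractional entries such as `1/6` are parsed as exact rationals, so the
#' reciprocal invariant holds to machine precision.
#'
#' @param path file path
#' @return an `esp_pairwise` object
#' @export
read_pairwise_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    vapply(tok, function(t) {
      if (grepl("^\\d+(\\.\\d+)?/\\d+(\\.\\d+)?$", t)) {
        p <- as.numeric(strsplit(t, "/")[[1]])
        p[1] / p[2]
      } else as.numeric(t)
    }, numeric(1), USE.NAMES = FALSE)
  })
  n <- length(rows)
  if (any(lengths(rows) != n))
    stop("matrix file must have n lines of n entries")
  pairwise_matrix(do.call(rbind, rows))
}

#' Principal eigenvalue and priority weights
#'
#' Dominant eigenvalue and normalized principal eigenvector of a reciprocal
#' comparison matrix, computed by power iteration started from the uniform
#' vector (relative tolerance 1e-10, at most 10,000 iterations). By
#' Perron-Frobenius the eigenvector of a positive matrix is positive and
#' unique up to scale; it is returned normalized to sum 1.
#'
#' @param matrix an `esp_pairwise` object (or a matrix accepted by
#'   [pairwise_matrix()])
#' @return list with `lambda_max` and `weights`
#' @export
principal_eigen <- function(matrix) {
  if (!inherits(matrix, "esp_pairwise")) matrix <- pairwise_matrix(matrix)
  A <- matrix$entries
  n <- matrix$n
  if (n == 1L) return(list(lambda_max = 1, weights = 1))
  w <- rep(1 / n, n)
  lambda <- NA_real_
  for (it in seq_len(10000L)) {
    v <- as.vector(A %*% w)
    lambda_new <- sum(v)           # since sum(w) == 1, Rayleigh-type estimate
    v <- v / sum(v)
    if (it > 1L && abs(lambda_new - lambda) <= 1e-10 * abs(lambda_new) &&
        max(abs(v - w)) <= 1e-10) {
      w <- v; lambda <- lambda_new
      break
    }
    w <- v; lambda <- lambda_new
  }
  list(lambda_max = lambda, weights = w)
}

#' Random consistency index (RI)
#'
#' Saaty's random index for matrix orders 1-10:
#' 0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49.
#'
#' @param n matrix order, 1-10
#' @export
ri_lookup <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > 10L)
    stop("RI is tabulated for orders 1 to 10 only")
  ri[n]
}

#' AHP consistency diagnostics
#'
#' Computes `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI(n)`; the
#' weight vector is considered consistent when `CR < 0.1`. For `n <= 2`
#' (where a reciprocal matrix is always consistent) `CI = 0`, and `CR = 0`
#' whenever `RI(n) = 0`.
#'
#' @param matrix an `esp_pairwise` object (or coercible matrix)
#' @return list of class `esp_ahp` with `lambda_max`, `weights`, `ci`,
#'   `cr`, `consistent`
#' @export
ahp_consistency <- function(matrix) {
  if (!inherits(matrix, "esp_pairwise")) matrix <- pairwise_matrix(matrix)
  n <- matrix$n
  pe <- principal_eigen(matrix)
  ci <- if (n <= 2L) 0 else (pe$lambda_max - n) / (n - 1)
  ri <- ri_lookup(n)
  cr <- if (ri == 0) 0 else ci / ri
  structure(list(lambda_max = pe$lambda_max, weights = pe$weights,
                 ci = ci, cr = cr, consistent = cr < 0.1),
            class = "esp_ahp")
}

#' @export
print.esp_ahp <- function(x, ...) {
  cat(sprintf("AHP: lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$ci, x$cr,
              if (x$consistent) "consistent, CR < 0.1" else "NOT consistent"))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Resistance-factor comparison matrix
#'
#' The 5x5 pairwise comparison matrix used to weight the five resistance
#' factors (land use, vegetation coverage, slope, distance to county road,
#' distance to highway), with fractional entries represented exactly. Read
#' from the plain-text copy shipped with the package.
#'
#' @return an `esp_pairwise` object of order 5
#' @export
resistance_comparison_matrix <- function() {
  read_pairwise_matrix(system.file("extdata", "resistance_comparisons.txt",
                                   package = "espmcr", mustWork = TRUE))
}
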