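# Gradient tables (FSL-style .bval / .bvec text files)

B0_THRESHOLD <- 50   # s/mm^2; entries below this count as baseline volumes

#' Construct and validate a gradient scheme
#'
#' A gradient scheme pairs a per-volume b-value (s/mm^2) with a per-volume
#' unit gradient direction. Directions with b > 0 are renormalized to unit
#' length; b = 0 entries may carry a zero vector. Entries with
#' b < 50 s/mm^2 are treated as baseline (b=0) volumes, which tolerates
#' the small nonzero values some scanners write.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions (columns).
#' @return object of class `grad_scheme` with fields `bvals`, `bvecs`,
#'   `n_b0`, `b_shell` (the distinct nonzero b-values) and `single_shell`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.vector(bvals, mode = "numeric")
  bvecs <- as.matrix(bvecs)
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3L)
    stop_format("bvecs must have 3 rows (x, y, z components)")
  if (length(bvals) != ncol(bvecs))
    stop_format("bval/bvec length mismatch: ", length(bvals), " b-values vs ",
                ncol(bvecs), " directions")
  if (length(bvals) < 2L)
    stop_validation("a gradient scheme needs at least 2 volumes")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop_validation("b-values must be finite and non-negative")
  is_b0 <- bvals < B0_THRESHOLD
  if (!any(is_b0))
    stop_validation("no baseline (b=0) volume in scheme")
  nrm <- sqrt(colSums(bvecs^2))
  if (any(!is_b0 & nrm < 1e-8))
    stop_validation("zero-norm gradient direction with b > 0")
  bvecs[, !is_b0] <- sweep(bvecs[, !is_b0, drop = FALSE], 2, nrm[!is_b0], "/")
  bvecs[, is_b0 & nrm < 1e-8] <- 0
  bnz <- bvals[!is_b0]
  # distinct nonzero b-values within relative tolerance 1e-3
  ub <- sort(unique(bnz))
  if (length(ub)) {
    keep <- c(TRUE, diff(ub) / ub[-1] > 1e-3)
    ub <- ub[keep]
  }
  structure(list(bvals = bvals, bvecs = bvecs,
                 n_b0 = sum(is_b0), is_b0 = is_b0,
                 b_shell = ub, single_shell = length(ub) == 1L),
            class = "grad_scheme")
}

#' @export
print.grad_scheme <- function(x, ...) {
  cat("grad_scheme:", length(x$bvals), "volumes (", x$n_b0, "baseline ),",
      if (x$single_shell) paste0("single shell b=", signif(x$b_shell, 6))
      else paste0(length(x$b_shell), " shells"), "\n")
  invisible(x)
}

#' Read an FSL-style gradient table
#'
#' `bval` is one whitespace-separated row of b-values; `bvec` has three
#' rows (x, y, z). A transposed (n x 3) bvec file is auto-detected from its
#' shape and accepted with a warning.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return a validated [gradient_scheme()].
#' @export
read_gradient_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    v[!is.na(v)]
  })
  rows <- rows[lengths(rows) > 0]
  if (!length(rows)) stop_format("empty bvec file: ", bvec_path)
  if (length(unique(lengths(rows))) != 1L)
    stop_format("ragged bvec file: ", bvec_path)
  m <- do.call(rbind, rows)
  if (nrow(m) != 3L && ncol(m) == 3L) {
    warning("bvec file appears transposed (n x 3); transposing on read")
    m <- t(m)
  }
  if (nrow(m) != 3L)
    stop_format("bvec file must have 3 rows (FSL dialect): ", bvec_path)
  gradient_scheme(bvals, m)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradient_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
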