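#' Construct a diffusion gradient table
#'
#' A gradient table pairs each acquired volume with a diffusion weighting
#' (b-value, s/mm^2) and a unit gradient direction. Baseline (b = 0) entries
#' carry a zero direction vector.
#'
#' @param bvals numeric vector of b-values (s/mm^2), all `>= 0`, at least one
#'   equal to zero (the baseline).
#' @param bvecs numeric matrix, one row per entry, 3 columns; unit rows for
#'   weighted entries, zero rows allowed only for baselines.
#' @return An object of class `gradient_table` with elements `bvals`, `bvecs`
#'   and `b0` (baseline indices).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns")
  if (nrow(bvecs) != length(bvals))
    stop("gradient count mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  b0 <- which(bvals == 0)
  if (length(b0) == 0L) stop("gradient table needs at least one b = 0 entry")
  nrm <- sqrt(rowSums(bvecs^2))
  w <- bvals > 0
  if (any(abs(nrm[w] - 1) > 1e-6)) {
    if (any(nrm[w] < 1e-6))
      stop("zero-norm direction paired with b > 0")
    bvecs[w, ] <- bvecs[w, , drop = FALSE] / nrm[w]
  }
  bvecs[!w, ] <- 0
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d entries (%d baseline), b = %s s/mm^2\n",
              length(x$bvals), length(x$b0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_path path to a whitespace-separated b-value file (one row).
#' @param bvec_path path to a 3-row whitespace-separated direction file.
#' @return A [gradient_table()].
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3L) stop("bvec file must have 3 rows, got ", length(rows))
  n <- unique(vapply(rows, length, 1L))
  if (length(n) != 1L)
    stop("bvec rows have unequal lengths: ", paste(vapply(rows, length, 1L),
                                                   collapse = ", "))
  if (n != length(bvals))
    stop("gradient count mismatch: ", length(bvals), " b-values vs ", n,
         " bvec columns")
  gradient_table(bvals, t(do.call(rbind, rows)))
}

#' Write an FSL-style bval/bvec pair
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the gradient table.
#' @export
write_bvalbvec <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(sprintf("%.10f", r), collapse = " ")), bvec_path)
  invisible(gtab)
}

#' Generate the acquisition protocol's gradient table
#'
#' Builds a single-shell gradient table with directions spread over the
#' hemisphere by deterministic electrostatic repulsion (golden-angle spiral
#' initialization followed by fixed-count repulsion sweeps on the antipodally
#' symmetrized set). The default reproduces the emulated clinical protocol:
#' 30 directions, one b = 0 baseline, b = 2000 s/mm^2.
#'
#' @param n_directions number of diffusion-weighted directions (`>= 6`).
#' @param b diffusion weighting of the shell (s/mm^2).
#' @param n_baseline number of b = 0 entries, placed first.
#' @return A [gradient_table()] with `n_baseline + n_directions` entries.
#' @export
make_protocol <- function(n_directions = 30L, b = 2000, n_baseline = 1L) {
  if (n_directions < 6L) stop("at least 6 gradient directions are required")
  if (n_baseline < 1L) stop("at least one baseline entry is required")
  dirs <- repulsion_directions(n_directions)
  bvals <- c(rep(0, n_baseline), rep(b, n_directions))
  bvecs <- rbind(matrix(0, n_baseline, 3L), dirs)
  gradient_table(bvals, bvecs)
}

# Deterministic near-uniform hemisphere directions: Fibonacci spiral start,
# then gradient-descent sweeps on the Coulomb energy of the +/- symmetrized
# point set. No RNG involved.
repulsion_directions <- function(n, sweeps = 80L) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  for (s in seq_len(sweeps)) {
    force <- matrix(0, n, 3L)
    for (a in seq_len(n)) {
      d1 <- sweep(-p, 2L, -p[a, ])               # p_a - p_j
      d2 <- sweep(p, 2L, p[a, ], `+`)            # p_a + p_j
      n1 <- rowSums(d1^2); n2 <- rowSums(d2^2)
      n1[a] <- Inf
      force[a, ] <- colSums(d1 / n1^1.5) + colSums(d2 / pmax(n2, 1e-9)^1.5)
    }
    p <- p + step * force / n
    p <- p / sqrt(rowSums(p^2))
    p[p[, 3L] < 0, ] <- -p[p[, 3L] < 0, , drop = FALSE]
  }
  p
}
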