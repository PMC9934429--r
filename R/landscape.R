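# Dimer-state classification, L-filtering, and Boltzmann-inversion free
# energy landscapes over the (dtheta_A, dtheta_B) rotation plane.

#' Classify the dimerization state from the lateral separation
#'
#' Three states partition L >= 0: dimeric (L < 1.5 nm), pre-dimeric
#' (1.5 <= L < 3 nm) and monomeric (L >= 3 nm). Boundaries are closed on
#' the right-hand state, so L = 1.5 is pre-dimeric and L = 3 is monomeric
#' (while the dimer-focused trajectory filter keeps L <= 3, see
#' [filter_dimeric()]).
#'
#' @param L numeric vector of lateral separations in nm, >= 0.
#' @param dimeric_max,monomeric_min state thresholds in nm.
#' @return factor with levels dimeric, pre_dimeric, monomeric.
#' @export
classify_state <- function(L, dimeric_max = 1.5, monomeric_min = 3.0) {
  if (any(!is.finite(L)) || any(L < 0))
    stop("'L' must be finite and >= 0", call. = FALSE)
  if (dimeric_max <= 0 || monomeric_min <= dimeric_max)
    stop("invalid state thresholds", call. = FALSE)
  out <- ifelse(L < dimeric_max, "dimeric",
                ifelse(L < monomeric_min, "pre_dimeric", "monomeric"))
  factor(out, levels = c("dimeric", "pre_dimeric", "monomeric"))
}

#' Keep frames at dimer-scale separation
#'
#' Retains, in order, the descriptor rows with L <= `L_max` (default 3 nm,
#' i.e. dimeric plus pre-dimeric frames), mirroring the filtering applied
#' before constructing rotation-angle free energy surfaces.
#'
#' @param descriptors data.frame with an `L_nm` (or `L`) column.
#' @param L_max retention threshold in nm (frames with L <= L_max kept).
#' @return the retained rows, with attribute `n_retained`.
#' @export
filter_dimeric <- function(descriptors, L_max = 3.0) {
  col <- if ("L_nm" %in% names(descriptors)) "L_nm" else "L"
  if (!col %in% names(descriptors))
    stop("'descriptors' must carry an L_nm (or L) column", call. = FALSE)
  keep <- descriptors[[col]] <= L_max
  out <- descriptors[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Boltzmann-inversion free energy grid over the rotation plane
#'
#' Histograms the (dtheta_A, dtheta_B) samples on a square grid and inverts
#' the occupancy to a free energy U = -kB T ln p. Two normalization
#' conventions are provided: `"per_bin"` (p = bin probability, so U >= 0
#' with the most occupied bin nearest 0) and `"density"` (p = probability
#' density per rad^2, which shifts U by a constant and can make well depths
#' negative). The convention used is recorded in the grid. Empty bins have
#' U = NA (masked).
#'
#' @param dtheta_A,dtheta_B sample vectors in degrees (equal length, >= 1).
#' @param T temperature in K (default 323, the simulation temperature).
#' @param bin_width bin width in degrees (default 5).
#' @param support numeric length-2: closed lower / open upper grid limits in
#'   degrees applied to both axes (default c(-180, 360), covering unwrapped
#'   rotations up to a full turn).
#' @param convention `"per_bin"` or `"density"`.
#' @return object of class `fes_grid`: list with `edges_A`, `edges_B`,
#'   `counts` (matrix, A rows x B cols), `U` (kcal/mol), `T`, `convention`.
#' @export
fes_2d <- function(dtheta_A, dtheta_B, T = 323, bin_width = 5,
                   support = c(-180, 360),
                   convention = c("per_bin", "density")) {
  convention <- match.arg(convention)
  stopifnot_scalar(T, "T", positive = TRUE)
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (length(dtheta_A) != length(dtheta_B) || !length(dtheta_A))
    stop("need >= 1 paired (dtheta_A, dtheta_B) samples", call. = FALSE)
  ok <- is.finite(dtheta_A) & is.finite(dtheta_B)
  dtheta_A <- dtheta_A[ok]; dtheta_B <- dtheta_B[ok]
  if (!length(dtheta_A)) stop("no finite samples", call. = FALSE)
  edges <- seq(support[1L], support[2L], by = bin_width)
  if (edges[length(edges)] < support[2L])
    edges <- c(edges, edges[length(edges)] + bin_width)
  ia <- findInterval(dtheta_A, edges, rightmost.closed = TRUE)
  ib <- findInterval(dtheta_B, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  if (any(ia < 1L | ia > nb | ib < 1L | ib > nb))
    stop("samples fall outside the grid support; widen 'support'",
         call. = FALSE)
  counts <- matrix(0, nb, nb)
  for (s in seq_along(ia)) counts[ia[s], ib[s]] <- counts[ia[s], ib[s]] + 1
  fes_from_counts(counts, edges, edges, T, convention)
}

# Invert a count matrix into a fes_grid.
fes_from_counts <- function(counts, edges_A, edges_B, T, convention) {
  total <- sum(counts)
  p <- counts / total
  if (convention == "density") {
    wA <- deg2rad(diff(edges_A))
    wB <- deg2rad(diff(edges_B))
    p <- p / outer(wA, wB)
  }
  U <- -KB_KCAL * T * log(p)
  U[counts == 0] <- NA_real_
  structure(list(edges_A = edges_A, edges_B = edges_B, counts = counts,
                 U = U, T = T, convention = convention),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf(
    "fes_grid: %d x %d bins (%d occupied), %d samples, T = %g K, %s convention\n",
    nrow(x$counts), ncol(x$counts), occ, sum(x$counts), x$T, x$convention))
  if (occ)
    cat(sprintf("  U range over occupied bins: %.3f .. %.3f kcal/mol\n",
                min(x$U, na.rm = TRUE), max(x$U, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fes_grid <- function(x, ...) {
  midA <- (x$edges_A[-length(x$edges_A)] + x$edges_A[-1L]) / 2
  midB <- (x$edges_B[-length(x$edges_B)] + x$edges_B[-1L]) / 2
  graphics::image(midA, midB, x$U,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = expression(Delta * theta[A] ~ "(deg)"),
                  ylab = expression(Delta * theta[B] ~ "(deg)"), ...)
  invisible(x)
}

#' Average free energy surfaces by pooling their histograms
#'
#' Counts are summed across grids and re-inverted to U; averaging is done
#' on the occupancies, not on the free energies, so empty-bin masking and
#' the Boltzmann weighting remain exact.
#'
#' @param grids list of `fes_grid`s with identical bin edges, temperature
#'   and convention.
#' @return a pooled `fes_grid`.
#' @export
average_fes <- function(grids) {
  if (!length(grids) || !all(vapply(grids, inherits, TRUE, "fes_grid")))
    stop("'grids' must be a non-empty list of fes_grid objects", call. = FALSE)
  g1 <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!isTRUE(all.equal(g$edges_A, g1$edges_A)) ||
        !isTRUE(all.equal(g$edges_B, g1$edges_B)))
      stop("all grids must share identical bin edges", call. = FALSE)
    if (g$T != g1$T || g$convention != g1$convention)
      stop("all grids must share temperature and convention", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(grids, `[[`, "counts"))
  fes_from_counts(counts, g1$edges_A, g1$edges_B, g1$T, g1$convention)
}

#' Rectangular window in the rotation plane
#'
#' @param dtheta_A_range,dtheta_B_range closed intervals in degrees.
#' @return object of class `region_window`.
#' @export
region_window <- function(dtheta_A_range, dtheta_B_range) {
  chk <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L])
      stop(sprintf("'%s' must be a non-empty interval c(lo, hi)", nm),
           call. = FALSE)
    as.numeric(r)
  }
  structure(list(dtheta_A_range = chk(dtheta_A_range, "dtheta_A_range"),
                 dtheta_B_range = chk(dtheta_B_range, "dtheta_B_range")),
            class = "region_window")
}

#' Mean descriptors inside a rotation-plane window
#'
#' Arithmetic means of the crossing angle, L and delta-d over the frames
#' whose (dtheta_A, dtheta_B) lie in the window — the per-region structural
#' summary used to characterize free-energy basins.
#'
#' @param descriptors descriptor data.frame (see [analyze_frames()]).
#' @param window a [region_window()].
#' @return list with `n`, `mean_omega`, `mean_L`, `mean_delta_d`; when no
#'   frame falls in the window, `n = 0` and the means are NA (an explicitly
#'   empty result, not zeros).
#' @export
region_summary <- function(descriptors, window) {
  if (!inherits(window, "region_window"))
    stop("'window' must be a region_window", call. = FALSE)
  a <- descriptors$dtheta_A_deg
  b <- descriptors$dtheta_B_deg
  inw <- a >= window$dtheta_A_range[1L] & a <= window$dtheta_A_range[2L] &
         b >= window$dtheta_B_range[1L] & b <= window$dtheta_B_range[2L]
  inw[is.na(inw)] <- FALSE
  if (!any(inw))
    return(list(n = 0L, mean_omega = NA_real_, mean_L = NA_real_,
                mean_delta_d = NA_real_))
  list(n = sum(inw),
       mean_omega = mean(descriptors$omega_deg[inw]),
       mean_L = mean(descriptors$L_nm[inw]),
       mean_delta_d = mean(descriptors$delta_d_nm[inw]))
}
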