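# Interhelical residue-residue contact scoring (RRCS-style piecewise-linear
# distance kernel), top-pair ranking and concordance between pair lists.

#' Contact-kernel parameters
#'
#' The published residue-residue contact score kernel operates on heavy-atom
#' distances with full weight inside 3.23 Angstrom and zero beyond 4.63
#' Angstrom (`"atomistic"`, the default, expressed here in nm). For
#' coarse-grained backbone beads a scaled, non-canonical variant with wider
#' cutoffs (4.7 / 7.0 Angstrom) is provided as `"cg"`; back-mapped atomistic
#' structures remain the canonical scoring input.
#'
#' @param mode `"atomistic"` or `"cg"`.
#' @param inner,outer optional explicit cutoffs in nm (inner < outer),
#'   overriding the mode presets.
#' @return list with `inner`, `outer` (nm) and `mode`.
#' @export
rrcs_params <- function(mode = c("atomistic", "cg"), inner = NULL,
                        outer = NULL) {
  mode <- match.arg(mode)
  preset <- switch(mode, atomistic = c(0.323, 0.463), cg = c(0.47, 0.70))
  inner <- if (is.null(inner)) preset[1L] else inner
  outer <- if (is.null(outer)) preset[2L] else outer
  stopifnot_scalar(inner, "inner", positive = TRUE)
  stopifnot_scalar(outer, "outer", positive = TRUE)
  if (inner >= outer)
    stop("'inner' cutoff must be smaller than 'outer'", call. = FALSE)
  list(inner = inner, outer = outer, mode = mode)
}

#' Contact score between two residues
#'
#' Sum over all cross-residue atom (or bead) pairs of a piecewise-linear
#' kernel of the pair distance d: weight 1 for d <= inner cutoff, 0 for
#' d >= outer cutoff, and (outer - d) / (outer - inner) in between.
#'
#' @param coords_i,coords_j coordinate matrices (n x 3, nm) of the atoms or
#'   beads of the two residues.
#' @param params kernel parameters from [rrcs_params()].
#' @return non-negative score.
#' @export
contact_score <- function(coords_i, coords_j, params = rrcs_params()) {
  A <- rbind(as.matrix(coords_i)); B <- rbind(as.matrix(coords_j))
  if (!nrow(A) || !nrow(B))
    stop("residue coordinate sets must be non-empty", call. = FALSE)
  d <- sqrt(pmax(0, cross_dist2(A, B)))
  w <- pmin(1, pmax(0, (params$outer - d) / (params$outer - params$inner)))
  sum(w)
}

#' Interhelical contact table for one frame
#'
#' Scores every cross-chain residue pair in `residue_range` (intra-chain
#' pairs are excluded by construction). With one bead per residue this is a
#' bead-pair kernel; on back-mapped atomistic input pass per-residue atom
#' sets via `atoms_A` / `atoms_B`.
#'
#' @param frame a `bead_frame` (rownames carry residue numbers).
#' @param residue_range residue numbers scored (default 765:789, the TMD
#'   core after excluding terminal loop residues).
#' @param params kernel parameters from [rrcs_params()]; defaults to the
#'   `"cg"` preset for bead input.
#' @param atoms_A,atoms_B optional named lists (by residue number) of atom
#'   coordinate matrices replacing the single-bead coordinates.
#' @return data.frame of class `contact_table` with columns res_A, res_B,
#'   score, one row per cross-chain pair; residues missing from a chain are
#'   reported in attribute `missing` and their pairs omitted.
#' @export
interhelical_table <- function(frame, residue_range = 765:789,
                               params = rrcs_params("cg"),
                               atoms_A = NULL, atoms_B = NULL) {
  getres <- function(mat, atoms, r) {
    if (!is.null(atoms)) return(atoms[[as.character(r)]])
    i <- match(as.character(r), rownames(mat))
    if (is.na(i)) NULL else mat[i, , drop = FALSE]
  }
  presentA <- residue_range[vapply(residue_range, function(r)
    !is.null(getres(frame$A, atoms_A, r)), logical(1L))]
  presentB <- residue_range[vapply(residue_range, function(r)
    !is.null(getres(frame$B, atoms_B, r)), logical(1L))]
  missing <- sort(unique(c(setdiff(residue_range, presentA),
                           setdiff(residue_range, presentB))))
  grid <- expand.grid(res_A = presentA, res_B = presentB,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- vapply(seq_len(nrow(grid)), function(q)
    contact_score(getres(frame$A, atoms_A, grid$res_A[q]),
                  getres(frame$B, atoms_B, grid$res_B[q]), params),
    numeric(1L))
  structure(grid, missing = missing,
            class = c("contact_table", "data.frame"))
}

#' Top-ranked contacting residue pairs
#'
#' Pairs ordered by score descending; ties broken deterministically by
#' (res_A, res_B) ascending.
#'
#' @param table a `contact_table`.
#' @param n number of pairs (default 30).
#' @return data.frame of class `pair_list` with the top `n` rows.
#' @export
top_pairs <- function(table, n = 30L) {
  o <- order(-table$score, table$res_A, table$res_B)
  out <- table[o[seq_len(min(n, nrow(table)))], , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pair_list", "data.frame"))
}

#' Concordance between two ranked pair lists
#'
#' Overlap of the two lists as unordered residue pairs ({i, j} = {j, i}),
#' the overlap fraction, and a pass flag that fires when more than
#' `pass_above` pairs are shared (default 25 of 30, i.e. better than 80%
#' agreement).
#'
#' @param list_a,list_b `pair_list`s of equal length.
#' @param pass_above pass when overlap is strictly greater than this.
#' @return list with `overlap`, `fraction`, `pass`.
#' @export
concordance <- function(list_a, list_b, pass_above = 25L) {
  if (nrow(list_a) != nrow(list_b))
    stop("pair lists must have equal length", call. = FALSE)
  key <- function(l) paste(pmin(l$res_A, l$res_B), pmax(l$res_A, l$res_B))
  overlap <- length(intersect(key(list_a), key(list_b)))
  list(overlap = overlap, fraction = overlap / nrow(list_a),
       pass = overlap > pass_above)
}
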