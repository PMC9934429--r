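# Structure I/O: multi-model PDB and (multi-frame) GRO readers and writers
# for two-chain backbone-bead selections, plus the descriptor CSV table.
# All in-memory coordinates are nm; PDB files are Angstrom per the format.

#' Backbone bead selection
#'
#' @param chainA,chainB distinct chain identifiers.
#' @param residue_range inclusive residue-number interval, default 765:792
#'   (the 25 TMD residues 765-789 plus 3 linker residues).
#' @param bead_name backbone bead/atom name; `"BB"` for coarse-grained
#'   MARTINI input.
#' @param fallback_name alternative atom name tried when `bead_name` is
#'   absent (default `"CA"` for atomistic input); set NULL to disable.
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(chainA = "A", chainB = "B",
                           residue_range = 765:792,
                           bead_name = "BB", fallback_name = "CA") {
  if (identical(chainA, chainB))
    stop("'chainA' and 'chainB' must be distinct", call. = FALSE)
  residue_range <- sort(unique(as.integer(residue_range)))
  if (!length(residue_range))
    stop("'residue_range' must be non-empty", call. = FALSE)
  structure(list(chainA = chainA, chainB = chainB,
                 residue_range = residue_range,
                 bead_name = bead_name, fallback_name = fallback_name),
            class = "selection_spec")
}

#' Read a multi-frame dimer structure
#'
#' Reads a multi-model PDB (via bio3d) or a concatenated multi-frame GRO
#' file and extracts the selected backbone beads of the two chains.
#' Coordinates are returned in nm regardless of source format; beads are
#' sorted by residue number within each chain. Frames without explicit time
#' stamps are stamped (model index - 1) * dt. Input is assumed pre-imaged
#' (no periodic-boundary treatment is applied; GRO box lines are ignored).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param selection a [selection_spec()].
#' @param dt frame interval used for time stamps.
#' @return a `dimer_frames` object.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "gro"),
                        selection = selection_spec(), dt = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  raw <- if (format == "pdb") read_raw_pdb(path) else read_raw_gro(path)
  frames <- lapply(seq_along(raw), function(s) {
    tab <- raw[[s]]
    A <- select_chain(tab, selection$chainA, selection, path)
    B <- select_chain(tab, selection$chainB, selection, path)
    bead_frame(A, B, time = (s - 1) * dt)
  })
  dimer_frames(frames, dt = dt)
}

# Extract one chain's beads as an n x 3 nm matrix, residue-sorted.
select_chain <- function(tab, chain, selection, path) {
  sub <- tab[tab$chain == chain & tab$resno %in% selection$residue_range, ,
             drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("chain '%s' not found in '%s' (chains present: %s)",
                 chain, path, paste(unique(tab$chain), collapse = ", ")),
         call. = FALSE)
  name <- selection$bead_name
  hit <- sub[sub$elety == name, , drop = FALSE]
  if (!nrow(hit) && !is.null(selection$fallback_name)) {
    name <- selection$fallback_name
    hit <- sub[sub$elety == name, , drop = FALSE]
  }
  if (!nrow(hit))
    stop(sprintf("no '%s' (or fallback) beads on chain '%s'",
                 selection$bead_name, chain), call. = FALSE)
  hit <- hit[order(hit$resno), , drop = FALSE]
  if (anyDuplicated(hit$resno))
    stop(sprintf("duplicate '%s' beads for a residue on chain '%s'",
                 name, chain), call. = FALSE)
  missing <- setdiff(selection$residue_range, hit$resno)
  if (length(missing))
    stop(sprintf("chain '%s' is missing residues %s in the selected range",
                 chain, paste(missing, collapse = ", ")), call. = FALSE)
  xyz <- as.matrix(hit[, c("x", "y", "z")])
  rownames(xyz) <- as.character(hit$resno)
  xyz
}

# Per-model atom tables from a (multi-model) PDB, coordinates converted to nm.
read_raw_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  nf <- nrow(pdb$xyz)
  lapply(seq_len(nf), function(s) {
    xyz <- matrix(pdb$xyz[s, ], ncol = 3L, byrow = TRUE)
    data.frame(chain = atom$chain, resno = atom$resno, elety = atom$elety,
               x = xyz[, 1L] / 10, y = xyz[, 2L] / 10, z = xyz[, 3L] / 10,
               stringsAsFactors = FALSE)
  })
}

# Minimal multi-frame GRO parser (fixed-width; box line ignored). A frame is
# title line, atom count, atoms, box; frames may be concatenated.
read_raw_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stop(sprintf("malformed GRO file '%s': bad atom count at line %d",
                   path, i + 1L), call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + natoms)]
    frames[[length(frames) + 1L]] <- data.frame(
      # GRO has no chain field; the residue name carries the chain label here
      chain = trimws(substr(block, 6L, 10L)),
      resno = as.integer(substr(block, 1L, 5L)),
      elety = trimws(substr(block, 11L, 15L)),
      x = as.numeric(substr(block, 21L, 28L)),
      y = as.numeric(substr(block, 29L, 36L)),
      z = as.numeric(substr(block, 37L, 44L)),
      stringsAsFactors = FALSE)
    i <- i + natoms + 3L   # title + count + atoms + box
  }
  if (!length(frames))
    stop(sprintf("no frames found in GRO file '%s'", path), call. = FALSE)
  frames
}

#' Write a trajectory as a multi-model PDB file
#'
#' One residue per bead, chains as labeled in the frames, coordinates
#' converted nm to Angstrom. The generator seed, when known, is recorded in
#' a REMARK header.
#'
#' @param frames a `dimer_frames` object.
#' @param path output file.
#' @param bead_name atom name written (default `"BB"`).
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path, bead_name = "BB") {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(frames, "seed")
  if (!is.null(seed) && !is.na(seed))
    writeLines(sprintf("REMARK   6 GENERATOR SEED %d", seed), con)
  for (s in seq_along(frames)) {
    fr <- frames[[s]]
    writeLines(sprintf("MODEL     %4d", s), con)
    serial <- 0L
    for (ch in c("A", "B")) {
      xyz <- fr[[ch]] * 10   # nm -> Angstrom
      resno <- as.integer(rownames(xyz))
      for (i in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, bead_name, "ALA", ch, resno[i],
          xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]), con)
      }
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Coordinates in nm per the format; the chain label is stored in the
#' residue-name field (GRO has no chain column). A large dummy box line is
#' written for each frame.
#'
#' @inheritParams write_frames_pdb
#' @return `path`, invisibly.
#' @export
write_frames_gro <- function(frames, path, bead_name = "BB") {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(frames, "seed")
  for (s in seq_along(frames)) {
    title <- sprintf("helix dimer frame %d t=%g%s", s, frames[[s]]$time,
                     if (!is.null(seed) && !is.na(seed))
                       sprintf(" seed=%d", seed) else "")
    writeLines(title, con)
    n <- nrow(frames[[s]]$A) + nrow(frames[[s]]$B)
    writeLines(sprintf("%5d", n), con)
    serial <- 0L
    for (ch in c("A", "B")) {
      xyz <- frames[[s]][[ch]]
      resno <- as.integer(rownames(xyz))
      for (i in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                           resno[i], ch, bead_name, serial,
                           xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]), con)
      }
    }
    writeLines("  20.00000  20.00000  20.00000", con)
  }
  invisible(path)
}

#' Write the per-frame descriptor table
#'
#' CSV with one row per frame and columns time, omega_deg, L_nm, delta_d_nm,
#' dtheta_A_deg, dtheta_B_deg, state. A '#'-prefixed header documents the
#' package version and the conventions in force.
#'
#' @param records a data.frame of descriptors (see [analyze_frames()]).
#' @param path output file.
#' @param conventions optional named character vector appended to the header.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(records, path, conventions = NULL) {
  if (!is.data.frame(records) || !nrow(records))
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# helixdimer %s descriptor table",
            as.character(utils::packageVersion("helixdimer"))),
    "# omega_deg: signed crossing angle, negative = left-handed packing",
    "# L_nm: lateral helix separation; delta_d_nm: d(N-termini) - d(C-termini)",
    "# dtheta_*_deg: unwrapped helix rotation relative to frame 0, CCW positive",
    if (!is.null(conventions))
      paste0("# ", names(conventions), ": ", conventions)), con)
  utils::write.table(format(records, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a descriptor table written by [write_descriptors()]
#'
#' @param path CSV file.
#' @return data.frame of descriptors.
#' @export
read_descriptors <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
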