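#' Molecular topology table
#'
#' Per-atom metadata for trajectory analysis: names, residues, group
#' labels, partial charges and Lennard-Jones parameters. Named selections
#' (e.g. probe ring atoms, acyl chains, hydrogen-bond donors) are carried
#' alongside as lists of atom indices.
#'
#' @param atoms Data frame with columns `name`, `resname`, `resid`,
#'   `group`, `charge` (e), `sigma` (A), `epsilon` (kcal/mol), `mass`
#'   (amu). Row order defines the (1-based) atom indexing.
#' @param selections Named list of integer atom-index vectors.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, selections = list()) {
  req <- c("name", "resname", "resid", "group", "charge", "sigma",
           "epsilon", "mass")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("topology table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(atoms$charge))) stop("charges must be finite")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0))
    stop("LJ sigma and epsilon must be non-negative")
  n <- nrow(atoms)
  for (nm in names(selections)) {
    idx <- selections[[nm]]
    if (any(idx < 1L | idx > n))
      stop("selection '", nm, "' references atoms outside the topology")
  }
  structure(list(atoms = atoms, selections = selections, n_atoms = n),
            class = "topology")
}

#' Multi-frame Cartesian trajectory
#'
#' @param coords List of `n_atoms x 3` coordinate matrices in Angstrom
#'   (one per frame), or a 3-D array `n_atoms x 3 x n_frames`.
#' @param box Orthorhombic box lengths in Angstrom: length-3 vector
#'   (constant box) or `n_frames x 3` matrix.
#' @param times Optional frame times in ns.
#' @return An object of class `trajectory` with elements `coords`
#'   (array `n_atoms x 3 x n_frames`), `box` (`n_frames x 3`), `times`.
#' @export
trajectory <- function(coords, box, times = NULL) {
  if (is.list(coords)) {
    n_frames <- length(coords)
    if (n_frames < 1L) stop("trajectory needs at least one frame")
    n_atoms <- nrow(coords[[1L]])
    arr <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      if (nrow(coords[[f]]) != n_atoms)
        stop("atom count changes between frames")
      arr[, , f] <- as.matrix(coords[[f]])
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  n_frames <- dim(coords)[3L]
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3L, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L)
    stop("box must be a length-3 vector or n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be positive")
  structure(list(coords = coords, box = box, times = times,
                 n_atoms = dim(coords)[1L], n_frames = n_frames),
            class = "trajectory")
}

#' Resolve an atom selection against a topology
#'
#' @param topo A [topology()].
#' @param selection A named selection stored in the topology, an integer
#'   index vector, or a logical mask.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(topo, selection) {
  if (!inherits(topo, "topology")) stop("`topo` must be a topology")
  idx <- if (is.character(selection) && length(selection) == 1L) {
    if (!selection %in% names(topo$selections))
      stop("unknown selection '", selection, "'; available: ",
           paste(names(topo$selections), collapse = ", "))
    topo$selections[[selection]]
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
  if (length(idx) == 0L) stop("empty atom selection")
  sort(unique(idx))
}

# mass-weighted center of a coordinate block
.center_of_mass <- function(xyz, mass) {
  w <- mass / sum(mass)
  colSums(xyz * w)
}

# minimum-image displacement(s) under an orthorhombic box;
# dx may be a vector or an n x 3 matrix
.min_image <- function(dx, box) {
  if (is.matrix(dx)) {
    for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  } else {
    dx <- dx - box * round(dx / box)
  }
  dx
}

#' Read a topology table from a delimited text file
#'
#' Expects columns
#' `index,name,resname,resid,group,charge_e,sigma_A,epsilon_kcal,mass_amu`.
#' An optional selections file holds one selection per line,
#' `name = spec`, where spec is either a comma-separated list of atom
#' indices, `group=LABEL`, or `resname=NAME`.
#'
#' @param path Topology table path.
#' @param selections_path Optional selections config path.
#' @return A [topology()].
#' @export
read_topology <- function(path, selections_path = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         comment.char = "#", stringsAsFactors = FALSE)
  atoms <- data.frame(name = as.character(d$name),
                      resname = as.character(d$resname),
                      resid = as.integer(d$resid),
                      group = as.character(d$group),
                      charge = as.numeric(d$charge_e),
                      sigma = as.numeric(d$sigma_A),
                      epsilon = as.numeric(d$epsilon_kcal),
                      mass = as.numeric(d$mass_amu))
  sels <- list()
  if (!is.null(selections_path)) {
    lines <- readLines(selections_path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (l in lines) {
      parts <- strsplit(l, "=", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop("malformed selection line: ", l)
      nm <- trimws(parts[1L])
      val <- trimws(paste(parts[-1L], collapse = "="))
      if (startsWith(val, "group:")) {
        sels[[nm]] <- which(atoms$group == trimws(sub("^group:", "", val)))
      } else if (startsWith(val, "resname:")) {
        sels[[nm]] <- which(atoms$resname == trimws(sub("^resname:", "", val)))
      } else {
        sels[[nm]] <- as.integer(strsplit(val, ",")[[1L]])
      }
    }
  }
  topology(atoms, sels)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; the (constant) box goes into a
#' CRYST1 record. Element symbols are taken from the first character of
#' the atom name.
#'
#' @param traj A [trajectory()] (the box must be constant across frames).
#' @param topo A [topology()] with matching atom count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, topo, path) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  if (topo$n_atoms != traj$n_atoms)
    stop("topology and trajectory atom counts differ")
  if (any(apply(traj$box, 2L, function(b) diff(range(b))) > 1e-9))
    warning("box varies across frames; CRYST1 records the first frame only")
  at <- topo$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     traj$box[1L, 1L], traj$box[1L, 2L], traj$box[1L, 3L]), con)
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f]
    writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(at)) %% 100000L,
                       substr(at$name, 1L, 4L), substr(at$resname, 1L, 3L),
                       at$resid %% 10000L,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L],
                       substr(at$name, 1L, 1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Coordinates are parsed with `bio3d::read.pdb(multi = TRUE)`; the box is
#' taken from the CRYST1 record (required, orthorhombic).
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB trajectories requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz   # n_frames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr) == 0L) stop("no CRYST1 record: box unknown")
  box <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                      substr(cr[1L], 25, 33)))
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory(coords, box)
}
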