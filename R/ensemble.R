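## Core containers: parsed topology + coordinate frames, selection, tabular I/O.
##
## Coordinates are Angstrom throughout. Frames are assumed pre-wrapped and whole
## (no periodic-boundary imaging is performed anywhere in this package); residue
## ids are taken verbatim from the source PDB.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a structure model
#'
#' @param atoms data.frame with columns serial, name, element, resname, resid,
#'   chain, and optionally role. Masses and the hydrogen flag are derived from
#'   the element.
#' @param roles named character vector mapping chain id to one of
#'   heavy, light, antigen, water, ion. Waters/ions may alternatively be
#'   recognised by residue name via `water_names` / `ion_names`.
#' @param water_names,ion_names residue names assigned role water / ion
#'   irrespective of chain.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, roles = character(),
                            water_names = c("HOH", "WAT", "SOL", "TIP3"),
                            ion_names = c("NA", "CL", "K", "MG", "CA2", "MN", "ZN")) {
  need <- c("serial", "name", "element", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  atoms$is_hydrogen <- toupper(trimws(atoms$element)) == "H"
  if (length(roles)) {
    bad <- setdiff(names(roles), unique(atoms$chain))
    if (length(bad)) {
      stop("configuration error: role map names unknown chain(s): ",
           paste(bad, collapse = ", "))
    }
    ok <- roles %in% c("heavy", "light", "antigen", "water", "ion")
    if (!all(ok)) stop("invalid role(s): ", paste(unique(roles[!ok]), collapse = ", "))
  }
  role <- rep(NA_character_, nrow(atoms))
  hit <- atoms$chain %in% names(roles)
  role[hit] <- unname(roles[atoms$chain[hit]])
  role[atoms$resname %in% water_names] <- "water"
  role[atoms$resname %in% ion_names] <- "ion"
  atoms$role <- role
  structure(list(atoms = atoms, roles = roles), class = "structure_model")
}

#' Construct an ensemble (topology + T coordinate frames)
#'
#' @param topology a `structure_model`.
#' @param frames numeric array T x N x 3 (or N x 3 matrix for T = 1), Angstrom.
#' @param frame_stride_ps optional picoseconds between deposited frames.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(topology, frames, frame_stride_ps = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.matrix(frames)) frames <- array(frames, dim = c(1, dim(frames)))
  if (length(dim(frames)) != 3 || dim(frames)[3] != 3) {
    stop("frames must be a T x N x 3 array")
  }
  if (dim(frames)[2] != nrow(topology$atoms)) {
    stop("frame atom count (", dim(frames)[2], ") != topology atom count (",
         nrow(topology$atoms), ")")
  }
  if (!all(is.finite(frames))) stop("non-finite coordinates in frames")
  structure(list(topology = topology, frames = frames,
                 frame_stride_ps = frame_stride_ps),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", dim(x$frames)[1], "frame(s),", dim(x$frames)[2], "atoms\n")
  rl <- x$topology$atoms$role
  cat("  roles:", paste(sprintf("%s=%d", names(table(rl)), table(rl)), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @export
n_frames <- function(ens) dim(ens$frames)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @param ens an `ensemble`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(ens, i) {
  stopifnot(i >= 1, i <= dim(ens$frames)[1])
  matrix(ens$frames[i, , ], ncol = 3)
}

## ---------------------------------------------------------------------------
## PDB I/O (multi-model), via bio3d

# Count atoms per MODEL block up front so mismatches are reported with the
# offending model index (bio3d would silently recycle or fail obscurely).
.check_model_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) <= 1) return(invisible(NULL))
  ends <- which(trimws(rec) == "ENDMDL")
  if (length(ends) != length(model_starts)) stop("unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, ends)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("model %d: expected %d atoms, found %d",
                 bad, counts[1], counts[bad]))
  }
  invisible(NULL)
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Reads ATOM/HETATM records of every MODEL (or the single model if no MODEL
#' records are present), assigns chain roles from the configuration, and
#' derives masses from element symbols (falling back to the first character of
#' the atom name when the element column is blank).
#'
#' @param path PDB file path.
#' @param config list with optional entries `chains` (named list/vector
#'   chain id -> role), `water_names`, `ion_names`, `frame_stride_ps`. See
#'   [read_config()].
#' @return an [ensemble()].
#' @export
read_ensemble <- function(path, config = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  .check_model_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- trimws(at$elesy)
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    # fall back: element from atom name (strip digits; two-letter monatomic
    # ions keep both letters, everything else keeps the first)
    nm <- gsub("[0-9']", "", trimws(at$elety[blank]))
    two <- nm %in% c("NA", "CL", "MG", "ZN", "MN", "K", "CA2")
    elesy[blank] <- ifelse(two, sub("2$", "", nm), substr(nm, 1, 1))
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elesy, resname = trimws(at$resid),
                      resid = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  roles <- config$chains
  if (!is.null(roles)) roles <- unlist(roles)
  if (is.null(roles)) roles <- character()
  args <- list(atoms = atoms, roles = roles)
  if (!is.null(config$water_names)) args$water_names <- config$water_names
  if (!is.null(config$ion_names)) args$ion_names <- config$ion_names
  model <- do.call(structure_model, args)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  tt <- nrow(xyz)
  n <- ncol(xyz) / 3
  frames <- array(NA_real_, dim = c(tt, n, 3))
  for (k in 1:3) frames[, , k] <- xyz[, seq(k, by = 3, length.out = n), drop = FALSE]
  ensemble(model, frames, frame_stride_ps = config$frame_stride_ps)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an [ensemble()].
#' @param path output file path.
#' @export
write_ensemble <- function(ens, path) {
  at <- ens$topology$atoms
  tt <- dim(ens$frames)[1]
  n <- nrow(at)
  xyz <- matrix(NA_real_, nrow = tt, ncol = 3 * n)
  for (k in 1:3) xyz[, seq(k, by = 3, length.out = n)] <- ens$frames[, , k]
  type <- ifelse(at$role %in% c("water", "ion") & !is.na(at$role), "HETATM", "ATOM")
  bio3d::write.pdb(file = path, xyz = xyz, type = type, eleno = at$serial,
                   elety = at$name, resid = at$resname, resno = at$resid,
                   chain = at$chain, elesy = at$element)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Selection

#' Select atom indices from a structure model
#'
#' All arguments are filters combined with AND; `NULL` means "no constraint".
#' The result is a deterministic, sorted integer index vector. An empty result
#' raises a warning, not an error.
#'
#' @param model a `structure_model` (or an `ensemble`, whose topology is used).
#' @param chain chain ids.
#' @param resid residue ids (vector; use `a:b` for ranges).
#' @param resname residue names.
#' @param name atom names.
#' @param role roles (heavy, light, antigen, water, ion).
#' @param heavy if TRUE, drop hydrogens.
#' @param backbone if TRUE, keep only N, CA, C, O.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(model, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, role = NULL, heavy = FALSE,
                         backbone = FALSE) {
  if (inherits(model, "ensemble")) model <- model$topology
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(role)) keep <- keep & !is.na(at$role) & at$role %in% role
  if (heavy) keep <- keep & !at$is_hydrogen
  if (backbone) keep <- keep & at$name %in% BACKBONE_NAMES
  idx <- which(keep)
  if (!length(idx)) warning("selection is empty")
  idx
}

## ---------------------------------------------------------------------------
## Tabular output and configuration

#' Write a result table as CSV
#'
#' Header included; numeric columns rendered at 6 significant digits; row
#' order is preserved (callers emit deterministic orders).
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records is NULL")
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Recognised top-level entries: `chains` (chain id -> role), `cdr_ranges`
#' (loop label -> list(chain, resid range)), `water_names`, `ion_names`,
#' `criteria` (overrides for [interaction_criteria()]), `seed`, `stride`,
#' `bin_width`, `cluster_threshold`, plus free-form path entries used by
#' [run_pipeline()].
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
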