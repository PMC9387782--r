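# Structure, trajectory and table I/O plus atom selections.
#
# Containers are plain S3 lists:
#   topology:   list(atoms = data.frame) -- one row per atom
#   trajectory: list(topology, coords = array(frames x atoms x 3), box, times)
#   selection:  integer vector of 1-based atom indices with a label attribute

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)
SOLVENT_RES <- c("HOH", "WAT", "TIP3", "SOL", "SPC")
ION_ELEMENTS <- c("ZN", "NA", "K", "CL", "MG", "CA", "FE", "MN", "CU", "BR", "I", "LI")

# atomic masses (amu) and fallback radii (A, Bondi-like van der Waals)
ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, ZN = 65.38, "NA" = 22.990,
  K = 39.098, MG = 24.305, CA = 40.078, FE = 55.845, MN = 54.938, CU = 63.546,
  LI = 6.94, SE = 78.971, B = 10.81
)
ELEMENT_RADIUS <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, ZN = 1.39, "NA" = 2.27,
  K = 2.75, MG = 1.73, CA = 2.31, FE = 1.40, MN = 1.40, CU = 1.40,
  LI = 1.82, SE = 1.90, B = 1.92
)

validation_error <- function(...) {
  stop(structure(
    class = c("trajthermo_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Construct a topology
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `mass`, `charge`, `sigma`, `epsilon`,
#'   `pb_radius`, `role`. Missing parameter columns are filled with element
#'   defaults (mass, pb_radius) or zeros (charge, sigma, epsilon).
#' @return `topology` object.
#' @export
new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    validation_error("topology atoms missing columns: ", paste(missing, collapse = ", "))
  }
  atoms$element <- toupper(atoms$element)
  if (anyDuplicated(atoms$serial)) {
    dup <- atoms$serial[duplicated(atoms$serial)][1]
    validation_error("duplicate atom serial ", dup)
  }
  unknown <- !(atoms$element %in% names(ELEMENT_MASS))
  if (any(unknown)) {
    i <- which(unknown)[1]
    validation_error(
      "unknown element '", atoms$element[i], "' in record serial ",
      atoms$serial[i], " (", atoms$resname[i], " ", atoms$name[i], ")"
    )
  }
  if (is.null(atoms$mass)) atoms$mass <- unname(ELEMENT_MASS[atoms$element])
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$sigma)) atoms$sigma <- 0
  if (is.null(atoms$epsilon)) atoms$epsilon <- 0
  if (is.null(atoms$pb_radius)) atoms$pb_radius <- unname(ELEMENT_RADIUS[atoms$element])
  if (is.null(atoms$role)) atoms$role <- infer_role(atoms)
  if (any(atoms$mass <= 0)) validation_error("atom masses must be positive")
  if (any(atoms$epsilon < 0)) validation_error("LJ epsilon must be non-negative")
  if (any(atoms$pb_radius < 0)) validation_error("PB radii must be non-negative")
  # residues must be contiguous runs of (chain, resid, resname)
  key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "|")
  runs <- rle(key)$values
  if (anyDuplicated(runs)) {
    validation_error("residue atom ranges are not contiguous: ", runs[duplicated(runs)][1])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "topology")
}

infer_role <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "|")
  res_size <- table(key)
  role <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    rn <- atoms$resname[i]
    if (rn %in% STANDARD_AA) {
      role[i] <- "protein"
    } else if (rn %in% SOLVENT_RES) {
      role[i] <- "solvent"
    } else if (res_size[[key[i]]] == 1 && atoms$element[i] %in% ION_ELEMENTS) {
      role[i] <- "ion"
    } else {
      role[i] <- "ligand"
    }
  }
  role
}

#' Number of atoms in a topology or trajectory
#' @param x topology or trajectory
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Number of frames in a trajectory
#' @param traj trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Construct a trajectory ensemble
#'
#' @param topology `topology` object.
#' @param coords numeric array `n_frames x n_atoms x 3` (A), or a single
#'   `n_atoms x 3` matrix for a one-frame ensemble.
#' @param box optional length-3 orthorhombic box lengths (A).
#' @param times optional frame times (ps); defaults to `0:(n-1)`.
#' @return `trajectory` object.
#' @export
new_trajectory <- function(topology, coords, box = NULL, times = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != n_atoms(topology)) {
    validation_error(
      "coordinate array has ", dim(coords)[2], " atoms; topology has ",
      n_atoms(topology)
    )
  }
  if (any(!is.finite(coords))) validation_error("non-finite coordinates")
  if (!is.null(box)) {
    stopifnot(length(box) == 3)
    if (any(box <= 0)) validation_error("box lengths must be positive")
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  stopifnot(length(times) == nf)
  if (is.unsorted(times)) validation_error("frame times must be non-decreasing")
  structure(
    list(topology = topology, coords = coords, box = box, times = times),
    class = "trajectory"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", n_atoms(x), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues; roles:",
      paste(names(table(x$atoms$role)), table(x$atoms$role), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms",
      if (!is.null(x$box)) sprintf("(box %.2f %.2f %.2f A)", x$box[1], x$box[2], x$box[3]) else "",
      "\n")
  invisible(x)
}

#' Extract one frame's coordinates
#' @param traj trajectory
#' @param i frame index (1-based)
#' @return `n_atoms x 3` matrix
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

# ---- parameter sidecar -------------------------------------------------------

#' Read a per-atom parameter sidecar table
#'
#' TSV with columns `residue_name`, `atom_name`, `mass` (amu), `charge` (e),
#' `sigma` (A), `epsilon` (kcal/mol), `pb_radius` (A). Rows key on
#' (residue_name, atom_name).
#'
#' @param path file path
#' @return data.frame
#' @export
read_param_sidecar <- function(path) {
  if (!file.exists(path)) stop("cannot read parameter sidecar: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("residue_name", "atom_name", "mass", "charge", "sigma", "epsilon", "pb_radius")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    validation_error("parameter sidecar missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

apply_sidecar <- function(atoms, params) {
  key_a <- paste(atoms$resname, atoms$name)
  key_p <- paste(params$residue_name, params$atom_name)
  idx <- match(key_a, key_p)
  hit <- !is.na(idx)
  atoms$mass[hit] <- params$mass[idx[hit]]
  atoms$charge[hit] <- params$charge[idx[hit]]
  atoms$sigma[hit] <- params$sigma[idx[hit]]
  atoms$epsilon[hit] <- params$epsilon[idx[hit]]
  atoms$pb_radius[hit] <- params$pb_radius[idx[hit]]
  atoms
}

# ---- PDB ---------------------------------------------------------------------

parse_pdb_atom_line <- function(line) {
  name <- trimws(substr(line, 13, 16))
  element <- trimws(substr(line, 77, 78))
  if (element == "") {
    # infer from the atom name: two-character elements occupy column 13
    lead <- trimws(substr(line, 13, 14))
    lead <- gsub("[0-9']", "", lead)
    if (toupper(lead) %in% names(ELEMENT_MASS) && nchar(lead) == 2) {
      element <- lead
    } else {
      stripped <- gsub("[0-9']", "", name)
      element <- substr(stripped, 1, 1)
    }
  }
  list(
    serial = as.integer(substr(line, 7, 11)),
    name = name,
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resid = as.integer(substr(line, 23, 26)),
    x = as.numeric(substr(line, 31, 38)),
    y = as.numeric(substr(line, 39, 46)),
    z = as.numeric(substr(line, 47, 54)),
    element = toupper(element)
  )
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  in_model <- FALSE
  for (line in lines) {
    rec <- substr(line, 1, 6)
    if (startsWith(rec, "MODEL")) {
      in_model <- TRUE
      cur <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      models[[length(models) + 1]] <- cur
      cur <- list()
      in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      cur[[length(cur) + 1]] <- parse_pdb_atom_line(line)
    }
  }
  if (length(cur) > 0) models[[length(models) + 1]] <- cur
  models <- Filter(function(m) length(m) > 0, models)
  if (length(models) == 0) validation_error("no ATOM/HETATM records in ", path)
  lapply(models, function(m) do.call(rbind.data.frame, c(m, stringsAsFactors = FALSE)))
}

#' Read a structure (single-frame ensemble) from PDB
#'
#' Parses ATOM/HETATM records (fixed-width wwPDB columns). Atoms lacking
#' sidecar parameters receive mass and PB radius from an element lookup,
#' zero charge and zero LJ epsilon. Molecule roles are inferred: standard
#' amino acids are `protein`, water residues `solvent`, single-atom metal
#' records `ion`, everything else `ligand`.
#'
#' @param path PDB file path
#' @param params_path optional parameter sidecar path (see
#'   [read_param_sidecar()])
#' @return one-frame `trajectory`
#' @export
read_structure <- function(path, params_path = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  models <- read_pdb_models(path)
  df <- models[[1]]
  atoms <- data.frame(
    serial = df$serial, name = df$name, element = df$element,
    resname = df$resname, resid = df$resid, chain = df$chain,
    stringsAsFactors = FALSE
  )
  if (!is.null(params_path)) {
    params <- read_param_sidecar(params_path)
    # fill defaults first, then override from sidecar
    topo <- new_topology(atoms)
    topo$atoms <- apply_sidecar(topo$atoms, params)
    topo <- new_topology(topo$atoms)
  } else {
    topo <- new_topology(atoms)
  }
  new_trajectory(topo, as.matrix(df[, c("x", "y", "z")]), times = 0)
}

#' Read a trajectory against a known topology
#'
#' Accepts a multi-model PDB (MODEL/ENDMDL) or an XYZ frame series; each
#' frame must contain exactly `n_atoms(topology)` atoms.
#'
#' @param path file path (`.pdb` or `.xyz`, judged by content)
#' @param topology `topology` for the coordinates
#' @return `trajectory`
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {
    read_xyz_trajectory(path, topology)
  } else {
    models <- read_pdb_models(path)
    nf <- length(models)
    na <- n_atoms(topology)
    coords <- array(NA_real_, dim = c(nf, na, 3))
    for (f in seq_len(nf)) {
      m <- models[[f]]
      if (nrow(m) != na) {
        validation_error("frame ", f, ": expected ", na, " atoms, got ", nrow(m))
      }
      coords[f, , ] <- as.matrix(m[, c("x", "y", "z")])
    }
    new_trajectory(topology, coords, times = as.numeric(seq_len(nf) - 1))
  }
}

read_xyz_trajectory <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  na <- n_atoms(topology)
  coords <- list()
  times <- numeric(0)
  i <- 1
  f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    f <- f + 1
    if (is.na(cnt)) validation_error("frame ", f, ": malformed XYZ atom count line")
    if (cnt != na) validation_error("frame ", f, ": expected ", na, " atoms, got ", cnt)
    comment <- lines[i + 1]
    t <- suppressWarnings(as.numeric(sub(".*t=([0-9eE.+-]+).*", "\\1", comment)))
    times <- c(times, if (is.na(t)) f - 1 else t)
    block <- lines[(i + 2):(i + 1 + cnt)]
    if (length(block) != cnt || any(is.na(block))) {
      validation_error("frame ", f, ": truncated XYZ block")
    }
    xyz <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(tok) {
      as.numeric(tok[2:4])
    }))
    coords[[f]] <- xyz
    i <- i + 2 + cnt
  }
  arr <- array(NA_real_, dim = c(length(coords), na, 3))
  for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
  new_trajectory(topology, arr, times = times)
}

#' Write a trajectory to multi-model PDB or XYZ
#'
#' @param traj trajectory
#' @param path output path; format chosen by extension (`.xyz` else PDB)
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    write_xyz_trajectory(traj, path)
  } else {
    write_pdb_trajectory(traj, path)
  }
  invisible(path)
}

write_pdb_trajectory <- function(traj, path) {
  atoms <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    rec <- ifelse(atoms$role == "protein", "ATOM  ", "HETATM")
    name4 <- ifelse(
      nchar(atoms$name) >= 4 | nchar(atoms$element) == 2,
      formatC(atoms$name, width = -4),
      paste0(" ", formatC(atoms$name, width = -3))
    )
    lines <- sprintf(
      "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, atoms$serial, substr(name4, 1, 4), atoms$resname, atoms$chain,
      atoms$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, atoms$element
    )
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_xyz_trajectory <- function(traj, path) {
  atoms <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%d", n_atoms(traj)), con)
    writeLines(sprintf("t=%g", traj$times[f]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

# ---- selections --------------------------------------------------------------

#' Select atoms with a small expression grammar
#'
#' The grammar supports role keywords (`protein`, `ligand`, `ion`,
#' `solvent`), atom-name matches (`name CA`, `name OD1 OD2`), residue ranges
#' (`resid 10-20`, `resid 5`), `and`/`or` conjunctions (with `and` binding
#' tighter) and parentheses.
#'
#' @param topology `topology`
#' @param expr selection expression string
#' @return `selection`: strictly increasing 1-based atom indices, with the
#'   expression kept as the `label` attribute
#' @export
#' @examples
#' topo <- gen_toy_complex(toy_complex_spec())$topology
#' select_atoms(topo, "protein")
#' select_atoms(topo, "ligand")
select_atoms <- function(topology, expr) {
  stopifnot(inherits(topology, "topology"), is.character(expr), length(expr) == 1)
  tokens <- strsplit(trimws(gsub("([()])", " \\1 ", expr)), "\\s+")[[1]]
  if (length(tokens) == 0) validation_error("empty selection expression")
  atoms <- topology$atoms
  pos <- 1

  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1; tok }

  parse_or <- function() {
    mask <- parse_and()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      mask <- mask | parse_and()
    }
    mask
  }
  parse_and <- function() {
    mask <- parse_term()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      mask <- mask & parse_term()
    }
    mask
  }
  parse_term <- function() {
    tok <- peek()
    if (is.na(tok)) validation_error("malformed selection: unexpected end of '", expr, "'")
    if (tok == "(") {
      advance()
      mask <- parse_or()
      if (is.na(peek()) || peek() != ")") validation_error("malformed selection: missing ')' in '", expr, "'")
      advance()
      return(mask)
    }
    if (tok %in% c("protein", "ligand", "ion", "solvent")) {
      advance()
      return(atoms$role == tok)
    }
    if (tok == "name") {
      advance()
      names <- character(0)
      while (!is.na(peek()) && !(peek() %in% c("and", "or", ")", "name", "resid"))) {
        names <- c(names, advance())
      }
      if (length(names) == 0) validation_error("malformed selection: 'name' needs at least one atom name")
      return(atoms$name %in% names)
    }
    if (tok == "resid") {
      advance()
      mask <- rep(FALSE, nrow(atoms))
      nspec <- 0
      while (!is.na(peek()) && grepl("^[0-9]+(-[0-9]+)?$", peek())) {
        spec <- advance()
        nspec <- nspec + 1
        if (grepl("-", spec)) {
          lim <- as.integer(strsplit(spec, "-")[[1]])
          mask <- mask | (atoms$resid >= lim[1] & atoms$resid <= lim[2])
        } else {
          mask <- mask | (atoms$resid == as.integer(spec))
        }
      }
      if (nspec == 0) validation_error("malformed selection: 'resid' needs a number or range")
      return(mask)
    }
    validation_error("malformed selection: unknown token '", tok, "' in '", expr, "'")
  }

  mask <- parse_or()
  if (pos <= length(tokens)) {
    validation_error("malformed selection: trailing tokens in '", expr, "'")
  }
  idx <- which(mask)
  if (length(idx) == 0) validation_error("selection '", expr, "' matched no atoms")
  structure(as.integer(idx), label = expr, class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection '", attr(x, "label"), "': ", length(x), " atoms\n", sep = "")
  invisible(x)
}

# ---- tabular reports ---------------------------------------------------------

#' Write keyed numeric records as a TSV report
#'
#' @param rows data.frame, or list of named lists with identical keys
#' @param path output path
#' @param digits decimal places for numeric columns (default 2, the printing
#'   convention for energy tables)
#' @return invisibly, `path`
#' @export
write_table <- function(rows, path, digits = 2) {
  if (!is.data.frame(rows)) {
    if (length(rows) > 0) {
      keys <- lapply(rows, names)
      if (!all(vapply(keys, identical, logical(1), y = keys[[1]]))) {
        validation_error("heterogeneous keys across rows")
      }
    }
    rows <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf(paste0("%.", digits, "f"), out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_table()]
#' @param path file path
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
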