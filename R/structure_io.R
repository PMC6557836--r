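#' @title Structure and trajectory I/O
#' @name structure_io
#' @description Fixed-column PDB v3.3 reading/writing for single structures
#'   and multi-model trajectories, plus deterministic atom selection.
NULL

# Standard atomic masses (Da) for elements common in protein structures.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971,
                    FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
                    NA. = 22.990, CL = 35.45, K = 39.098, MN = 54.938)
DEFAULT_MASS <- 12.011  # carbon fallback for unknown elements

element_mass <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- ELEMENT_MASSES[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default mass %.3f Da",
                    paste(unique(element[unknown]), collapse = ", "),
                    DEFAULT_MASS))
    m[unknown] <- DEFAULT_MASS
  }
  unname(m)
}

guess_element <- function(atom_name) {
  # PDB atom names right-justify the element in cols 13-14; after trimming,
  # a leading digit (e.g. 1HG1) marks hydrogens, otherwise the first letter
  # is the element for standard protein atoms (two-letter ions are taken
  # from the element field when present).
  nm <- toupper(trimws(atom_name))
  ifelse(grepl("^[0-9]", nm), "H", substr(gsub("^[0-9]+", "", nm), 1, 1))
}

new_structure <- function(atoms, coords, masses) {
  structure(list(atoms = atoms, coords = coords, masses = masses),
            class = "md_structure")
}

#' Construct a structure from an atom table and coordinates
#'
#' @param atoms data frame with columns `serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_number`, `element`.
#' @param coords numeric matrix, n_atoms x 3, angstrom.
#' @param masses optional numeric masses (Da); derived from `element` when
#'   omitted.
#' @return an `md_structure`.
#' @export
md_structure <- function(atoms, coords, masses = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  need <- c("serial", "atom_name", "residue_name", "chain_id",
            "residue_number", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop(sprintf("atom table missing columns: %s",
                 paste(miss, collapse = ", ")))
  if (nrow(atoms) != nrow(coords) || ncol(coords) != 3L)
    stop("coords must be n_atoms x 3")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop(sprintf("duplicate atom address: %s", key[duplicated(key)][1L]))
  if (is.null(masses)) masses <- element_mass(atoms$element)
  if (any(masses <= 0)) stop("masses must be positive")
  new_structure(as.data.frame(atoms), coords, as.numeric(masses))
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id,
                                  x$atoms$residue_number))),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory
#'
#' Ordered coordinate frames sharing one topology (atom table authority).
#'
#' @param topology an `md_structure`; its coordinates are frame 1's unless
#'   frames are given explicitly.
#' @param frames list of n_atoms x 3 matrices.
#' @param frame_times optional times (ps).
#' @return an `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(frames) < 1L) stop("trajectory needs >= 1 frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    storage.mode(frames[[i]]) <- "double"
    if (!identical(dim(frames[[i]]), c(n, 3L)))
      stop(sprintf("frame %d atom count (%d) != topology (%d)", i,
                   nrow(frames[[i]]), n))
  }
  if (!is.null(frame_times) && length(frame_times) != length(frames))
    stop("frame_times length mismatch")
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms\n", length(x$frames),
              nrow(x$topology$atoms)))
  invisible(x)
}

parse_pdb_lines <- function(lines, keep_hetero = FALSE,
                            keep_waters = FALSE) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | (keep_hetero & rec == "HETATM")
  lines <- lines[is_atom]
  if (!length(lines)) return(NULL)
  field <- function(a, b) trimws(substr(lines, a, b))
  altloc <- substr(lines, 17, 17)
  keep <- altloc %in% c(" ", "A", "")
  lines <- lines[keep]
  field <- function(a, b) trimws(substr(lines, a, b))
  resname <- field(18, 20)
  if (!keep_waters) {
    w <- resname %in% c("HOH", "WAT", "SOL")
    lines <- lines[!w]
    field <- function(a, b) trimws(substr(lines, a, b))
    resname <- resname[!w]
  }
  if (!length(lines)) return(NULL)
  elem <- field(77, 78)
  name <- field(13, 16)
  elem[elem == ""] <- guess_element(name[elem == ""])
  data.frame(serial = as.integer(field(7, 11)),
             atom_name = name,
             residue_name = resname,
             chain_id = field(22, 22),
             residue_number = as.integer(field(23, 26)),
             element = toupper(elem),
             x = as.numeric(field(31, 38)),
             y = as.numeric(field(39, 46)),
             z = as.numeric(field(47, 54)),
             stringsAsFactors = FALSE)
}

#' Read a PDB structure
#'
#' Parses ATOM records from fixed-column PDB v3.3. Only the first MODEL is
#' read; altloc 'A' or blank is kept; waters and (by default) hetero
#' records are skipped. Masses come from a built-in element table with a
#' warning-and-default rule for unknown elements.
#'
#' @param path PDB file path.
#' @param keep_hetero also parse HETATM records?
#' @return an `md_structure`.
#' @export
read_pdb <- function(path, keep_hetero = FALSE) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  tab <- parse_pdb_lines(lines, keep_hetero = keep_hetero)
  if (is.null(tab)) stop(sprintf("no ATOM records in %s", path))
  md_structure(tab[, 1:6], as.matrix(tab[, c("x", "y", "z")]))
}

#' Read a multi-model PDB as a trajectory
#'
#' One frame per MODEL/ENDMDL block (a file without MODEL records yields a
#' single-frame trajectory); the topology is taken from model 1 and every
#' other model must present the same atom count.
#'
#' @param path PDB file path.
#' @param keep_hetero also parse HETATM records?
#' @return an `md_trajectory`.
#' @export
read_multimodel_pdb <- function(path, keep_hetero = FALSE) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(substr(lines, 1, 5) == "MODEL")
  if (!length(starts)) {
    s <- read_pdb(path, keep_hetero = keep_hetero)
    return(md_trajectory(s, list(s$coords)))
  }
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(ends) < length(starts))
    stop("unterminated MODEL block")
  topo <- NULL
  frames <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    tab <- parse_pdb_lines(blk, keep_hetero = keep_hetero)
    if (is.null(tab)) stop(sprintf("model %d: no ATOM records", i))
    if (i == 1L) {
      topo <- md_structure(tab[, 1:6], as.matrix(tab[, c("x", "y", "z")]))
    } else if (nrow(tab) != nrow(topo$atoms)) {
      stop(sprintf("model %d atom count (%d) differs from model 1 (%d)",
                   i, nrow(tab), nrow(topo$atoms)))
    }
    frames[[i]] <- unname(as.matrix(tab[, c("x", "y", "z")]))
  }
  md_trajectory(topo, frames)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, elem) {
  # PDB convention: 1-3 char atom names start in col 14
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, chain, resno, xyz[1], xyz[2], xyz[3], elem)
}

#' Write a structure as PDB
#' @param structure an `md_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    pdb_atom_line(a$serial[i], a$atom_name[i], a$residue_name[i],
                  a$chain_id[i], a$residue_number[i],
                  structure$coords[i, ], a$element[i]), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as multi-model PDB
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  out <- character()
  for (f in seq_along(traj$frames)) {
    out <- c(out, sprintf("MODEL     %4d", f),
             vapply(seq_len(nrow(a)), function(i)
               pdb_atom_line(a$serial[i], a$atom_name[i],
                             a$residue_name[i], a$chain_id[i],
                             a$residue_number[i], traj$frames[[f]][i, ],
                             a$element[i]), character(1)),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' Deterministic, topology-ordered atom indices. An empty selection is not
#' an error; it carries a `flag` attribute so callers can decide.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param chain optional chain id(s).
#' @param residues optional residue numbers (vector), or a 2-column matrix /
#'   list of `c(start, end)` inclusive ranges.
#' @param atom_names optional atom name(s), e.g. `"CA"`.
#' @return integer vector of atom indices (attribute `flag` set to
#'   `"empty selection"` when nothing matches).
#' @export
select_atoms <- function(x, chain = NULL, residues = NULL,
                         atom_names = NULL) {
  atoms <- if (inherits(x, "md_trajectory")) x$topology$atoms else x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain_id %in% chain
  if (!is.null(residues)) {
    resset <- if (is.list(residues)) {
      unlist(lapply(residues, function(r) seq(r[1], r[2])))
    } else if (is.matrix(residues)) {
      unlist(apply(residues, 1, function(r) seq(r[1], r[2]),
                   simplify = FALSE))
    } else as.numeric(residues)
    keep <- keep & atoms$residue_number %in% resset
  }
  if (!is.null(atom_names)) keep <- keep & atoms$atom_name %in% atom_names
  idx <- which(keep)
  if (!length(idx)) attr(idx, "flag") <- "empty selection"
  idx
}

#' Parse a CLI-style selection string
#'
#' Understands the compact form `chain:A,res:50-163,atom:CA` (residues may
#' be single numbers, ranges, or both: `res:59,113,150-160`).
#'
#' @param text selection string.
#' @return a list of arguments for [select_atoms()].
#' @export
parse_selection <- function(text) {
  out <- list(chain = NULL, residues = NULL, atom_names = NULL)
  if (!nzchar(text)) return(out)
  # split on commas not inside res lists: parse key by key
  parts <- strsplit(text, ",")[[1]]
  key <- NULL
  for (p in parts) {
    if (grepl(":", p, fixed = TRUE)) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1]]
      key <- kv[1]; val <- kv[2]
    } else val <- p
    if (is.null(key)) stop(sprintf("malformed selection token '%s'", p))
    switch(key,
           chain = { out$chain <- c(out$chain, val) },
           res = {
             if (grepl("-", val)) {
               r <- as.numeric(strsplit(val, "-")[[1]])
               out$residues <- c(out$residues, seq(r[1], r[2]))
             } else out$residues <- c(out$residues, as.numeric(val))
           },
           atom = { out$atom_names <- c(out$atom_names, val) },
           stop(sprintf("unknown selection key '%s'", key)))
  }
  out
}

#' Define a named residue-range domain
#'
#' @param name domain name.
#' @param residue_ranges list of inclusive `c(start, end)` residue-number
#'   pairs (or a single pair); ranges must not overlap.
#' @return a `domain_definition`.
#' @export
domain_definition <- function(name, residue_ranges) {
  if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
  spans <- lapply(residue_ranges, function(r) {
    if (length(r) != 2L || r[1] > r[2])
      stop("each range must be c(start, end) with start <= end")
    seq(r[1], r[2])
  })
  all_res <- unlist(spans)
  if (anyDuplicated(all_res))
    stop("residue ranges overlap within the domain definition")
  structure(list(name = name, residue_ranges = residue_ranges),
            class = "domain_definition")
}

#' Default two-domain split for a WW + PPIase architecture
#'
#' WW domain residues 6-39 and catalytic (PPIase) domain residues 50-163 in
#' author numbering; the linker is excluded. These boundaries are
#' conventional defaults, not assertions — override per structure.
#'
#' @return named list of two `domain_definition`s (`WW`, `PPIase`).
#' @export
pin1_default_domains <- function() {
  list(WW = domain_definition("WW", list(c(6, 39))),
       PPIase = domain_definition("PPIase", list(c(50, 163))))
}

#' Select a domain's atoms
#'
#' @param x structure or trajectory.
#' @param domain a `domain_definition`.
#' @param atom_names atom subset within the domain (default C-alpha).
#' @return integer atom indices (flagged when empty).
#' @export
select_domain <- function(x, domain, atom_names = "CA") {
  stopifnot(inherits(domain, "domain_definition"))
  select_atoms(x, residues = domain$residue_ranges, atom_names = atom_names)
}

#' Resolve a unique atom address
#'
#' @param x structure or trajectory.
#' @param residue residue number.
#' @param atom atom name.
#' @param chain optional chain id.
#' @return single integer atom index; error if missing or ambiguous.
#' @export
resolve_atom <- function(x, residue, atom, chain = NULL) {
  idx <- select_atoms(x, chain = chain, residues = residue,
                      atom_names = atom)
  if (length(idx) == 0L)
    stop(sprintf("atom %s of residue %s not found", atom, residue))
  if (length(idx) > 1L)
    stop(sprintf("ambiguous atom address %s:%s (%d matches)", residue,
                 atom, length(idx)))
  idx
}
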