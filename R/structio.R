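#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM coordinates and the declared full sequence (SEQRES)
#' through [bio3d::read.pdb()], plus the unit cell (CRYST1) and
#' crystallographic symmetry operators (REMARK 290 SMTRY rows, Cartesian
#' convention with translations in Angstrom).  Alternate locations are
#' resolved by keeping the highest-occupancy conformer; insertion codes are
#' treated as distinct residues; only the first NMR model is read.
#'
#' @param path path to a PDB file.
#' @param fasta optional named character vector of full-length one-letter
#'   sequences per chain (or path to a FASTA file).  When given it overrides
#'   SEQRES: the construct crystallized is often shorter than the biological
#'   full-length protein, and missing-mass accounting must use the latter.
#' @return an object of class `ccs_structure`: a list with `atoms` (data
#'   frame: element, resid, resno, insert, chain, x, y, z, occ, elety, type),
#'   `seqres` (per-chain one-letter sequences), `cell` (lengths in Angstrom and
#'   angles in degrees, or NULL) and `sym_ops` (list of `list(R, t)` rigid
#'   operators, or NULL; the identity is guaranteed to be present when any
#'   operators are).
#' @seealso [mass_account()], [expand_symmetry()]
#' @export
read_structure <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines)

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no atomic coordinates in '", path, "'")

  atoms <- data.frame(
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             guess_element(at$elety), at$elesy)),
    resid = at$resid,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    elety = at$elety,
    type = at$type,
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in '", path, "'")

  seqres <- parse_seqres(pdb)
  if (is.null(seqres)) seqres <- observed_sequences(atoms)
  if (!is.null(fasta)) {
    if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
      fasta <- read_fasta_chains(fasta)
    for (ch in names(fasta)) seqres[[ch]] <- toupper(fasta[[ch]])
  }

  structure(
    list(atoms = atoms, seqres = seqres,
         cell = parse_cryst1(lines),
         sym_ops = parse_remark290(lines)),
    class = "ccs_structure")
}

#' @export
print.ccs_structure <- function(x, ...) {
  cat("ccs_structure:", nrow(x$atoms), "atoms,",
      length(x$seqres), "chain(s)\n")
  if (!is.null(x$cell))
    cat("  cell:", paste(round(x$cell$lengths, 2), collapse = " "), "/",
        paste(round(x$cell$angles, 2), collapse = " "), "\n")
  if (!is.null(x$sym_ops))
    cat("  symmetry operators:", length(x$sym_ops), "\n")
  invisible(x)
}

validate_pdb_records <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed coordinate record at line ", i)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) stop("malformed coordinates at line ", i)
  }
  invisible(TRUE)
}

guess_element <- function(elety) {
  toupper(substr(gsub("[0-9 ']", "", elety), 1, 1))
}

# Keep the highest-occupancy alternate conformer of each
# (chain, residue, insertion, atom-name) group; ties keep the first.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    ii[which.max(atoms$occ[ii])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

parse_seqres <- function(pdb) {
  sr <- pdb$seqres
  if (is.null(sr) || length(sr) == 0) return(NULL)
  chains <- names(sr)
  out <- lapply(split(unname(sr), chains), function(three) {
    paste(bio3d::aa321(three), collapse = "")
  })
  out[order(names(out))]
}

observed_sequences <- function(atoms) {
  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0) return(list())
  out <- lapply(split(prot, prot$chain), function(df) {
    df <- df[!duplicated(paste(df$resno, df$insert)), , drop = FALSE]
    df <- df[order(df$resno), , drop = FALSE]
    paste(bio3d::aa321(df$resid), collapse = "")
  })
  out[order(names(out))]
}

parse_cryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (length(i) == 0) return(NULL)
  ln <- lines[i[1]]
  vals <- suppressWarnings(as.numeric(c(
    substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
    substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
  if (any(is.na(vals))) stop("malformed CRYST1 record")
  list(lengths = vals[1:3], angles = vals[4:6])
}

# REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000
parse_remark290 <- function(lines) {
  sm <- grep("^REMARK 290[ ]+SMTRY[123]", lines, value = TRUE)
  if (length(sm) == 0) return(NULL)
  toks <- lapply(strsplit(trimws(sm), "[ ]+"), function(t) t[-(1:2)])
  row <- as.integer(substr(vapply(toks, `[`, "", 1), 6, 6))
  opid <- as.integer(vapply(toks, `[`, "", 2))
  mat <- t(vapply(toks, function(t) as.numeric(t[3:6]), numeric(4)))
  ops <- lapply(sort(unique(opid)), function(id) {
    sel <- which(opid == id)
    sel <- sel[order(row[sel])]
    if (length(sel) != 3) stop("REMARK 290 operator ", id, " incomplete")
    list(R = mat[sel, 1:3, drop = FALSE], t = mat[sel, 4])
  })
  has_id <- any(vapply(ops, function(o) {
    max(abs(o$R - diag(3))) < 1e-6 && max(abs(o$t)) < 1e-4
  }, logical(1)))
  if (!has_id) ops <- c(list(list(R = diag(3), t = numeric(3))), ops)
  ops
}

read_fasta_chains <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  names(seqs) <- sub("[| ].*$", "", rownames(fa$ali))
  as.list(toupper(seqs))
}

#' Account for mass missing from a structure
#'
#' Compares the residues observed in a structure (a residue counts as present
#' iff at least one heavy atom is observed) with the declared full-length
#' sequence, and reports the present mass, the full mass and the missing-mass
#' fraction that drives the model-completion decision tree.  Masses are
#' computed from per-residue amino-acid masses (average by default) with one
#' water per chain; position `i` of the full sequence corresponds to residue
#' number `i` in the coordinate file.
#'
#' @param structure a `ccs_structure`.
#' @param full_sequence optional named per-chain one-letter sequences
#'   overriding the structure's declared sequence.
#' @param kind `"average"` (default) or `"monoisotopic"` residue masses.
#' @return an object of class `mass_account`: `m_present` and `m_full` (Da),
#'   `f_missing` = (m_full - m_present)/m_full, and `missing_segments`
#'   (data frame chain/start/end of unobserved runs).
#' @export
mass_account <- function(structure, full_sequence = NULL,
                         kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- residue_mass_table(kind)
  atoms <- structure$atoms
  prot <- atoms[atoms$type == "ATOM" & atoms$element != "H", , drop = FALSE]

  chains <- union(names(structure$seqres), unique(prot$chain))
  if (!is.null(full_sequence)) chains <- union(chains, names(full_sequence))
  chains <- sort(chains)

  m_present <- 0
  m_full <- 0
  segs <- list()
  for (ch in chains) {
    full <- full_sequence[[ch]] %||% structure$seqres[[ch]]
    obs <- prot[prot$chain == ch, , drop = FALSE]
    if (is.null(full)) {
      obs1 <- obs[!duplicated(paste(obs$resno, obs$insert)), , drop = FALSE]
      obs1 <- obs1[order(obs1$resno), , drop = FALSE]
      full <- paste(bio3d::aa321(obs1$resid), collapse = "")
      obs$resno <- match(paste(obs$resno, obs$insert),
                         paste(obs1$resno, obs1$insert))
    }
    full <- toupper(full)
    L <- nchar(full)
    aa_full <- strsplit(full, "")[[1]]
    m_full <- m_full + sum(tab$aa[aa_full]) + tab$water

    pos <- sort(unique(obs$resno))
    if (length(pos) > 0) {
      if (any(pos < 1 | pos > L))
        stop("chain ", ch, ": observed residue number outside declared ",
             "sequence (1..", L, ")")
      obs_types <- vapply(split(obs$resid, obs$resno),
                          function(r) bio3d::aa321(r[1]), "")
      mism <- names(obs_types)[obs_types != aa_full[as.integer(names(obs_types))] &
                               obs_types != "X"]
      if (length(mism) > 0)
        stop("chain ", ch, ": observed residue type disagrees with declared ",
             "sequence at position(s) ", paste(head(mism, 5), collapse = ", "))
      m_present <- m_present + sum(tab$aa[aa_full[pos]]) + tab$water
    }
    absent <- setdiff(seq_len(L), pos)
    if (length(absent) > 0) {
      runs <- split(absent, cumsum(c(1, diff(absent) != 1)))
      segs[[ch]] <- data.frame(
        chain = ch,
        start = vapply(runs, min, 0),
        end = vapply(runs, max, 0), row.names = NULL)
    }
  }
  segs <- if (length(segs)) do.call(rbind, c(segs, make.row.names = FALSE))
          else data.frame(chain = character(), start = numeric(),
                          end = numeric())
  if (!(m_full >= m_present && m_present >= 0))
    stop("inconsistent mass account")
  structure(list(m_present = m_present, m_full = m_full,
                 f_missing = (m_full - m_present) / m_full,
                 missing_segments = segs, kind = kind),
            class = "mass_account")
}

#' @export
print.mass_account <- function(x, ...) {
  cat(sprintf("mass_account: present %.1f Da of %.1f Da (%.1f%% missing)\n",
              x$m_present, x$m_full, 100 * x$f_missing))
  invisible(x)
}

#' Sphere models
#'
#' A sphere model represents subunits, structural domains or unresolved
#' residue segments as labelled spheres with a centre, radius and mass.
#'
#' @param label character labels.
#' @param x,y,z centre coordinates in Angstrom.
#' @param radius sphere radii in Angstrom (> 0).
#' @param mass sphere masses in Da (> 0).
#' @param kind one of `"domain"`, `"subunit"`, `"missing"` per sphere.
#' @param provenance optional identifier of the source structure.
#' @return an object of class `sphere_model` (a data frame).
#' @export
sphere_model <- function(label, x, y, z, radius, mass,
                         kind = "domain", provenance = NULL) {
  df <- data.frame(label = as.character(label), x = x, y = y, z = z,
                   radius = radius, mass = mass,
                   kind = rep_len(kind, length(x)),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty sphere model")
  if (any(!is.finite(c(df$x, df$y, df$z))))
    stop("sphere centres must be finite")
  if (any(df$radius <= 0)) stop("all sphere radii must be positive")
  if (any(df$mass <= 0)) stop("all sphere masses must be positive")
  attr(df, "provenance") <- provenance
  class(df) <- c("sphere_model", "data.frame")
  df
}

#' Write a sphere model as a pseudo-atom PDB
#'
#' Each sphere becomes one HETATM pseudo-atom; the radius is stored in the
#' B-factor column (2 decimals) and masses/labels/kinds in REMARK 250 rows so
#' that the file round-trips through [read_sphere_pdb()].
#'
#' @param model a `sphere_model`.
#' @param path output file path.
#' @export
write_sphere_pdb <- function(model, path) {
  stopifnot(inherits(model, "sphere_model"))
  if (nrow(model) == 0) stop("empty sphere model")
  if (any(model$radius > 999.99))
    stop("sphere radius exceeds B-factor column precision (max 999.99)")
  rem <- sprintf("REMARK 250 SPHERE %4d LABEL %s KIND %s MASS %.3f",
                 seq_len(nrow(model)), model$label, model$kind, model$mass)
  het <- sprintf(
    "HETATM%5d  S   SPH S%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(model)), seq_len(nrow(model)),
    model$x, model$y, model$z, 1.0, model$radius)
  writeLines(c(rem, het, "END"), path)
  invisible(path)
}

#' Read a pseudo-atom sphere-model PDB written by [write_sphere_pdb()]
#'
#' @param path file path.
#' @return a `sphere_model`.
#' @export
read_sphere_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  het <- grep("^HETATM", lines, value = TRUE)
  if (length(het) == 0) stop("no HETATM pseudo-atoms in '", path, "'")
  xyz <- t(vapply(het, function(ln) {
    as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54),
                 substr(ln, 61, 66)))
  }, numeric(4)))
  rem <- grep("^REMARK 250 SPHERE", lines, value = TRUE)
  lab <- rep("sphere", length(het))
  kind <- rep("domain", length(het))
  mass <- rep(1, length(het))
  if (length(rem) > 0) {
    toks <- strsplit(trimws(rem), "[ ]+")
    for (t in toks) {
      i <- as.integer(t[4])
      lab[i] <- t[6]; kind[i] <- t[8]; mass[i] <- as.numeric(t[10])
    }
  }
  sphere_model(lab, xyz[, 1], xyz[, 2], xyz[, 3], xyz[, 4], mass, kind)
}
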