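# Multi-model PDB reading/writing and atom selection.
#
# Only the fixed-column PDB dialect is supported; MODEL/ENDMDL blocks give
# one frame each (a file without MODEL records yields a single frame).
# Coordinates are in Angstrom throughout. Alternate locations: the first
# altloc encountered for an atom wins; occupancy is ignored (ensembles here
# are models, not experimental data).

.parse_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & nzchar(trimws(s))
  bad <- bad | !nzchar(trimws(s))
  if (any(bad))
    stop(sprintf("malformed %s field on line %d: '%s'",
                 what, lineno[which(bad)[1]], s[which(bad)[1]]), call. = FALSE)
  v
}

#' Parse a (multi-model) PDB file or text
#'
#' Reads fixed-column ATOM/HETATM records. Each MODEL/ENDMDL block becomes
#' one frame of the returned [Ensemble-class]; files without MODEL records
#' give a single frame. All models must share an identical atom topology
#' (same atoms in the same order); a mismatch is an error. For atoms with
#' alternate locations the first altloc encountered is kept.
#'
#' @param x path to a PDB file, or a character vector of PDB lines
#' @return an [Ensemble-class]
#' @examples
#' lines <- c(
#'  "ATOM      1  NE2 HIS A 259       1.000   2.000   3.000  1.00  0.00           N")
#' ens <- parsePDB(lines)
#' coords(ens, 1)
#' @export
parsePDB <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  lineno <- seq_along(lines)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom))
    stop("no ATOM/HETATM records found", call. = FALSE)

  # assign a model id to every line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  al <- lines[is_atom]
  an <- lineno[is_atom]
  am <- model_id[is_atom]
  if (any(am == 0L))
    stop(sprintf("ATOM record outside a MODEL block on line %d", an[am == 0L][1]),
         call. = FALSE)

  if (any(nchar(al) < 54))
    stop(sprintf("truncated ATOM/HETATM record on line %d (need 54+ columns)",
                 an[nchar(al) < 54][1]), call. = FALSE)

  serial <- .parse_num(substr(al, 7, 11), an, "serial")
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  resseq <- .parse_num(substr(al, 23, 26), an, "resseq")
  x_ <- .parse_num(substr(al, 31, 38), an, "x coordinate")
  y_ <- .parse_num(substr(al, 39, 46), an, "y coordinate")
  z_ <- .parse_num(substr(al, 47, 54), an, "z coordinate")
  element <- if (all(nchar(al) >= 78)) trimws(substr(al, 77, 78)) else
    toupper(substr(name, 1, 1))
  element[!nzchar(element)] <- toupper(substr(name[!nzchar(element)], 1, 1))

  # first altloc wins, per frame
  key <- paste(am, chain, resseq, resname, name, sep = "\r")
  has_alt <- altloc != " "
  drop <- has_alt & duplicated(key)
  keep <- !drop
  serial <- serial[keep]; name <- name[keep]; resname <- resname[keep]
  chain <- chain[keep]; resseq <- resseq[keep]; element <- element[keep]
  x_ <- x_[keep]; y_ <- y_[keep]; z_ <- z_[keep]; am <- am[keep]

  models <- unique(am)
  nm <- length(models)
  split_idx <- split(seq_along(am), factor(am, levels = models))
  n0 <- length(split_idx[[1]])
  topo0 <- NULL
  coords <- array(NA_real_, dim = c(n0, 3, nm))
  for (k in seq_len(nm)) {
    idx <- split_idx[[k]]
    topo <- paste(name[idx], resname[idx], chain[idx], resseq[idx],
                  sep = "|", collapse = ";")
    if (k == 1L) topo0 <- topo
    else if (!identical(topo, topo0) || length(idx) != n0)
      stop(sprintf("inconsistent atom topology in model %d (expected %d atoms with identical names/residues)",
                   models[k], n0), call. = FALSE)
    coords[, 1, k] <- x_[idx]
    coords[, 2, k] <- y_[idx]
    coords[, 3, k] <- z_[idx]
  }
  i1 <- split_idx[[1]]
  atoms <- data.frame(
    serial = as.integer(serial[i1]),
    name = name[i1], resname = resname[i1], chain = chain[i1],
    resseq = as.integer(resseq[i1]), element = element[i1],
    stringsAsFactors = FALSE
  )
  frame_no <- if (any(is_model)) {
    mline <- lines[is_model]
    idx <- suppressWarnings(as.integer(trimws(substr(mline, 7, 14))))
    idx[is.na(idx)] <- seq_along(idx)[is.na(idx)]
    idx[models]
  } else 1L
  Ensemble(atoms, coords, frame_no)
}

#' Write an ensemble as (multi-model) PDB text
#'
#' Single-frame ensembles are written as bare ATOM records; multi-frame
#' ensembles get one MODEL/ENDMDL block per frame. Output re-parses with
#' [parsePDB()] to the same topology and to coordinates within the 1e-3
#' Angstrom column precision.
#'
#' @param ens an [Ensemble-class]
#' @param file optional path; when given, lines are written there
#' @return invisibly (when \code{file} is given) or visibly, the character
#'   vector of PDB lines
#' @export
writePDB <- function(ens, file = NULL) {
  if (any(abs(ens@coords) >= 10000))
    stop("coordinate magnitude >= 10000 A cannot be written in PDB fixed columns",
         call. = FALSE)
  a <- ens@atoms
  nf <- nFrames(ens)
  # PDB v3 atom-name justification: names shorter than 4 chars start in col 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  fmt_frame <- function(k) {
    xyz <- ens@coords[, , k, drop = FALSE]
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$serial, nm, a$resname, a$chain, a$resseq,
            xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], a$element)
  }
  out <- if (nf == 1L) c(fmt_frame(1L), "END") else {
    c(unlist(lapply(seq_len(nf), function(k)
      c(sprintf("MODEL     %4d", ens@frameIndex[k]), fmt_frame(k), "ENDMDL"))),
      "END")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Resolve an atom selection
#'
#' Returns the (frame-order-preserving) indices of atoms matching every set
#' criterion of the selector. An empty result is valid; downstream
#' operations decide whether that is an error.
#'
#' @param ens an [Ensemble-class] (topology is shared by all frames)
#' @param sel a [Selector-class]
#' @return integer vector of atom indices into \code{atomData(ens)}
#' @examples
#' \dontrun{
#' idx <- selectAtoms(ens, selector(resseq = 259, atomNames = "NE2"))
#' atomData(ens)[idx, ]
#' }
#' @export
selectAtoms <- function(ens, sel) {
  a <- ens@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.na(sel@chain)) keep <- keep & a$chain == sel@chain
  if (!is.na(sel@resseq)) keep <- keep & a$resseq == sel@resseq
  if (!is.na(sel@resname)) keep <- keep & a$resname == sel@resname
  if (length(sel@atomNames)) keep <- keep & a$name %in% sel@atomNames
  which(keep)
}

.resolve_one <- function(ens, sel, what) {
  idx <- selectAtoms(ens, sel)
  if (length(idx) != 1L)
    stop(sprintf("selector for %s resolved to %d atoms (need exactly 1)",
                 what, length(idx)), call. = FALSE)
  idx
}
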