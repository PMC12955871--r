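# Shared fixtures: tiny in-code structures and geometry helpers.

# A single fixed-column ATOM line (columns per the PDB standard).
pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          altloc = " ", element = toupper(substr(name, 1, 1))) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s%s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, altloc, resname, chain, resseq, x, y, z, element)
}

# Minimal ensemble: atoms at given coordinate matrices (list of n x 3).
make_ensemble <- function(coord_list, names = NULL, resseq = NULL,
                          chain = "A", resname = "GLY") {
  n <- nrow(coord_list[[1]])
  if (is.null(names)) names <- paste0("C", seq_len(n))
  if (is.null(resseq)) resseq <- seq_len(n)
  atoms <- data.frame(serial = seq_len(n), name = names, resname = resname,
                      chain = chain, resseq = as.integer(resseq),
                      element = toupper(substr(names, 1, 1)),
                      stringsAsFactors = FALSE)
  xyz <- array(0, dim = c(n, 3, length(coord_list)))
  for (k in seq_along(coord_list)) xyz[, , k] <- coord_list[[k]]
  Ensemble(atoms, xyz)
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Scaffold site spec matching generateEnsemble()'s chain-A site.
scaffold_site <- function(chain = "A", label = "site") {
  siteSpec(label,
           oSel = selector(chain = chain, resname = "LIG", atomNames = "O"),
           nSels = selector(chain = chain, resname = "HIS", atomNames = "NE2"),
           c1Sel = selector(chain = chain, resname = "SAM", atomNames = "C1"),
           sSel = selector(chain = chain, resname = "SAM", atomNames = "S"))
}
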