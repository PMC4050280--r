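#' Read an atomic model from PDB
#'
#' Parses ATOM/HETATM records (through bio3d) into a flat atom table.
#' Alternate locations are resolved by keeping the first altloc seen for
#' each (chain, residue, atom name); insertion codes are retained as part
#' of the residue identity but residue numbers alone address residues in
#' all downstream operations.
#'
#' @param path PDB-format text file.
#' @return an `atomic_model`: a tibble with columns `serial`, `element`,
#'   `atom_name`, `residue_name`, `residue_number`, `chain`, `x`, `y`, `z`
#'   (Angstrom), in file order.
#' @export
read_atomic_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse error: ",
                                                   conditionMessage(e))))
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) abort("empty-model error: no ATOM/HETATM records")
  # first altloc kept: drop later duplicates of the same addressed atom
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ]
  atomic_model(tibble(
    serial = as.integer(a$eleno),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     toupper(substr(trimws(a$elety), 1, 1)), trimws(a$elesy)),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z
  ))
}

#' Atomic model constructor
#'
#' @param atoms a data frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain`, `x`, `y`, `z`; `serial` and `element`
#'   are filled in when absent.
#' @return a tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("atom_name", "residue_name", "residue_number", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    abort(paste0("atomic model lacks column(s): ", paste(miss, collapse = ", ")))
  if (!nrow(atoms)) abort("empty-model error: no atoms")
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"element" %in% names(atoms))
    atoms$element <- toupper(substr(atoms$atom_name, 1, 1))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    abort("atomic coordinates must be finite")
  out <- atoms[, c("serial", "element", "atom_name", "residue_name",
                   "residue_number", "chain", "x", "y", "z")]
  out$residue_number <- as.integer(out$residue_number)
  class(out) <- c("atomic_model", class(out))
  out
}

is_atomic_model <- function(x) inherits(x, "atomic_model")

#' Write an atomic model as PDB
#' @param model an `atomic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atomic_model <- function(model, path) {
  if (!is_atomic_model(model)) model <- atomic_model(model)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    model$serial %% 100000,
    ifelse(nchar(model$atom_name) < 4, paste0(" ", model$atom_name),
           model$atom_name),
    model$residue_name, model$chain, model$residue_number %% 10000,
    model$x, model$y, model$z, model$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

model_coords <- function(model) as.matrix(model[, c("x", "y", "z")])

transform_model <- function(model, R = diag(3), t = c(0, 0, 0),
                            centre = c(0, 0, 0)) {
  xyz <- model_coords(model)
  xyz <- sweep(xyz, 2, centre)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, centre + t, `+`)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# approximate atomic masses for density synthesis
.atomic_mass <- c(H = 1, C = 12, N = 14, O = 16, S = 32, P = 31, FE = 56,
                  ZN = 65, MG = 24, CA = 40, "NA" = 23, K = 39, CL = 35)

atom_masses <- function(model) {
  m <- .atomic_mass[toupper(model$element)]
  m[is.na(m)] <- 12
  unname(m)
}

#' Domain assignment for a multi-domain model
#'
#' Residue ranges for domains I, II, III and the membrane-proximal region,
#' plus the hinge residues joining domain I to II and I to III. Hinge
#' residues must lie between the domains they join (i.e. belong to neither
#' core domain range).
#'
#' @param domain1,domain2,domain3 integer vectors of residue numbers
#'   (ranges) for the three core domains.
#' @param mpr optional residue numbers of the membrane-proximal region.
#' @param hinge12,hinge13 residue numbers of the I-II and I-III hinges.
#' @return an object of class `domain_assignment`.
#' @export
domain_assignment <- function(domain1, domain2, domain3, mpr = integer(),
                              hinge12, hinge13) {
  d1 <- as.integer(domain1); d2 <- as.integer(domain2); d3 <- as.integer(domain3)
  if (length(intersect(d1, d2)) || length(intersect(d1, d3)) ||
      length(intersect(d2, d3)))
    abort("domain residue ranges must not overlap")
  h12 <- as.integer(hinge12); h13 <- as.integer(hinge13)
  core <- c(d1, d2, d3)
  if (any(h12 %in% core) || any(h13 %in% core))
    abort("hinge residues must lie between (not inside) the domains they join")
  structure(list(domain1 = d1, domain2 = d2, domain3 = d3,
                 mpr = as.integer(mpr), hinge12 = h12, hinge13 = h13),
            class = "domain_assignment")
}

domain_atoms <- function(model, residues, backbone_only = FALSE) {
  sel <- model$residue_number %in% residues
  if (backbone_only)
    sel <- sel & model$atom_name %in% c("N", "CA", "C", "O")
  model[sel, , drop = FALSE]
}
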