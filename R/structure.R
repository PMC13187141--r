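# Structure models: a minimal PDB-backed container for receptor/ligand
# complexes, a toy generator for ligand + linker fixtures with octant ground
# truth, and a fixed-column PDB reader/writer (no structural-biology R
# package is assumed).

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Construct a structure model
#'
#' @param atoms data.frame with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `x`, `y`, `z`, `occupancy`, `element`.
#' @param ligand_chains character vector of ligand chain ids.
#' @param receptor_chain receptor chain id.
#' @param id model identifier.
#' @param rank model rank (smaller = better; used by cutoff analysis).
#' @export
structure_model <- function(atoms, ligand_chains = "L", receptor_chain = "R",
                            id = "model", rank = 1L) {
  need <- c("record", "serial", "name", "altloc", "resname", "chain",
            "resseq", "x", "y", "z", "occupancy", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    abort_field("atoms", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort_field("atoms", "coordinates must be finite")
  found <- unique(atoms$chain)
  for (ch in c(ligand_chains, receptor_chain)) {
    if (!ch %in% found && nrow(atoms) > 0)
      stop(sprintf("designated chain '%s' absent; chains found: %s", ch,
                   paste(found, collapse = ", ")), call. = FALSE)
  }
  structure(list(atoms = atoms, ligand_chains = ligand_chains,
                 receptor_chain = receptor_chain, id = id,
                 rank = as.integer(rank)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (rank %d): %d atoms, ligand %s, receptor %s\n",
              x$id, x$rank, nrow(x$atoms),
              paste(x$ligand_chains, collapse = "+"), x$receptor_chain))
  invisible(x)
}

# Heavy atoms of the designated ligand chains: non-hydrogen, waters excluded,
# HETATM records included.
ligand_heavy_atoms <- function(model) {
  a <- model$atoms
  a[a$chain %in% model$ligand_chains & a$element != "H" &
      !(a$resname %in% c("HOH", "WAT")), , drop = FALSE]
}

# Cα table for the receptor chain, ordered by residue number.
receptor_ca <- function(model) {
  a <- model$atoms
  ca <- a[a$chain == model$receptor_chain & a$name == "CA", , drop = FALSE]
  ca[order(ca$resseq), , drop = FALSE]
}

#' One-letter sequence of the receptor chain (from Cα residue names)
#' @param model a `structure_model`.
#' @export
model_receptor_sequence <- function(model) {
  ca <- receptor_ca(model)
  letters1 <- AA3TO1[ca$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# --- PDB I/O ----------------------------------------------------------------

#' Read a PDB file into a structure model
#'
#' Parses `ATOM`/`HETATM` records (first MODEL only), drops hydrogens from
#' the heavy-atom set at query time, resolves altloc duplicates to the
#' highest occupancy, and errors when a designated chain is missing.
#'
#' @param path PDB file.
#' @param ligand_chains,receptor_chain chain designations.
#' @param id,rank model identity (rank defaults to 1).
#' @export
read_pdb <- function(path, ligand_chains = "L", receptor_chain = "R",
                     id = basename(path), rank = 1L) {
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  fx <- function(from, to) trimws(substring(lines, from, to))
  element <- fx(77, 78)
  name <- fx(13, 16)
  no_el <- element == ""
  if (any(no_el))
    element[no_el] <- sub("^[0-9]*", "", name[no_el])
  element[no_el] <- substring(gsub("[^A-Za-z].*$", "",
                                   element[no_el]), 1, 1)
  atoms <- data.frame(
    record = trimws(substring(lines, 1, 6)),
    serial = as.integer(fx(7, 11)),
    name = name,
    altloc = substring(lines, 17, 17),
    resname = fx(18, 20),
    chain = substring(lines, 22, 22),
    resseq = as.integer(fx(23, 26)),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element = toupper(element),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # altloc resolution: keep highest occupancy per (chain, resseq, name)
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$name, sep = "\r")
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  structure_model(atoms, ligand_chains, receptor_chain, id = id, rank = rank)
}

#' Write a structure model to PDB
#' @param model a `structure_model`.
#' @param path output file.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  fmt_name <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$record, a$serial, fmt_name, a$altloc, a$resname, a$chain,
                   a$resseq, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# --- synthetic ligand/linker structures ------------------------------------

#' Specification of a toy ligand + linker structure
#'
#' @param ligand_atom_count number of ligand heavy atoms (0 allowed).
#' @param ligand_shape `"slab"` (20 x 20 x 6 A box), `"shell"` (sphere
#'   surface of radius `shell_radius`) or `"two_lobe"` (two 6 A-radius lobes
#'   at x = +/- 8, a toy dimer).
#' @param linker_length number of linker residues (>= 1).
#' @param linker_mode `"threading"` (straight path through the ligand
#'   interior) or `"wrapping"` (arc of radius `path_radius` outside it).
#' @param ca_spacing consecutive-Calpha spacing in Angstrom (default 3.8).
#' @param shell_radius radius of the shell shape.
#' @param path_radius radius of the wrapping arc (default: outside the
#'   shape's support by 10 A).
#' @param with_domains add two 5-atom receptor domain clusters at the path
#'   ends (for placement-QC fixtures).
#' @param seed RNG seed.
#' @export
structure_sim_spec <- function(ligand_atom_count = 600L,
                               ligand_shape = c("slab", "shell", "two_lobe"),
                               linker_length = 20L,
                               linker_mode = c("threading", "wrapping"),
                               ca_spacing = 3.8, shell_radius = 20,
                               path_radius = NULL, with_domains = FALSE,
                               seed = NULL) {
  ligand_shape <- match.arg(ligand_shape)
  linker_mode <- match.arg(linker_mode)
  assert_scalar_num(ligand_atom_count, "ligand_atom_count", lower = 0)
  assert_scalar_num(linker_length, "linker_length", lower = 1)
  assert_scalar_num(ca_spacing, "ca_spacing", lower = 0, strict = TRUE)
  assert_scalar_num(shell_radius, "shell_radius", lower = 0, strict = TRUE)
  if (is.null(path_radius)) {
    support <- switch(ligand_shape,
                      slab = sqrt(200),          # corner of the 20x20 box
                      shell = shell_radius,
                      two_lobe = 14)
    path_radius <- support + 10
  }
  structure(list(ligand_atom_count = as.integer(ligand_atom_count),
                 ligand_shape = ligand_shape,
                 linker_length = as.integer(linker_length),
                 linker_mode = linker_mode, ca_spacing = ca_spacing,
                 shell_radius = shell_radius, path_radius = path_radius,
                 with_domains = with_domains, seed = seed),
            class = "structure_sim_spec")
}

# support membership test for each toy shape (exact for these shapes)
shape_inside <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  switch(spec$ligand_shape,
         slab = abs(x) <= 10 & abs(y) <= 10 & abs(z) <= 3,
         shell = sqrt(x^2 + y^2 + z^2) <= spec$shell_radius,
         two_lobe = (sqrt((x - 8)^2 + y^2 + z^2) <= 6) |
                    (sqrt((x + 8)^2 + y^2 + z^2) <= 6) |
                    (abs(x) <= 8 & sqrt(y^2 + z^2) <= 6))
}

sample_ligand <- function(spec) {
  n <- spec$ligand_atom_count
  if (n == 0) return(matrix(numeric(0), 0, 3))
  switch(spec$ligand_shape,
         slab = cbind(stats::runif(n, -10, 10), stats::runif(n, -10, 10),
                      stats::runif(n, -3, 3)),
         shell = {
           v <- matrix(stats::rnorm(3 * n), n, 3)
           v / sqrt(rowSums(v^2)) * spec$shell_radius
         },
         two_lobe = {
           ctr <- ifelse(stats::runif(n) < 0.5, -8, 8)
           repeat_sample <- function(m) {
             p <- matrix(stats::runif(3 * m, -6, 6), m, 3)
             ok <- sqrt(rowSums(p^2)) <= 6
             if (all(ok)) return(p)
             p[!ok, ] <- repeat_sample(sum(!ok))
             p
           }
           p <- repeat_sample(n)
           cbind(p[, 1] + ctr, p[, 2], p[, 3])
         })
}

linker_path <- function(spec) {
  L <- spec$linker_length
  s <- spec$ca_spacing
  if (spec$linker_mode == "threading") {
    # straight line through the ligand centroid; axis chosen so the path
    # crosses the shape interior (z for slab/shell, x for the two-lobe dimer)
    t <- (seq_len(L) - (L + 1) / 2) * s
    if (spec$ligand_shape == "two_lobe") cbind(t, 0, 0) else cbind(0, 0, t)
  } else {
    dtheta <- s / spec$path_radius
    theta <- (seq_len(L) - (L + 1) / 2) * dtheta
    cbind(spec$path_radius * cos(theta), 0, spec$path_radius * sin(theta))
  }
}

#' Generate a toy ligand + linker structure with octant ground truth
#'
#' The ligand occupies chain L (heavy carbon atoms); the receptor chain R
#' carries one Calpha per linker residue along the requested path (glycine
#' residues), plus optional terminal domain clusters. Truth labels come from
#' the independent brute-force octant oracle [octant_counts_brute()].
#'
#' @param spec a [structure_sim_spec()].
#' @param params embedding parameters used for the truth labels
#'   (see [embedding_params()]).
#' @return list: `model` (a `structure_model`), `span` (linker residue
#'   range), `truth` (per-residue octant counts and embedded flags).
#' @export
make_linker_structure <- function(spec, params = embedding_params()) {
  if (!inherits(spec, "structure_sim_spec"))
    abort_field("spec", "must be a structure_sim_spec")
  with_seed(spec$seed, {
    lig <- sample_ligand(spec)
    path <- linker_path(spec)
    if (nrow(lig) > 0) {
      inside <- shape_inside(spec, path)
      if (spec$linker_mode == "wrapping" && any(inside))
        stop("impossible geometry: wrapping path intersects the ligand hull",
             call. = FALSE)
    }
    rows <- list()
    serial <- 0L
    add_atom <- function(record, name, resname, chain, resseq, xyz, element) {
      serial <<- serial + 1L
      data.frame(record = record, serial = serial, name = name, altloc = " ",
                 resname = resname, chain = chain, resseq = resseq,
                 x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
                 element = element, stringsAsFactors = FALSE)
    }
    if (nrow(lig) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "HETATM", serial = seq_len(nrow(lig)), name = "C1",
        altloc = " ", resname = "LIG", chain = "L",
        resseq = seq_len(nrow(lig)),
        x = lig[, 1], y = lig[, 2], z = lig[, 3], occupancy = 1,
        element = "C", stringsAsFactors = FALSE)
      serial <- nrow(lig)
    }
    resseq <- 0L
    dom_res <- list()
    if (isTRUE(spec$with_domains)) {
      # 5-atom cluster just before the first linker residue
      anchor <- path[1, ] + c(0, 4, 0)
      for (k in 1:5) {
        resseq <- resseq + 1L
        rows[[length(rows) + 1L]] <- add_atom("ATOM", "CA", "ALA", "R",
                                              resseq,
                                              anchor + c(k - 3, 0, 0), "C")
      }
      dom_res$before <- c(1L, 5L)
    }
    span_start <- resseq + 1L
    for (i in seq_len(nrow(path))) {
      resseq <- resseq + 1L
      rows[[length(rows) + 1L]] <- add_atom("ATOM", "CA", "GLY", "R", resseq,
                                            path[i, ], "C")
    }
    span_end <- resseq
    if (isTRUE(spec$with_domains)) {
      anchor <- path[nrow(path), ] + c(0, 4, 0)
      first <- resseq + 1L
      for (k in 1:5) {
        resseq <- resseq + 1L
        rows[[length(rows) + 1L]] <- add_atom("ATOM", "CA", "ALA", "R",
                                              resseq,
                                              anchor + c(k - 3, 0, 0), "C")
      }
      dom_res$after <- c(first, resseq)
    }
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    model <- structure_model(atoms,
                             if (nrow(lig) > 0) "L" else character(0), "R",
                             id = sprintf("sim_%s_%s_L%d", spec$ligand_shape,
                                          spec$linker_mode,
                                          spec$linker_length))
    span <- linker_span(span_start, span_end, how = "explicit")
    truth <- octant_counts_brute(model, span, params)
    list(model = model, span = span, truth = truth, domain_residues = dom_res)
  })
}

#' Brute-force octant oracle
#'
#' Independent reference implementation of the embedding metric: explicit
#' per-atom loops over sign patterns, no vectorization shared with
#' [octant_counts()]. Used for generator ground truth and oracle-equivalence
#' checks.
#'
#' @param model a `structure_model`.
#' @param span a [linker_span()].
#' @param params an [embedding_params()].
#' @return data.frame: `resseq`, `octant_count`, `embedded`.
#' @export
octant_counts_brute <- function(model, span, params = embedding_params()) {
  lig <- ligand_heavy_atoms(model)
  ca <- receptor_ca(model)
  ca <- ca[ca$resseq >= span$start & ca$resseq <= span$end, , drop = FALSE]
  if (nrow(ca) != span$end - span$start + 1L)
    stop("missing Calpha for residue(s): ",
         paste(setdiff(span$start:span$end, ca$resseq), collapse = ", "),
         call. = FALSE)
  R <- frame_rotation(lig, params)
  out <- data.frame(resseq = ca$resseq, octant_count = 0L, embedded = FALSE)
  for (i in seq_len(nrow(ca))) {
    seen <- rep(FALSE, 8)
    for (j in seq_len(nrow(lig))) {
      dx <- lig$x[j] - ca$x[i]
      dy <- lig$y[j] - ca$y[i]
      dz <- lig$z[j] - ca$z[i]
      if (sqrt(dx * dx + dy * dy + dz * dz) > params$radius) next
      v <- R %*% c(dx, dy, dz)
      oct <- 1L
      if (v[1] < 0) oct <- oct + 1L
      if (v[2] < 0) oct <- oct + 2L
      if (v[3] < 0) oct <- oct + 4L
      seen[oct] <- TRUE
    }
    out$octant_count[i] <- sum(seen)
    out$embedded[i] <- sum(seen) >= params$min_octants
  }
  out
}
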