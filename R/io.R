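# File interfaces. Energies in files are always eV, geometry always
# Angstrom; conversion to the internal hartree/bohr happens on read/write.

#' Read and write XYZ geometries
#'
#' Standard XYZ dialect: atom count, comment line, then `tag x y z` per atom
#' in Angstrom. Internally positions are bohr.
#'
#' @param path file path.
#' @param sites data.frame with `tag`, `x`, `y`, `z` (bohr).
#' @param comment second-line comment.
#' @return `read_xyz` returns a data.frame with columns `tag`, `x`, `y`,
#'   `z` in bohr.
#' @name xyz_io
NULL

#' @rdname xyz_io
#' @export
write_xyz <- function(sites, path, comment = "") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(nrow(sites)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-4s %18.12f %18.12f %18.12f", sites$tag,
                     bohr_to_angstrom(sites$x), bohr_to_angstrom(sites$y),
                     bohr_to_angstrom(sites$z)), con)
  invisible(path)
}

#' @rdname xyz_io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n))
    diabex_error("malformed XYZ file: line 1 is not an atom count", "parse")
  if (length(lines) < n + 2)
    diabex_error(sprintf("malformed XYZ file: expected %d atom lines", n),
                 "parse")
  out <- data.frame(tag = character(n), x = 0, y = 0, z = 0)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4)
      diabex_error(sprintf("malformed XYZ file at line %d", i + 2), "parse")
    out$tag[i] <- tok[1]
    out[i, c("x", "y", "z")] <- angstrom_to_bohr(as.numeric(tok[2:4]))
  }
  out
}

#' Read and write snapshot tables
#'
#' Tab-delimited with header `snapshot  label  value_eV  provenance`
#' (an optional `set` column is written/read as the table's set attribute).
#'
#' @param table a [snapshot_table()].
#' @param path file path.
#' @return `read_snapshot_table` returns a [snapshot_table()].
#' @name snapshot_io
NULL

#' @rdname snapshot_io
#' @export
write_snapshot_table <- function(table, path) {
  df <- as.data.frame(table)
  df$set <- attr(table, "set")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname snapshot_io
#' @export
read_snapshot_table <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e)
      diabex_error(paste("malformed snapshot table:", conditionMessage(e)),
                   "parse"))
  for (col in c("snapshot", "label", "value_eV"))
    if (is.null(df[[col]]))
      diabex_error(sprintf("snapshot table missing column '%s'", col),
                   "parse")
  set <- if (!is.null(df$set)) df$set[1] else "set"
  df$set <- NULL
  snapshot_table(df, set_label = set)
}

#' Read and write fragment definitions
#'
#' Structured YAML document: sites in Angstrom with core charges, Slater
#' exponents in bohr^-1, orbital energies in eV, occupation count and
#' optional orbital coefficients.
#'
#' @param frag a [toy_fragment()].
#' @param path file path.
#' @return `read_fragment` returns a [toy_fragment()].
#' @name fragment_io
NULL

#' @rdname fragment_io
#' @export
write_fragment <- function(frag, path) {
  doc <- list(
    label = frag$label,
    sites = lapply(seq_len(nrow(frag$sites)), function(i) list(
      tag = frag$sites$tag[i],
      position_angstrom = as.numeric(bohr_to_angstrom(
        unlist(frag$sites[i, c("x", "y", "z")]))),
      charge = frag$sites$charge[i])),
    basis = lapply(seq_len(nrow(frag$basis)), function(i) list(
      site = frag$basis$site[i], zeta = frag$basis$zeta[i])),
    n_occ = frag$n_occ,
    orbital_energies_eV = as.numeric(hartree_to_ev(frag$orbital_energies)),
    mo_coeffs = apply(frag$mo_coeffs, 2, as.numeric, simplify = FALSE))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' @rdname fragment_io
#' @export
read_fragment <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    diabex_error(paste("malformed fragment document:",
                       conditionMessage(e)), "parse"))
  sites <- do.call(rbind, lapply(doc$sites, function(s)
    data.frame(tag = s$tag,
               x = angstrom_to_bohr(s$position_angstrom[1]),
               y = angstrom_to_bohr(s$position_angstrom[2]),
               z = angstrom_to_bohr(s$position_angstrom[3]),
               charge = s$charge)))
  basis <- do.call(rbind, lapply(doc$basis, function(b)
    data.frame(site = b$site, zeta = b$zeta)))
  mo <- if (!is.null(doc$mo_coeffs))
    do.call(cbind, lapply(doc$mo_coeffs, as.numeric)) else NULL
  toy_fragment(doc$label, sites, basis, n_occ = doc$n_occ,
               orbital_energies = ev_to_hartree(doc$orbital_energies_eV),
               mo_coeffs = mo)
}

#' Read and write diabatic models
#'
#' JSON document holding the ordered labels, the 6x6 `H` (eV) and `S`
#' matrices and the block provenance; numbers are serialized at full
#' precision so a write/read round trip is lossless.
#'
#' @param model a [assemble_diabatic()] result.
#' @param path file path.
#' @return `read_diabatic_model` returns a `diabatic_model`.
#' @name model_io
NULL

#' @rdname model_io
#' @export
write_diabatic_model <- function(model, path) {
  doc <- list(labels = model$labels,
              H_eV = apply(model$H, 1, as.numeric, simplify = FALSE),
              S = apply(model$S, 1, as.numeric, simplify = FALSE),
              provenance = model$provenance)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
read_diabatic_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    diabex_error(paste("malformed model document:",
                                       conditionMessage(e)), "parse"))
  H <- do.call(rbind, doc$H_eV)
  S <- do.call(rbind, doc$S)
  dimnames(H) <- dimnames(S) <- list(doc$labels, doc$labels)
  structure(list(labels = doc$labels, H = H, S = S,
                 provenance = doc$provenance),
            class = "diabatic_model")
}

#' Read and write environment tables
#'
#' Tab-delimited columns `x`, `y`, `z` (Angstrom), `q` (e), `alpha`
#' (Angstrom^3); converted to bohr / bohr^3 on read.
#'
#' @param env an [environment_sites()] table.
#' @param path file path.
#' @return `read_environment` returns an [environment_sites()] table.
#' @name environment_io
NULL

#' @rdname environment_io
#' @export
write_environment <- function(env, path) {
  df <- data.frame(x = bohr_to_angstrom(env$x), y = bohr_to_angstrom(env$y),
                   z = bohr_to_angstrom(env$z), q = env$q,
                   alpha = env$alpha * BOHR_ANGSTROM^3)
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname environment_io
#' @export
read_environment <- function(path) {
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t"),
                 error = function(e)
                   diabex_error(paste("malformed environment table:",
                                      conditionMessage(e)), "parse"))
  environment_sites(angstrom_to_bohr(df$x), angstrom_to_bohr(df$y),
                    angstrom_to_bohr(df$z), q = df$q,
                    alpha = df$alpha / BOHR_ANGSTROM^3)
}

#' Minimal Molden import of orbital energies and coefficients
#'
#' Parses the `[MO]` section of a Molden file (energies, occupations and
#' coefficient vectors; s-type basis functions are sufficient for the toy
#' backend). Returns the pieces needed to populate a dimer-like orbital
#' set; it does not attempt full basis-set reconstruction.
#'
#' @param path Molden file path.
#' @return list with `energies` (hartree), `occupations` and `coeffs`
#'   (basis x orbitals matrix).
#' @export
read_molden_mos <- function(path) {
  lines <- readLines(path)
  mo_start <- grep("^\\s*\\[MO\\]", lines)
  if (!length(mo_start))
    diabex_error("no [MO] section found in Molden file", "parse")
  i <- mo_start[1] + 1
  energies <- numeric(0); occs <- numeric(0); coeffs <- list()
  current <- NULL
  flush_current <- function() {
    if (!is.null(current)) coeffs[[length(coeffs) + 1]] <<- current
    current <<- NULL
  }
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^\\[", ln)) break
    if (grepl("^Ene=", ln, ignore.case = TRUE)) {
      flush_current()
      energies <- c(energies, as.numeric(sub("(?i)^Ene=\\s*", "", ln,
                                             perl = TRUE)))
      current <- numeric(0)
    } else if (grepl("^Occup=", ln, ignore.case = TRUE)) {
      occs <- c(occs, as.numeric(sub("(?i)^Occup=\\s*", "", ln,
                                     perl = TRUE)))
    } else if (grepl("^(Sym|Spin)=", ln, ignore.case = TRUE)) {
      # metadata lines, ignored
    } else if (nzchar(ln)) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != 2 || is.na(as.numeric(tok[2])))
        diabex_error(sprintf("malformed Molden coefficient at line %d", i),
                     "parse")
      idx <- as.integer(tok[1])
      current[idx] <- as.numeric(tok[2])
    }
    i <- i + 1
  }
  flush_current()
  if (!length(coeffs))
    diabex_error("empty [MO] section in Molden file", "parse")
  nb <- max(vapply(coeffs, length, integer(1)))
  C <- vapply(coeffs, function(v) { length(v) <- nb; v[is.na(v)] <- 0; v },
              numeric(nb))
  list(energies = energies, occupations = occs, coeffs = C)
}
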