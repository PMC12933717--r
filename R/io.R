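# XYZ / extended-XYZ readers and writers, JSON Lines dataset manifests,
# YAML config loading.

#' Pair a reference geometry with its low-fidelity counterpart
#'
#' @param reference high-fidelity structure.
#' @param low_fidelity low-fidelity counterpart; must share the reference's
#'   element sequence (atom order is meaningful).
#' @param reaction_id text identifier.
#' @return An object of class \code{aefm_refinement_pair}.
#' @export
refinement_pair <- function(reference, low_fidelity, reaction_id = NULL) {
  stopifnot(is_aefm_structure(reference), is_aefm_structure(low_fidelity))
  if (n_atoms(reference) != n_atoms(low_fidelity) ||
      !identical(reference$elements, low_fidelity$elements))
    .aefm_error(sprintf(
      "reference and low-fidelity structures disagree in elements/atom count%s",
      if (is.null(reaction_id)) "" else paste0(" for reaction ", reaction_id)),
      "aefm_pairing_error")
  structure(list(reference = reference, low_fidelity = low_fidelity,
                 reaction_id = reaction_id),
            class = "aefm_refinement_pair")
}

#' Read a (multi-frame) XYZ or extended-XYZ file
#'
#' Each frame is an atom count line, a comment line (kept verbatim as the
#' structure's \code{id} when non-empty; extended-XYZ key/value metadata is
#' therefore preserved), then one \code{element x y z} line per atom (extra
#' columns beyond the first four fields are ignored). Coordinates are
#' Angstrom; no unit autodetection is attempted.
#'
#' @param path file path.
#' @return list of \code{aefm_structure}, in file order.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    .aefm_error(paste0("no such file: ", path), "aefm_missing_file")
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }  # trailing blanks
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      .aefm_error(sprintf("line %d: expected an atom count, got '%s'",
                          i, lines[i]), "aefm_parse_error")
    if (i + 1L + nat > nline)
      .aefm_error(sprintf(
        "line %d: frame declares %d atoms but the file ends early", i, nat),
        "aefm_parse_error")
    comment <- lines[i + 1L]
    elements <- character(nat)
    coords <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L)
        .aefm_error(sprintf("line %d: expected 'element x y z'", ln),
                    "aefm_parse_error")
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        .aefm_error(sprintf("line %d: unparseable coordinate", ln),
                    "aefm_parse_error")
      elements[k] <- tok[1]
      coords[k, ] <- xyz
    }
    id <- if (nzchar(trimws(comment))) comment else NULL
    frames[[length(frames) + 1L]] <- aefm_structure(elements, coords, id = id)
    i <- i + 2L + nat
  }
  frames
}

#' Write structures to a multi-frame XYZ file
#'
#' Deterministic fixed-format output with 8 decimal places; an empty input
#' list yields an empty file.
#'
#' @param structures an \code{aefm_structure} or list of them.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(structures, path) {
  if (is_aefm_structure(structures)) structures <- list(structures)
  out <- character(0)
  for (s in structures) {
    stopifnot(is_aefm_structure(s))
    comment <- if (is.null(s$id)) "" else s$id
    body <- sprintf("%-3s %15.8f %15.8f %15.8f",
                    s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3])
    out <- c(out, as.character(n_atoms(s)), comment, body)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(out)) writeLines(out, con)
  invisible(path)
}

#' Write a JSON Lines dataset manifest
#'
#' One JSON object per line. An optional header object (e.g. recording the
#' true corruption scale of a synthetic benchmark) is written first and is
#' recognized on reading by the absence of a \code{reaction_id} field.
#'
#' @param entries list of entries, each a list with \code{reaction_id},
#'   \code{reference = list(file, frame)} and
#'   \code{low_fidelity = list(file, frame)}; frame indices are 0-based.
#' @param path destination path; entry file paths are interpreted relative
#'   to its directory.
#' @param header optional named list of metadata.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(entries, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header))
    lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  ids <- vapply(entries, function(e) as.character(e$reaction_id), "")
  if (anyDuplicated(ids))
    .aefm_error("duplicate reaction_id values in manifest entries",
                "aefm_pairing_error")
  lines <- c(lines, vapply(entries, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Load reference/low-fidelity pairs from a JSON Lines manifest
#'
#' Resolves each entry's file/frame pointers (paths relative to the
#' manifest, frames 0-based), verifies element-sequence agreement within
#' each pair, and returns pairs in manifest order.
#'
#' @param manifest_path path to a JSON Lines manifest (see
#'   \code{\link{write_manifest}}).
#' @return list of \code{aefm_refinement_pair}. The manifest header (if any)
#'   is attached as attribute \code{"header"}.
#' @export
load_pairs <- function(manifest_path) {
  if (!file.exists(manifest_path))
    .aefm_error(paste0("no such manifest: ", manifest_path),
                "aefm_missing_file")
  root <- dirname(manifest_path)
  lines <- readLines(manifest_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(lines, jsonlite::fromJSON)
  is_entry <- vapply(objs, function(o) !is.null(o$reaction_id), TRUE)
  header <- if (any(!is_entry)) objs[[which(!is_entry)[1]]] else NULL
  entries <- objs[is_entry]
  ids <- vapply(entries, function(e) as.character(e$reaction_id), "")
  if (anyDuplicated(ids))
    .aefm_error("duplicate reaction_id values in manifest",
                "aefm_pairing_error")
  cache <- new.env(parent = emptyenv())
  frame_of <- function(ptr, id) {
    f <- file.path(root, ptr$file)
    if (!file.exists(f))
      .aefm_error(sprintf("reaction %s points to missing file %s", id, f),
                  "aefm_missing_file")
    key <- normalizePath(f)
    if (!exists(key, envir = cache)) assign(key, read_xyz(f), envir = cache)
    frames <- get(key, envir = cache)
    k <- as.integer(ptr$frame) + 1L   # manifest frames are 0-based
    if (is.na(k) || k < 1L || k > length(frames))
      .aefm_error(sprintf("reaction %s: frame %s out of range in %s",
                          id, ptr$frame, f), "aefm_pairing_error")
    frames[[k]]
  }
  pairs <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    ref <- frame_of(e$reference, e$reaction_id)
    low <- frame_of(e$low_fidelity, e$reaction_id)
    ref$id <- e$reaction_id
    low$id <- e$reaction_id
    pairs[[i]] <- refinement_pair(ref, low, reaction_id = e$reaction_id)
  }
  attr(pairs, "header") <- header
  pairs
}

#' Load and validate a YAML configuration file
#'
#' A single schema with optional \code{train} and \code{solver} sections;
#' recognized keys override the package defaults of
#' \code{\link{train_config}} and \code{\link{solver_config}}.
#'
#' @param path YAML file path.
#' @return list with validated \code{train} and \code{solver} configs.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    .aefm_error(paste0("no such config file: ", path), "aefm_missing_file")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("train", "solver")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    .aefm_error(paste0("unknown config section(s): ",
                       paste(extra, collapse = ", ")), "aefm_parameter_error")
  apply_section <- function(fn, args) {
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      .aefm_error(paste0("unknown config key(s): ",
                         paste(bad, collapse = ", ")), "aefm_parameter_error")
    do.call(fn, args)
  }
  list(train = apply_section(train_config, raw$train),
       solver = apply_section(solver_config, raw$solver))
}
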