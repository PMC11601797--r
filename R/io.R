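# ---------------------------------------------------------------------------
# Dataset-level I/O: SDF conformer reading/writing, curated dataset
# export, and the headline statistics table (compound/active counts,
# percent active, unique Bemis-Murcko scaffolds).
# ---------------------------------------------------------------------------

#' Read 3D conformers from an SDF file
#'
#' Each molecule block contributes one entry keyed by compound id, taken
#' from the `compound_id` data field when present and from the molecule
#' name line otherwise. Coordinates and elements are returned exactly as
#' read (hydrogens included when present). Blocks without a resolvable id
#' are skipped with a warning; when an id repeats, the last occurrence
#' wins (logged). Molecules whose coordinates are all zero carry the
#' `no-3d` flag.
#'
#' @param path an MDL SDF file (V2000).
#' @return named list; each element has `coords` (n x 3 matrix, Angstrom),
#'   `elements` (character) and `flags` (character).
#' @export
read_sdf_conformers <- function(path) {
  if (!file.exists(path)) stop("cannot read SDF: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into molecule blocks; the general-purpose SDF container cannot
  # represent bond-less (single-atom) molecules, so the coordinate block
  # is scanned directly at the fixed V2000 columns
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  skipped <- 0L
  for (b in seq_along(ends)) {
    blk <- lines[starts[b]:ends[b]]
    if (length(blk) < 5) next
    name <- trimws(blk[1])
    n_atoms <- suppressWarnings(as.integer(substr(blk[4], 1, 3)))
    if (is.na(n_atoms) || length(blk) < 4 + n_atoms) {
      skipped <- skipped + 1L
      next
    }
    atom_lines <- blk[4 + seq_len(n_atoms)]
    coords <- cbind(
      x = as.numeric(substr(atom_lines, 1, 10)),
      y = as.numeric(substr(atom_lines, 11, 20)),
      z = as.numeric(substr(atom_lines, 21, 30))
    )
    elements <- trimws(substr(atom_lines, 32, 34))
    # id: a <compound_id> data field wins over the name line
    id <- name
    fld <- grep("^>.*<compound_id>", blk)
    if (length(fld) && fld[1] < length(blk)) id <- trimws(blk[fld[1] + 1])
    if (is.na(id) || !nzchar(id)) {
      skipped <- skipped + 1L
      next
    }
    entry <- list(coords = coords, elements = elements,
                  flags = character(0))
    if (all(abs(coords) < 1e-12)) entry$flags <- "no-3d"
    if (!is.null(out[[id]])) {
      warning("duplicate id '", id, "' in SDF; last occurrence wins")
    }
    out[[id]] <- entry
  }
  if (skipped > 0) {
    warning(skipped, " molecule block(s) without resolvable id skipped")
  }
  out
}

#' Write a conformer set to an SDF file
#'
#' Inverse of [read_sdf_conformers()]: writes one V2000 molecule block
#' per entry with the id on the name line and in a `compound_id` data
#' field. Coordinates are written at the MDL precision of 4 decimals.
#'
#' @param conformers named list as returned by [read_sdf_conformers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf_conformers <- function(conformers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(conformers)) {
    cf <- conformers[[id]]
    n <- nrow(cf$coords)
    lines <- c(
      id, " htscurate", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              cf$coords[, 1], cf$coords[, 2], cf$coords[, 3],
              cf$elements),
      "M  END",
      "> <compound_id>", id, "", "$$$$"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a curated dataset to standard formats
#'
#' Emits the requested formats into `directory`, deterministically
#' ordered by compound id, together with a JSON manifest listing files,
#' record counts and the toolkit version.
#'
#' @param records a labelled `compound_records` table (or the `records`
#'   element of a `curated_dataset`).
#' @param directory output directory, created when missing.
#' @param formats subset of `smiles_csv`, `inchi_csv`, `sdf`.
#' @return the manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
write_curated_dataset <- function(records, directory,
                                  formats = c("smiles_csv", "inchi_csv")) {
  formats <- match.arg(formats, c("smiles_csv", "inchi_csv", "sdf"),
                       several.ok = TRUE)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", directory)
  }
  if (file.access(directory, 2) != 0) {
    stop("output directory not writable: ", directory)
  }
  if (!"label" %in% names(records)) {
    stop("records must carry an active/inactive label")
  }
  ord <- order(records$compound_id)
  records <- records[ord, , drop = FALSE]
  files <- list()
  if ("smiles_csv" %in% formats) {
    p <- file.path(directory, "curated_smiles.csv")
    utils::write.csv(data.frame(compound_id = records$compound_id,
                                smiles = records$smiles,
                                label = records$label),
                     p, row.names = FALSE, quote = FALSE)
    files$smiles_csv <- basename(p)
  }
  if ("inchi_csv" %in% formats) {
    p <- file.path(directory, "curated_inchi.csv")
    utils::write.csv(data.frame(compound_id = records$compound_id,
                                inchi = records$inchi,
                                label = records$label),
                     p, row.names = FALSE, quote = FALSE)
    files$inchi_csv <- basename(p)
  }
  if ("sdf" %in% formats) {
    p <- file.path(directory, "curated.sdf")
    prs <- parse_smiles(records$smiles, ids = records$compound_id)
    if (!all(prs$ok)) {
      stop("unparsable SMILES in curated records: ",
           paste(records$compound_id[!prs$ok], collapse = ", "))
    }
    ChemmineR::write.SDF(prs$sdf, p, cid = TRUE)
    files$sdf <- basename(p)
  }
  manifest <- list(files = files, n_records = nrow(records),
                   n_actives = sum(records$label == "active"),
                   version = as.character(utils::packageVersion("htscurate")))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Dataset statistics
#'
#' Computes the headline statistics reported for curated HTS datasets:
#' compound count, active count, percent active (displayed at 3 decimal
#' places) and the number of unique Bemis-Murcko scaffolds.
#'
#' @param records a labelled `compound_records` table.
#' @param scaffold_fn function mapping a SMILES vector to scaffold
#'   strings; defaults to [murcko_scaffold()]. Pass `NULL` to skip
#'   scaffold counting.
#' @return object of class `stats_report`: list with `n_compounds`,
#'   `n_actives`, `percent_active` (exact value), `percent_active_display`
#'   (3-decimal string) and `n_unique_scaffolds` (`NA` when skipped).
#' @export
dataset_stats <- function(records, scaffold_fn = murcko_scaffold) {
  n <- nrow(records)
  if (n == 0) {
    warning("dataset_stats on zero records")
    return(structure(list(n_compounds = 0L, n_actives = 0L,
                          percent_active = 0, percent_active_display = "0.000%",
                          n_unique_scaffolds = 0L), class = "stats_report"))
  }
  n_act <- sum(records$label == "active")
  pct <- percent_active(n, n_act)
  n_scaf <- if (is.null(scaffold_fn)) NA_integer_ else {
    scaf <- scaffold_fn(records$smiles)
    length(unique(scaf[!is.na(scaf)]))
  }
  structure(list(n_compounds = n, n_actives = n_act,
                 percent_active = pct$value,
                 percent_active_display = pct$display,
                 n_unique_scaffolds = n_scaf),
            class = "stats_report")
}

#' Percent-active arithmetic
#'
#' @param n_compounds,n_actives dataset counts.
#' @return list with `value` (exact percentage) and `display` (formatted
#'   at 3 decimals with a percent sign, the conventional table format).
#' @export
percent_active <- function(n_compounds, n_actives) {
  stopifnot(n_actives >= 0, n_actives <= n_compounds)
  value <- 100 * n_actives / n_compounds
  list(value = value, display = sprintf("%.3f%%", value))
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Dataset statistics\n")
  cat("  compounds       :", x$n_compounds, "\n")
  cat("  actives         :", x$n_actives, "\n")
  cat("  percent active  :", x$percent_active_display, "\n")
  cat("  unique scaffolds:", x$n_unique_scaffolds, "\n")
  invisible(x)
}
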