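# ---------------------------------------------------------------------------
# Compound records: one row per tested compound, carrying identifiers
# (id, isomeric SMILES, standard InChI), per-screen outcomes and audit
# flags. Stored as a plain data.frame subclass so the usual data.frame
# tooling keeps working.
# ---------------------------------------------------------------------------

.OUTCOME_LEVELS <- c("active", "inactive", "inconclusive", "untested")
.OUTCOME_CODES <- c(A = "active", I = "inactive", Q = "inconclusive",
                    U = "untested")

#' Construct a compound record table
#'
#' @param compound_id character vector of non-empty identifiers.
#' @param smiles,inchi character vectors (either may contain `NA`, but at
#'   least one identifier must be present per record).
#' @param outcomes named list of outcome vectors, one per screen id, each
#'   with values in `active`, `inactive`, `inconclusive`, `untested`.
#' @param flags optional character vector of `;`-separated audit flags.
#' @param hierarchy optional `screen_hierarchy`; when given, outcome
#'   columns must correspond to declared screens.
#' @return data.frame of class `compound_records` with columns
#'   `compound_id`, `smiles`, `inchi`, `flags`, then one column per screen.
#' @export
compound_records <- function(compound_id, smiles = NA, inchi = NA,
                             outcomes = list(), flags = NULL,
                             hierarchy = NULL) {
  n <- length(compound_id)
  compound_id <- as.character(compound_id)
  if (any(is.na(compound_id) | !nzchar(compound_id))) {
    stop("compound_id must be non-empty")
  }
  smiles <- rep_len(as.character(smiles), n)
  inchi <- rep_len(as.character(inchi), n)
  no_struct <- (is.na(smiles) | !nzchar(smiles)) &
    (is.na(inchi) | !nzchar(inchi))
  if (any(no_struct)) {
    stop("records without smiles and inchi: ",
         paste(utils::head(compound_id[no_struct], 5), collapse = ", "))
  }
  if (!is.null(hierarchy)) {
    if (length(bad <- setdiff(names(outcomes), screen_ids(hierarchy)))) {
      stop("outcomes reference undeclared screen(s): ",
           paste(bad, collapse = ", "))
    }
  }
  df <- data.frame(compound_id = compound_id, smiles = smiles, inchi = inchi,
                   flags = rep_len(as.character(flags %||% ""), n),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (sid in names(outcomes)) {
    v <- as.character(rep_len(outcomes[[sid]], n))
    if (length(bad <- setdiff(stats::na.omit(unique(v)), .OUTCOME_LEVELS))) {
      stop("invalid outcome value(s) for screen ", sid, ": ",
           paste(bad, collapse = ", "))
    }
    v[is.na(v)] <- "untested"
    df[[sid]] <- v
  }
  class(df) <- c("compound_records", "data.frame")
  attr(df, "screens") <- names(outcomes)
  df
}

#' Screen outcome columns of a record table
#' @param records a `compound_records` table.
#' @return character vector of screen ids carried by the table.
#' @export
record_screens <- function(records) {
  scr <- attr(records, "screens")
  if (is.null(scr)) {
    scr <- setdiff(names(records),
                   c("compound_id", "smiles", "inchi", "flags", "label"))
  }
  scr
}

# append a flag to selected rows, keeping the ;-separated encoding tidy
.add_flag <- function(records, idx, flag) {
  cur <- records$flags[idx]
  has <- vapply(strsplit(cur, ";", fixed = TRUE),
                function(f) flag %in% f, TRUE)
  records$flags[idx][!has] <- ifelse(nzchar(cur[!has]),
                                     paste0(cur[!has], ";", flag), flag)
  records
}

#' Audit flags of each record as a list
#' @param records a `compound_records` table.
#' @return list of character vectors.
#' @export
record_flags <- function(records) {
  lapply(strsplit(records$flags, ";", fixed = TRUE),
         function(f) f[nzchar(f)])
}

#' Does an InChI string carry a stereochemical layer?
#'
#' Stereo information lives in the `/b` (double bond), `/t` (tetrahedral),
#' `/m` (parity) and `/s` (stereo type) layers.
#'
#' @param inchi character vector of InChI strings.
#' @return logical vector.
#' @export
inchi_has_stereo <- function(inchi) {
  !is.na(inchi) & grepl("/[bt][0-9]|/m[0-9]|/s[0-9]", inchi)
}

#' Does a SMILES string carry stereo marks?
#' @param smiles character vector.
#' @return logical vector (`@`, `/` or `\` present).
#' @export
smiles_has_stereo <- function(smiles) {
  !is.na(smiles) & grepl("[@/\\\\]", smiles)
}

# formula + connectivity + hydrogen layers of an InChI: the part that must
# agree between a SMILES-derived and a deposited InChI regardless of
# stereo/protonation annotation
.inchi_skeleton <- function(inchi) {
  vapply(strsplit(inchi, "/", fixed = TRUE), function(tok) {
    if (length(tok) < 2 || is.na(tok[1])) return(NA_character_)
    keep <- c(tok[2], tok[-(1:2)][grepl("^[ch]", tok[-(1:2)])])
    paste(keep, collapse = "/")
  }, NA_character_)
}

#' Read a compound table from delimited text
#'
#' Expects a header with `compound_id`, `smiles` and/or `inchi`, plus one
#' outcome column per screen declared in `hierarchy`, coded
#' `A`/`I`/`Q`/`U` (active/inactive/inconclusive/untested). Unknown
#' outcome codes are mapped to `inconclusive` with a warning. Rows are
#' never dropped: questionable identifiers are flagged
#' (`non-isomeric-smiles` when the InChI has a stereo layer the SMILES
#' lacks; `nonstandard-inchi` when the InChI does not start `InChI=1S/`).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   `.tsv`/`.txt` read as tab-separated).
#' @param hierarchy a `screen_hierarchy` declaring the screens.
#' @return a `compound_records` table.
#' @export
read_compound_table <- function(path, hierarchy) {
  if (!file.exists(path)) stop("cannot read compound table: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(df)) {
    stop("compound table is missing required column 'compound_id'")
  }
  if (!any(c("smiles", "inchi") %in% names(df))) {
    stop("compound table is missing required column 'smiles' (or 'inchi')")
  }
  if (nrow(df) == 0) {
    warning("compound table '", basename(path), "' has no data rows")
  }
  scr <- intersect(screen_ids(hierarchy), names(df))
  outcomes <- list()
  for (sid in scr) {
    code <- toupper(trimws(df[[sid]]))
    code[is.na(code) | !nzchar(code)] <- "U"
    unknown <- !code %in% names(.OUTCOME_CODES)
    if (any(unknown)) {
      warning(sum(unknown), " unknown outcome code(s) in screen ", sid,
              " mapped to inconclusive")
      code[unknown] <- "Q"
    }
    outcomes[[sid]] <- unname(.OUTCOME_CODES[code])
  }
  rec <- compound_records(
    compound_id = df$compound_id,
    smiles = if ("smiles" %in% names(df)) df$smiles else NA,
    inchi = if ("inchi" %in% names(df)) df$inchi else NA,
    outcomes = outcomes, hierarchy = hierarchy
  )
  bad_inchi <- !is.na(rec$inchi) & nzchar(rec$inchi) &
    !startsWith(rec$inchi, "InChI=1S/")
  if (any(bad_inchi)) rec <- .add_flag(rec, which(bad_inchi), "nonstandard-inchi")
  noniso <- inchi_has_stereo(rec$inchi) & !smiles_has_stereo(rec$smiles) &
    !is.na(rec$smiles)
  if (any(noniso)) rec <- .add_flag(rec, which(noniso), "non-isomeric-smiles")
  rec
}

#' Encode outcomes back to single-letter codes
#' @param outcome character vector of outcome levels.
#' @return character vector of `A`/`I`/`Q`/`U` codes.
#' @export
outcome_code <- function(outcome) {
  names(.OUTCOME_CODES)[match(outcome, .OUTCOME_CODES)]
}

#' Write a compound record table to CSV
#' @param records a `compound_records` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path) {
  df <- as.data.frame(records)
  for (sid in record_screens(records)) df[[sid]] <- outcome_code(df[[sid]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
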