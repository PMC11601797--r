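#' @importFrom methods is slot slot<-
NULL

# ---------------------------------------------------------------------------
# OpenBabel-backed chemistry primitives.
#
# Everything that touches molecular structure funnels through this file:
# SMILES parsing, canonicalization, property calculation, SMARTS matching,
# charge neutralization and Bemis-Murcko framework extraction. All public
# entry points are vectorized over character vectors of SMILES and batch
# their OpenBabel calls, because per-molecule round trips dominate runtime
# on campaign-sized inputs.
# ---------------------------------------------------------------------------

# Maximum permitted total bond order (kekulized) per element, before charge
# adjustment. OpenBabel parses hypervalent SMILES without complaint, so the
# package enforces a standard valence model itself.
.MAX_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
  Cl = 1, Se = 6, Br = 1, I = 1
)

# Typical (lowest) valence used to infer implicit hydrogen counts.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Se = 2, Br = 1, I = 1
)

# Elements regarded as organic for the inorganic-substance filter.
.ORGANIC_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I"
)

# MDL ctab charge codes <-> formal charges (0 = neutral, 1..3 = +3..+1,
# 4 = radical, 5..7 = -1..-3).
.mdl_code_to_charge <- function(code) {
  ch <- integer(length(code))
  ch[code >= 1 & code <= 3] <- 4L - as.integer(code[code >= 1 & code <= 3])
  ch[code >= 5 & code <= 7] <- 4L - as.integer(code[code >= 5 & code <= 7])
  ch
}

.charge_to_mdl_code <- function(charge) {
  code <- integer(length(charge))
  code[charge != 0] <- 4L - as.integer(charge[charge != 0])
  code
}

.sdf_element <- function(sdf) {
  sub("_[0-9]+$", "", rownames(ChemmineR::atomblock(sdf)))
}

.sdf_charges <- function(sdf) {
  .mdl_code_to_charge(ChemmineR::atomblock(sdf)[, "C6"])
}

.sdf_bonds <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("a1", "a2", "order"))))
  }
  m <- cbind(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  # order code 4 marks an aromatic bond in some writers; count it as 1.5
  m[m[, "order"] == 4, "order"] <- 1.5
  m
}

.sdfset_text <- function(sdfset) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  ChemmineR::write.SDF(sdfset, tmp)
  paste(readLines(tmp, warn = FALSE), collapse = "\n")
}

.ob_quiet <- function(expr) {
  # OpenBabel chats on stderr; keep parse diagnostics out of user output.
  msgs <- character(0)
  res <- withCallingHandlers(expr, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  res
}

#' Parse SMILES strings into an SDF container
#'
#' Batch-parses a character vector of SMILES through OpenBabel. Parsing
#' failures do not abort the batch: failed entries are reported in the
#' `ok` vector and omitted from the returned `SDFset`.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers; defaults to `names(smiles)` or
#'   positional labels.
#' @return list with components `sdf` (an [ChemmineR::SDFset] of the
#'   molecules that parsed), `ok` (logical, one per input), and `index`
#'   (position in `sdf` for each input, `NA` where parsing failed).
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- sprintf("mol%05d", seq_along(smiles))
  smiles <- as.character(smiles)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))

  parse_block <- function(idx) {
    # bisecting batch parser: one OpenBabel call when everything is valid,
    # log-factor fallback when a bad SMILES poisons the batch
    if (!length(idx)) return(list())
    res <- tryCatch(
      suppressWarnings(
        .ob_quiet(ChemmineR::smiles2sdf(stats::setNames(smiles[idx],
                                                        ids[idx])))),
      error = function(e) NULL)
    if (!is.null(res) && length(res) == length(idx)) {
      # bond-less molecules (single atoms) break downstream SDF writers;
      # they are handled by the single-atom fallback, not the SDF path
      valid <- suppressWarnings(ChemmineR::validSDF(res))
      if (!all(valid)) {
        if (!any(valid)) return(list())
        return(list(list(idx = idx[valid], sdf = res[valid])))
      }
      return(list(list(idx = idx, sdf = res)))
    }
    if (length(idx) == 1L) return(list())
    half <- length(idx) %/% 2
    c(parse_block(idx[seq_len(half)]), parse_block(idx[-seq_len(half)]))
  }

  blocks <- parse_block(which(ok))
  parsed_idx <- unlist(lapply(blocks, `[[`, "idx"))
  ok <- seq_along(smiles) %in% parsed_idx
  index <- rep(NA_integer_, length(smiles))
  if (length(parsed_idx)) {
    sdf_list <- lapply(blocks, `[[`, "sdf")
    sdfs <- if (length(sdf_list) == 1L) sdf_list[[1L]]
            else do.call(c, sdf_list)
    index[parsed_idx] <- seq_along(parsed_idx)
  } else {
    sdfs <- NULL
  }
  list(sdf = sdfs, ok = ok, index = index)
}

#' Canonical SMILES via OpenBabel
#'
#' Canonicalization also performs aromaticity perception, so kekulized and
#' aromatic spellings of the same molecule map to one string.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  valid <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (!length(valid)) return(out)
  tags <- sprintf("t%06d", seq_along(valid))
  src <- paste(paste(smiles[valid], tags), collapse = "\n")
  res <- tryCatch(
    .ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", source = paste0(src, "\n"))),
    error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_tag <- vapply(parts, function(p) trimws(p[length(p)]), "")
    got_smi <- vapply(parts, `[[`, "", 1L)
    hit <- match(tags, got_tag)
    out[valid] <- got_smi[hit]
  }
  if (anyNA(out[valid])) {
    # batch produced fewer molecules than inputs: recover stragglers singly
    for (i in valid[is.na(out[valid])]) {
      res1 <- tryCatch(
        .ob_quiet(ChemmineOB::convertFormat("SMI", "CAN",
                                            source = paste0(smiles[i], "\n"))),
        error = function(e) "")
      line <- strsplit(res1, "\n", fixed = TRUE)[[1]][1]
      if (!is.na(line) && nzchar(trimws(line))) {
        out[i] <- strsplit(trimws(line), "[ \t]")[[1]][1]
      }
    }
  }
  out
}

#' Molecular properties for a set of SMILES
#'
#' Computes, through OpenBabel, the properties the curation filters need:
#' molecular weight (standard atomic masses), logP, Lipinski hydrogen-bond
#' donors, Lipinski acceptors (N + O count), molecular formula, canonical
#' SMILES and standard InChI.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with one row per input (`NA` rows for parse
#'   failures) and columns `smiles`, `cansmi`, `formula`, `mw`, `logp`,
#'   `hbd`, `hba`, `inchi`.
#' @export
mol_properties <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(
    smiles = as.character(smiles), cansmi = rep(NA_character_, n),
    formula = rep(NA_character_, n), mw = rep(NA_real_, n),
    logp = rep(NA_real_, n), hbd = rep(NA_real_, n),
    hba = rep(NA_real_, n), inchi = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  p <- parse_smiles(smiles)
  for (i in which(!p$ok)) {
    sa <- .single_atom_props(out$smiles[i])
    if (!is.null(sa)) {
      out$cansmi[i] <- out$smiles[i]
      out$formula[i] <- sa$formula
      out$mw[i] <- sa$mw
      out$logp[i] <- 0
      out$hbd[i] <- 0
      out$hba[i] <- as.numeric(sa$element %in% c("N", "O"))
      out$inchi[i] <- sa$inchi
    }
  }
  if (is.null(p$sdf)) return(out)
  props <- .ob_quiet(ChemmineR::propOB(p$sdf))
  hit <- !is.na(p$index)
  out$cansmi[hit] <- props$cansmi[p$index[hit]]
  out$formula[hit] <- props$formula[p$index[hit]]
  out$mw[hit] <- props$MW[p$index[hit]]
  out$logp[hit] <- props$logP[p$index[hit]]
  out$hbd[hit] <- props$HBD[p$index[hit]]
  out$inchi[hit] <- props$InChI[p$index[hit]]
  out$hba[hit] <- vapply(which(hit), function(i) {
    cnt <- formula_counts(out$formula[i])
    sum(cnt[names(cnt) %in% c("N", "O")])
  }, numeric(1))
  out
}

#' Parse a molecular formula into element counts
#'
#' @param formula a Hill-order molecular formula, possibly with a trailing
#'   charge sign (as emitted by OpenBabel, e.g. `"C2H3O2-"`).
#' @return named integer vector of element counts.
#' @export
formula_counts <- function(formula) {
  if (is.na(formula)) return(stats::setNames(integer(0), character(0)))
  body <- gsub("[+-]+[0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  toks <- regmatches(body, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  vapply(split(ct, el), sum, integer(1))
}

#' Check a parsed molecule against a standard valence model
#'
#' @param sdf a single `SDF` object.
#' @return `NULL` when all atoms are within their permitted valence, else a
#'   message naming the first offending atom.
#' @keywords internal
check_valence <- function(sdf) {
  el <- .sdf_element(sdf)
  ch <- .sdf_charges(sdf)
  bonds <- .sdf_bonds(sdf)
  n <- length(el)
  bsum <- numeric(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds[r, 1]] <- bsum[bonds[r, 1]] + bonds[r, "order"]
      bsum[bonds[r, 2]] <- bsum[bonds[r, 2]] + bonds[r, "order"]
    }
  }
  for (i in seq_len(n)) {
    maxv <- .MAX_VALENCE[el[i]]
    if (is.na(maxv)) next  # element outside the model: inorganic filter's job
    # lone-pair bearing elements gain a bond per positive charge; carbon
    # family loses one per unit of charge either way
    allowed <- if (el[i] %in% c("C", "Si")) maxv - abs(ch[i]) else maxv + ch[i]
    if (bsum[i] > allowed + 1e-9) {
      return(sprintf("atom %d (%s) has total bond order %.1f > %g",
                     i, el[i], bsum[i], allowed))
    }
  }
  NULL
}

# Implicit hydrogen counts from the kekulized connection table.
.implicit_h <- function(sdf) {
  el <- .sdf_element(sdf)
  ch <- .sdf_charges(sdf)
  bonds <- .sdf_bonds(sdf)
  bsum <- numeric(length(el))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds[r, 1]] <- bsum[bonds[r, 1]] + bonds[r, "order"]
      bsum[bonds[r, 2]] <- bsum[bonds[r, 2]] + bonds[r, "order"]
    }
  }
  dv <- .DEFAULT_VALENCE[el]
  dv[is.na(dv)] <- 0
  adj <- ifelse(el %in% c("C", "Si"), dv - abs(ch), dv + ch)
  # promote to the next standard valence when bonds already exceed it
  # (e.g. sulfone S, phosphate P)
  pmax(0, round(pmax(adj, ceiling(bsum)) - bsum))
}

#' Neutralize charged atoms in place
#'
#' Applies a neutralize-by-atom rule: every atom carrying a formal charge
#' whose bonded neighbors do not include an oppositely charged atom has its
#' charge zeroed, with hydrogen counts re-derived from standard valences.
#' Internally compensated groups such as nitro or N-oxide are left intact.
#' If zeroing a charge would violate the valence model (e.g. a quaternary
#' ammonium), the molecule is returned unchanged and marked.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `smiles` (neutralized canonical SMILES,
#'   or the original when untouched/failed), `changed`, and `failed`
#'   (valence conflict, original kept).
#' @export
neutralize_charges <- function(smiles) {
  out <- data.frame(smiles = as.character(smiles),
                    changed = rep(FALSE, length(smiles)),
                    failed = rep(FALSE, length(smiles)),
                    stringsAsFactors = FALSE)
  p <- parse_smiles(smiles)
  todo <- which(p$ok)
  if (!length(todo)) return(out)
  edited <- list()
  for (i in todo) {
    mol <- p$sdf[[p$index[i]]]
    ch <- .sdf_charges(mol)
    if (!any(ch != 0)) next
    bonds <- .sdf_bonds(mol)
    nb <- function(a) {
      c(bonds[bonds[, 1] == a, 2], bonds[bonds[, 2] == a, 1])
    }
    target <- ch
    for (a in which(ch != 0)) {
      neigh <- nb(a)
      if (!any(sign(ch[neigh]) == -sign(ch[a]))) target[a] <- 0L
    }
    if (all(target == ch)) next
    ab <- ChemmineR::atomblock(mol)
    ab[, "C6"] <- .charge_to_mdl_code(target)
    mol2 <- mol
    slot(mol2, "atomblock") <- ab
    if (!is.null(check_valence(mol2))) {
      out$failed[i] <- TRUE
      next
    }
    edited[[length(edited) + 1L]] <- list(i = i, mol = mol2)
  }
  if (length(edited)) {
    set <- methods::new("SDFset", SDF = lapply(edited, `[[`, "mol"),
                        ID = sprintf("n%06d", seq_along(edited)))
    txt <- .sdfset_text(set)
    res <- .ob_quiet(ChemmineOB::convertFormat("SDF", "CAN", source = txt))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    smis <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    for (j in seq_along(edited)) {
      i <- edited[[j]]$i
      if (j <= length(smis) && nzchar(smis[j])) {
        out$smiles[i] <- smis[j]
        out$changed[i] <- TRUE
      } else {
        out$failed[i] <- TRUE
      }
    }
  }
  out
}

#' Rewrite molecules in aromatic (non-kekulized) canonical form
#'
#' Kekulized spellings of aromatic systems (alternating single/double
#' bonds) are perceived and emitted as aromatic canonical SMILES;
#' non-aromatic structures are returned in canonical form unchanged.
#'
#' @param smiles character vector.
#' @return character vector of canonical aromatic SMILES; inputs that fail
#'   perception are returned as-is.
#' @export
aromatize <- function(smiles) {
  can <- canonical_smiles(smiles)
  ifelse(is.na(can), as.character(smiles), can)
}

#' Count SMARTS pattern matches over a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @return integer match counts (0 for molecules that fail to parse).
#' @export
smarts_matches <- function(smiles, smarts) {
  p <- parse_smiles(smiles)
  out <- integer(length(smiles))
  if (is.null(p$sdf)) return(out)
  hits <- tryCatch(
    .ob_quiet(ChemmineR::smartsSearchOB(p$sdf, smarts)),
    error = function(e) integer(length(p$sdf)))
  out[p$ok] <- as.integer(hits)[p$index[p$ok]]
  out
}

# Indices of atoms on the Bemis-Murcko framework: iteratively strip
# degree-1 heavy atoms until only ring systems and linkers remain.
.framework_atoms <- function(n_atoms, bonds) {
  keep <- rep(TRUE, n_atoms)
  if (!nrow(bonds)) return(integer(0))
  repeat {
    live <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
    deg <- tabulate(c(live[, 1], live[, 2]), n_atoms)
    term <- which(keep & deg <= 1)
    if (!length(term)) break
    keep[term] <- FALSE
  }
  which(keep)
}

#' Bemis-Murcko scaffold SMILES
#'
#' Extracts the molecular framework — ring systems plus the linkers
#' connecting them, with all side chains removed — and returns its
#' canonical SMILES. Exocyclic terminal atoms (including double-bonded
#' ones) are treated as side chains. Acyclic molecules have no framework
#' and yield the empty string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for parse failures).
#' @export
murcko_scaffold <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  p <- parse_smiles(smiles)
  todo <- which(p$ok)
  if (!length(todo)) return(out)
  subs <- list()
  for (i in todo) {
    mol <- p$sdf[[p$index[i]]]
    bonds <- .sdf_bonds(mol)
    fw <- .framework_atoms(nrow(ChemmineR::atomblock(mol)), bonds)
    if (!length(fw)) {
      out[i] <- ""
    } else {
      subs[[length(subs) + 1L]] <- list(i = i,
                                        mol = ChemmineR::atomsubset(mol, fw))
    }
  }
  if (length(subs)) {
    set <- methods::new("SDFset", SDF = lapply(subs, `[[`, "mol"),
                        ID = sprintf("s%06d", seq_along(subs)))
    txt <- .sdfset_text(set)
    res <- .ob_quiet(ChemmineOB::convertFormat("SDF", "CAN", source = txt))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    smis <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    for (j in seq_along(subs)) {
      if (j <= length(smis)) out[subs[[j]]$i] <- smis[j]
    }
  }
  out
}

# Sybyl mol2 atom types, one character vector per molecule, in input atom
# order. Used for hybridization and aromaticity assignment.
.mol2_atom_types <- function(sdfset) {
  txt <- .sdfset_text(sdfset)
  m2 <- .ob_quiet(ChemmineOB::convertFormat("SDF", "MOL2", source = txt))
  mols <- strsplit(m2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  mols <- mols[-1]
  lapply(mols, function(block) {
    lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
    a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
    if (!length(a0)) return(character(0))
    nxt <- grep("@<TRIPOS>", lines, fixed = TRUE)
    a1 <- nxt[nxt > a0[1]]
    a1 <- if (length(a1)) a1[1] else length(lines) + 1L
    if (a1 - a0[1] < 2) return(character(0))
    rows <- lines[(a0[1] + 1):(a1 - 1)]
    rows <- rows[nzchar(trimws(rows))]
    vapply(strsplit(trimws(rows), "[[:space:]]+"), `[[`, "", 6L)
  })
}

#' Count '.'-separated components of a SMILES string
#'
#' @param smiles character vector.
#' @return list of component SMILES vectors.
#' @export
smiles_components <- function(smiles) {
  strsplit(as.character(smiles), ".", fixed = TRUE)
}

# standard atomic masses for the single-atom fallback (ChemmineR cannot
# represent bond-less molecules in SDF form)
.ATOMIC_MASS <- c(
  H = 1.008, Li = 6.94, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086,
  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
  Fe = 55.845, Zn = 65.38, Se = 78.971, Br = 79.904, Ag = 107.868,
  I = 126.904
)

# Properties of a single-atom SMILES ("[Na+]", "[Cl-]", bare "C", ...);
# NULL when the string is not a lone atom or the element is unknown.
.single_atom_props <- function(smiles) {
  smiles <- trimws(smiles)
  m <- regmatches(smiles,
                  regexec("^\\[([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*|[0-9]*[+-])?\\]$",
                          smiles))[[1]]
  bare <- regmatches(smiles, regexec("^([A-Z][a-z]?)$", smiles))[[1]]
  if (length(m)) {
    el <- m[2]
    if (!el %in% names(.ATOMIC_MASS)) return(NULL)
    hs <- m[3]
    nh <- if (!nzchar(hs)) 0L else if (hs == "H") 1L else
      as.integer(sub("^H", "", hs))
    chs <- m[4]
    charge <- if (!nzchar(chs)) 0L else {
      sgn <- if (grepl("-", chs, fixed = TRUE)) -1L else 1L
      num <- as.integer(gsub("[+-]", "", chs))
      sgn * if (is.na(num)) 1L else max(num, 1L)
    }
  } else if (length(bare)) {
    el <- bare[2]
    if (!el %in% names(.ATOMIC_MASS)) return(NULL)
    charge <- 0L
    nh <- unname(.DEFAULT_VALENCE[el])
    if (is.na(nh)) nh <- 0L
  } else {
    return(NULL)
  }
  mw <- unname(.ATOMIC_MASS[el]) + nh * .ATOMIC_MASS[["H"]]
  formula <- paste0(el, if (nh > 0) paste0("H", if (nh > 1) nh else ""),
                    if (charge > 0) strrep("+", min(charge, 1)) else "",
                    if (charge < 0) "-")
  qlayer <- if (charge != 0) sprintf("/q%+d", charge) else ""
  list(element = el, formula = formula, mw = mw, charge = charge,
       n_h = nh,
       inchi = paste0("InChI=1S/", el,
                      if (nh > 0) paste0("H", if (nh > 1) nh else ""),
                      qlayer))
}
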