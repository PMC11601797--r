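# ---------------------------------------------------------------------------
# Structural filters used by the curation pipeline: parser/valence check,
# inorganic-substance rule, mixture resolution, PAINS substructure screen
# and Rule-of-Five druglikeness. All filters are vectorized over SMILES
# and return per-record verdicts with reasons, never silently dropping
# anything themselves — exclusion is the pipeline's job.
# ---------------------------------------------------------------------------

#' Curation configuration
#'
#' @param mixture_mw_tolerance molecular-weight window (Da) below which
#'   mixture components are considered indistinguishable and the record is
#'   discarded (default 5).
#' @param ro5_max_violations Rule-of-Five violations tolerated before a
#'   molecule fails druglikeness; 1 per Lipinski's original formulation,
#'   configurable to 0.
#' @param pains_layers subset of `promiscuity`, `optical_interference`,
#'   `other_interference` to enable (default all).
#' @param unconfirmed_policy what to do with primary-screen actives never
#'   confirmed (or refuted) in a confirmatory screen: `drop` (default;
#'   their activity status is ambiguous) or `inactive`.
#' @param strict when `TRUE`, audit flags become exclusions at the final
#'   review stage instead of being left for human inspection.
#' @return object of class `curation_config`.
#' @export
curation_config <- function(mixture_mw_tolerance = 5,
                            ro5_max_violations = 1,
                            pains_layers = c("promiscuity",
                                             "optical_interference",
                                             "other_interference"),
                            unconfirmed_policy = c("drop", "inactive"),
                            strict = FALSE) {
  stopifnot(mixture_mw_tolerance >= 0, ro5_max_violations %in% c(0L, 1L))
  pains_layers <- match.arg(pains_layers,
                            c("promiscuity", "optical_interference",
                              "other_interference"), several.ok = TRUE)
  structure(list(
    mixture_mw_tolerance = mixture_mw_tolerance,
    ro5_max_violations = as.integer(ro5_max_violations),
    pains_layers = pains_layers,
    unconfirmed_policy = match.arg(unconfirmed_policy),
    strict = isTRUE(strict)
  ), class = "curation_config")
}

#' PAINS substructure catalog
#'
#' A curated catalog of pan-assay interference substructure patterns,
#' organized into three layers: promiscuous reactors, optical/fluorescence
#' interferers, and other interference chemotypes. The patterns cover the
#' canonical PAINS families (quinones, rhodanines, catechols,
#' hydroxyphenyl hydrazones, azo dyes, Mannich phenols, alkylidene
#' barbiturates, ...). It is a documented in-package reimplementation of
#' the family structure, not a copy of any published pattern list.
#'
#' @return data.frame with columns `name`, `layer`, `smarts`.
#' @export
pains_catalog <- function() {
  rbind(
    data.frame(layer = "promiscuity", stringsAsFactors = FALSE, rbind(
      c("quinone_para", "O=C1[#6]=,:[#6]C(=O)[#6]=,:[#6]1"),
      c("quinone_ortho", "O=C1C(=O)[#6]=,:[#6][#6]=,:[#6]1"),
      c("rhodanine", "O=C1[#6]SC(=S)N1"),
      c("ene_rhodanine", "S=C1SC(=[#6])C(=O)N1"),
      c("mannich_phenol", "[OX2H]c1ccccc1[CH2][NX3]"),
      c("hydroxyphenyl_hydrazone", "[OX2H]c1ccccc1[#6]=[NX2][NX3]"),
      c("isothiazolinone", "O=[#6]1[#6]=,:[#6][#16][#7]1"),
      c("epoxide_ketone", "O=C([#6])C1OC1")
    )),
    data.frame(layer = "optical_interference", stringsAsFactors = FALSE, rbind(
      c("azo_aryl", "c[NX2]=[NX2]c"),
      c("acyl_hydrazone", "[#6]C(=O)[NX3][NX2]=[#6]"),
      c("polyene_chain", "C=CC=CC=C"),
      c("nitro_aromatic_azo", "O=[N+]([O-])c1ccc(cc1)[NX2]=[NX2]")
    )),
    data.frame(layer = "other_interference", stringsAsFactors = FALSE, rbind(
      c("catechol", "[OX2H]c1ccccc1[OX2H]"),
      c("hydroquinone", "[OX2H]c1ccc([OX2H])cc1"),
      c("alkylidene_barbiturate", "O=C1NC(=O)C(=[#6])C(=O)N1"),
      c("thiourea_open", "[NX3][CX3](=S)[NX3]"),
      c("cyanoacrylate", "N#C[#6]=[#6X3]"),
      c("beta_aminoketone_aryl", "O=C(c)[CH2][CH2][NX3]")
    ))
  ) -> cat0
  names(cat0) <- c("layer", "name", "smarts")
  cat0[, c("name", "layer", "smarts")]
}

#' Parser filter
#'
#' Fails molecules whose SMILES do not parse or violate a standard valence
#' model. When a deposited InChI is supplied, the connectivity skeleton of
#' the SMILES-derived InChI is compared with it; disagreement earns the
#' `representation-mismatch` flag (an exclusion only in strict mode).
#'
#' @param smiles character vector of SMILES.
#' @param inchi optional character vector of deposited InChI strings.
#' @return data.frame with columns `pass`, `reason`
#'   (`parse-error`/`valence`/`NA`) and `flag`
#'   (`representation-mismatch`/`NA`).
#' @export
filter_parse <- function(smiles, inchi = NULL) {
  n <- length(smiles)
  out <- data.frame(pass = logical(n),
                    reason = rep(NA_character_, n),
                    flag = rep(NA_character_, n), stringsAsFactors = FALSE)
  p <- parse_smiles(smiles)
  out$pass <- p$ok
  for (i in which(!p$ok)) {
    # lone atoms/ions are chemically valid even though the SDF path
    # cannot carry them
    if (!is.null(.single_atom_props(smiles[i]))) out$pass[i] <- TRUE
  }
  out$reason[!out$pass] <- "parse-error"
  for (i in which(p$ok)) {
    msg <- check_valence(p$sdf[[p$index[i]]])
    if (!is.null(msg)) {
      out$pass[i] <- FALSE
      out$reason[i] <- "valence"
    }
  }
  if (!is.null(inchi)) {
    chk <- which(out$pass & !is.na(inchi) & nzchar(inchi))
    if (length(chk)) {
      props <- mol_properties(smiles[chk])
      mism <- .inchi_skeleton(props$inchi) != .inchi_skeleton(inchi[chk])
      out$flag[chk][which(mism)] <- "representation-mismatch"
    }
  }
  out
}

#' Inorganic-substance filter
#'
#' A molecule fails when it contains no carbon atom or contains an element
#' outside the documented organic set
#' \{H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I\}. Carbon-containing
#' species such as CO2 pass under the carbon rule; this is a documented
#' edge of the approximation.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `pass` and `reason`.
#' @export
filter_inorganic <- function(smiles) {
  props <- mol_properties(smiles)
  n <- length(smiles)
  out <- data.frame(pass = logical(n), reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(props$formula[i])) {
      out$reason[i] <- "parse-error"
      next
    }
    cnt <- formula_counts(props$formula[i])
    if (!"C" %in% names(cnt)) {
      out$reason[i] <- "no-carbon"
    } else if (length(setdiff(names(cnt), .ORGANIC_ELEMENTS))) {
      out$reason[i] <- "non-organic-element"
    } else {
      out$pass[i] <- TRUE
    }
  }
  out
}

#' Rule-of-Five druglikeness filter
#'
#' Violations are counted over molecular weight > 500 Da, logP > 5,
#' hydrogen-bond donors > 5 and acceptors (N + O) > 10; a molecule fails
#' when violations exceed `config$ro5_max_violations`.
#'
#' @param smiles character vector of SMILES.
#' @param config a [curation_config()].
#' @return data.frame with columns `pass`, `n_violations`, `violations`
#'   (`;`-separated labels).
#' @export
filter_druglikeness <- function(smiles, config = curation_config()) {
  props <- mol_properties(smiles)
  viol <- cbind(
    `mw>500` = !is.na(props$mw) & props$mw > 500,
    `logp>5` = !is.na(props$logp) & props$logp > 5,
    `hbd>5` = !is.na(props$hbd) & props$hbd > 5,
    `hba>10` = !is.na(props$hba) & props$hba > 10
  )
  nv <- rowSums(viol)
  data.frame(
    pass = nv <= config$ro5_max_violations & !is.na(props$mw),
    n_violations = nv,
    violations = apply(viol, 1, function(v)
      paste(colnames(viol)[v], collapse = ";")),
    stringsAsFactors = FALSE
  )
}

#' PAINS filter
#'
#' Screens molecules against the enabled layers of [pains_catalog()]; a
#' molecule fails when any pattern matches.
#'
#' @param smiles character vector of SMILES.
#' @param config a [curation_config()]; `pains_layers` selects the layers.
#' @return data.frame with columns `pass`, `patterns` (`;`-separated
#'   matched pattern names) and `layers`.
#' @export
filter_pains <- function(smiles, config = curation_config()) {
  cat0 <- pains_catalog()
  cat0 <- cat0[cat0$layer %in% config$pains_layers, , drop = FALSE]
  n <- length(smiles)
  # one pass with the union of all enabled patterns (recursive SMARTS),
  # then per-pattern attribution only for the molecules that hit
  union_smarts <- paste0("[", paste0("$(", cat0$smarts, ")",
                                     collapse = ","), "]")
  any_hit <- smarts_matches(smiles, union_smarts) > 0
  matched <- matrix(FALSE, nrow = n, ncol = nrow(cat0))
  if (any(any_hit)) {
    for (j in seq_len(nrow(cat0))) {
      matched[any_hit, j] <- smarts_matches(smiles[any_hit],
                                            cat0$smarts[j]) > 0
    }
  }
  data.frame(
    pass = rowSums(matched) == 0,
    patterns = apply(matched, 1, function(m)
      paste(cat0$name[m], collapse = ";")),
    layers = apply(matched, 1, function(m)
      paste(unique(cat0$layer[m]), collapse = ";")),
    stringsAsFactors = FALSE
  )
}

#' Resolve a multi-component (mixture) SMILES
#'
#' Applies the mixture rules in order: identical components collapse to
#' one; if any two distinct components differ in molecular weight by at
#' most `mixture_mw_tolerance` the record is discarded as ambiguous;
#' otherwise components are sieved through the inorganic and druglikeness
#' filters — exactly one survivor is kept, zero survivors discard the
#' record, several survivors keep the heaviest with a
#' `mixture-multisurvivor` flag.
#'
#' @param smiles character vector (components separated by `.`).
#' @param config a [curation_config()].
#' @return data.frame with columns `smiles` (resolved structure, `NA` when
#'   dropped), `dropped`, `reason`, `flag`.
#' @export
resolve_mixture <- function(smiles, config = curation_config()) {
  n <- length(smiles)
  out <- data.frame(smiles = as.character(smiles),
                    dropped = rep(FALSE, n),
                    reason = rep(NA_character_, n),
                    flag = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  comps <- smiles_components(smiles)
  multi <- which(lengths(comps) > 1)
  for (i in multi) {
    parts <- unique(canonical_smiles(comps[[i]]))
    parts <- parts[!is.na(parts)]
    if (length(parts) <= 1) {
      out$smiles[i] <- if (length(parts)) parts else NA_character_
      out$dropped[i] <- length(parts) == 0
      if (out$dropped[i]) out$reason[i] <- "parse-error"
      next
    }
    props <- mol_properties(parts)
    mw <- props$mw
    dmat <- abs(outer(mw, mw, "-"))
    if (min(dmat[upper.tri(dmat)]) <= config$mixture_mw_tolerance) {
      out$smiles[i] <- NA_character_
      out$dropped[i] <- TRUE
      out$reason[i] <- "ambiguous-mixture"
      next
    }
    keep <- filter_inorganic(parts)$pass &
      filter_druglikeness(parts, config)$pass
    surv <- parts[keep]
    if (length(surv) == 0) {
      out$smiles[i] <- NA_character_
      out$dropped[i] <- TRUE
      out$reason[i] <- "no-valid-component"
    } else if (length(surv) == 1) {
      out$smiles[i] <- surv
    } else {
      out$smiles[i] <- surv[which.max(mw[keep])]
      out$flag[i] <- "mixture-multisurvivor"
    }
  }
  out
}
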