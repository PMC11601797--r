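# ---------------------------------------------------------------------------
# The curation pipeline: deduplication, hierarchical label assignment and
# the ordered structural filter chain, with a per-record exclusion ledger.
# Stage order is fixed: deduplicate -> hierarchy -> parse -> inorganic ->
# mixture -> neutralize -> aromatize -> pains -> druglikeness ->
# flag_review. Every exclusion is attributed to the first failing stage.
# ---------------------------------------------------------------------------

.PIPELINE_STAGES <- c("deduplicate", "hierarchy", "parse", "inorganic",
                      "mixture", "neutralize", "aromatize", "pains",
                      "druglikeness", "flag_review")

.exclusion_df <- function(compound_id = character(0),
                          stage = character(0), reason = character(0)) {
  n <- length(compound_id)
  data.frame(compound_id = compound_id,
             stage = rep_len(stage, n), reason = rep_len(reason, n),
             stringsAsFactors = FALSE)
}

#' Remove duplicate records
#'
#' Records are triple-checked for duplication on compound id, canonical
#' SMILES and InChI: any two records agreeing on one of the three keys are
#' treated as the same compound. Among duplicates with identical screen
#' outcomes the lexicographically smallest compound id is kept; duplicate
#' groups with conflicting outcomes are excluded entirely.
#'
#' @param records a `compound_records` table.
#' @return list with `records` (the deduplicated table) and `exclusions`
#'   (data.frame `compound_id`, `stage`, `reason`).
#' @export
deduplicate <- function(records) {
  n <- nrow(records)
  if (n == 0) return(list(records = records, exclusions = .exclusion_df()))
  cansmi <- canonical_smiles(records$smiles)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_key <- function(key) {
    ok <- !is.na(key) & nzchar(key)
    for (grp in split(which(ok), key[ok])) {
      if (length(grp) > 1) {
        r <- find(grp[1])
        for (j in grp[-1]) parent[find(j)] <<- r
      }
    }
  }
  union_key(records$compound_id)
  union_key(cansmi)
  union_key(records$inchi)
  comp <- vapply(seq_len(n), find, 0L)
  scr <- record_screens(records)
  keep <- rep(TRUE, n)
  excl <- list()
  for (grp in split(seq_len(n), comp)) {
    if (length(grp) == 1) next
    oc <- as.data.frame(records)[grp, scr, drop = FALSE]
    agreeing <- nrow(unique(oc)) == 1
    if (agreeing) {
      keeper <- grp[order(records$compound_id[grp])[1]]
      drop <- setdiff(grp, keeper)
      keep[drop] <- FALSE
      excl[[length(excl) + 1L]] <- .exclusion_df(
        records$compound_id[drop], "deduplicate", "duplicate")
    } else {
      keep[grp] <- FALSE
      excl[[length(excl) + 1L]] <- .exclusion_df(
        records$compound_id[grp], "deduplicate", "conflicting-duplicate")
    }
  }
  list(records = records[keep, , drop = FALSE],
       exclusions = do.call(rbind, c(excl, list(.exclusion_df()))))
}

#' Assign final activity labels through the screen hierarchy
#'
#' Walks each record's outcomes down the hierarchy: a compound is finally
#' active when it is active in a primary screen, active in a linked
#' confirmatory screen, and not active in any linked counter screen.
#' Primary inactives become final inactives. Primary actives that were
#' refuted or never tested in a confirmatory screen are handled by
#' `config$unconfirmed_policy` (dropped by default). Counter-screen
#' actives are removed from the dataset.
#'
#' @param records a `compound_records` table.
#' @param hierarchy a `screen_hierarchy`.
#' @param config a [curation_config()].
#' @return list with `records` (labelled survivors, `label` column added)
#'   and `exclusions`.
#' @export
assign_hierarchical_labels <- function(records, hierarchy,
                                       config = curation_config()) {
  validate_hierarchy(hierarchy)
  scr <- record_screens(records)
  if (length(bad <- setdiff(scr, screen_ids(hierarchy)))) {
    stop("records carry outcomes for undeclared screen(s): ",
         paste(bad, collapse = ", "))
  }
  primaries <- intersect(.stage_ids(hierarchy, "primary"), scr)
  confs <- intersect(.stage_ids(hierarchy, "confirmatory"), scr)
  counters <- intersect(.stage_ids(hierarchy, "counter"), scr)
  conf_anc <- lapply(confs, function(cid) .ancestors(hierarchy, cid))
  names(conf_anc) <- confs
  ctr_anc <- lapply(counters, function(cid) .ancestors(hierarchy, cid))
  names(ctr_anc) <- counters

  n <- nrow(records)
  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  df <- as.data.frame(records)
  for (i in seq_len(n)) {
    oc <- vapply(scr, function(s) df[[s]][i], "")
    act_prim <- primaries[oc[primaries] == "active"]
    if (!length(act_prim)) {
      if (any(oc[primaries] == "inactive")) {
        label[i] <- "inactive"
      } else {
        reason[i] <- "no-primary-outcome"
      }
      next
    }
    # confirmatory screens downstream of an active primary
    linked_conf <- confs[vapply(confs, function(cid)
      any(act_prim %in% conf_anc[[cid]]), TRUE)]
    confirmed <- linked_conf[oc[linked_conf] == "active"]
    if (!length(confirmed)) {
      if (length(linked_conf) &&
            config$unconfirmed_policy == "inactive") {
        label[i] <- "inactive"
      } else if (!length(linked_conf)) {
        # no confirmatory tier declared: primary call stands
        label[i] <- "active"
      } else {
        reason[i] <- "unconfirmed-primary-active"
      }
      next
    }
    linked_ctr <- counters[vapply(counters, function(cid)
      any(c(act_prim, confirmed) %in% ctr_anc[[cid]]), TRUE)]
    if (any(oc[linked_ctr] == "active")) {
      reason[i] <- "counter-active"
      next
    }
    label[i] <- "active"
  }
  # counter-actives that are otherwise active are removed; fully untested
  # compounds have no defensible label and are removed too
  drop <- is.na(label)
  out <- records[!drop, , drop = FALSE]
  out$label <- label[!drop]
  list(records = out,
       exclusions = .exclusion_df(records$compound_id[drop], "hierarchy",
                                  reason[drop]))
}

#' Run the full curation pipeline
#'
#' Applies, in order: duplicate removal, hierarchical label assignment,
#' the parser/valence filter, the inorganic filter (single-component
#' molecules), mixture resolution, charge neutralization, aromatization,
#' the PAINS filter, the Rule-of-Five druglikeness filter and the final
#' flag review (audit-only unless `config$strict`). Multi-component
#' records bypass the whole-record inorganic stage and are judged
#' per-component at the mixture stage. InChI identifiers are refreshed for
#' records whose structure was rewritten, so the pipeline is idempotent on
#' its own output.
#'
#' @param records a `compound_records` table.
#' @param hierarchy a `screen_hierarchy`.
#' @param config a [curation_config()].
#' @return object of class `curated_dataset`: list with `records`
#'   (labelled, curated table), `report` (a `curation_report`) and
#'   `version`.
#' @export
run_curation_pipeline <- function(records, hierarchy,
                                  config = curation_config()) {
  stage_counts <- data.frame(stage = .PIPELINE_STAGES, n_in = 0L,
                             n_out = 0L, n_excluded = 0L,
                             stringsAsFactors = FALSE)
  all_excl <- list()
  note <- function(stage, n_in, n_out, excl) {
    k <- match(stage, stage_counts$stage)
    stage_counts$n_in[k] <<- n_in
    stage_counts$n_out[k] <<- n_out
    stage_counts$n_excluded[k] <<- n_in - n_out
    if (!is.null(excl) && nrow(excl)) all_excl[[stage]] <<- excl
  }

  # 1. deduplicate
  dd <- deduplicate(records)
  note("deduplicate", nrow(records), nrow(dd$records), dd$exclusions)
  cur <- dd$records

  # 2. hierarchy
  hl <- assign_hierarchical_labels(cur, hierarchy, config)
  note("hierarchy", nrow(cur), nrow(hl$records), hl$exclusions)
  cur <- hl$records

  # 3. parse / valence
  pf <- filter_parse(cur$smiles, cur$inchi)
  flag_idx <- which(!is.na(pf$flag))
  if (length(flag_idx)) cur <- .add_flag(cur, flag_idx, pf$flag[flag_idx[1]])
  excl <- .exclusion_df(cur$compound_id[!pf$pass], "parse",
                        pf$reason[!pf$pass])
  note("parse", nrow(cur), sum(pf$pass), excl)
  cur <- cur[pf$pass, , drop = FALSE]

  # 4. inorganic (single-component records only; mixtures judged later)
  single <- lengths(smiles_components(cur$smiles)) == 1
  inog <- rep(TRUE, nrow(cur))
  reason <- rep(NA_character_, nrow(cur))
  if (any(single)) {
    fi <- filter_inorganic(cur$smiles[single])
    inog[single] <- fi$pass
    reason[single] <- fi$reason
  }
  excl <- .exclusion_df(cur$compound_id[!inog], "inorganic", reason[!inog])
  note("inorganic", nrow(cur), sum(inog), excl)
  cur <- cur[inog, , drop = FALSE]

  # 5. mixtures
  mx <- resolve_mixture(cur$smiles, config)
  changed <- !mx$dropped & mx$smiles != cur$smiles
  cur$smiles[which(changed)] <- mx$smiles[which(changed)]
  fl <- which(!is.na(mx$flag))
  for (i in fl) cur <- .add_flag(cur, i, mx$flag[i])
  excl <- .exclusion_df(cur$compound_id[mx$dropped], "mixture",
                        mx$reason[mx$dropped])
  note("mixture", nrow(cur), sum(!mx$dropped), excl)
  cur <- cur[!mx$dropped, , drop = FALSE]

  # 6. neutralization (transform stage: no exclusions)
  nz <- neutralize_charges(cur$smiles)
  cur$smiles[nz$changed] <- nz$smiles[nz$changed]
  if (any(nz$failed)) cur <- .add_flag(cur, which(nz$failed),
                                       "neutralization-failed")
  note("neutralize", nrow(cur), nrow(cur), NULL)

  # 7. aromatization (canonical aromatic form; transform stage)
  ar <- aromatize(cur$smiles)
  failed_ar <- is.na(canonical_smiles(cur$smiles))
  if (any(failed_ar)) cur <- .add_flag(cur, which(failed_ar),
                                       "aromatization-failed")
  cur$smiles <- ar
  note("aromatize", nrow(cur), nrow(cur), NULL)

  # 8. PAINS
  pn <- filter_pains(cur$smiles, config)
  excl <- .exclusion_df(cur$compound_id[!pn$pass], "pains",
                        paste0("pains:", pn$patterns[!pn$pass]))
  note("pains", nrow(cur), sum(pn$pass), excl)
  cur <- cur[pn$pass, , drop = FALSE]

  # 9. druglikeness
  dl <- filter_druglikeness(cur$smiles, config)
  excl <- .exclusion_df(cur$compound_id[!dl$pass], "druglikeness",
                        paste0("ro5:", dl$violations[!dl$pass]))
  note("druglikeness", nrow(cur), sum(dl$pass), excl)
  cur <- cur[dl$pass, , drop = FALSE]

  # 10. flag review: audit log normally, exclusions in strict mode
  flags <- record_flags(cur)
  flagged <- lengths(flags) > 0
  if (config$strict) {
    excl <- .exclusion_df(cur$compound_id[flagged], "flag_review",
                          paste0("flagged:", vapply(flags[flagged],
                                                    paste, "",
                                                    collapse = ";")))
    note("flag_review", nrow(cur), sum(!flagged), excl)
    cur <- cur[!flagged, , drop = FALSE]
  } else {
    note("flag_review", nrow(cur), nrow(cur), NULL)
  }

  # refresh InChI for rewritten structures so identifiers stay consistent
  if (nrow(cur)) {
    props <- mol_properties(cur$smiles)
    upd <- !is.na(props$inchi) & (is.na(cur$inchi) | cur$inchi != props$inchi)
    cur$inchi[upd] <- props$inchi[upd]
  }

  report <- structure(list(
    stage_counts = stage_counts,
    exclusions = do.call(rbind, c(unname(all_excl), list(.exclusion_df())))
  ), class = "curation_report")
  structure(list(records = cur, report = report,
                 version = as.character(utils::packageVersion("htscurate"))),
            class = "curated_dataset")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  print(x$stage_counts, row.names = FALSE)
  cat("Total excluded:", nrow(x$exclusions), "\n")
  invisible(x)
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated dataset (toolkit version ", x$version, ")\n", sep = "")
  cat("  records: ", nrow(x$records),
      " (", sum(x$records$label == "active"), " active, ",
      sum(x$records$label == "inactive"), " inactive)\n", sep = "")
  cat("  excluded:", nrow(x$report$exclusions), "\n")
  invisible(x)
}

#' @export
summary.curated_dataset <- function(object, ...) {
  print(object)
  print(object$report)
  invisible(object)
}
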