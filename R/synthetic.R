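# ---------------------------------------------------------------------------
# Synthetic HTS campaigns with known ground truth. The generator emulates
# a PubChem-style screening campaign: a mostly clean drug-like library
# with a sub-percent true hit rate, a noisy primary screen, a confirmatory
# screen run on primary actives, a counter screen, and planted curation
# artifacts (duplicate rows, ambiguous mixtures, salt adducts, charged
# species, PAINS chemotypes, Rule-of-Five violators) whose fate in the
# curation pipeline is known by construction.
# ---------------------------------------------------------------------------

.htscurate_env <- new.env(parent = emptyenv())

.ARTIFACT_TAGS <- c("duplicates", "mixtures", "salts", "charged",
                    "pains_like", "ro5_violators")

#' Specify a synthetic screening campaign
#'
#' @param n_compounds library size (rows, planted artifacts included).
#' @param true_hit_rate fraction of truly active compounds (default
#'   0.005, matching the sub-1\% hit rates typical of HTS campaigns).
#' @param primary_fp_rate probability that a truly inactive compound
#'   shows activity in the primary screen (loose thresholds make this
#'   large in practice; default 0.3).
#' @param primary_fn_rate probability that a truly active compound is
#'   missed by the primary screen (default 0.01).
#' @param counter_cross_react_rate probability that a confirmed active
#'   also fires the counter screen (default 0.02).
#' @param confirmatory_error_rate probability that the confirmatory
#'   screen contradicts the truth (default 0: confirmatory assays are
#'   treated as the gold standard).
#' @param artifact_counts named integer vector over `duplicates`,
#'   `mixtures`, `salts`, `charged`, `pains_like`, `ro5_violators`.
#' @param seed integer seed; the whole campaign is a deterministic
#'   function of the spec.
#' @return object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_compounds = 2000L, true_hit_rate = 0.005,
                          primary_fp_rate = 0.3, primary_fn_rate = 0.01,
                          counter_cross_react_rate = 0.02,
                          confirmatory_error_rate = 0,
                          artifact_counts = c(duplicates = 10, mixtures = 10,
                                              salts = 10, charged = 10,
                                              pains_like = 10,
                                              ro5_violators = 10),
                          seed = 1L) {
  rates <- c(true_hit_rate, primary_fp_rate, primary_fn_rate,
             counter_cross_react_rate, confirmatory_error_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  ac <- stats::setNames(rep(0L, length(.ARTIFACT_TAGS)), .ARTIFACT_TAGS)
  ac[names(artifact_counts)] <- as.integer(artifact_counts)
  if (sum(ac) > n_compounds) {
    stop("artifact counts (", sum(ac), ") exceed n_compounds (",
         n_compounds, ")")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 true_hit_rate = true_hit_rate,
                 primary_fp_rate = primary_fp_rate,
                 primary_fn_rate = primary_fn_rate,
                 counter_cross_react_rate = counter_cross_react_rate,
                 confirmatory_error_rate = confirmatory_error_rate,
                 artifact_counts = ac, seed = as.integer(seed)),
            class = "campaign_spec")
}

#' The three-screen hierarchy used by synthetic campaigns
#' @return a `screen_hierarchy` with one primary, one confirmatory and
#'   one counter screen.
#' @export
synthetic_hierarchy <- function() {
  screen_hierarchy(list(
    aid_primary = list(stage = "primary", parents = character(0),
                       description = "primary single-point screen"),
    aid_confirmatory = list(stage = "confirmatory",
                            parents = "aid_primary",
                            description = "dose-response confirmation"),
    aid_counter = list(stage = "counter", parents = "aid_confirmatory",
                       description = "off-target counter screen")
  ))
}

# Deterministic drug-like fragment vocabulary. Substituted (hetero)arene
# and saturated-ring scaffolds with two variable substituents give a few
# thousand distinct, filter-clean molecules.
.fragment_vocabulary <- function() {
  prefixes <- c("C", "CC", "CCC", "CCCC", "CC(C)", "COC", "CCO", "CN(C)",
                "CC(=O)N", "CC(=O)", "FC(F)(F)", "CCS", "Cl", "F",
                "C[C@@H](C)", "N#C")
  infixes <- c("C", "CC", "CCC", "OC", "OCC", "N", "NC", "F", "Cl", "Br",
               "C#N", "C(=O)OC", "C(=O)N", "SC", "C(C)C", "CO")
  templates <- c("c1ccc(%s)cc1", "c1cccc(%s)c1", "c1ccc2cc(%s)ccc2c1",
                 "c1cnc(%s)cn1", "c1ccc(%s)nc1", "C1CCN(%s)CC1",
                 "c1csc(%s)n1", "C1CCC(%s)CC1", "c1oc(%s)cc1",
                 "c1ccc(%s)cc1F")
  out <- character(0)
  for (tp in templates) {
    core <- sprintf(tp, rep(infixes, each = 1))
    out <- c(out, as.vector(outer(prefixes, core, paste0)))
  }
  unique(out)
}

# The sieved base pool: canonical, single-component, neutral, organic,
# PAINS-free, zero Rule-of-Five violations. Expensive, so memoized for
# the session (the pool is a deterministic constant).
.base_pool <- function() {
  if (!is.null(.htscurate_env$base_pool)) return(.htscurate_env$base_pool)
  raw <- .fragment_vocabulary()
  can <- unique(canonical_smiles(raw))
  can <- can[!is.na(can) & !grepl("[.+-]", can)]
  props <- mol_properties(can)
  ok_org <- vapply(props$formula, function(f) {
    cnt <- formula_counts(f)
    "C" %in% names(cnt) && !length(setdiff(names(cnt), .ORGANIC_ELEMENTS))
  }, TRUE)
  ok_ro5 <- !is.na(props$mw) & props$mw <= 500 & props$logp <= 5 &
    props$hbd <= 5 & props$hba <= 10
  keep <- !is.na(props$mw) & ok_org & ok_ro5 &
    filter_pains(can, curation_config())$pass
  ord <- order(can)
  pool <- data.frame(smiles = can, mw = props$mw, inchi = props$inchi,
                     stringsAsFactors = FALSE)[ord, , drop = FALSE]
  pool <- pool[keep[ord], , drop = FALSE]
  rownames(pool) <- NULL
  .htscurate_env$base_pool <- pool
  .htscurate_env$base_pool
}

# charged species whose neutralized forms are clean and outside the base
# pool (distinct head groups guarantee that)
.charged_variants <- function(k) {
  heads <- c("[NH3+]CCc1ccc(%s)cc1", "[O-]C(=O)Cc1ccc(%s)cc1",
             "C[NH2+]Cc1ccc(%s)cc1", "[O-]C(=O)c1ccc(%s)nc1")
  subs <- c("C", "CC", "CCC", "F", "Cl", "OC", "C(C)C", "COC", "CCO",
            "C#N", "CO", "SC")
  grid <- as.vector(outer(heads, subs, function(h, s) sprintf(h, s)))
  grid[seq_len(k)]
}

.pains_variants <- function(k) {
  fams <- c("O=C1C=CC(=O)C(%s)=C1", "Oc1ccc(%s)cc1O",
            "O=C1CSC(=S)N1%s", "c1ccc(N=Nc2ccc(%s)cc2)cc1")
  subs <- c("C", "CC", "CCC", "CCCC", "C(C)C", "COC", "F", "Cl",
            "CCO", "CCCCC", "CCOC", "CC(C)C")
  grid <- as.vector(outer(fams, subs, function(f, s) sprintf(f, s)))
  grid[seq_len(k)]
}

.ro5_variants <- function(k) {
  vapply(seq_len(k), function(i) strrep("C", 36 + i), "")
}

.salt_ion_pairs <- c("[Na+].[Cl-]", "[K+].[Br-]", "[Na+].[I-]")

#' Generate a synthetic compound library with planted artifacts
#'
#' Assembles `n_compounds` records: clean drug-like molecules from a
#' deterministic fragment vocabulary, plus the requested numbers of
#' planted artifacts (exact counts, each record carrying at most one
#' artifact tag). True actives are drawn among the clean records at the
#' specified hit rate; planted artifacts are never true actives. All
#' screen outcomes are left `untested` until [simulate_screens()].
#'
#' @param spec a [campaign_spec()].
#' @return object of class `synthetic_campaign`: list with `records`,
#'   `hierarchy`, `truth` (data.frame `compound_id`, `true_active`,
#'   `artifact`) and `spec`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  ac <- spec$artifact_counts
  n_clean <- spec$n_compounds - sum(ac)
  pool <- .base_pool()
  # reserve pool molecules: clean set, then salts' organic parents, then
  # ambiguous mixture pairs (disjoint so no canonical structure repeats)
  need_pool <- n_clean + ac[["salts"]]
  if (need_pool > nrow(pool)) {
    stop("library size exceeds fragment pool capacity (",
         nrow(pool), " clean molecules)")
  }
  rng <- .seeded_rng(spec$seed)
  pick <- rng$sample(nrow(pool), need_pool)
  clean_idx <- pick[seq_len(n_clean)]
  salt_idx <- pick[n_clean + seq_len(ac[["salts"]])]

  smiles <- pool$smiles[clean_idx]
  inchi <- pool$inchi[clean_idx]
  artifact <- rep(NA_character_, n_clean)

  add <- function(smi, inc, tag, k) {
    if (k > 0) {
      smiles <<- c(smiles, smi)
      inchi <<- c(inchi, inc)
      artifact <<- c(artifact, rep(tag, k))
    }
  }

  # duplicate rows: exact copies of clean records under a fresh id
  kd <- ac[["duplicates"]]
  if (kd > n_clean) stop("more duplicates requested than clean records")
  dup_src <- seq_len(kd)
  add(smiles[dup_src], inchi[dup_src], "duplicate", kd)

  # ambiguous mixtures: two distinct pool molecules within 5 Da
  km <- ac[["mixtures"]]
  if (km > 0) {
    rest <- pool[-pick, , drop = FALSE]
    rest <- rest[order(rest$mw), , drop = FALSE]
    gaps <- which(diff(rest$mw) <= 5)
    pairs <- integer(0)  # greedy disjoint adjacent pairs
    last <- -1L
    for (g in gaps) {
      if (g > last + 1L) {
        pairs <- c(pairs, g)
        last <- g
      }
    }
    if (length(pairs) < km) stop("not enough close-mass pairs for mixtures")
    mix_smi <- paste(rest$smiles[pairs[seq_len(km)]],
                     rest$smiles[pairs[seq_len(km)] + 1], sep = ".")
    add(mix_smi, mol_properties(mix_smi)$inchi, "mixture", km)
  }

  # salt adducts: clean organic + inorganic counter-ion pair
  ks <- ac[["salts"]]
  if (ks > 0) {
    # pick an ion pair whose masses keep all pairwise MW gaps above the
    # ambiguity window, so the organic parent always survives
    ion_mw <- list(c(22.990, 35.45), c(39.098, 79.904), c(22.990, 126.904))
    ions <- vapply(seq_len(ks), function(j) {
      base_mw <- pool$mw[salt_idx[j]]
      for (p in seq_along(.salt_ion_pairs)[c(
        ((j - 1) %% length(.salt_ion_pairs)) + 1,
        seq_along(.salt_ion_pairs))]) {
        if (all(abs(base_mw - ion_mw[[p]]) > 6)) {
          return(.salt_ion_pairs[p])
        }
      }
      .salt_ion_pairs[1]
    }, "")
    salt_smi <- paste(pool$smiles[salt_idx], ions, sep = ".")
    add(salt_smi, mol_properties(salt_smi)$inchi, "salt", ks)
  }

  # charged species, PAINS chemotypes, Rule-of-Five violators
  kc <- ac[["charged"]]
  if (kc > 0) {
    ch <- .charged_variants(kc)
    add(ch, mol_properties(ch)$inchi, "charged", kc)
  }
  kp <- ac[["pains_like"]]
  if (kp > 0) {
    pn <- .pains_variants(kp)
    add(pn, mol_properties(pn)$inchi, "pains", kp)
  }
  kr <- ac[["ro5_violators"]]
  if (kr > 0) {
    r5 <- .ro5_variants(kr)
    add(r5, mol_properties(r5)$inchi, "ro5", kr)
  }

  n <- length(smiles)
  ids <- sprintf("SYN%06d", seq_len(n))
  hierarchy <- synthetic_hierarchy()
  outcomes <- stats::setNames(
    rep(list(rep("untested", n)), length(screen_ids(hierarchy))),
    screen_ids(hierarchy))
  records <- compound_records(ids, smiles, inchi, outcomes,
                              hierarchy = hierarchy)

  true_active <- rep(FALSE, n)
  clean_rows <- which(is.na(artifact))
  true_active[clean_rows] <- rng$runif(length(clean_rows)) < spec$true_hit_rate
  # a duplicate row must mirror its source record's truth so outcomes agree
  truth <- data.frame(compound_id = ids, true_active = true_active,
                      artifact = artifact, dup_of = NA_character_,
                      stringsAsFactors = FALSE)
  if (kd > 0) {
    dup_rows <- which(artifact == "duplicate")
    truth$dup_of[dup_rows] <- ids[dup_src]
    truth$true_active[dup_rows] <- true_active[dup_src]
  }
  structure(list(records = records, hierarchy = hierarchy, truth = truth,
                 spec = spec), class = "synthetic_campaign")
}

#' Simulate the three screening stages of a campaign
#'
#' The primary screen reports truth corrupted by the false-positive /
#' false-negative rates; the confirmatory screen is run only on primary
#' actives and reports truth flipped with `confirmatory_error_rate`; the
#' counter screen is run on confirmed actives and fires with
#' `counter_cross_react_rate`. Duplicate rows receive their source
#' record's outcomes, so planted duplicates always agree.
#'
#' @param campaign a `synthetic_campaign` from [generate_library()].
#' @return the campaign with outcome columns filled in.
#' @export
simulate_screens <- function(campaign) {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  spec <- campaign$spec
  rng <- .seeded_rng(spec$seed + 104729L)  # independent stream
  rec <- campaign$records
  truth <- campaign$truth
  n <- nrow(rec)
  ta <- truth$true_active
  u1 <- rng$runif(n)
  primary <- ifelse(ta, ifelse(u1 < spec$primary_fn_rate, "inactive",
                               "active"),
                    ifelse(u1 < spec$primary_fp_rate, "active",
                           "inactive"))
  u2 <- rng$runif(n)
  conf <- rep("untested", n)
  tested_conf <- primary == "active"
  conf[tested_conf] <- ifelse(
    xor(ta[tested_conf], u2[tested_conf] < spec$confirmatory_error_rate),
    "active", "inactive")
  u3 <- rng$runif(n)
  ctr <- rep("untested", n)
  tested_ctr <- conf == "active"
  ctr[tested_ctr] <- ifelse(u3[tested_ctr] < spec$counter_cross_react_rate,
                            "active", "inactive")
  # duplicates mirror their source record exactly
  dup <- which(!is.na(truth$dup_of))
  if (length(dup)) {
    src <- match(truth$dup_of[dup], truth$compound_id)
    primary[dup] <- primary[src]
    conf[dup] <- conf[src]
    ctr[dup] <- ctr[src]
  }
  rec$aid_primary <- primary
  rec$aid_confirmatory <- conf
  rec$aid_counter <- ctr
  campaign$records <- rec
  campaign
}

#' Expected per-stage exclusion counts for a simulated campaign
#'
#' An independent oracle for the curation pipeline: using only the
#' planted-artifact tags and the simulated outcomes (never the structural
#' filters), predicts how many records each pipeline stage excludes.
#' Exact for the deterministic structural filters under the default
#' mixture tolerance; the hierarchy stage is predicted from the outcome
#' logic and the configured unconfirmed policy.
#'
#' @param campaign a simulated `synthetic_campaign`.
#' @param config a [curation_config()].
#' @return named numeric vector over the pipeline stages.
#' @export
expected_curation_counts <- function(campaign, config = curation_config()) {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  rec <- as.data.frame(campaign$records)
  if (all(rec$aid_primary == "untested")) {
    stop("campaign has no simulated outcomes; run simulate_screens() first")
  }
  truth <- campaign$truth
  counts <- stats::setNames(numeric(length(.PIPELINE_STAGES)),
                            .PIPELINE_STAGES)
  for (i in seq_len(nrow(rec))) {
    tag <- truth$artifact[i]
    if (!is.na(tag) && tag == "duplicate") {
      counts[["deduplicate"]] <- counts[["deduplicate"]] + 1
      next
    }
    prim <- rec$aid_primary[i]
    conf <- rec$aid_confirmatory[i]
    ctr <- rec$aid_counter[i]
    if (prim != "active") {
      if (prim != "inactive") {
        counts[["hierarchy"]] <- counts[["hierarchy"]] + 1
        next
      }
      # survives as inactive
    } else if (conf != "active") {
      if (config$unconfirmed_policy == "drop") {
        counts[["hierarchy"]] <- counts[["hierarchy"]] + 1
        next
      }
      # survives as inactive
    } else if (ctr == "active") {
      counts[["hierarchy"]] <- counts[["hierarchy"]] + 1
      next
    }
    if (is.na(tag) || tag %in% c("salt", "charged")) next
    stage <- switch(tag, mixture = "mixture", pains = "pains",
                    ro5 = "druglikeness", NA_character_)
    if (!is.na(stage)) counts[[stage]] <- counts[[stage]] + 1
  }
  counts
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat("Synthetic campaign:", nrow(x$records), "compounds,",
      sum(x$truth$true_active), "true actives\n")
  planted <- table(x$truth$artifact)
  if (length(planted)) {
    cat("  planted artifacts:",
        paste(names(planted), planted, sep = "=", collapse = ", "), "\n")
  }
  simulated <- !all(x$records$aid_primary == "untested")
  cat("  outcomes:", if (simulated) "simulated" else "unset", "\n")
  invisible(x)
}
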