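# ---------------------------------------------------------------------------
# Screen hierarchies: the DAG of assays making up an HTS campaign.
# Primary screens sit at the roots; confirmatory screens validate primary
# actives; counter screens knock out off-target actives.
# ---------------------------------------------------------------------------

#' Construct a screen hierarchy
#'
#' A screen hierarchy is a directed acyclic graph of assays. Each node has
#' a stage (`primary`, `confirmatory` or `counter`) and parent links
#' pointing toward the screen(s) whose actives feed it.
#'
#' @param nodes named list; each element is a list with fields `stage`,
#'   `parents` (character vector, possibly empty) and optional
#'   `description`.
#' @return object of class `screen_hierarchy`.
#' @examples
#' h <- screen_hierarchy(list(
#'   "626"  = list(stage = "primary", parents = character(0)),
#'   "1488" = list(stage = "confirmatory", parents = "626"),
#'   "1741" = list(stage = "counter", parents = "1488")
#' ))
#' @export
screen_hierarchy <- function(nodes) {
  stopifnot(is.list(nodes), length(names(nodes)) == length(nodes))
  nodes <- lapply(nodes, function(nd) {
    list(stage = match.arg(nd$stage, c("primary", "confirmatory", "counter")),
         parents = as.character(nd$parents %||% character(0)),
         description = nd$description %||% "")
  })
  h <- structure(list(nodes = nodes), class = "screen_hierarchy")
  validate_hierarchy(h)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a screen hierarchy
#'
#' Checks acyclicity, that every confirmatory/counter screen has at least
#' one parent, that at least one parentless primary screen exists, and
#' that all parent links resolve.
#'
#' @param h a `screen_hierarchy`.
#' @return `h`, invisibly; errors on violation.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "screen_hierarchy"))
  ids <- names(h$nodes)
  stages <- vapply(h$nodes, `[[`, "", "stage")
  for (id in ids) {
    par <- h$nodes[[id]]$parents
    if (length(bad <- setdiff(par, ids))) {
      stop("screen '", id, "' references unknown parent(s): ",
           paste(bad, collapse = ", "))
    }
    if (h$nodes[[id]]$stage != "primary" && !length(par)) {
      stop("screen '", id, "' is ", h$nodes[[id]]$stage,
           " but has no parent")
    }
  }
  roots <- ids[stages == "primary" &
                 !vapply(h$nodes, function(nd) length(nd$parents) > 0, TRUE)]
  if (!length(roots)) stop("hierarchy has no parentless primary screen")
  # Kahn topological sort for acyclicity
  indeg <- vapply(h$nodes, function(nd) length(nd$parents), 0L)
  seen <- character(0)
  queue <- ids[indeg == 0]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- c(seen, v)
    for (w in ids) {
      if (v %in% h$nodes[[w]]$parents) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) queue <- c(queue, w)
      }
    }
  }
  if (length(seen) != length(ids)) stop("hierarchy contains a cycle")
  invisible(h)
}

#' Screen ids of a hierarchy
#' @param h a `screen_hierarchy`.
#' @return character vector of screen identifiers.
#' @export
screen_ids <- function(h) names(h$nodes)

.stage_ids <- function(h, stage) {
  names(h$nodes)[vapply(h$nodes, `[[`, "", "stage") == stage]
}

# transitive ancestor set (parent links) of a node
.ancestors <- function(h, id) {
  out <- character(0)
  frontier <- h$nodes[[id]]$parents
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(
      lapply(frontier, function(p) h$nodes[[p]]$parents))), out)
  }
  out
}

#' Read a screen hierarchy from YAML or JSON
#'
#' The file maps screen ids to `stage`, `parents` and optional
#' `description`, either at top level or under a `screens:` key.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `screen_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$screens)) raw <- raw$screens
  screen_hierarchy(lapply(raw, function(nd) {
    list(stage = nd$stage, parents = unlist(nd$parents), description = nd$description)
  }))
}

#' Write a screen hierarchy to YAML
#' @param h a `screen_hierarchy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  yaml::write_yaml(list(screens = lapply(h$nodes, function(nd) {
    list(stage = nd$stage, parents = as.list(nd$parents),
         description = nd$description)
  })), path)
  invisible(path)
}

#' @export
print.screen_hierarchy <- function(x, ...) {
  cat("Screen hierarchy with", length(x$nodes), "screens\n")
  for (id in names(x$nodes)) {
    nd <- x$nodes[[id]]
    cat(sprintf("  %s [%s]%s\n", id, nd$stage,
                if (length(nd$parents))
                  paste0(" <- ", paste(nd$parents, collapse = ", "))
                else ""))
  }
  invisible(x)
}
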